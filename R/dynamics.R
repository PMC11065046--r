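#' Ornstein-Uhlenbeck spring parameters for one dye
#'
#' Overdamped harmonic tether: `dX = -K (X - X_eq) dt + sigma dB` with a
#' diagonal spring-rate matrix `K` (entries in 1/ns).  The stationary law is
#' Gaussian with per-axis variance `sigma^2 / (2 k_i)`.  An anisotropy
#' factor `p` in (0, 1] softens two axes to `p * k`; the remaining axis
#' (the `stiff_axis`) keeps the full rate.
#'
#' @param k spring relaxation rate(s), 1/ns: a scalar (isotropic) or a
#'   length-3 diagonal.
#' @param sigma volatility of the thermal noise, Angstrom / sqrt(ns).
#' @param x_eq equilibrium (attachment) point, 3-vector, Angstrom.
#' @param p anisotropy factor in (0, 1]; used only when `k` is scalar.
#' @param stiff_axis index 1..3 of the axis keeping the full rate when
#'   `p < 1`.
#' @return An object of class `spring_params` with fields `k` (length-3
#'   diagonal), `sigma`, `x_eq`, `p`.
#' @examples
#' sp <- spring_params(k = 0.004, sigma = 0.4)
#' diag(spring_matrix(sp))
#' @export
spring_params <- function(k, sigma, x_eq = c(0, 0, 0), p = 1,
                          stiff_axis = 1L) {
  if (length(k) == 1L) {
    .check_number(k, "k"); .check_number(p, "p")
    if (p > 1) .stop_invalid("'p' must be in (0, 1]")
    kv <- rep(p * k, 3); kv[stiff_axis] <- k
  } else {
    .check_number(k, "k", len = 3L)
    kv <- k
    p <- min(kv) / max(kv)
  }
  .check_number(sigma, "sigma")
  .check_number(x_eq, "x_eq", positive = FALSE, len = 3L)
  structure(list(k = kv, sigma = sigma, x_eq = x_eq, p = p),
            class = "spring_params")
}

#' Diagonal spring-rate matrix of a [spring_params()]
#' @param params a [spring_params()].
#' @export
spring_matrix <- function(params) {
  stopifnot(inherits(params, "spring_params"))
  diag(params$k, 3)
}

#' Elastic-pendulum parameters for one dye
#'
#' Spherical-coordinate Langevin system for a dye on a flexible tether free
#' to swing: radial spring toward `r_eq` with a short-range `c_r / r`
#' repulsive drift, nonlinear pendulum restoring force in the polar angle,
#' free diffusion in azimuth:
#' \deqn{dr = [-k_r (r - r_{eq}) + c_r / r] dt + \sigma_r \circ dB}
#' \deqn{d\theta = [-k_\theta \sin\theta + \sigma_\theta^2 /
#'   (2 r^2 \tan\theta)] dt + (\sigma_\theta / r) \circ dB}
#' \deqn{d\phi = (\sigma_\phi / (r \sin\theta)) \circ dB}
#'
#' @param k_r radial spring rate, 1/ns.
#' @param k_theta polar restoring rate, 1/ns.
#' @param r_eq radial spring equilibrium, Angstrom.
#' @param sigma_r radial volatility, Angstrom / sqrt(ns).
#' @param sigma_theta,sigma_phi angular volatilities, Angstrom / sqrt(ns)
#'   (they enter divided by r).
#' @param c_r dimensionless-in-spirit coefficient of the `1/r` drift term
#'   (units A^2/ns); default 1 is the literal reading, `sigma_r^2` is the
#'   noise-induced-drift alternative.
#' @return An object of class `pendulum_params`.
#' @export
pendulum_params <- function(k_r, k_theta, r_eq, sigma_r, sigma_theta,
                            sigma_phi = sigma_theta, c_r = 1) {
  for (nm in c("k_r", "k_theta", "r_eq", "sigma_r", "sigma_theta",
               "sigma_phi", "c_r"))
    .check_number(get(nm), nm)
  structure(list(k_r = k_r, k_theta = k_theta, r_eq = r_eq,
                 sigma_r = sigma_r, sigma_theta = sigma_theta,
                 sigma_phi = sigma_phi, c_r = c_r),
            class = "pendulum_params")
}

#' Deterministic radial fixed point of the pendulum
#'
#' Positive root of `k_r r^2 - k_r r_eq r - c_r = 0`, the zero-noise rest
#' radius where the spring and the `c_r / r` drift balance.
#'
#' @param params a [pendulum_params()].
#' @export
pendulum_rest_radius <- function(params) {
  stopifnot(inherits(params, "pendulum_params"))
  (params$r_eq + sqrt(params$r_eq^2 + 4 * params$c_r / params$k_r)) / 2
}

#' Rotational diffusion parameters of a dye dipole
#'
#' Either give the rotational diffusion coefficient `D` directly (rad^2/ns)
#' or the physical inputs, from which the overdamped spherical-rotor value
#' `D = kT / (8 pi nu R_h^3)` is derived.
#'
#' @param D rotational diffusion coefficient, rad^2/ns; `NULL` to derive.
#' @param kT thermal energy.
#' @param viscosity dynamic viscosity `nu`.
#' @param R_h hydrodynamic radius of the dye.
#' @param D_acceptor optional distinct acceptor coefficient; defaults to `D`.
#' @return An object of class `rotation_params` with fields `D_donor`,
#'   `D_acceptor` plus any physical inputs supplied.
#' @export
rotation_params <- function(D = NULL, kT = NULL, viscosity = NULL,
                            R_h = NULL, D_acceptor = NULL) {
  if (is.null(D)) {
    for (nm in c("kT", "viscosity", "R_h"))
      if (is.null(get(nm))) .stop_invalid("give 'D' or all of kT, viscosity, R_h")
    D <- rotational_diffusion_coefficient(kT, viscosity, R_h)
  }
  .check_number(D, "D")
  if (is.null(D_acceptor)) D_acceptor <- D else .check_number(D_acceptor, "D_acceptor")
  structure(list(D = D, D_donor = D, D_acceptor = D_acceptor, kT = kT,
                 viscosity = viscosity, R_h = R_h),
            class = "rotation_params")
}

#' Rotational diffusion coefficient of a spherical rotor
#'
#' `D = kT / (8 pi nu R_h^3)`.
#'
#' @param kT thermal energy.
#' @param viscosity dynamic viscosity.
#' @param R_h hydrodynamic radius.
#' @export
rotational_diffusion_coefficient <- function(kT, viscosity, R_h) {
  .check_number(kT, "kT"); .check_number(viscosity, "viscosity")
  .check_number(R_h, "R_h")
  kT / (8 * pi * viscosity * R_h^3)
}

#' Integrator time-scale configuration
#'
#' Declares the translational and orientational step sizes with the
#' time-scale ordering T_D >> T_O enforced (`dt_orient < dt_trans`).
#'
#' @param dt_trans translational step, ns.
#' @param dt_orient orientational step, ns.
#' @export
timescale_config <- function(dt_trans = 0.1, dt_orient = 0.001) {
  .check_number(dt_trans, "dt_trans"); .check_number(dt_orient, "dt_orient")
  if (dt_orient >= dt_trans)
    .stop_invalid("time-scale ordering violated: need dt_orient < dt_trans")
  structure(list(dt_trans = dt_trans, dt_orient = dt_orient),
            class = "timescale_config")
}

#' Exact Ornstein-Uhlenbeck propagation
#'
#' Advances a diagonal OU spring state by `dt` using the exact Gaussian
#' transition kernel: per axis, mean
#' `x_eq + (x - x_eq) exp(-k dt)` and variance
#' `sigma^2 (1 - exp(-2 k dt)) / (2 k)`.  The constant-noise OU equation has
#' identical Stratonovich and Ito readings, so the exact kernel represents
#' the model without discretisation error.
#'
#' @param x current position, 3-vector (or n x 3 matrix of states,
#'   propagated independently), Angstrom.
#' @param params a [spring_params()].
#' @param dt time step, ns.
#' @export
ou_propagate <- function(x, params, dt) {
  stopifnot(inherits(params, "spring_params"))
  .check_number(dt, "dt")
  x <- if (is.matrix(x)) x else matrix(x, 1L)
  if (ncol(x) != 3L) .stop_invalid("'x' must have 3 columns")
  e <- exp(-params$k * dt)
  sdv <- params$sigma * sqrt((1 - e^2) / (2 * params$k))
  out <- x
  for (i in 1:3)
    out[, i] <- params$x_eq[i] + (x[, i] - params$x_eq[i]) * e[i] +
      rnorm(nrow(x), 0, sdv[i])
  if (nrow(out) == 1L) drop(out) else out
}

#' Draw from the stationary law of an OU spring
#'
#' Per-axis Gaussian with mean `x_eq` and variance `sigma^2 / (2 k_i)`.
#'
#' @param params a [spring_params()].
#' @param n number of draws.
#' @return An n x 3 matrix (or 3-vector for `n = 1`).
#' @export
spring_equilibrium_sample <- function(params, n = 1L) {
  stopifnot(inherits(params, "spring_params"))
  sdv <- params$sigma / sqrt(2 * params$k)
  out <- cbind(rnorm(n, params$x_eq[1], sdv[1]),
               rnorm(n, params$x_eq[2], sdv[2]),
               rnorm(n, params$x_eq[3], sdv[3]))
  if (n == 1L) drop(out) else out
}

#' One (or more) Stratonovich-Heun steps of the elastic pendulum
#'
#' Integrates the pendulum Langevin system with the Heun
#' predictor-corrector (the Stratonovich-consistent scheme for the
#' state-dependent angular noise).  Steps that would drive `r <= 0` are
#' retried with halved step size; the number of such refinements is
#' reported.
#'
#' @param state numeric (r, theta, phi): radius Angstrom, angles rad.
#' @param params a [pendulum_params()].
#' @param dt step size, ns.
#' @param n_steps number of steps.
#' @return For `n_steps = 1` the new state vector (with attribute
#'   `n_retries`); otherwise a `(n_steps+1) x 3` path matrix.
#' @export
pendulum_step <- function(state, params, dt, n_steps = 1L) {
  stopifnot(inherits(params, "pendulum_params"))
  .check_number(dt, "dt")
  if (length(state) != 3L || state[1] <= 0)
    .stop_invalid("'state' must be (r > 0, theta, phi)")
  res <- cpp_pendulum_path(as.numeric(state), params$k_r, params$k_theta,
                           params$r_eq, params$c_r, params$sigma_r,
                           params$sigma_theta, params$sigma_phi, dt,
                           as.integer(n_steps))
  if (res$n_retries > 0)
    message(sprintf("pendulum_step: %d step(s) retried with halved dt (r <= 0)",
                    res$n_retries))
  if (n_steps == 1L)
    structure(res$path[2L, ], names = c("r", "theta", "phi"),
              n_retries = res$n_retries)
  else
    structure(res$path, dimnames = list(NULL, c("r", "theta", "phi")),
              n_retries = res$n_retries)
}

#' One (or more) spherical-Brownian-motion steps of a dipole
#'
#' Diffusion on the unit sphere with coefficient `D`: polar-angle drift
#' `(sigma^2/2) cot(theta)` with additive noise and azimuthal noise
#' `sigma / sin(theta)` (`sigma^2 = 2 D`), integrated by a
#' Stratonovich-Heun step in angle coordinates; inside a pole tolerance the
#' step is taken in the local tangent plane and projected back, which
#' removes the coordinate singularity.  The stationary law is uniform on
#' the sphere.
#'
#' @param orientation a unit 3-vector, or numeric (theta, phi) in radians.
#' @param D rotational diffusion coefficient, rad^2/ns (or a
#'   [rotation_params()], whose donor coefficient is used).
#' @param dt step size, ns.
#' @param n_steps number of steps.
#' @return For `n_steps = 1` a unit 3-vector; otherwise a
#'   `(n_steps+1) x 3` matrix of unit vectors.
#' @export
sphere_step <- function(orientation, D, dt, n_steps = 1L) {
  if (inherits(D, "rotation_params")) D <- D$D_donor
  .check_number(D, "D", positive = FALSE)
  if (D < 0) .stop_invalid("'D' must be nonnegative")
  .check_number(dt, "dt")
  if (length(orientation) == 3L) {
    .check_unit(orientation / sqrt(sum(orientation^2)), "orientation")
    th <- acos(min(1, max(-1, orientation[3] / sqrt(sum(orientation^2)))))
    ph <- atan2(orientation[2], orientation[1])
  } else if (length(orientation) == 2L) {
    th <- orientation[1]; ph <- orientation[2]
  } else .stop_invalid("'orientation' must be a 3-vector or (theta, phi)")
  ang <- cpp_sphere_path(th, ph, D, dt, as.integer(n_steps))
  vec <- cbind(sin(ang[, 1]) * cos(ang[, 2]),
               sin(ang[, 1]) * sin(ang[, 2]), cos(ang[, 1]))
  if (n_steps == 1L) vec[2L, ] else vec
}

#' Synchronized donor/acceptor dye-pair trajectories
#'
#' Propagates both dyes' translational states (isotropic spring,
#' anisotropic spring, or elastic pendulum) on the translational grid and
#' both dipole orientations (spherical Brownian motion) on the finer
#' orientational grid.  The translational and orientational processes are
#' independent by construction (separate draws); donor and acceptor are
#' likewise independent.
#'
#' @param model `"isotropic"`, `"anisotropic"` or `"pendulum"`.
#' @param duration total simulated time, ns.
#' @param timescales a [timescale_config()].
#' @param donor,acceptor per-dye translational parameter objects
#'   ([spring_params()] or [pendulum_params()]); defaults come from
#'   [fret_config()].
#' @param rotation a [rotation_params()] for the dipoles.
#' @param attachment_donor,attachment_acceptor attachment points, Angstrom.
#' @param pole_donor,pole_acceptor pendulum pole (rest) directions.
#' @param orientational_stride keep every k-th orientational sample to bound
#'   memory; the dynamics are still integrated at `dt_orient`.
#' @return A list of class `dye_pair_trajectory` with elements
#'   `time_trans`, `donor`, `acceptor` (n x 3 position matrices),
#'   `time_orient`, `mu_donor`, `mu_acceptor` (unit-vector matrices) and
#'   `distance`.
#' @export
simulate_dye_pair <- function(model = c("isotropic", "anisotropic", "pendulum"),
                              duration, timescales = timescale_config(),
                              donor = NULL, acceptor = NULL,
                              rotation = rotation_params(D = 0.026),
                              attachment_donor = c(0, 0, 0),
                              attachment_acceptor = c(50, 0, 0),
                              pole_donor = c(1, 0, 0),
                              pole_acceptor = c(-1, 0, 0),
                              orientational_stride = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(timescales, "timescale_config"))
  .check_number(duration, "duration")
  cfg <- fret_config(model = model)
  n_t <- max(2L, ceiling(duration / timescales$dt_trans))
  dt_t <- duration / n_t
  if (model %in% c("isotropic", "anisotropic")) {
    if (is.null(donor))
      donor <- .spring_from_config(cfg, attachment_donor, model, stiff_axis = 1L)
    if (is.null(acceptor))
      acceptor <- .spring_from_config(cfg, attachment_acceptor, model, stiff_axis = 1L)
    pos_d <- matrix(NA_real_, n_t + 1L, 3L)
    pos_a <- matrix(NA_real_, n_t + 1L, 3L)
    pos_d[1L, ] <- spring_equilibrium_sample(donor)
    pos_a[1L, ] <- spring_equilibrium_sample(acceptor)
    for (i in seq_len(n_t)) {
      pos_d[i + 1L, ] <- ou_propagate(pos_d[i, ], donor, dt_t)
      pos_a[i + 1L, ] <- ou_propagate(pos_a[i, ], acceptor, dt_t)
    }
  } else {
    if (is.null(donor)) donor <- .pendulum_from_config(cfg)
    if (is.null(acceptor)) acceptor <- donor
    burn <- 500L
    init <- function(par) {
      st <- c(pendulum_rest_radius(par), 1, 2 * pi * runif(1))
      p <- pendulum_step(st, par, dt = 10, n_steps = burn)
      p[nrow(p), ]
    }
    path_d <- pendulum_step(init(donor), donor, dt_t, n_steps = n_t)
    path_a <- pendulum_step(init(acceptor), acceptor, dt_t, n_steps = n_t)
    pos_d <- .pendulum_to_lab(path_d, attachment_donor, pole_donor)
    pos_a <- .pendulum_to_lab(path_a, attachment_acceptor, pole_acceptor)
  }
  n_o_full <- max(2L, ceiling(duration / timescales$dt_orient))
  dt_o <- duration / n_o_full
  stride <- max(1L, as.integer(orientational_stride))
  mu_d <- sphere_step(c(acos(1 - 2 * runif(1)), 2 * pi * runif(1)),
                      rotation$D_donor, dt_o, n_steps = n_o_full)
  mu_a <- sphere_step(c(acos(1 - 2 * runif(1)), 2 * pi * runif(1)),
                      rotation$D_acceptor, dt_o, n_steps = n_o_full)
  keep <- seq(1L, n_o_full + 1L, by = stride)
  structure(list(
    model = model,
    time_trans = seq(0, duration, length.out = n_t + 1L),
    donor = pos_d, acceptor = pos_a,
    distance = sqrt(rowSums((pos_a - pos_d)^2)),
    time_orient = (keep - 1L) * dt_o,
    mu_donor = mu_d[keep, , drop = FALSE],
    mu_acceptor = mu_a[keep, , drop = FALSE]),
    class = "dye_pair_trajectory")
}

# local spherical (r, theta, phi) -> lab Cartesian around an attachment
# point, with theta measured from the given pole direction
.pendulum_to_lab <- function(path, attachment, pole) {
  u <- pole / sqrt(sum(pole^2))
  a <- if (abs(u[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  path <- if (is.matrix(path)) path else matrix(path, 1L)
  st <- sin(path[, 2L])
  loc <- cbind(path[, 1L] * st * cos(path[, 3L]),
               path[, 1L] * st * sin(path[, 3L]),
               path[, 1L] * cos(path[, 2L]))
  t(attachment + t(loc %*% rbind(e1, e2, u)))
}

#' Cartesian/spherical coordinate conversion for translational states
#'
#' Round-trips are identity to numerical tolerance; used by the pendulum
#' model, whose native coordinates are spherical.
#'
#' @param x 3-vector (x, y, z) or (r, theta, phi).
#' @name coordinate_conversion
#' @export
cartesian_to_spherical <- function(x) {
  .check_number(x, "x", positive = FALSE, len = 3L)
  r <- sqrt(sum(x^2))
  if (r == 0) return(c(r = 0, theta = 0, phi = 0))
  c(r = r, theta = acos(min(1, max(-1, x[3] / r))), phi = atan2(x[2], x[1]))
}

#' @rdname coordinate_conversion
#' @export
spherical_to_cartesian <- function(x) {
  .check_number(x, "x", positive = FALSE, len = 3L)
  if (x[1] < 0) .stop_invalid("radius must be nonnegative")
  c(x = x[1] * sin(x[2]) * cos(x[3]), y = x[1] * sin(x[2]) * sin(x[3]),
    z = x[1] * cos(x[2]))
}
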