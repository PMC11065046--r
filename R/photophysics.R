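#' Photophysical rate parameters
#'
#' Donor and acceptor de-excitation rates plus the Forster coupling
#' constant.  The coupling is parameterised either by the reference Forster
#' radius `R0_ref` at the dynamic-averaging orientational value
#' (kappa^2 = 2/3) or directly by the constant `C` in
#' `R0^6(t) = C * kappa^2(t)`; the two are tied by `R0_ref^6 = (2/3) C`.
#'
#' `k_D` is the total donor de-excitation rate (the CTMC has no separate
#' non-radiative channel); photon detection losses are applied downstream as
#' Bernoulli thinning in the experiment layer.
#'
#' @param k_D donor de-excitation rate, 1/ns.
#' @param k_A acceptor fluorescence rate, 1/ns.
#' @param R0_ref reference Forster radius at kappa^2 = 2/3, Angstrom.
#'   Ignored when `C` is given.
#' @param C optional Forster constant such that `R0^6 = C kappa^2`, A^6.
#' @return An object of class `photophysics_params`.
#' @examples
#' pp <- photophysics_params(k_D = 0.25, k_A = 0.5, R0_ref = 50)
#' static_efficiency(50, pp)   # 0.5 at r = R0 by definition
#' @export
photophysics_params <- function(k_D = 0.25, k_A = 0.5, R0_ref = 50,
                                C = NULL) {
  .check_number(k_D, "k_D"); .check_number(k_A, "k_A")
  if (is.null(C)) {
    .check_number(R0_ref, "R0_ref")
    C <- R0_ref^6 * 3 / 2
  } else {
    .check_number(C, "C")
    R0_ref <- (C * 2 / 3)^(1 / 6)
  }
  structure(list(k_D = k_D, k_A = k_A, C = C, R0_ref = R0_ref),
            class = "photophysics_params")
}

#' @export
print.photophysics_params <- function(x, ...) {
  cat(sprintf(
    "Photophysics: k_D = %.4g /ns, k_A = %.4g /ns, R0_ref = %.4g A (C = %.4g A^6)\n",
    x$k_D, x$k_A, x$R0_ref, x$C))
  invisible(x)
}

.check_unit <- function(v, name, tol = 1e-6) {
  if (!is.numeric(v) || length(v) != 3L || anyNA(v))
    .stop_invalid(sprintf("'%s' must be a numeric 3-vector", name))
  if (abs(sqrt(sum(v^2)) - 1) > tol)
    .stop_invalid(sprintf("'%s' must be a unit vector (|norm - 1| <= %g)", name, tol))
  invisible(v)
}

#' Dipole orientation factor kappa
#'
#' `kappa = muD . muA - 3 (rhat . muD)(rhat . muA)` for unit dipole moments
#' `muD`, `muA` and unit separation direction `rhat`.  `kappa^2` lies in
#' \[0, 4\]; it vanishes when the three vectors are mutually orthogonal and
#' attains -2 (kappa^2 = 4) when all three are collinear.
#'
#' @param mu_D,mu_A,r_hat unit 3-vectors (checked to 1e-6).
#' @return The signed orientation factor kappa (square it for kappa^2).
#' @export
kappa_factor <- function(mu_D, mu_A, r_hat) {
  .check_unit(mu_D, "mu_D"); .check_unit(mu_A, "mu_A")
  .check_unit(r_hat, "r_hat")
  sum(mu_D * mu_A) - 3 * sum(r_hat * mu_D) * sum(r_hat * mu_A)
}

#' Orientation-dependent sixth power of the Forster radius
#'
#' `R0^6 = C * kappa^2`.
#'
#' @param C Forster constant, A^6.
#' @param kappa_sq orientation factor kappa^2 in \[0, 4\] (vectorised).
#' @return `R0^6` values, A^6.
#' @export
forster_radius6 <- function(C, kappa_sq) {
  .check_number(C, "C")
  if (any(kappa_sq < 0 | kappa_sq > 4))
    .stop_invalid("'kappa_sq' must lie in [0, 4]")
  C * kappa_sq
}

#' Instantaneous energy transfer rate
#'
#' `k_ET = k_D (R0 / r)^6` with `R0^6 = C kappa^2`, i.e.
#' `k_ET = k_D C kappa^2 / r^6`.
#'
#' @param r inter-dye distance, Angstrom, > 0 (vectorised).
#' @param kappa_sq orientation factor kappa^2 (vectorised).
#' @param params a [photophysics_params()].
#' @return Transfer rate, 1/ns.
#' @export
transfer_rate <- function(r, kappa_sq, params) {
  stopifnot(inherits(params, "photophysics_params"))
  if (any(r <= 0)) .stop_invalid("'r' must be positive (r = 0 is the caller's CTMC reduction)")
  params$k_D * forster_radius6(params$C, kappa_sq) / r^6
}

#' Static (time-homogeneous) FRET efficiency
#'
#' `E = 1 / (1 + (r / R0)^6)` at the dynamic-averaging orientational value.
#' Equals 0.5 at `r = R0` and 1 at contact.
#'
#' @param r inter-dye distance, Angstrom, >= 0 (vectorised).
#' @param params a [photophysics_params()].
#' @export
static_efficiency <- function(r, params) {
  stopifnot(inherits(params, "photophysics_params"))
  if (any(r < 0)) .stop_invalid("'r' must be nonnegative")
  1 / (1 + (r / params$R0_ref)^6)
}

#' kappa^2 path during one excitation event
#'
#' A time grid from excitation (t = 0) with kappa^2 samples and the (frozen
#' or slowly varying) inter-dye distance, the basis of the inhomogeneous
#' transfer hazard.
#'
#' @param times increasing time grid starting at 0, ns.
#' @param kappa_sq kappa^2 samples on the grid, each in \[0, 4\].
#' @param distance inter-dye distance, a scalar (frozen) or one value per
#'   grid point, Angstrom.
#' @return An object of class `kappa_path`.
#' @export
kappa_path <- function(times, kappa_sq, distance) {
  if (length(times) != length(kappa_sq))
    .stop_invalid("'times' and 'kappa_sq' must have equal length")
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0))
    .stop_invalid("'times' must increase from 0")
  if (any(kappa_sq < 0 | kappa_sq > 4))
    .stop_invalid("'kappa_sq' must lie in [0, 4]")
  if (!length(distance) %in% c(1L, length(times)) || any(distance <= 0))
    .stop_invalid("'distance' must be positive, length 1 or length(times)")
  structure(list(times = as.numeric(times), kappa_sq = as.numeric(kappa_sq),
                 distance = rep_len(as.numeric(distance), length(times))),
            class = "kappa_path")
}

.path_rate <- function(path, params) {
  params$k_D * params$C * path$kappa_sq / path$distance^6
}

#' Integrated transfer hazard along a kappa^2 path
#'
#' `H(t) = integral_0^t k_ET(s) ds` by trapezoidal quadrature on the path
#' grid (rates linearly interpolated inside grid cells).  Nonnegative,
#' nondecreasing, `H(0) = 0`.
#'
#' @param path a [kappa_path()].
#' @param t evaluation times within the path support (vectorised).
#' @param params a [photophysics_params()].
#' @return `H(t)` values.
#' @export
integrated_hazard <- function(path, t, params) {
  stopifnot(inherits(path, "kappa_path"), inherits(params, "photophysics_params"))
  if (any(t < 0) || any(t > path$times[length(path$times)] + 1e-12))
    .stop_invalid("'t' outside the path support")
  rate <- .path_rate(path, params)
  tt <- path$times
  n <- length(tt)
  cumH <- c(0, cumsum(diff(tt) * (rate[-n] + rate[-1]) / 2))
  # exact integral of the piecewise-linear rate up to t
  i <- pmin(pmax(findInterval(t, tt, rightmost.closed = TRUE), 1L), n - 1L)
  t0 <- tt[i]
  fr <- pmin(pmax((t - t0) / (tt[i + 1L] - t0), 0), 1)
  rt <- rate[i] + fr * (rate[i + 1L] - rate[i])
  pmax(cumH[i] + (t - t0) * (rate[i] + rt) / 2, 0)
}

#' Time-dependent FRET efficiency along a kappa^2 path
#'
#' `E(T) = H(T) / (H(T) + k_D T)` with `H` the integrated transfer hazard;
#' the path-history generalisation of the static efficiency.
#'
#' @inheritParams integrated_hazard
#' @param T evaluation horizon, must lie inside the path support.
#' @export
time_dependent_efficiency <- function(path, T, params) {
  stopifnot(inherits(path, "kappa_path"))
  if (any(T > path$times[length(path$times)] + 1e-12))
    .stop_invalid("path does not cover the requested horizon T")
  H <- integrated_hazard(path, T, params)
  ifelse(T == 0, 0, H / (H + params$k_D * T))
}

#' CTMC rate matrix of one excitation event
#'
#' Generator of the four-state chain over S = (D, A, FD, FA): the excited
#' donor D exits to fluorescence FD at `k_D` or transfers to the excited
#' acceptor A at `k_ET`; A fluoresces to FA at `k_A`; FD and FA are
#' absorbing.
#'
#' @param k_ET energy transfer rate, >= 0, 1/ns.
#' @param params a [photophysics_params()].
#' @return A 4x4 generator matrix with zero row sums.
#' @export
build_rate_matrix <- function(k_ET, params) {
  stopifnot(inherits(params, "photophysics_params"))
  .check_number(k_ET, "k_ET", positive = FALSE)
  if (k_ET < 0) .stop_invalid("'k_ET' must be nonnegative")
  Q <- matrix(0, 4, 4, dimnames = list(c("D", "A", "FD", "FA"),
                                       c("D", "A", "FD", "FA")))
  Q["D", ] <- c(-(params$k_D + k_ET), k_ET, params$k_D, 0)
  Q["A", ] <- c(0, -params$k_A, 0, params$k_A)
  Q
}

#' Sample one excitation event
#'
#' Resolves one laser-pulse excitation into a donor or acceptor photon by
#' simulating the competing exits from the donor excited state.  With
#' `kappa = "static"` the event is time-homogeneous (exit rate
#' `k_D + k_ET`).  With `kappa = "dynamic"` both dipoles start from the
#' uniform equilibrium (or the supplied angles) and diffuse on the sphere
#' during the dwell; the exit time is sampled exactly by Lewis-Shedler
#' thinning of the inhomogeneous hazard `k_D + k_ET(t)` bounded via
#' kappa^2 <= 4, with the inter-dye distance frozen over the event.
#'
#' @param r inter-dye displacement: a 3-vector, or a scalar distance taken
#'   along x.  `r = 0` triggers the CTMC reduction: certain transfer and an
#'   `Exp(k_A)` acceptor delay.
#' @param params a [photophysics_params()].
#' @param kappa `"static"` or `"dynamic"`.
#' @param kappa_sq kappa^2 used in static mode (default 2/3).
#' @param rotation a [rotation_params()] (dynamic mode), or a list with
#'   donor/acceptor diffusion coefficients `D_donor`, `D_acceptor`.
#' @param dipoles optional 2x2 matrix of initial (theta, phi) rows for donor
#'   and acceptor (dynamic mode); uniform draws when `NULL`.
#' @param dt_orient orientational integrator step, ns.
#' @return A list of class `excitation_record`: `outcome`
#'   (`"donor_photon"`/`"acceptor_photon"`), `donor_dwell`,
#'   `emission_delay` (adds the acceptor dwell for acceptor photons) and
#'   `path_mean_kappa_sq`.
#' @export
sample_excitation_event <- function(r, params, kappa = c("static", "dynamic"),
                                    kappa_sq = 2 / 3, rotation = NULL,
                                    dipoles = NULL, dt_orient = 0.01) {
  kappa <- match.arg(kappa)
  stopifnot(inherits(params, "photophysics_params"))
  rvec <- if (length(r) == 1L) c(r, 0, 0) else r
  if (length(rvec) != 3L) .stop_invalid("'r' must be a scalar or 3-vector")
  rn <- sqrt(sum(rvec^2))
  rec <- function(outcome, dwell, delay, mk2)
    structure(list(outcome = outcome, donor_dwell = dwell,
                   emission_delay = delay, path_mean_kappa_sq = mk2),
              class = "excitation_record")
  if (rn < 1e-9)
    return(rec("acceptor_photon", 0, rexp(1, params$k_A), kappa_sq))
  if (kappa == "static") {
    kET <- transfer_rate(rn, kappa_sq, params)
    ktot <- params$k_D + kET
    dwell <- rexp(1, ktot)
    if (runif(1) * ktot < params$k_D)
      rec("donor_photon", dwell, dwell, kappa_sq)
    else
      rec("acceptor_photon", dwell, dwell + rexp(1, params$k_A), kappa_sq)
  } else {
    if (is.null(rotation)) .stop_invalid("dynamic kappa requires 'rotation'")
    DD <- if (!is.null(rotation$D_donor)) rotation$D_donor else rotation$D
    DA <- if (!is.null(rotation$D_acceptor)) rotation$D_acceptor else DD
    if (is.null(dipoles)) {
      dipoles <- cbind(acos(1 - 2 * runif(2)), 2 * pi * runif(2))
    }
    out <- cpp_sample_event_dynamic(rvec, dipoles[1, 1], dipoles[1, 2],
                                    dipoles[2, 1], dipoles[2, 2],
                                    params$k_D, params$k_A, params$C,
                                    DD, DA, dt_orient)
    rec(if (out[1] == 0) "donor_photon" else "acceptor_photon",
        out[2], out[3], out[4])
  }
}

#' Sample many excitation events
#'
#' Convenience replication of [sample_excitation_event()] returning a
#' data frame with one row per event.
#'
#' @param n number of events.
#' @inheritParams sample_excitation_event
#' @export
sample_excitation_events <- function(n, r, params,
                                     kappa = c("static", "dynamic"), ...) {
  kappa <- match.arg(kappa)
  recs <- vector("list", n)
  for (i in seq_len(n))
    recs[[i]] <- sample_excitation_event(r, params, kappa, ...)
  data.frame(
    outcome = vapply(recs, `[[`, "", "outcome"),
    donor_dwell = vapply(recs, `[[`, 0, "donor_dwell"),
    emission_delay = vapply(recs, `[[`, 0, "emission_delay"),
    path_mean_kappa_sq = vapply(recs, `[[`, 0, "path_mean_kappa_sq"))
}
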