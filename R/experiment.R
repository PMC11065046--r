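#' Burst schedule configuration
#'
#' Confocal burst protocol: each scheduled burst is one molecule observed
#' for `burst_duration` with pulsed excitation every `excitation_period`;
#' each excitation yields one photon which is detected with probability
#' `detection_efficiency` (equal for both channels, so detection commutes
#' with the photophysics).
#'
#' @param burst_duration burst length, ns (default 1 ms).
#' @param excitation_period laser pulse period, ns.
#' @param detection_efficiency per-channel detection probability in (0, 1].
#' @param bursts_per_second burst scheduling rate, 1/s.
#' @param total_duration experiment length, seconds.
#' @return An object of class `burst_config`.
#' @export
burst_config <- function(burst_duration = 1e6, excitation_period = 50,
                         detection_efficiency = 0.04, bursts_per_second = 1,
                         total_duration = 25200) {
  .check_number(burst_duration, "burst_duration")
  .check_number(excitation_period, "excitation_period")
  .check_number(detection_efficiency, "detection_efficiency")
  if (detection_efficiency > 1)
    .stop_invalid("'detection_efficiency' must be in (0, 1]")
  .check_number(bursts_per_second, "bursts_per_second")
  .check_number(total_duration, "total_duration")
  if (burst_duration >= 1e9 / bursts_per_second)
    .stop_invalid("burst_duration must be shorter than the scheduling period")
  structure(list(burst_duration = burst_duration,
                 excitation_period = excitation_period,
                 detection_efficiency = detection_efficiency,
                 bursts_per_second = bursts_per_second,
                 total_duration = total_duration),
            class = "burst_config")
}

#' Number of bursts scheduled by a protocol
#'
#' One burst per 1/`bursts_per_second`; e.g. 7 hours at one burst per
#' second schedules about 25,000 bursts.
#'
#' @param config a [burst_config()] or `fret_config`.
#' @export
schedule_bursts <- function(config) {
  if (inherits(config, "fret_config"))
    config <- with(config$experiment,
                   burst_config(burst_duration_ns, excitation_period_ns,
                                detection_efficiency, bursts_per_second,
                                total_duration_s))
  stopifnot(inherits(config, "burst_config"))
  as.integer(floor(config$total_duration * config$bursts_per_second))
}

# assemble the cpp_run_bursts argument list from a fret_config
.kernel_args <- function(cfg) {
  pp <- .photophysics_from_config(cfg)
  d <- cfg$dynamics$attachment_separation_A
  attD <- c(0, 0, 0); attA <- c(d, 0, 0)
  model_code <- if (cfg$model == "pendulum") 1L else 0L
  if (model_code == 0L) {
    par_d <- .spring_from_config(cfg, attD, cfg$model)
    par_a <- .spring_from_config(cfg, attA, cfg$model)
    kvecD <- par_d$k; kvecA <- par_a$k
    sigD <- par_d$sigma; sigA <- par_a$sigma
    pen <- list(k_r = 1, k_theta = 1, r_eq = 1, sigma_r = 1,
                sigma_theta = 1, sigma_phi = 1, c_r = 1)
  } else {
    pen <- .pendulum_from_config(cfg)
    kvecD <- kvecA <- rep(1, 3); sigD <- sigA <- 1
  }
  ro <- .rotation_from_config(cfg)
  st <- cfg$dynamics$steps
  ex <- cfg$experiment
  # orientational step: the configured step is the finest resolution; a
  # per-step angular MSD cap (2e-3 rad^2) refines down to it for fast
  # rotation, while slow rotation may coarsen up to 2.5 ns per step
  Dmax <- max(ro$D_donor, ro$D_acceptor)
  dt_orient <- max(st$orientational_dt_ns, min(2e-3 / (4 * Dmax), 2.5))
  list(model = model_code,
       n_pulses = as.integer(floor(ex$burst_duration_ns / ex$excitation_period_ns)),
       period = ex$excitation_period_ns,
       det_eff = ex$detection_efficiency,
       kD = pp$k_D, kA = pp$k_A, C = pp$C,
       kappa_dynamic = identical(cfg$kappa, "dynamic"),
       kappa_static = 2 / 3,
       DD = ro$D_donor, DA = ro$D_acceptor,
       dt_orient = dt_orient,
       dipole_reset_burst = identical(cfg$dynamics$rotation$dipole_reset,
                                      "burst"),
       kvecD = kvecD, kvecA = kvecA, sigD_tr = sigD, sigA_tr = sigA,
       attD = attD, attA = attA,
       kr = pen$k_r, kth = pen$k_theta, req = pen$r_eq, cr = pen$c_r,
       sr = pen$sigma_r, sth = pen$sigma_theta, sph = pen$sigma_phi,
       poleD = c(1, 0, 0), poleA = c(-1, 0, 0),
       dt_trans = st$translational_dt_ns,
       n_burn = as.integer(cfg$dynamics$steps$pendulum_burn_in_steps))
}

.bursts_to_df <- function(mat, cfg) {
  pp <- .photophysics_from_config(cfg)
  I_D <- mat[, 1]; I_A <- mat[, 2]
  n_phot <- I_D + I_A
  tau_mean <- ifelse(I_D > 0, mat[, 3] / I_D, NA_real_)
  tau_norm <- tau_mean * pp$k_D           # tau_D(0) = 1 / k_D
  usable <- n_phot >= cfg$experiment$min_photons & I_D > 0
  data.frame(
    burst_id = seq_len(nrow(mat)),
    I_D = as.integer(I_D), I_A = as.integer(I_A),
    E_intensity = ifelse(n_phot > 0, I_A / n_phot, NA_real_),
    tau_norm = tau_norm,
    mean_kappa_sq = ifelse(mat[, 5] > 0, mat[, 4] / mat[, 5], NA_real_),
    n_events = as.integer(mat[, 5]),
    mean_distance = ifelse(mat[, 5] > 0, mat[, 6] / mat[, 5], NA_real_),
    usable = usable)
}

#' Simulate one confocal burst
#'
#' One molecule, one burst: dye translational state drawn fresh from its
#' stationary law (springs) or from a burnt-in pendulum trajectory,
#' propagated between detected excitation events; each event is resolved
#' into a donor or acceptor photon (see [sample_excitation_event()]), and
#' per-burst counts, the donor delay mean and FRET coordinates are
#' aggregated.
#'
#' Bursts with fewer detected photons than `min_photons`, or with no donor
#' photon (undefined lifetime), are flagged `usable = FALSE` and excluded
#' from shift statistics.
#'
#' @param config a [fret_config()].
#' @return A one-row data frame (a burst record): `I_D`, `I_A`,
#'   `E_intensity`, `tau_norm`, `mean_kappa_sq`, `n_events`,
#'   `mean_distance`, `usable`.
#' @export
run_burst <- function(config = fret_config()) {
  stopifnot(inherits(config, "fret_config"))
  a <- .kernel_args(config)
  mat <- do.call(cpp_run_bursts, c(list(n_bursts = 1L), a)[c(
    "model", "n_bursts", "n_pulses", "period", "det_eff", "kD", "kA", "C",
    "kappa_dynamic", "kappa_static", "DD", "DA", "dt_orient",
    "dipole_reset_burst", "kvecD",
    "kvecA", "sigD_tr", "sigA_tr", "attD", "attA", "kr", "kth", "req",
    "cr", "sr", "sth", "sph", "poleD", "poleA", "dt_trans", "n_burn")])
  .bursts_to_df(mat, config)
}

#' Simulate a full smFRET experiment
#'
#' Schedules bursts (one molecule each) and simulates every burst under the
#' configured dye model and orientation handling.  The result is
#' bit-reproducible from `(config, seed)`.
#'
#' @param config a [fret_config()]; convenience arguments `model` and
#'   `kappa` override the config's.
#' @param seed integer master seed.
#' @param n_bursts number of bursts; default is the scheduled count
#'   (`total_duration_s * bursts_per_second`, about 25,000 for the default
#'   7-hour protocol).
#' @param model,kappa optional overrides of `config$model`, `config$kappa`.
#' @return An object of class `fret_experiment`: list with `bursts` (data
#'   frame of burst records), `config`, `seed`, `n_scheduled`.
#' @examples
#' \donttest{
#' ex <- run_experiment(fret_config("isotropic", "static"),
#'                      seed = 1, n_bursts = 50)
#' summary(ex)
#' }
#' @export
run_experiment <- function(config = fret_config(), seed = 1L,
                           n_bursts = NULL, model = NULL, kappa = NULL) {
  stopifnot(inherits(config, "fret_config"))
  if (!is.null(model) || !is.null(kappa)) {
    config <- unclass(config)
    if (!is.null(model)) config$model <- model
    if (!is.null(kappa)) config$kappa <- kappa
    config$dynamics$attachment_separation_A <- NULL
    config <- structure(.apply_config_defaults(config), class = "fret_config")
    validate_config(config)
  }
  n_sched <- schedule_bursts(config)
  if (is.null(n_bursts)) n_bursts <- n_sched
  set.seed(as.integer(seed))
  a <- .kernel_args(config)
  mat <- do.call(cpp_run_bursts, c(list(n_bursts = as.integer(n_bursts)), a)[c(
    "model", "n_bursts", "n_pulses", "period", "det_eff", "kD", "kA", "C",
    "kappa_dynamic", "kappa_static", "DD", "DA", "dt_orient",
    "dipole_reset_burst", "kvecD",
    "kvecA", "sigD_tr", "sigA_tr", "attD", "attA", "kr", "kth", "req",
    "cr", "sr", "sth", "sph", "poleD", "poleA", "dt_trans", "n_burn")])
  structure(list(bursts = .bursts_to_df(mat, config), config = config,
                 seed = as.integer(seed), n_scheduled = n_sched,
                 rng_kind = RNGkind()[1]),
            class = "fret_experiment")
}

#' Intensity-based FRET efficiency estimator
#'
#' `E_I = I_A / (I_A + I_D)`, the sample proportion of acceptor photons.
#'
#' @param I_A,I_D acceptor and donor photon counts (vectorised).
#' @export
estimate_intensity_fret <- function(I_A, I_D) {
  if (any(I_A < 0) || any(I_D < 0)) .stop_invalid("counts must be nonnegative")
  tot <- I_A + I_D
  if (any(tot == 0)) .stop_invalid("undefined estimate: I_A + I_D = 0")
  I_A / tot
}

#' Lifetime-based FRET efficiency estimator
#'
#' `E_tau = 1 - tau_DA / tau_D0`, with `tau_DA` the donor lifetime in the
#' presence of the acceptor and `tau_D0 = 1/k_D` the donor-only lifetime.
#'
#' @param tau_DA donor delay mean with acceptor present, ns (vectorised).
#' @param tau_D0 donor-only lifetime, ns.
#' @export
estimate_lifetime_fret <- function(tau_DA, tau_D0) {
  .check_number(tau_D0, "tau_D0")
  if (any(tau_DA < 0)) .stop_invalid("'tau_DA' must be nonnegative")
  1 - tau_DA / tau_D0
}
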