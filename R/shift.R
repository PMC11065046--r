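#' Signed dynamic shift of a FRET-lifetime coordinate
#'
#' Signed deviation of a burst coordinate `(E, tau)` (intensity FRET
#' efficiency vs normalized donor lifetime) from the static line
#' `E + tau = 1`.  Two variants are provided:
#' * `"printed"`: `(E + tau - 1) / sqrt(E^2 + tau^2)` (undefined at the
#'   origin);
#' * `"perpendicular"`: `(E + tau - 1) / sqrt(2)`, the Euclidean signed
#'   distance to the line.
#'
#' Both vanish exactly on the static line and are positive above it (the
#' mixing side).  The two variants disagree away from the line; for points
#' in the unit square the perpendicular variant is bounded by
#' `1/sqrt(2)` at `(1, 1)`.
#'
#' @param E intensity FRET efficiency in \[0, 1\] (vectorised).
#' @param tau normalized donor lifetime (vectorised).
#' @param variant `"printed"` or `"perpendicular"`.
#' @return Signed shift values Delta.
#' @export
dynamic_shift <- function(E, tau, variant = c("printed", "perpendicular")) {
  variant <- match.arg(variant)
  if (length(E) != length(tau)) .stop_invalid("'E' and 'tau' lengths differ")
  num <- E + tau - 1
  if (variant == "printed") {
    den <- sqrt(E^2 + tau^2)
    if (any(den == 0, na.rm = TRUE))
      .stop_invalid("printed variant undefined at (0, 0)")
    num / den
  } else {
    num / sqrt(2)
  }
}

#' Dynamic-shift distribution of an experiment
#'
#' Per-burst shift values Delta from the usable bursts' `(E_intensity,
#' tau_norm)` coordinates, with their sample mean and standard deviation.
#' A nonzero mean indicates state mixing during bursts; for a static system
#' the distribution is centred at zero and quantifies shot noise.
#'
#' @param bursts a `fret_experiment` or a burst-record data frame.
#' @param variant shift variant, see [dynamic_shift()].
#' @return An object of class `fret_shift`: `delta` (per-burst values),
#'   `mu`, `sigma`, `n`, `variant`.
#' @export
shift_distribution <- function(bursts, variant = c("printed", "perpendicular")) {
  variant <- match.arg(variant)
  df <- if (inherits(bursts, "fret_experiment")) bursts$bursts else bursts
  if (!is.data.frame(df) || nrow(df) == 0)
    .stop_invalid("empty input: no bursts")
  if (!is.null(df$usable)) df <- df[df$usable, , drop = FALSE]
  df <- df[is.finite(df$E_intensity) & is.finite(df$tau_norm), , drop = FALSE]
  if (nrow(df) < 2L) .stop_invalid("need at least 2 usable bursts")
  delta <- dynamic_shift(df$E_intensity, df$tau_norm, variant)
  structure(list(delta = delta, mu = mean(delta), sigma = sd(delta),
                 n = length(delta), variant = variant),
            class = "fret_shift")
}

#' @export
print.fret_shift <- function(x, ...) {
  cat(sprintf("Dynamic shift (%s variant), %d bursts:\n", x$variant, x$n))
  cat(sprintf("  mu(Delta) = %.4f, sigma(Delta) = %.4f\n", x$mu, x$sigma))
  invisible(x)
}

#' Moment-difference dynamic shift
#'
#' For static systems the first and second FRET moments satisfy
#' `E[E(1-E)] = E[tau(1-tau)]`, so the coordinate
#' `(E_I, E_tau (1 - E_tau))` lies on the parabola `y = x (1 - x)`.
#' Mixing pushes points below it.  The statistic is the signed orthogonal
#' distance from each burst's coordinate to the parabola (negative below),
#' found by bracketed 1-D minimisation of the squared distance along the
#' curve parameter.
#'
#' @param bursts a `fret_experiment` or burst-record data frame
#'   (`E_tau` is derived from `tau_norm` as `1 - tau_norm`), or a
#'   data frame with columns `E_I` and `E_tau`.
#' @return A numeric vector of signed distances, one per usable burst.
#' @export
moment_difference_shift <- function(bursts) {
  df <- if (inherits(bursts, "fret_experiment")) bursts$bursts else bursts
  if (!is.data.frame(df) || nrow(df) == 0) .stop_invalid("empty input")
  if (!is.null(df$E_I) && !is.null(df$E_tau)) {
    E_I <- df$E_I; E_tau <- df$E_tau
  } else {
    if (!is.null(df$usable)) df <- df[df$usable, , drop = FALSE]
    E_I <- df$E_intensity
    E_tau <- 1 - df$tau_norm
  }
  vapply(seq_along(E_I), function(i) {
    .parabola_signed_distance(E_I[i], E_tau[i] * (1 - E_tau[i]))
  }, 0)
}

# signed orthogonal distance from (x0, y0) to y = x (1 - x); negative below
.parabola_signed_distance <- function(x0, y0) {
  if (!is.finite(x0) || !is.finite(y0)) return(NA_real_)
  f <- function(t) (t - x0)^2 + (t * (1 - t) - y0)^2
  # the nearest point of the parabola lies within a bounded parameter range
  lo <- min(x0, 0) - 1; hi <- max(x0, 1) + 1
  opt <- optimize(f, c(lo, hi), tol = 1e-10)
  # refine around the optimum (optimize is unimodal-safe here in practice;
  # a small grid guard protects against a second local minimum)
  tg <- seq(lo, hi, length.out = 201L)
  tbest <- tg[which.min(f(tg))]
  if (f(tbest) < opt$objective) opt <- optimize(f, c(tbest - 0.05, tbest + 0.05),
                                                tol = 1e-10)
  sign(y0 - x0 * (1 - x0)) * sqrt(opt$objective)
}

#' Jensen bounds for a mixture of fluorescence rates
#'
#' For a population with rate distribution (rates `K_i`, weights `pi_i`)
#' the mean lifetime is `tau_bar = sum(pi_i / K_i)` while the lifetime of
#' the mean rate is `1 / sum(pi_i K_i)`.  Convexity of `1/x` (Jensen) makes
#' the gap `tau_bar - 1/E[K]` nonnegative, the root cause of the dynamic
#' shift for mixtures.
#'
#' @param rates positive rates `K_i`.
#' @param weights probabilities `pi_i` (nonnegative, summing to 1; default
#'   uniform).
#' @return A list: `mean_lifetime`, `lifetime_of_mean_rate`, `gap`.
#' @export
jensen_bounds <- function(rates, weights = NULL) {
  if (any(rates <= 0)) .stop_invalid("'rates' must be positive")
  if (is.null(weights)) weights <- rep(1 / length(rates), length(rates))
  if (length(weights) != length(rates) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    .stop_invalid("'weights' must be a probability vector matching 'rates'")
  tau_bar <- sum(weights / rates)
  inv_mean <- 1 / sum(weights * rates)
  list(mean_lifetime = tau_bar, lifetime_of_mean_rate = inv_mean,
       gap = tau_bar - inv_mean)
}

#' Two-state mixing reference
#'
#' Burst simulation of the classic two-state system: a molecule switches
#' between FRET efficiency states `E1`, `E2` at equal exchange rate
#' `lambda` while excitation events (homogeneous within the occupied state)
#' accumulate over the burst.  As `lambda` grows the per-burst
#' `(E_I, tau)` coordinates travel from the two static points `(E_i,
#' 1 - E_i)` along the mixing arc
#' `E(tau) = 1 - tau1 tau2 / (tau1 + tau2 - tau)` (`tau_i = 1 - E_i`)
#' toward the fully mixed point; every within-burst mixture weight lies
#' exactly on that arc.
#'
#' @param E1,E2 the two efficiency states, in (0, 1), distinct.
#' @param lambda exchange rate, 1/ns, >= 0.
#' @param n_bursts number of bursts.
#' @param n_events excitation events per burst.
#' @param event_spacing time between events, ns.
#' @param params a [photophysics_params()].
#' @return A list of class `two_state_reference`: `bursts` (data frame with
#'   `E_intensity`, `tau_norm`, `occupancy1`), `arc` (function tau ->
#'   E on the reference arc), `spec`.
#' @export
two_state_reference <- function(E1, E2, lambda, n_bursts = 500,
                                n_events = 400, event_spacing = 1250,
                                params = photophysics_params()) {
  if (E1 <= 0 || E1 >= 1 || E2 <= 0 || E2 >= 1 || E1 == E2)
    .stop_invalid("'E1' and 'E2' must be distinct values in (0, 1)")
  if (lambda < 0) .stop_invalid("'lambda' must be nonnegative")
  kD <- params$k_D
  kET <- kD * c(E1 / (1 - E1), E2 / (1 - E2))
  ktot <- kD + kET
  p_flip <- (1 - exp(-2 * lambda * event_spacing)) / 2
  bursts <- matrix(NA_real_, n_bursts, 3L)
  for (b in seq_len(n_bursts)) {
    state <- sample.int(2L, 1L)
    I <- c(0, 0); delay_sum <- 0
    for (i in seq_len(n_events)) {
      if (i > 1L && runif(1) < p_flip) state <- 3L - state
      dwell <- rexp(1, ktot[state])
      if (runif(1) * ktot[state] < kD) {
        I[1] <- I[1] + 1; delay_sum <- delay_sum + dwell
      } else I[2] <- I[2] + 1
      if (state == 1L) bursts[b, 3] <- sum(bursts[b, 3], 1, na.rm = TRUE)
    }
    bursts[b, 1] <- I[2] / sum(I)
    bursts[b, 2] <- if (I[1] > 0) (delay_sum / I[1]) * kD else NA_real_
  }
  tau1 <- 1 - E1; tau2 <- 1 - E2
  arc <- function(tau) 1 - tau1 * tau2 / (tau1 + tau2 - tau)
  structure(list(
    bursts = data.frame(E_intensity = bursts[, 1], tau_norm = bursts[, 2],
                        occupancy1 = ifelse(is.na(bursts[, 3]), 0,
                                            bursts[, 3]) / n_events),
    arc = arc,
    spec = list(E1 = E1, E2 = E2, lambda = lambda)),
    class = "two_state_reference")
}
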