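# Independent oracles used across the suite.  These deliberately avoid the
# package's production code paths (fine-step Euler-Maruyama instead of the
# exact OU kernel; grid inversion of the integrated hazard instead of
# thinning) so the two routes check each other.

# fine-step Euler-Maruyama transition sampler for a 1-D OU process
euler_ou_sample <- function(n, x0, k, sigma, x_eq, dt, n_sub = 200L) {
  h <- dt / n_sub
  x <- rep(x0, n)
  for (i in seq_len(n_sub))
    x <- x - k * (x - x_eq) * h + sigma * sqrt(h) * rnorm(n)
  x
}

# random piecewise-linear kappa^2 path covering [0, t_max]
random_kappa_path <- function(t_max = 200, n_knots = 100L, r = 50) {
  kappa_path(times = seq(0, t_max, length.out = n_knots),
             kappa_sq = runif(n_knots, 0, 4), distance = r)
}

# total-exit dwell (hazard k_D + k_ET(t)) by Lewis-Shedler thinning on a
# deterministic path, vectorised over samples
thinning_dwell <- function(n, path, params) {
  r6 <- path$distance[1]^6
  lmax <- params$k_D * (1 + params$C * max(path$kappa_sq) / r6)
  rate_at <- function(t)
    params$k_D * (1 + params$C *
                    approx(path$times, path$kappa_sq, t, rule = 2)$y / r6)
  t <- numeric(n)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    idx <- which(alive)
    t[idx] <- t[idx] + rexp(length(idx), lmax)
    acc <- runif(length(idx)) * lmax < rate_at(t[idx])
    alive[idx[acc]] <- FALSE
  }
  t
}

# the same dwell by inversion of the integrated total hazard on a fine grid
inversion_dwell <- function(n, path, params) {
  tt <- seq(0, path$times[length(path$times)], length.out = 20000L)
  H <- integrated_hazard(path, tt, params) + params$k_D * tt
  approx(H, tt, xout = rexp(n), rule = 2, ties = "ordered")$y
}

# small, fast experiment config: 4000 pulses per burst (~1000 detected
# photons at the default efficiency)
fast_config <- function(model = "isotropic", kappa = "static", ...) {
  dots <- list(...)
  ex <- list(burst_duration_ns = 2e5, total_duration_s = 600)
  if (!is.null(dots$experiment)) {
    ex <- utils::modifyList(ex, dots$experiment)
    dots$experiment <- NULL
  }
  do.call(fret_config, c(list(model, kappa, experiment = ex), dots))
}

expect_within_se <- function(est, truth, se, n_se = 3) {
  expect_lt(abs(est - truth), n_se * se)
}
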