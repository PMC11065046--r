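#' Count kernel-density modes
#'
#' Number of strict local maxima of the Gaussian kernel density estimate of
#' `x` at bandwidth `bw`.
#'
#' @param x numeric sample.
#' @param bw bandwidth; default `bw.nrd0(x)`.
#' @return Integer mode count.
#' @export
count_kde_modes <- function(x, bw = bw.nrd0(x)) {
  length(.density_modes(density(x, bw = bw, n = 512)))
}

.density_modes <- function(dens) {
  y <- dens$y
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  # drop numerical micro-bumps below 1% of the peak
  idx[y[idx] > 0.01 * max(y)]
}

#' Silverman's critical-bandwidth test for unimodality
#'
#' The critical bandwidth `h_crit` is the smallest Gaussian-kernel
#' bandwidth at which the density estimate of `x` has at most `k` modes;
#' multimodal data need a large `h_crit` to be smoothed to `k` modes.  The
#' p-value is obtained by the smoothed bootstrap: samples drawn from the
#' `h_crit`-KDE (variance-rescaled) are tested for whether their own
#' critical bandwidth exceeds `h_crit`.  Small p-values reject the
#' hypothesis that the data have at most `k` modes.
#'
#' @param x numeric sample.
#' @param k null number of modes (default 1: test of unimodality).
#' @param n_boot bootstrap replicates.
#' @return A list of class `silverman_test`: `h_crit`, `p_value`, `k`,
#'   `n_boot`.
#' @export
silverman_test <- function(x, k = 1L, n_boot = 200L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10L) .stop_invalid("need at least 10 observations")
  h_crit <- .critical_bandwidth(x, k)
  s2 <- var(x)
  greater <- 0L
  for (b in seq_len(n_boot)) {
    # smoothed bootstrap, rescaled to keep the sample variance
    xb <- sample(x, n, replace = TRUE) + h_crit * rnorm(n)
    xb <- mean(x) + (xb - mean(xb)) / sqrt(1 + h_crit^2 / s2)
    if (.n_modes_at(xb, h_crit) > k) greater <- greater + 1L
  }
  structure(list(h_crit = h_crit, p_value = (greater + 1) / (n_boot + 1),
                 k = k, n_boot = n_boot),
            class = "silverman_test")
}

.n_modes_at <- function(x, bw) {
  length(.density_modes(density(x, bw = bw, n = 512)))
}

.critical_bandwidth <- function(x, k, tol = 1e-3) {
  lo <- max(diff(range(x)) * 1e-4, 1e-12)
  hi <- diff(range(x))
  if (.n_modes_at(x, lo) <= k) return(lo)
  while (.n_modes_at(x, hi) > k) hi <- hi * 2
  while ((hi - lo) / hi > tol) {
    mid <- sqrt(lo * hi)
    if (.n_modes_at(x, mid) <= k) hi <- mid else lo <- mid
  }
  hi
}

#' @export
print.silverman_test <- function(x, ...) {
  cat(sprintf(
    "Silverman unimodality test (k = %d): h_crit = %.4g, p = %.3f (%d bootstraps)\n",
    x$k, x$h_crit, x$p_value, x$n_boot))
  invisible(x)
}
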