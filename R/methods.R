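#' @export
print.fret_experiment <- function(x, ...) {
  df <- x$bursts
  cat(sprintf("smFRET experiment: %s dye model, %s kappa, %d bursts (%d usable)\n",
              x$config$model, x$config$kappa, nrow(df), sum(df$usable)))
  use <- df[df$usable, , drop = FALSE]
  if (nrow(use)) {
    cat(sprintf("  mean photons/burst = %.1f, <E_I> = %.3f, <tau> = %.3f\n",
                mean(use$I_D + use$I_A), mean(use$E_intensity),
                mean(use$tau_norm)))
  }
  cat(sprintf("  seed = %d (%s)\n", x$seed, x$rng_kind))
  invisible(x)
}

#' Summarise a simulated experiment
#'
#' Burst-level aggregates plus the dynamic-shift distribution summary.
#'
#' @param object a `fret_experiment`.
#' @param variant shift variant.
#' @param ... unused.
#' @export
summary.fret_experiment <- function(object,
                                    variant = c("printed", "perpendicular"),
                                    ...) {
  variant <- match.arg(variant)
  df <- object$bursts
  use <- df[df$usable, , drop = FALSE]
  sh <- tryCatch(shift_distribution(object, variant), error = function(e) NULL)
  out <- list(model = object$config$model, kappa = object$config$kappa,
              n_bursts = nrow(df), n_usable = nrow(use),
              mean_photons = mean(use$I_D + use$I_A),
              mean_E_intensity = mean(use$E_intensity),
              mean_tau_norm = mean(use$tau_norm),
              mean_kappa_sq = mean(use$mean_kappa_sq),
              shift_mu = if (is.null(sh)) NA_real_ else sh$mu,
              shift_sigma = if (is.null(sh)) NA_real_ else sh$sigma,
              shift_variant = variant)
  class(out) <- "summary.fret_experiment"
  out
}

#' @export
print.summary.fret_experiment <- function(x, ...) {
  cat(sprintf("smFRET experiment summary (%s, %s kappa)\n", x$model, x$kappa))
  cat(sprintf("  bursts: %d (%d usable), %.1f photons/burst\n",
              x$n_bursts, x$n_usable, x$mean_photons))
  cat(sprintf("  <E_I> = %.3f  <tau> = %.3f  <kappa^2> = %.3f\n",
              x$mean_E_intensity, x$mean_tau_norm, x$mean_kappa_sq))
  cat(sprintf("  dynamic shift (%s): mu = %.4f, sigma = %.4f\n",
              x$shift_variant, x$shift_mu, x$shift_sigma))
  invisible(x)
}

#' Plot a simulated experiment in the FRET-lifetime plane
#'
#' Scatter of per-burst `(tau, E_I)` with the static line `E = 1 - tau`;
#' points above the line carry a positive dynamic shift.
#'
#' @param x a `fret_experiment`.
#' @param ... passed to [plot()].
#' @export
plot.fret_experiment <- function(x, ...) {
  use <- x$bursts[x$bursts$usable, , drop = FALSE]
  plot(use$tau_norm, use$E_intensity,
       xlab = expression(tau[D(A)] / tau[D(0)]),
       ylab = expression(E[I]),
       xlim = c(0, 1.2), ylim = c(0, 1), pch = 16, cex = 0.4,
       col = adjustcolor("steelblue4", 0.4),
       main = sprintf("%s model, %s kappa", x$config$model, x$config$kappa),
       ...)
  abline(1, -1, col = "grey30", lwd = 2)
  invisible(x)
}

#' Plot a dynamic-shift distribution
#'
#' @param x a `fret_shift`.
#' @param ... passed to [hist()].
#' @export
plot.fret_shift <- function(x, ...) {
  hist(x$delta, breaks = "FD", xlab = expression(Delta),
       main = sprintf("Dynamic shift (%s), mu = %.3f, sigma = %.3f",
                      x$variant, x$mu, x$sigma), ...)
  abline(v = 0, col = "grey30", lwd = 2)
  abline(v = x$mu, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Plot a dye-pair trajectory's inter-dye distance
#'
#' @param x a `dye_pair_trajectory`.
#' @param ... passed to [hist()].
#' @export
plot.dye_pair_trajectory <- function(x, ...) {
  hist(x$distance, breaks = "FD", xlab = "inter-dye distance (A)",
       main = sprintf("%s model", x$model), ...)
  invisible(x)
}
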