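#' Write a burst table to TSV
#'
#' Tab-separated burst records with header, full double precision
#' (`%.17g`) and deterministic row order.  A header comment line records
#' the unit convention.
#'
#' @param result a `fret_experiment` or burst-record data frame.
#' @param path output file.
#' @export
write_burst_table <- function(result, path) {
  df <- if (inherits(result, "fret_experiment")) result$bursts else result
  if (!is.data.frame(df)) .stop_invalid("'result' must hold a burst data frame")
  out <- df
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# fretsim burst table; units: lengths A, times ns, rates 1/ns", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a burst table written by [write_burst_table()]
#'
#' @param path TSV file.
#' @return A burst-record data frame.
#' @export
read_burst_table <- function(path) {
  if (!file.exists(path)) .stop_invalid("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (!is.null(df$usable)) df$usable <- as.logical(df$usable)
  df
}

#' Write an experiment summary as JSON
#'
#' Config echo, master seed, RNG algorithm and aggregate burst/shift
#' statistics.
#'
#' @param result a `fret_experiment`.
#' @param path output JSON file.
#' @param variant shift variant for the summary statistics.
#' @export
write_summary_json <- function(result, path,
                               variant = c("printed", "perpendicular")) {
  stopifnot(inherits(result, "fret_experiment"))
  variant <- match.arg(variant)
  sh <- tryCatch(shift_distribution(result, variant), error = function(e) NULL)
  df <- result$bursts
  use <- df[df$usable, , drop = FALSE]
  summ <- list(
    units = "lengths A, times ns, rates 1/ns",
    seed = result$seed,
    rng = result$rng_kind,
    config = unclass(result$config),
    n_bursts = nrow(df),
    n_usable = nrow(use),
    mean_E_intensity = mean(use$E_intensity),
    mean_tau_norm = mean(use$tau_norm),
    mean_photons = mean(use$I_D + use$I_A),
    shift = if (is.null(sh)) NULL else
      list(variant = sh$variant, mu = sh$mu, sigma = sh$sigma, n = sh$n))
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
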