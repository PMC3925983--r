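#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Ct on log10(known copies) over the
#' dilution points. A perfect-doubling assay (efficiency 1.0) gives a
#' slope of exactly -log2(10) = -3.3219; the amplification efficiency is
#' recovered from the slope as `10^(-1/slope) - 1`.
#'
#' @param points Data frame with columns `known_copies` and `ct`
#'   (one row per replicate; e.g. a [simulate_dilution_series()] result
#'   or a table of measured Cts).
#' @param qc_r_squared Warn if the fit's R-squared falls below this
#'   (default 0.99; a QC check, not a failure).
#' @return Object of class `standard_curve`: list with `slope`
#'   (Ct per log10 copies), `intercept` (Ct at 1 copy), `r_squared`,
#'   `efficiency`, `n_levels` and the per-level `means` table.
#' @export
fit_standard_curve <- function(points, qc_r_squared = 0.99) {
  points <- as.data.frame(points)
  if (!all(c("known_copies", "ct") %in% names(points)))
    stop("points needs columns known_copies and ct", call. = FALSE)
  if (any(points$known_copies <= 0))
    stop("known_copies must be > 0", call. = FALSE)
  agg <- aggregate(ct ~ known_copies, data = points, FUN = mean)
  if (nrow(agg) < 3L)
    stop("need at least 3 distinct copy levels to fit a standard curve",
         call. = FALSE)
  agg$log10_copies <- log10(agg$known_copies)
  if (sd(agg$log10_copies) == 0)
    stop("zero variance in log10(known_copies)", call. = FALSE)
  fit <- lm(ct ~ log10_copies, data = agg)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  # noise-free series trip summary.lm's perfect-fit warning; R^2 is still 1
  r2 <- suppressWarnings(summary(fit)$r.squared)
  efficiency <- 10^(-1 / slope) - 1
  if (r2 < qc_r_squared)
    warning(sprintf("standard curve R^2 = %.4f below QC threshold %.2f",
                    r2, qc_r_squared), call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, efficiency = efficiency,
                 n_levels = nrow(agg),
                 means = agg[order(-agg$known_copies),
                             c("known_copies", "log10_copies", "ct")]),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve over %d copy levels\n", x$n_levels))
  cat(sprintf("  slope %.2f Ct/log10(copies), intercept %.2f Ct at 1 copy\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2 %.4f, efficiency %.1f%%\n",
              x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Absolute quantification of an unknown sample
#'
#' Back-transforms replicate Cts through the standard curve:
#' `copies = 10^((Ct - intercept) / slope)`. The estimate is the
#' back-transform of the replicate-mean Ct; the spread is the standard
#' deviation of the per-replicate back-transformed copies (the error
#' bars of a copy-number bar chart).
#'
#' @param ct_values Numeric vector of replicate Ct values.
#' @param curve A [fit_standard_curve()] result with negative slope.
#' @param label Optional sample label.
#' @return Object of class `quant_result`: list with
#'   `estimated_copies`, `replicate_spread`, `replicate_copies`, `label`.
#' @export
quantify_sample <- function(ct_values, curve, label = NA_character_) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.numeric(ct_values) || length(ct_values) < 1L || anyNA(ct_values))
    stop("ct_values must be a non-empty numeric vector", call. = FALSE)
  if (curve$slope >= 0)
    stop("invalid standard curve: slope must be negative", call. = FALSE)
  per_rep <- 10^((ct_values - curve$intercept) / curve$slope)
  est <- 10^((mean(ct_values) - curve$intercept) / curve$slope)
  structure(list(estimated_copies = est,
                 replicate_spread = if (length(per_rep) > 1L) sd(per_rep) else 0,
                 replicate_copies = per_rep,
                 label = label),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("%s: %.0f copies (replicate SD %.0f, n = %d)\n",
              if (is.na(x$label)) "sample" else x$label,
              x$estimated_copies, x$replicate_spread,
              length(x$replicate_copies)))
  invisible(x)
}

#' Signed copy-number difference between two samples
#'
#' @param a,b [quantify_sample()] results.
#' @return `a - b` in copies, rounded to the nearest integer copy.
#' @export
copy_difference <- function(a, b) {
  stopifnot(inherits(a, "quant_result"), inherits(b, "quant_result"))
  round(a$estimated_copies - b$estimated_copies)
}
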