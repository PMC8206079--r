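# Between-year and between-method agreement of standardised detection
# probabilities: pairing estimates by taxon and summarising their linear
# association (slope, intercept, R^2), on the probability scale.

#' Pair two sets of detection estimates by taxon
#'
#' Inner join on taxon name; optionally restricted to taxa a camera-trap
#' survey targets (for method comparisons where only those taxa are
#' meaningful on both axes).
#'
#' @param a,b `detection_estimates` data.frames (see
#'   [estimate_detection()]).
#' @param taxa optional [taxon_table()] supplying `camera_detectable`
#'   flags.
#' @param camera_detectable_only drop taxa not flagged camera-detectable.
#' @return data.frame with `taxon`, `p60_a`, `p60_b`.
#' @export
paired_estimates <- function(a, b, taxa = NULL,
                             camera_detectable_only = FALSE) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  common <- intersect(a$taxon, b$taxon)
  if (camera_detectable_only) {
    if (is.null(taxa)) stop("need a taxon table to filter on detectability")
    common <- intersect(common, taxa$name[taxa$camera_detectable])
  }
  if (length(common) == 0) stop("no taxa shared between the two estimates")
  common <- sort(common)
  data.frame(taxon = common,
             p60_a = a$p60_mean[match(common, a$taxon)],
             p60_b = b$p60_mean[match(common, b$taxon)],
             stringsAsFactors = FALSE)
}

#' Ordinary least-squares fit with R-squared
#'
#' @param x,y numeric vectors, `n >= 3`, with `var(x) > 0`.
#' @return list of class `regression_summary`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 n = length(x)),
            class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS: y = %.4f + %.4f x, R^2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Compare two sets of detection estimates
#'
#' Convenience wrapper: pair by taxon, then regress `b` on `a`.
#'
#' @inheritParams paired_estimates
#' @param name label for the comparison.
#' @return one-row data.frame: `comparison`, `n`, `slope`, `intercept`,
#'   `r_squared`.
#' @export
compare_estimates <- function(a, b, name = "a_vs_b", taxa = NULL,
                              camera_detectable_only = FALSE) {
  pr <- paired_estimates(a, b, taxa, camera_detectable_only)
  fit <- linear_fit(pr$p60_a, pr$p60_b)
  data.frame(comparison = name, n = fit$n, slope = fit$slope,
             intercept = fit$intercept, r_squared = fit$r_squared,
             stringsAsFactors = FALSE)
}
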