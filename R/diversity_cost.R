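# Diversity summaries, bootstrap species-accumulation curves and
# cost-efficiency (richness versus dollars) curves per survey method,
# design and year.

#' Per-unit species richness
#'
#' @param m a [detection_matrix()].
#' @return list with `richness` (named per-unit counts) and `mean`.
#' @export
site_richness <- function(m) {
  stopifnot(inherits(m, "detection_matrix"), ncol(m$y) > 0)
  r <- colSums(m$y)
  list(richness = r, mean = mean(r))
}

#' Diversity turnover from total and mean per-unit richness
#'
#' The additive beta-diversity fraction `(gamma - alpha_bar) / gamma`:
#' the share of total richness that the average single sampling unit
#' misses.  0 when every unit holds all taxa; approaches 1 when units
#' share nothing.
#'
#' @param gamma total richness across units (> 0).
#' @param alpha_bar mean per-unit richness (<= gamma).
#' @return turnover fraction in \[0, 1\].
#' @export
turnover_value <- function(gamma, alpha_bar) {
  if (gamma <= 0) stop("turnover undefined for gamma = 0")
  if (alpha_bar < 0 || alpha_bar > gamma)
    stop("need 0 <= alpha_bar <= gamma")
  (gamma - alpha_bar) / gamma
}

#' Diversity summary of a detection matrix
#'
#' Total richness gamma (taxa detected in at least one unit), mean
#' per-unit richness alpha-bar, and their turnover
#' `(gamma - alpha_bar) / gamma`.
#'
#' @param m a [detection_matrix()].
#' @return list of class `diversity_summary`: `gamma`, `alpha_bar`,
#'   `turnover`.
#' @export
diversity_summary <- function(m) {
  stopifnot(inherits(m, "detection_matrix"))
  gamma <- sum(rowSums(m$y) > 0)
  alpha_bar <- mean(colSums(m$y))
  structure(list(gamma = gamma, alpha_bar = alpha_bar,
                 turnover = turnover_value(gamma, alpha_bar)),
            class = "diversity_summary")
}

#' @rdname diversity_summary
#' @export
turnover <- function(m) diversity_summary(m)

#' Bootstrap species-accumulation curve
#'
#' Each bootstrap iteration draws a sequence of `M` units uniformly with
#' replacement and records the cumulative union richness along the
#' sequence, so the first `m` entries are exactly `m` units resampled
#' with replacement and every iteration's curve — hence the mean curve —
#' is non-decreasing in effort.  Means and percentile 95% confidence
#' bands are taken over `n_iter` iterations.  A true bootstrap (with
#' replacement), not permutation rarefaction.
#'
#' @param m a [detection_matrix()].
#' @param n_iter bootstrap iterations; default 1000.
#' @param seed integer seed.
#' @return object of class `accumulation_curve`: data.frame `curve`
#'   (`m`, `mean`, `lo`, `hi`) plus `n_iter` and `seed`.
#' @export
bootstrap_accumulation <- function(m, n_iter = 1000, seed = 1) {
  stopifnot(inherits(m, "detection_matrix"), n_iter >= 1)
  y <- m$y > 0
  M <- ncol(y)
  set.seed(seed)
  rich <- matrix(0L, n_iter, M)      # iterations x effort
  for (it in seq_len(n_iter)) {
    seq_units <- sample.int(M, M, replace = TRUE)
    det <- rep(FALSE, nrow(y))
    for (j in seq_len(M)) {
      det <- det | y[, seq_units[j]]
      rich[it, j] <- sum(det)
    }
  }
  qs <- apply(rich, 2, stats::quantile, c(0.025, 0.975), names = FALSE)
  curve <- data.frame(m = seq_len(M), mean = colMeans(rich),
                      lo = qs[1, ], hi = qs[2, ])
  structure(list(curve = curve, n_iter = n_iter, seed = seed),
            class = "accumulation_curve")
}

#' Cost-efficiency curve: richness per dollar invested
#'
#' Re-indexes an accumulation curve by cumulative survey cost: deploying
#' `m` units costs `m` times the per-unit cost from the cost model.  A
#' zero-effort origin row (cost 0, richness 0) is included.
#'
#' @param ac an [bootstrap_accumulation()] curve.
#' @param cost a one-row [cost_model()] / `cost_table` for the matching
#'   method and year.
#' @return data.frame of class `cost_curve`: `m`, `cost` (USD), `mean`,
#'   `lo`, `hi`.
#' @export
cost_curve <- function(ac, cost) {
  stopifnot(inherits(ac, "accumulation_curve"),
            inherits(cost, "cost_table"), nrow(cost) == 1)
  if (cost$per_unit <= 0) stop("per-unit cost must be positive")
  out <- rbind(data.frame(m = 0, mean = 0, lo = 0, hi = 0),
               ac$curve[c("m", "mean", "lo", "hi")])
  out$cost <- out$m * cost$per_unit
  out <- out[c("m", "cost", "mean", "lo", "hi")]
  class(out) <- c("cost_curve", "data.frame")
  out
}

#' Restrict a detection matrix to camera-detectable taxa
#'
#' Drops rows for taxa a camera-trap survey cannot detect or identify
#' (volant mammals, most small rodents, semi-aquatic species), so that
#' eDNA and camera diversity compare on the same taxon set.
#'
#' @param m a [detection_matrix()] whose `taxa` table carries the
#'   `camera_detectable` flag, or supply `taxa` explicitly.
#' @param taxa optional [taxon_table()] overriding `m$taxa`.
#' @return the filtered [detection_matrix()] (units unchanged).
#' @export
restrict_to_camera_detectable <- function(m, taxa = NULL) {
  stopifnot(inherits(m, "detection_matrix"))
  if (is.null(taxa)) taxa <- m$taxa
  if (is.null(taxa)) stop("no taxon table with camera_detectable flags")
  flag <- taxa$camera_detectable[match(rownames(m$y), taxa$name)]
  if (anyNA(flag))
    stop("camera_detectable flag missing for: ",
         paste(rownames(m$y)[is.na(flag)], collapse = ", "))
  keep <- which(flag)
  if (length(keep) == 0)
    warning("no camera-detectable taxa remain")
  m$y <- m$y[keep, , drop = FALSE]
  if (!is.null(m$taxa))
    m$taxa <- m$taxa[m$taxa$name %in% rownames(m$y), , drop = FALSE]
  m
}
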