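# GLM machinery for the covariate analyses: Poisson regression with log
# link for per-sample species richness, binomial logistic regression for
# per-species detection, fitted by iteratively reweighted least squares
# written out in full so that the likelihood, covariance and AICc used in
# model selection are exactly the quantities documented here.  Candidate
# models are all additive subsets of the covariate list, ranked by AICc;
# subsets within 2 AICc of the best are treated as equivalent.

.glm_families <- c("poisson", "binomial")

.link_inv <- function(eta, family)
  switch(family, poisson = exp(eta), binomial = stats::plogis(eta))

# d mu / d eta
.mu_eta <- function(eta, family)
  switch(family,
         poisson = exp(eta),
         binomial = stats::plogis(eta) * stats::plogis(-eta))

.exact_loglik <- function(y, mu, family)
  switch(family,
         poisson = sum(stats::dpois(y, mu, log = TRUE)),
         binomial = sum(stats::dbinom(y, 1, mu, log = TRUE)))

#' Fit a GLM by iteratively reweighted least squares
#'
#' Matrix-level fitting routine behind [fit_glm()].  Supports Poisson
#' (log link) responses — per-sample species counts — and binary binomial
#' (logit link) responses — per-species detections.  Iterates weighted
#' least squares until the largest coefficient change falls below `tol`
#' (default 1e-8) or `max_iter` iterations; the reported log-likelihood
#' uses the exact mass functions (the Poisson includes the `-log y!`
#' term) and the covariance is the inverse Fisher information at
#' convergence.
#'
#' @param X design matrix (full column rank; the rank check names
#'   collinear columns on failure).
#' @param y response vector: non-negative counts (Poisson) or 0/1
#'   (binomial).
#' @param family `"poisson"` or `"binomial"`.
#' @param tol convergence tolerance on `max |delta beta|`.
#' @param max_iter iteration cap; exceeding it returns
#'   `converged = FALSE` rather than an error.
#' @return object of class `glm_fit`: `coefficients`, `vcov`, `logLik`,
#'   `k`, `n`, `converged`, `fitted`, `family`.
#' @export
irls_fit <- function(X, y, family = c("poisson", "binomial"),
                     tol = 1e-8, max_iter = 100L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (family == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial responses must be 0/1")
  if (family == "poisson" && any(y < 0))
    stop("poisson responses must be non-negative")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  eta <- switch(family,
                poisson = log(y + 0.1),
                binomial = stats::qlogis((y + 0.5) / 2))
  beta <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- .link_inv(eta, family)
    dmu <- .mu_eta(eta, family)
    w <- switch(family, poisson = mu, binomial = dmu)   # canonical links
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / pmax(dmu, 1e-10)
    sw <- sqrt(w)
    fit <- qr(sw * X)
    beta_new <- qr.coef(fit, sw * z)
    if (!is.null(beta) && max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    eta <- drop(X %*% beta)
  }
  eta <- drop(X %*% beta)
  mu <- .link_inv(eta, family)
  w <- pmax(switch(family, poisson = mu, binomial = .mu_eta(eta, family)),
            1e-10)
  R <- qr.R(qr(sqrt(w) * X))
  vcov <- chol2inv(R)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(drop(beta), colnames(X)),
                 vcov = vcov,
                 logLik = .exact_loglik(y, mu, family),
                 k = ncol(X), n = nrow(X), converged = converged,
                 fitted = mu, family = family),
            class = "glm_fit")
}

#' Fit a GLM from a model formula
#'
#' Formula interface over [irls_fit()]; factors use treatment contrasts
#' (first level as reference), so with diet coded as
#' `factor(diet, levels = c("carnivore", ...))` the carnivore class is the
#' baseline the omnivore/herbivore effects are measured against.
#'
#' @param formula model formula.
#' @param data data.frame holding response and covariates.
#' @param family `"poisson"` or `"binomial"`.
#' @param ... passed to [irls_fit()].
#' @return a `glm_fit` carrying `terms` and factor levels for prediction.
#' @export
fit_glm <- function(formula, data, family = c("poisson", "binomial"), ...) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data, drop.unused.levels = TRUE)
  tt <- attr(mf, "terms")
  X <- stats::model.matrix(tt, mf)
  fit <- irls_fit(X, stats::model.response(mf), family, ...)
  fit$terms <- tt
  fit$xlevels <- stats::.getXlevels(tt, mf)
  fit$formula <- formula
  fit
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("glm_fit (", x$family, "), n = ", x$n, ", k = ", x$k,
      ", logLik = ", format(x$logLik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param fit a `glm_fit`, or a log-likelihood scalar when `k` and `n`
#'   are supplied.
#' @param k,n parameter count and sample size (taken from `fit` when it
#'   is a `glm_fit`).
#' @return AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "glm_fit")) {
    ll <- fit$logLik; k <- fit$k; n <- fit$n
  } else ll <- fit
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Wald coefficient table with 95% confidence intervals
#'
#' @param fit a `glm_fit`.
#' @return data.frame with `term`, `beta`, `se`, `ci_low`, `ci_high`.
#' @export
coef_table <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  data.frame(term = names(fit$coefficients),
             beta = unname(fit$coefficients), se = unname(se),
             ci_low = unname(fit$coefficients - 1.96 * se),
             ci_high = unname(fit$coefficients + 1.96 * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' All-subsets model selection by AICc
#'
#' Fits every additive subset of the candidate covariates (factors enter
#' and leave as whole blocks), including the intercept-only null model,
#' and ranks them by AICc.  Subsets whose fit does not converge, or for
#' which AICc is undefined (`n <= k + 1`), are kept in the table with an
#' `NA` AICc.  Competing models within 2 AICc of the best are flagged as
#' equivalent.
#'
#' @param response name of the response column in `data`.
#' @param candidates character vector (<= 12) of candidate covariate
#'   terms; each may be any valid formula term, e.g. `"log(body_mass)"`.
#' @param data data.frame.
#' @param family `"poisson"` or `"binomial"`.
#' @param ... passed to [fit_glm()].
#' @return object of class `model_selection`: `table` (covariates, k,
#'   logLik, AICc, dAICc, equivalent, converged; sorted by AICc), `best`
#'   (the best `glm_fit`) and `fits` (all fits, in table order).
#' @export
all_subsets <- function(response, candidates, data,
                        family = c("poisson", "binomial"), ...) {
  family <- match.arg(family)
  p <- length(candidates)
  if (p > 12) stop("at most 12 candidate covariates (2^12 model cap)")
  if (anyDuplicated(candidates)) stop("duplicated candidate covariates")
  subsets <- lapply(0:p, function(sz)
    if (sz == 0) list(character(0)) else
      utils::combn(candidates, sz, simplify = FALSE))
  subsets <- do.call(c, subsets)
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    f <- stats::reformulate(if (length(s)) s else "1", response)
    fit <- tryCatch(fit_glm(f, data, family, ...), error = function(e) e)
    label <- if (length(s)) paste(s, collapse = " + ") else "(null)"
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(covariates = label, k = NA_integer_,
                              logLik = NA_real_, AICc = NA_real_,
                              converged = FALSE, stringsAsFactors = FALSE)
      next
    }
    ic <- if (fit$converged && fit$n - fit$k - 1 > 0) aicc(fit) else
      NA_real_
    rows[[i]] <- data.frame(covariates = label, k = fit$k,
                            logLik = fit$logLik, AICc = ic,
                            converged = fit$converged,
                            stringsAsFactors = FALSE)
    fits[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$AICc, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  rownames(tab) <- NULL
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$equivalent <- !is.na(tab$dAICc) & tab$dAICc < 2
  structure(list(table = tab, best = fits[[1]], fits = fits),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Predict from a fitted GLM with delta-method standard errors
#'
#' Linear predictor `eta = x' beta` with `SE(eta) = sqrt(x' Sigma x)`;
#' response-scale mean is the inverse link of `eta` and its SE follows by
#' the delta method.
#'
#' @param fit a `glm_fit` from [fit_glm()] (or [irls_fit()], in which
#'   case `newdata` must be a design matrix).
#' @param newdata data.frame of covariate rows (or a design matrix).
#' @return data.frame with `fit` (response-scale mean) and `se`.
#' @export
predict_glm <- function(fit, newdata) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.matrix(newdata)) {
    X <- newdata
  } else {
    if (is.null(fit$terms))
      stop("fit has no terms; supply a design matrix")
    tt <- stats::delete.response(fit$terms)
    mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
    X <- stats::model.matrix(tt, mf)
  }
  eta <- drop(X %*% fit$coefficients)
  se_eta <- sqrt(rowSums((X %*% fit$vcov) * X))
  mu <- .link_inv(eta, fit$family)
  se <- abs(.mu_eta(eta, fit$family)) * se_eta
  data.frame(fit = mu, se = se)
}

#' Mean camera detection rates in the catchment of each eDNA site
#'
#' For every taxon and eDNA sampling site, the mean over all camera traps
#' in the site's upstream catchment of independent pictures per trap-day.
#' Cameras that never photographed a taxon contribute a rate of zero for
#' it.
#'
#' @param records a [camera_records()] table (one deployment per camera
#'   site).
#' @param membership named list mapping each eDNA site id to the camera
#'   site ids inside its catchment (a GIS input, not computed here).
#' @param taxa optional taxon set; defaults to all taxa in `records`.
#' @return data.frame of class `camera_rate_table` with `taxon`,
#'   `edna_site`, `rate` (detections per trap-day).
#' @export
camera_rates <- function(records, membership, taxa = NULL) {
  stopifnot(inherits(records, "camera_records"), is.list(membership))
  if (any(lengths(membership) == 0))
    stop("empty catchment membership for eDNA site(s): ",
         paste(names(membership)[lengths(membership) == 0], collapse = ", "))
  cams <- sort(unique(records$site_id))
  unknown <- setdiff(unlist(membership), cams)
  if (length(unknown))
    stop("membership refers to unknown camera site(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(taxa)) taxa <- sort(unique(records$taxon))
  trap_days <- tapply(records$trap_days, records$site_id,
                      function(x) unique(x)[1])
  rate <- matrix(0, length(taxa), length(cams),
                 dimnames = list(taxa, cams))
  rec <- records[records$taxon %in% taxa, , drop = FALSE]
  rate[cbind(match(rec$taxon, taxa), match(rec$site_id, cams))] <-
    rec$n_pictures / rec$trap_days
  out <- do.call(rbind, lapply(names(membership), function(s) {
    data.frame(taxon = taxa, edna_site = s,
               rate = rowMeans(rate[, membership[[s]], drop = FALSE]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  class(out) <- c("camera_rate_table", "data.frame")
  out
}

#' Predicted eDNA detection curves over a camera-rate gradient
#'
#' Response curves in the style of a taxonomic detection-curve figure:
#' for each group (or diet) level and each rainfall value, the predicted
#' site-level eDNA detection probability (with delta-method SE) over a
#' grid of mean camera detection rates, holding the remaining covariates
#' at reference values (default 60 L filtered, 500 km2 catchment).
#'
#' @param fit a binomial `glm_fit` whose model includes `rate_var`.
#' @param rate_grid numeric grid of camera detection rates (per trap-day).
#' @param group_var optional name of the factor column (e.g. `"group"` or
#'   `"diet"`); each of `groups` must be a level seen by the fit.
#' @param groups factor levels to predict for; default all fitted levels.
#' @param rain rainfall values (mm) to contrast; default `c(0, 30)`.
#' @param at named list of fixed values for the remaining covariates;
#'   defaults supply `volume_l = 60` and `catchment_km2 = 500`.
#' @param rate_var,rain_var column names of the camera-rate and rainfall
#'   covariates.
#' @return data.frame with `group`, `rain`, `rate`, `fit`, `se`.
#' @export
detection_curves <- function(fit, rate_grid, group_var = NULL,
                             groups = NULL, rain = c(0, 30),
                             at = list(volume_l = 60, catchment_km2 = 500),
                             rate_var = "camera_rate",
                             rain_var = "rain_mm") {
  stopifnot(inherits(fit, "glm_fit"), fit$family == "binomial")
  vars <- all.vars(stats::delete.response(fit$terms))
  if (!rate_var %in% vars)
    stop("fitted model does not include '", rate_var, "'")
  if (!is.null(group_var)) {
    lev <- fit$xlevels[[group_var]]
    if (is.null(lev)) stop("'", group_var, "' is not a factor in the fit")
    if (is.null(groups)) groups <- lev
    bad <- setdiff(groups, lev)
    if (length(bad))
      stop("level(s) absent from fit: ", paste(bad, collapse = ", "))
  } else groups <- NA_character_
  grid <- expand.grid(rate = rate_grid, rain = rain, group = groups,
                      stringsAsFactors = FALSE)
  nd <- data.frame(grid$rate, grid$rain)
  names(nd) <- c(rate_var, rain_var)
  if (!is.null(group_var)) nd[[group_var]] <- grid$group
  for (v in names(at)) nd[[v]] <- at[[v]]
  pr <- predict_glm(fit, nd)
  data.frame(group = grid$group, rain = grid$rain, rate = grid$rate,
             fit = pr$fit, se = pr$se, stringsAsFactors = FALSE)
}
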