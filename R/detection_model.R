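# Effort-standardised detection probabilities.  Each taxon x method x year
# gets a single pooled detection probability p60, defined per reference
# sampling unit (60 L of filtered stream water, or 60 camera-trap days).
# A unit of effort e detects the taxon with probability
#   pi(e) = 1 - (1 - p60)^(e / 60),
# the unique memoryless scaling consistent with a "per 60 L" probability
# across heterogeneous volumes.  Inference is Bayesian with a Beta prior:
# a deterministic grid posterior (quadrature) and a random-walk Metropolis
# sampler on the logit scale give interchangeable summaries; the grid is
# the default engine and the oracle for the sampler.

# log(1 - exp(x)) for x <= 0, numerically stable
.log1mexp <- function(x) {
  out <- x
  lo <- x < -log(2)
  out[lo] <- log1p(-exp(x[lo]))
  out[!lo] <- log(-expm1(x[!lo]))
  out[x == -Inf] <- 0
  out
}

#' Scale a standardised detection probability to another effort
#'
#' `effort_scaled_prob(p60, e)` is the probability of at least one
#' detection in a unit of effort `e`, given probability `p60` per `unit`
#' of effort: `1 - (1 - p60)^(e/unit)`.  Strictly increasing in both
#' arguments, equal to `p60` at `e = unit`, and self-consistent under
#' splitting (two 30 L samples miss a taxon exactly as often as one 60 L
#' sample).
#'
#' @param p60 probability per reference unit, in \[0, 1\].
#' @param effort positive effort (litres or trap-days); vectorised.
#' @param unit reference effort; default 60.
#' @return detection probability at `effort`.
#' @export
effort_scaled_prob <- function(p60, effort, unit = 60) {
  if (any(p60 < 0 | p60 > 1)) stop("p60 must lie in [0, 1]")
  if (any(effort <= 0)) stop("effort must be positive")
  -expm1(effort / unit * log1p(-p60))
}

#' Bernoulli log-likelihood of a pooled standardised detection probability
#'
#' Sum over sampling units of `y_j log pi_j + (1 - y_j) log(1 - pi_j)`
#' with `pi_j = effort_scaled_prob(p60, effort_j, unit)`.  Returns `-Inf`
#' when the data are impossible under `p60` (e.g. a detection with
#' `p60 = 0`).
#'
#' @param p60 probability per reference unit.
#' @param y binary 0/1 detection vector.
#' @param effort positive effort per unit, same length as `y`.
#' @param unit reference effort; default 60.
#' @return log-likelihood (scalar).
#' @export
detection_loglik <- function(p60, y, effort, unit = 60) {
  stopifnot(length(y) == length(effort), all(y %in% c(0, 1)))
  if (p60 < 0 || p60 > 1) stop("p60 must lie in [0, 1]")
  if (any(effort <= 0)) stop("effort must be positive")
  log_q <- effort / unit * log1p(-p60)   # log P(miss)
  log_pi <- .log1mexp(log_q)
  sum(ifelse(y == 1, log_pi, log_q))
}

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Grid (quadrature) posterior for a standardised detection probability
#'
#' Deterministic posterior of `p60` under a Beta prior on a uniform grid
#' over \[0, 1\]; the density, posterior mean and central 95% credible
#' interval are obtained by trapezoid integration.  With all efforts equal
#' to `unit` and a uniform prior this reproduces the conjugate
#' Beta(1 + k, 1 + n - k) posterior.
#'
#' @inheritParams detection_loglik
#' @param prior Beta hyperparameters `c(a, b)`; default uniform `c(1, 1)`.
#' @param grid_size number of grid points (>= 101); default 4001.
#' @return object of class `grid_posterior`: `p`, `density`, `mean`, `ci`
#'   (2.5 and 97.5 posterior percentiles).
#' @export
posterior_grid <- function(y, effort, prior = c(1, 1), grid_size = 4001,
                           unit = 60) {
  stopifnot(grid_size >= 101, length(prior) == 2, all(prior > 0))
  stopifnot(length(y) == length(effort), all(y %in% c(0, 1)),
            all(effort > 0))
  p <- seq(0, 1, length.out = grid_size)
  e <- effort / unit
  log_q <- outer(log1p(-p), e)              # grid x units, log P(miss)
  log_pi <- .log1mexp(log_q)
  # cap -Inf so that 0 * (-Inf) cannot poison the matrix products; the
  # capped value still underflows to posterior weight zero
  log_q[log_q == -Inf] <- -1e12
  log_pi[log_pi == -Inf] <- -1e12
  lp <- drop(log_q %*% (1 - y) + log_pi %*% y)
  if (prior[1] != 1) lp <- lp + (prior[1] - 1) * pmax(log(p), -1e12)
  if (prior[2] != 1) lp <- lp + (prior[2] - 1) * pmax(log1p(-p), -1e12)
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(w)] <- 0
  z <- .trapz(p, w)
  dens <- w / z
  m <- .trapz(p, p * dens)
  cdf <- c(0, cumsum((dens[-1] + dens[-grid_size]) / 2 * diff(p)))
  cdf <- cdf / cdf[grid_size]
  ci <- vapply(c(0.025, 0.975), function(q) {
    i <- which(cdf >= q)[1]
    if (i == 1) return(p[1])
    # linear interpolation between bracketing grid points
    p[i - 1] + (q - cdf[i - 1]) / (cdf[i] - cdf[i - 1]) * (p[i] - p[i - 1])
  }, 0)
  structure(list(p = p, density = dens, mean = m,
                 ci = c(lower = ci[1], upper = ci[2])),
            class = "grid_posterior")
}

#' MCMC settings for the Metropolis sampler
#'
#' @param n_iter iterations per chain (post-burn draws are
#'   `n_iter - n_burn`).
#' @param n_burn burn-in iterations discarded per chain.
#' @param n_chains number of chains, started from spread initial values.
#' @param proposal_sd random-walk standard deviation on the logit scale.
#' @param seed integer seed making summaries bit-reproducible.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 20000, n_burn = 5000, n_chains = 3,
                        proposal_sd = 0.8, seed = 1) {
  stopifnot(n_iter > n_burn, n_burn >= 0, n_chains >= 1)
  if (proposal_sd <= 0) stop("proposal_sd must be positive")
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 n_chains = as.integer(n_chains), proposal_sd = proposal_sd,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# effective sample size from the truncated autocorrelation sum
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  r <- stats::acf(x, lag.max = min(1000L, n - 1L), plot = FALSE)$acf[-1]
  neg <- which(r < 0)
  k <- if (length(neg)) neg[1] - 1L else length(r)
  n / (1 + 2 * sum(r[seq_len(k)]))
}

#' Random-walk Metropolis sampler for a standardised detection probability
#'
#' Samples the posterior of `p60` under a Beta prior by random-walk
#' Metropolis on `theta = logit(p60)`; the log target includes the
#' Jacobian of the transform, so the chain targets the posterior of `p60`
#' itself.  All-zero and all-one data are legal (the posterior
#' concentrates near a boundary).
#'
#' @inheritParams posterior_grid
#' @param cfg an [mcmc_config()].
#' @return object of class `detection_posterior`: `draws` (pooled
#'   post-burn draws of `p60`), `mean`, `ci`, `acceptance_rate`, `ess`.
#' @export
sample_posterior <- function(y, effort, prior = c(1, 1),
                             cfg = mcmc_config(), unit = 60) {
  stopifnot(inherits(cfg, "mcmc_config"), length(prior) == 2,
            all(prior > 0))
  a <- prior[1]; b <- prior[2]
  # target on theta: loglik(p) + (a-1)log p + (b-1)log(1-p) + log|dp/dtheta|
  #                = loglik(p) + a log p + b log(1-p) + const
  log_target <- function(theta) {
    detection_loglik(stats::plogis(theta), y, effort, unit) +
      a * stats::plogis(theta, log.p = TRUE) +
      b * stats::plogis(-theta, log.p = TRUE)
  }
  set.seed(cfg$seed)
  inits <- stats::qlogis(rep_len(c(0.2, 0.5, 0.8, 0.35, 0.65),
                                 cfg$n_chains))
  draws <- vector("list", cfg$n_chains)
  ess <- numeric(cfg$n_chains)
  n_acc <- 0L
  for (ch in seq_len(cfg$n_chains)) {
    theta <- inits[ch]
    lp <- log_target(theta)
    out <- numeric(cfg$n_iter - cfg$n_burn)
    steps <- stats::rnorm(cfg$n_iter, 0, cfg$proposal_sd)
    logu <- log(stats::runif(cfg$n_iter))
    for (i in seq_len(cfg$n_iter)) {
      prop <- theta + steps[i]
      lpp <- log_target(prop)
      if (logu[i] < lpp - lp) {
        theta <- prop; lp <- lpp; n_acc <- n_acc + 1L
      }
      if (i > cfg$n_burn) out[i - cfg$n_burn] <- theta
    }
    draws[[ch]] <- stats::plogis(out)
    ess[ch] <- .ess(draws[[ch]])
  }
  p <- unlist(draws)
  structure(list(draws = p, mean = mean(p),
                 ci = stats::quantile(p, c(0.025, 0.975), names = FALSE),
                 acceptance_rate = n_acc / (cfg$n_iter * cfg$n_chains),
                 ess = sum(ess)),
            class = "detection_posterior")
}

#' Estimate standardised detection probabilities for every taxon
#'
#' One pooled estimate per taxon of a [detection_matrix()], standardised
#' to the reference effort.  Engine `"grid"` (default) uses the
#' deterministic quadrature posterior; `"mcmc"` uses the Metropolis
#' sampler.
#'
#' @param m a [detection_matrix()].
#' @param method label recorded in the output, e.g. `"edna_spatial"`,
#'   `"edna_catchment"`, `"camera"`.
#' @param year survey year recorded in the output.
#' @param prior Beta hyperparameters; default uniform.
#' @param engine `"grid"` or `"mcmc"`.
#' @param cfg an [mcmc_config()], used when `engine = "mcmc"`.
#' @param unit reference effort (60 L or 60 trap-days).
#' @param grid_size grid points for the quadrature engine.
#' @return `data.frame` of class `detection_estimates` with columns
#'   `taxon`, `method`, `year`, `p60_mean`, `ci_low`, `ci_high`,
#'   `n_units`, `ess`.
#' @export
estimate_detection <- function(m, method, year = NA_integer_,
                               prior = c(1, 1),
                               engine = c("grid", "mcmc"),
                               cfg = mcmc_config(), unit = 60,
                               grid_size = 4001) {
  stopifnot(inherits(m, "detection_matrix"), nrow(m$y) > 0)
  engine <- match.arg(engine)
  res <- lapply(seq_len(nrow(m$y)), function(i) {
    y <- m$y[i, ]
    if (engine == "grid") {
      g <- posterior_grid(y, m$effort, prior, grid_size, unit)
      c(g$mean, g$ci, NA_real_)
    } else {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + i - 1L
      s <- sample_posterior(y, m$effort, prior, cfg_i, unit)
      c(s$mean, s$ci, s$ess)
    }
  })
  res <- do.call(rbind, res)
  out <- data.frame(taxon = rownames(m$y), method = method, year = year,
                    p60_mean = res[, 1], ci_low = res[, 2],
                    ci_high = res[, 3], n_units = ncol(m$y),
                    ess = res[, 4], stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("detection_estimates", "data.frame")
  out
}

#' Build the camera detection matrix from camera records
#'
#' A taxon counts as detected at a camera site when it was photographed at
#' least once during the season; effort is the site's active trap-days,
#' used with `unit = 60` days in [estimate_detection()].
#'
#' @param records a [camera_records()] table.
#' @param year optional year filter.
#' @param taxa optional character vector fixing the taxon set (taxa with
#'   no record get all-zero rows).
#' @return a [detection_matrix()].
#' @export
cameras_to_matrix <- function(records, year = NULL, taxa = NULL) {
  stopifnot(inherits(records, "camera_records"))
  d <- records
  if (!is.null(year)) d <- d[d$year == year, , drop = FALSE]
  if (nrow(d) == 0) stop("no camera records", if (!is.null(year))
    paste0(" for year ", year))
  if (any(d$trap_days <= 0)) stop("trap_days must be positive")
  sites <- sort(unique(d$site_id))
  if (is.null(taxa)) taxa <- sort(unique(d$taxon))
  y <- matrix(0L, length(taxa), length(sites),
              dimnames = list(taxa, sites))
  pos <- d[d$n_pictures > 0 & d$taxon %in% taxa, , drop = FALSE]
  y[cbind(match(pos$taxon, taxa), match(pos$site_id, sites))] <- 1L
  eff <- tapply(d$trap_days, d$site_id, function(x) unique(x)[1])
  detection_matrix(y, as.numeric(eff[sites]))
}
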