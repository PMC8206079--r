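test_that("intercept-only fits recover closed-form MLEs", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "(Intercept)"))
  f <- irls_fit(X, c(3, 5, 7), "poisson")
  expect_equal(unname(f$coefficients), log(5), tolerance = 1e-8)
  expect_true(f$converged)
  X4 <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  f2 <- irls_fit(X4, c(1, 0, 1, 1), "binomial")
  expect_equal(unname(f2$coefficients), log(3), tolerance = 1e-8)
})

test_that("IRLS matches independent likelihood maximisers on random
           designs", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 40
    X <- cbind(1, rnorm(n), runif(n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    for (family in c("poisson", "binomial")) {
      beta_true <- c(0.3, 0.6, -0.8)
      eta <- drop(X %*% beta_true)
      y <- if (family == "poisson") rpois(n, exp(eta)) else
        rbinom(n, 1, plogis(eta))
      if (family == "binomial" && (sum(y) < 3 || sum(y) > n - 3)) next
      f <- irls_fit(X, y, family)
      # derivative-free/quasi-Newton oracle on the exact likelihood
      expect_lt(max(abs(unname(f$coefficients) -
                          nm_glm_oracle(X, y, family))), 1e-6)
      # second independent route: stats::glm
      expect_equal(unname(f$coefficients),
                   unname(coef(glm(y ~ X - 1, family = family))),
                   tolerance = 1e-7)
      g <- glm(y ~ X - 1, family = family,
               control = glm.control(epsilon = 1e-12))
      expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-8)
      expect_equal(unname(sqrt(diag(f$vcov))),
                   unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
    }
  }
})

test_that("rank-deficient designs fail with the collinear column named", {
  X <- cbind("(Intercept)" = 1, a = 1:10, b = 2 * (1:10))
  expect_error(irls_fit(X, rpois(10, 3), "poisson"), "collinear.*b")
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-10, k = 2, n = 10), 20 + 4 + 12 / 7,
               tolerance = 1e-10)
  expect_equal(aicc(-10, k = 0, n = 10), 20)
  # approaches plain AIC for huge n
  expect_equal(aicc(-10, k = 3, n = 1e8), 20 + 6, tolerance = 1e-6)
  expect_error(aicc(-10, k = 9, n = 10), "n > k")
})

test_that("all-subsets enumerates every additive model including the null", {
  set.seed(5)
  d <- data.frame(y = rpois(30, 4), a = rnorm(30), b = rnorm(30))
  ms <- all_subsets("y", c("a", "b"), d, "poisson")
  expect_equal(nrow(ms$table), 4)
  expect_setequal(ms$table$covariates, c("(null)", "a", "b", "a + b"))
  expect_equal(ms$table$dAICc[1], 0)
  expect_true(all(diff(ms$table$AICc[!is.na(ms$table$AICc)]) >= 0))
})

test_that("a planted covariate is recovered by AICc selection", {
  set.seed(9)
  n <- 500
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- rpois(n, exp(0.5 + 1 * d$a))
  ms <- all_subsets("y", c("a", "b", "c"), d, "poisson")
  expect_match(ms$table$covariates[1], "a")
  # binomial flavour
  d$z <- rbinom(n, 1, plogis(-0.5 + 1.5 * d$b))
  ms2 <- all_subsets("z", c("a", "b", "c"), d, "binomial")
  expect_match(ms2$table$covariates[1], "b")
})

test_that("AICc ordering is invariant to affine rescaling of covariates", {
  set.seed(17)
  n <- 80
  d <- data.frame(a = rnorm(n), b = runif(n, 10, 20))
  d$y <- rpois(n, exp(0.3 + 0.5 * d$a - 0.05 * d$b))
  m1 <- all_subsets("y", c("a", "b"), d, "poisson")
  d2 <- transform(d, a = 100 * a + 3, b = (b - 15) / 2)
  m2 <- all_subsets("y", c("a", "b"), d2, "poisson")
  expect_equal(m1$table$covariates, m2$table$covariates)
  expect_equal(m1$table$AICc, m2$table$AICc, tolerance = 1e-6)
})

test_that("delta-method prediction matches closed forms", {
  fit <- structure(list(coefficients = c("(Intercept)" = log(5)),
                        vcov = matrix(0.04, 1, 1,
                                      dimnames = list("(Intercept)",
                                                      "(Intercept)")),
                        family = "poisson", k = 1L, n = 10L,
                        logLik = 0, converged = TRUE),
                   class = "glm_fit")
  pr <- predict_glm(fit, matrix(1, 1, 1))
  expect_equal(pr$fit, 5)
  expect_equal(pr$se, 5 * 0.2)
  # zero-variance fit -> SE 0
  fit$vcov[] <- 0
  expect_equal(predict_glm(fit, matrix(1, 1, 1))$se, 0)
  # logistic eta = 0 -> mean 0.5
  fitb <- fit
  fitb$coefficients[] <- 0
  fitb$family <- "binomial"
  expect_equal(predict_glm(fitb, matrix(1, 1, 1))$fit, 0.5)
})

test_that("formula fits predict correctly on new factor data", {
  set.seed(23)
  d <- data.frame(diet = factor(rep(c("carnivore", "omnivore",
                                      "herbivore"), each = 40),
                                levels = c("carnivore", "omnivore",
                                           "herbivore")),
                  volume_l = runif(120, 25, 80))
  d$y <- rbinom(120, 1, plogis(-1 + 0.8 * (d$diet != "carnivore") +
                                 0.02 * d$volume_l))
  fit <- fit_glm(y ~ diet + volume_l, d, "binomial")
  g <- glm(y ~ diet + volume_l, binomial(), d)
  expect_equal(fit$coefficients, coef(g), tolerance = 1e-7)
  nd <- data.frame(diet = "herbivore", volume_l = 60)
  pr <- predict_glm(fit, nd)
  expect_equal(pr$fit,
               unname(predict(g, nd, type = "response")),
               tolerance = 1e-7)
  ct <- coef_table(fit)
  expect_equal(ct$ci_high - ct$beta, 1.96 * ct$se)
})

test_that("camera rates average pictures per trap-day over member cameras", {
  rec <- camera_records(data.frame(
    site_id = c("c1", "c2", "c2"), year = 2018,
    trap_days = c(90, 60, 60),
    taxon = c("Alces alces", "Alces alces", "Lepus americanus"),
    n_pictures = c(9, 18, 6), n_detection_days = c(9, 15, 6)))
  rt <- camera_rates(rec, list(e1 = c("c1", "c2"), e2 = "c1"))
  get <- function(tx, s) rt$rate[rt$taxon == tx & rt$edna_site == s]
  expect_equal(get("Alces alces", "e2"), 0.1)       # 9 / 90
  expect_equal(get("Alces alces", "e1"), (0.1 + 0.3) / 2)
  # never photographed at the member camera -> 0
  expect_equal(get("Lepus americanus", "e2"), 0)
  expect_error(camera_rates(rec, list(e1 = character(0))), "empty")
})

test_that("detection curves are monotone in rate and ordered by rain when
           the coefficients are positive", {
  set.seed(41)
  n <- 400
  d <- data.frame(camera_rate = runif(n, 0, 1),
                  rain_mm = sample(c(0, 10, 30), n, TRUE),
                  volume_l = runif(n, 25, 80),
                  catchment_km2 = runif(n, 50, 600),
                  group = factor(sample(c("ungulates", "felids"), n, TRUE)))
  eta <- -2 + 2.5 * d$camera_rate + 0.04 * d$rain_mm +
    0.01 * d$volume_l + 0.001 * d$catchment_km2 +
    0.8 * (d$group == "ungulates")
  d$y <- rbinom(n, 1, plogis(eta))
  fit <- fit_glm(y ~ camera_rate + rain_mm + volume_l + catchment_km2 +
                   group, d, "binomial")
  cv <- detection_curves(fit, rate_grid = seq(0, 1, 0.1),
                         group_var = "group")
  for (gr in unique(cv$group)) for (rn in unique(cv$rain)) {
    sub <- cv[cv$group == gr & cv$rain == rn, ]
    expect_true(all(diff(sub$fit[order(sub$rate)]) > 0))
  }
  # rain = 30 curve sits above rain = 0 everywhere (positive rain effect)
  w <- cv[cv$group == "ungulates", ]
  expect_true(all(w$fit[w$rain == 30] >= w$fit[w$rain == 0]))
  expect_error(detection_curves(fit, 0:1, group_var = "group",
                                groups = "bats"), "absent")
})
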