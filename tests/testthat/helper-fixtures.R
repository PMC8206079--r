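# In-code fixtures shared across the suite.

# small detection matrix with known structure
toy_matrix <- function() {
  y <- rbind(Alces_alces = c(1L, 0L, 1L),
             Lepus_americanus = c(0L, 1L, 1L))
  colnames(y) <- c("s1", "s2", "s3")
  detection_matrix(y, c(s1 = 30, s2 = 60, s3 = 80))
}

# MOTU table: 5 MOTUs, 4 samples in 2 libraries
toy_motu_table <- function() {
  motus <- data.frame(
    motu_id = paste0("m", 1:5),
    candidates = c("Alces alces",
                   "Canis lupus;Canis latrans",
                   "Myodes gapperi;Microtus sp.",
                   "Homo sapiens",
                   "Marmota caligata"),
    best_similarity = c(0.99, 0.98, 0.97, 1.00, 0.94),
    in_negative_control = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    whitelist = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  counts <- matrix(c(100, 0, 40, 7,
                     0, 250, 0, 0,
                     60, 60, 0, 12,
                     5, 5, 5, 5,
                     0, 0, 33, 0),
                   nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("m", 1:5),
                                   c("a1", "a2", "b1", "b2")))
  motu_table(motus, counts,
             c(a1 = "L1", a2 = "L1", b1 = "L2", b2 = "L2"))
}

toy_samples <- function(ids = c("a1", "a2", "b1", "b2"),
                        volume = c(30, 60, 80, 30)) {
  d <- data.frame(sample_id = ids, site_id = paste0("site_", seq_along(ids)),
                  year = 2018L, design = "spatial",
                  volume_l = volume, rain_mm = 0,
                  catchment_km2 = 100, stringsAsFactors = FALSE)
  class(d) <- c("water_samples", "data.frame")
  d
}

# random sparse MOTU table for property tests
random_motu_table <- function(n_motu = 8, n_samp = 6, seed = 1) {
  set.seed(seed)
  species_pool <- c("Alces alces", "Ursus arctos", "Lepus americanus",
                    "Canis lupus;Canis latrans",
                    "Myodes gapperi;Microtus sp.",
                    "Odocoileus hemionus", "Martes americana",
                    "Castor canadensis")
  motus <- data.frame(
    motu_id = sprintf("m%02d", seq_len(n_motu)),
    candidates = sample(species_pool, n_motu, replace = TRUE),
    best_similarity = round(runif(n_motu, 0.9, 1), 3),
    in_negative_control = runif(n_motu) < 0.15,
    whitelist = FALSE,
    stringsAsFactors = FALSE)
  counts <- matrix(rpois(n_motu * n_samp, 40) *
                     (runif(n_motu * n_samp) < 0.6),
                   n_motu, n_samp,
                   dimnames = list(motus$motu_id,
                                   sprintf("s%02d", seq_len(n_samp))))
  libs <- setNames(rep(c("L1", "L2"), length.out = n_samp),
                   colnames(counts))
  motu_table(motus, counts, libs)
}

# random binary matrix for diversity property tests
random_detection_matrix <- function(n_taxa = 10, n_units = 8, p = 0.3,
                                    seed = 1) {
  set.seed(seed)
  y <- matrix(rbinom(n_taxa * n_units, 1, p), n_taxa, n_units,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("u%02d", seq_len(n_units))))
  detection_matrix(y, runif(n_units, 20, 90))
}

# independent maximum-likelihood oracle for GLM fits: Nelder-Mead on the
# exact log-likelihood, started away from the IRLS solution
nm_glm_oracle <- function(X, y, family) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- if (family == "poisson") exp(eta) else plogis(eta)
    -(if (family == "poisson") sum(dpois(y, mu, log = TRUE))
      else sum(dbinom(y, 1, mu, log = TRUE)))
  }
  o <- optim(rep(0, ncol(X)), nll, method = "Nelder-Mead",
             control = list(maxit = 5000, reltol = 1e-14))
  # polish with BFGS for the 1e-6 comparison
  optim(o$par, nll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}
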