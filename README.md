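# ednacam

Compare environmental DNA (eDNA) metabarcoding of stream water with
camera trapping for landscape-scale terrestrial mammal monitoring.

Streams drain DNA shed by the animals of their catchment, so filtering
large volumes of stream water and metabarcoding a mammal 12S marker can
inventory a landscape's mammal community without deploying a device per
site. Whether that signal is trustworthy — and cheaper — than a dense
camera-trap grid is a quantitative question. `ednacam` provides the full
analysis chain for answering it:

- **MOTU filtering** (`filter_motus()` and the individual steps):
  converts a taxonomically assigned MOTU read-count table into a binary
  detection matrix — negative-control MOTU removal, a 96 % best-match
  similarity threshold (with a whitelist for taxa whose only database
  relatives are congeners), collapse of ambiguous matches to genus or
  subfamily, a per-taxon per-library tag-jump filter at frequency 0.001,
  then 1/0 coding per sample.
- **Effort-standardised detection probabilities**
  (`estimate_detection()`): each taxon gets a single pooled probability
  *p60* of detection per reference sampling unit — 60 L of filtered
  water or 60 camera-trap days. A unit of effort *e* detects the taxon
  with probability

  &nbsp;&nbsp;&nbsp;&nbsp;π(e) = 1 − (1 − p60)^(e/60),

  the unique memoryless scaling consistent with a "per 60 L" probability
  across heterogeneous volumes. Inference is Bayesian (Beta prior,
  Bernoulli likelihood) with 95 % credible intervals, via a
  deterministic quadrature posterior or a built-in random-walk
  Metropolis sampler on the logit scale.
- **Covariate GLMs with AICc all-subsets selection** (`fit_glm()`,
  `all_subsets()`): from-scratch IRLS for Poisson (log link,
  species-per-sample richness) and binomial (logit link, per-species
  detection) models; exact log-likelihoods,
  AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1), ΔAICc < 2 equivalence sets,
  delta-method prediction (`predict_glm()`, `detection_curves()`), and
  per-catchment camera detection rates (`camera_rates()`) as the
  abundance-proxy covariate.
- **Diversity and cost-efficiency** (`diversity_summary()`,
  `bootstrap_accumulation()`, `cost_curve()`): total richness γ, mean
  per-unit richness ᾱ, turnover (γ − ᾱ)/γ, bootstrap
  species-accumulation curves (1000 iterations, percentile 95 % bands)
  and their re-indexing by cumulative survey dollars from a validated
  cost table (`cost_model()`).
- **Method agreement** (`compare_estimates()`): OLS slope/intercept/R²
  between paired per-taxon detection probabilities across years,
  designs, or methods.
- **Synthetic landscape** (`generate_community()`, `simulate_edna()`,
  `simulate_cameras()`): surveys generated under the exact model the
  analysis assumes, with presets for a 50-sample spatial design and a
  36-sample catchment design, so every stage is testable end-to-end and
  parameter recovery can be verified.
- **Pipeline** (`pipeline_config()`, `run_pipeline()`): one call from a
  directory of input tables to all artifacts (detection estimates,
  diversity summaries, accumulation and cost curves, comparisons, a
  seed-recording manifest).

## Worked example

Simulate a 36-sample catchment survey of a 20-taxon community, estimate
standardised detection probabilities, and price the diversity recovered:

```r
library(ednacam)

cm  <- generate_community(n_species = 20, seed = 42)
sc  <- survey_scenario("catchment-2019")           # 36 mixed-volume samples, 2 sites
sim <- simulate_edna(cm, sc, seed = 42)

est <- estimate_detection(sim$matrix, method = "edna_catchment", year = 2019)
head(est[order(-est$p60_mean), c("taxon", "p60_mean", "ci_low", "ci_high")], 5)
#>        taxon p60_mean ci_low ci_high
#> 8  Taxon_008    0.885  0.761   0.967
#> 3  Taxon_003    0.836  0.701   0.936
#> 17 Taxon_017    0.782  0.640   0.896
#> 1  Taxon_001    0.745  0.595   0.870
#> 6  Taxon_006    0.737  0.583   0.866
```

`p60_mean` is the posterior mean probability of detecting the taxon in
one standardised 60 L sample; `ci_low`/`ci_high` bound the central 95 %
credible interval.

```r
ds <- diversity_summary(sim$matrix)
#> gamma = 20 taxa, alpha_bar = 11.6, turnover = 0.42

ac   <- bootstrap_accumulation(sim$matrix, n_iter = 1000, seed = 42)
cost <- cost_model("edna", 2019, reusable = 3498, single_use = 2721,
                   labour_lab = 13858, logistics = 441,
                   n_units = 36, total = 20465)   # per_unit: $568
cc <- cost_curve(ac, cost)
cc[cc$m %in% c(0, 2, 10, 36), ]
#>     m  cost mean lo hi
#> 1   0     0  0.0  0  0
#> 3   2  1136 15.5 12 19
#> 11 10  5680 19.4 18 20
#> 37 36 20448 19.9 19 20
```

Two catchment samples ($1,136) already recover 15.5 of 20 taxa on
average. And because the survey was simulated, recovery can be checked
against truth:

```r
linear_fit(cm$taxa$true_p60, est$p60_mean[match(cm$taxa$name, est$taxon)])
#> OLS: y = 0.1207 + 1.0550 x, R^2 = 0.908 (n = 20)
```

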