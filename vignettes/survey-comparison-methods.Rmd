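---
title: "Methods: effort-standardised detection, model selection and cost-efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: effort-standardised detection, model selection and cost-efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednacam)
```

`ednacam` compares two ways of monitoring a landscape's terrestrial
mammal community: metabarcoding of environmental DNA (eDNA) filtered
from stream water, and a grid of camera traps. The two methods produce
incommensurable raw data — read counts per molecular taxonomic unit
(MOTU) per water sample versus pictures per camera per day — so the
package reduces both to a common currency (a standardised per-taxon
detection probability), models what drives detection, and prices the
diversity each method recovers. This vignette documents the models,
their assumptions, the tunable parameters, and the design decisions
taken where the methodology was genuinely open.

## From reads to detections

Raw sequencing reads are assumed to be already clustered into MOTUs and
taxonomically assigned against a reference database (that upstream
bioinformatics is out of scope). The filter chain applied here, in a
fixed order, is:

1. **Negative-control removal** — any MOTU observed in an extraction or
   PCR negative control is deleted outright (`remove_control_motus()`).
2. **Similarity threshold** — MOTUs whose best database match is
   *strictly below* 0.96 are removed (`filter_similarity()`). A
   *whitelist* flag retains a MOTU regardless: the intended use is a
   taxon whose species is absent from the reference database so that
   its best match, a congener, is legitimately below threshold.
3. **Reporting level** — a MOTU matching one candidate taxon is
   reported at species rank; candidates confined to one genus collapse
   to the genus; candidates spanning several genera of one subfamily
   collapse to the subfamily (`assign_reporting_level()`, with a
   genus-to-subfamily map covering the arvicoline rodents by default).
   Candidates spanning more than one subfamily are removed with a
   warning rather than guessed.
4. **Tag-jump filter** — tag jumps misassign a small fraction of a
   library's reads to the wrong sample. For each assigned taxon and
   sequencing library, any sample cell below 0.001 of the taxon's total
   reads in that library is zeroed (`filter_tag_jumps()`). Two
   decisions are worth making explicit because other readings exist:
   the **denominator is the taxon's library total** (not the sample's
   library total), and totals are computed **once from the input**, not
   recomputed as cells are zeroed. The single-pass rule makes the
   filter idempotent: zeroing cells only shrinks totals, which can only
   raise the relative frequency of surviving cells.
5. **Binarisation** — MOTUs sharing an assigned taxon pool, and a taxon
   is scored 1 in a sample when its pooled post-filter count is
   positive (`to_detection_matrix()`). Downstream analyses use only
   this 1/0 matrix; read counts are treated as evidence of presence,
   never of abundance.

The chain is non-increasing in reads and MOTUs at every step,
idempotent on its own output, and its binarisation is invariant to
rescaling all counts — all property-tested.

## The standardised detection probability

Let $p_{60}$ be the probability that one reference sampling unit —
60 L of filtered stream water, or 60 camera-trap days — detects a given
taxon. A sampling unit of effort $e$ (litres or trap-days) then detects
it with probability

$$\pi(e) \;=\; 1 - (1 - p_{60})^{e/60}.$$

This complementary-log-log effort scaling is the unique *memoryless*
choice: splitting a 60 L sample into two independent 30 L samples
leaves the probability of missing the taxon unchanged,
$(1-p)^{1/2}(1-p)^{1/2} = 1-p$. It is the natural standardisation when
volumes vary (25–80 L here, with filtration sometimes ending early),
and it lets camera sites with unequal active trap-days enter the same
model. The volume-effect assumption it encodes — every extra litre is
an independent Bernoulli opportunity — is a modelling idealisation;
DNA transport, decay and clumping in real streams will violate it to an
unknown degree, which is one reason covariates are modelled separately
(below).

**Pooling.** One $p_{60}$ is estimated per taxon, method and year,
pooling across all sites and field replicates. This deliberately
targets the landscape-level average detectability; it is not an
occupancy model and does not separate presence from conditional
detection. Site-to-site heterogeneity shows up instead in the turnover
and accumulation analyses.

**Inference.** With binary detections $y_j$ and efforts $e_j$, the
likelihood is the product of Bernoulli terms with success probability
$\pi(e_j)$, and the prior is Beta($a$, $b$), uniform by default.
Two engines compute the posterior:

- `posterior_grid()` — deterministic quadrature on a uniform grid
  (default 4001 points) with trapezoid integration for the mean and the
  central 95% interval. For equal 60-unit efforts this reproduces the
  conjugate Beta($1+k$, $1+n-k$) answers to ~1e-5, and it serves as the
  independent oracle for the sampler.
- `sample_posterior()` — a self-contained random-walk Metropolis
  sampler on $\theta = \mathrm{logit}(p_{60})$. The log target includes
  the Jacobian ($+\,a\log p + b\log(1-p)$ up to a constant), so the
  chain targets the posterior of $p_{60}$ itself. Defaults: 3 chains
  of 20,000 iterations, 5,000 burn-in, proposal SD 0.8 on the logit
  scale (acceptance rates around 0.5–0.8 on the datasets in the test
  suite), spread initial values, one seeded RNG stream, and an
  autocorrelation-truncation estimate of effective sample size.

`estimate_detection()` defaults to the grid engine: for a
one-dimensional parameter the quadrature is exact to grid resolution,
deterministic, and ~60× faster; the sampler is retained because it
generalises and because agreement of two independent routes is itself a
correctness check (enforced in the test suite: mean differences below
0.005 and interval endpoints below 0.01 across randomised datasets).
Boundary data (all-zero, all-one) are legal; the capped log-density
arithmetic keeps the grid free of NaNs at $p \in \{0, 1\}$.

## Covariate models and AICc selection

Two GLMs relate detection to environment and species traits:

- **Richness model** — Poisson regression with log link of the number
  of taxa per eDNA sample on upstream catchment area (km²), volume
  filtered (L), rainfall the previous day (mm) and year (factor).
- **Detection model** — binomial logistic regression of per-(taxon ×
  sample) 1/0 detection on the same environmental covariates plus
  either the higher taxonomic group, or diet class and log body mass,
  plus the taxon's mean camera detection rate in the sample's catchment
  (`camera_rates()`: mean over member cameras of independent pictures
  per trap-day, zero for never-photographed taxa).

The fitting is written out in full (`irls_fit()`): iteratively
reweighted least squares with canonical links, convergence when the
largest coefficient change drops below 1e-8 (cap 100 iterations, with
an explicit `converged` flag rather than an error), exact
log-likelihoods, and covariance from the inverse Fisher information at
convergence. Rank-deficient designs fail loudly with the collinear
columns named. The test suite holds the implementation to within 1e-6
of independent derivative-free/quasi-Newton maximisation of the same
likelihood, and to `stats::glm` as a second route.

Model selection fits **all additive subsets** of the candidate list
(capped at 12 candidates; factors enter as blocks), ranks by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, and flags models
within 2 AICc of the best as equivalent. Interactions are deliberately
not searched. Design choices: treatment contrasts with carnivore (diet)
and felids (group) as reference levels, so reported effects are
contrasts against the hardest-to-detect baseline; body mass enters
log-transformed (the taxa span voles to moose); volume is a covariate,
not an offset, keeping the two modelling layers (Bayesian
standardisation vs. additive covariate effects) independent; Wald 95%
intervals ($\beta \pm 1.96\,\mathrm{SE}$). Predictions
(`predict_glm()`) use the delta method on the response scale, and
`detection_curves()` evaluates them over a camera-rate grid at
reference conditions (60 L, 500 km², rainfall 0 vs 30 mm).

## Diversity, turnover and cost

For a binary matrix, $\gamma$ is the number of taxa detected anywhere,
$\bar\alpha$ the mean per-unit richness, and turnover
$(\gamma - \bar\alpha)/\gamma$ — the share of total diversity the
average single unit misses: 0 when every unit holds everything,
$1 - 1/n$ for $n$ units with disjoint equal-sized taxon sets.

`bootstrap_accumulation()` resamples units **with replacement** (a true
bootstrap, not permutation rarefaction): each of 1000 iterations draws
a full-length resampled sequence of units and records cumulative union
richness, so the first $m$ entries are exactly $m$ uniform draws with
replacement and each iteration's curve is monotone by construction.
Means and percentile 2.5/97.5 bands summarise the iterations. The
coupled-sequence scheme was chosen over independent redraws per effort
level so that the *reported* mean curve inherits monotonicity exactly
rather than only in expectation.

Cost models validate a four-component budget (reusable equipment,
single-use equipment, labour + lab work, logistics). When an explicit
total is supplied it takes precedence over the component sum, with a
warning when the two disagree by more than $1 — published cost tables
sometimes carry totals that include unlisted line items, and the
per-unit figures derive from the totals. Per-unit cost is total /
units, rounded half-up to the whole dollar. `cost_curve()` then
re-indexes an accumulation curve by cumulative dollars ($m$ units cost
$m \times$ per-unit); it is an affine re-indexing, so richness values
are identical to the accumulation curve's.

Method agreement (`compare_estimates()`) is ordinary least squares of
one set of per-taxon $p_{60}$ estimates on another, on the probability
scale as plotted, reporting slope, intercept and $R^2$. Both axes are
estimates, so this is a descriptive association, not an
errors-in-variables calibration.

## The synthetic landscape

`generate_community()` / `simulate_edna()` / `simulate_cameras()`
generate data **from the model the analysis assumes**: true $p_{60}$
values drawn from diet-specific Beta distributions (defaults
Beta(2, 6) for carnivores, Beta(4, 4) for omnivores and herbivores,
encoding the expectation that plant-eaters — more abundant, producing
more faeces — shed more detectable DNA), rain and log-catchment-area
effects added on the cloglog scale, Bernoulli detections with the
effort scaling above, and Poisson daily camera detections with
log-normal rates. Two presets encode the study designs: `"spatial-2018"`
(50 spatial samples from 42 small-stream sites, 30 L target with
shortfalls to 25 L from sediment clogging) and `"catchment-2019"` (36
catchment samples from 2 large-stream sites, volumes mixed over the
pump settings 70–80, 50–60 and 25–35 L with the largest dominating),
both with a 57-camera grid at 92 trap-days.

Because the generator and the estimator share the effort-scaling model,
passing parameter-recovery tests demonstrates *inferential
self-consistency* — the machinery recovers what it assumes — not that
real streams obey the model. Deliberately **not** simulated: DNA
transport, decay and dilution; spatial autocorrelation between nearby
sites; taxon misassignment; replicate correlation at a site. One
mismatch is built in on purpose: covariate effects are generated on the
cloglog scale of the per-60 L probability while the covariate model
fits a logistic link, mirroring the mild misspecification inherent in
running a separate standardisation and covariate analysis.

## Test problem sizes and numerical choices

The suite verifies, among others: sampler-vs-quadrature agreement on 20
randomised datasets of 5–15 samples; parameter recovery over 200
simulated 36-sample mixed-volume surveys at true $p_{60} \in \{0.1,
0.3, 0.5, 0.8\}$ (absolute bias of the posterior mean below 0.03,
95%-interval coverage between 90% and 99%); IRLS against independent
maximisers on 50 random designs of 30–60 rows; planted-covariate AICc
containment over 200 replicates at $n = 500$; and bootstrap
monotonicity/unbiasedness on 20 random matrices at 1000 iterations.
These sizes were chosen to make Monte-Carlo error comfortably smaller
than each tolerance while keeping the default suite quick to run.

Numerical details worth knowing: likelihood evaluations use
`log1p`/`expm1`-stable forms with a $\log(1-e^{x})$ helper; impossible
data return $-\infty$, never NaN; grid boundary cells are capped at a
log-density of $-10^{12}$ (exactly zero weight after normalisation);
IRLS floors working weights at $10^{-10}$ so quasi-separated logistic
fits flag non-convergence instead of crashing; and every stochastic
function takes an explicit integer seed, making all reported numbers
bit-reproducible.

## Known limitations

- The pooled $p_{60}$ has no site-occupancy layer; a taxon absent from
  half the landscape and one poorly detected everywhere can yield the
  same estimate.
- Detection probability is not abundance: the camera-rate covariate
  captures local activity, and the link from either quantity to density
  is species-dependent and unresolved.
- Turnover uses observed richness only; no Chao/ACE-style richness
  extrapolation is attempted, so $\gamma$ is a lower bound under
  undersampling.
- The cost model prices survey execution only (no capital amortisation
  across seasons beyond the reusable/single-use split, no permitting or
  data-management costs).
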