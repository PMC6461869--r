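---
title: "Methods: community tolerance distributions along salinity and pH gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community tolerance distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`tolgrad` quantifies how strongly an abiotic factor has filtered a soil
bacterial community by measuring the community's aggregated tolerance
distribution, and ties shifts in that distribution to shifts in 16S
community composition. This vignette is the package's methodological
account: the models, their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices behind the implementation.

## 1. Dose–response models and trait indicators

A tolerance assay exposes one sample's community to a series of stressor
levels and measures bacterial growth (leucine incorporation, arbitrary
units) at each. Growth is first normalised to the maximum observed growth
within the sample (`normalize_growth()`), so curves are comparable across
samples whose absolute rates differ; all fitting happens on this scale.

For **salt**, the predictor is `x = log10(suspension EC)` (dS m⁻¹).
Communities inhibited only by *increasing* salinity follow the logistic
model

$$Y = \frac{c}{1 + e^{b(x-a)}},$$

in which `a` is the logIC50 — by construction the level at which the
fitted curve returns exactly `c/2` — `b > 0` the inhibition slope (per
log10 unit), and `c` the uninhibited growth rate. Communities from saline
soils typically also lose growth at *low* EC; they follow the
double-logistic model

$$Y = \frac{c_{opt}}{1 + e^{b_{low}(x-a_{low})}} +
      \frac{c_{opt}}{1 + e^{b_{high}(x-a_{high})}} - c_{opt},$$

with `b_low < 0`, `b_high > 0` and an internal optimum between `a_low`
and `a_high`. The salt trait indicator is always the logIC50 toward
**higher** EC (`a` or `a_high`), so single- and double-model samples are
comparable. For **pH** the same double-logistic form is fitted on a
linear pH axis, and the trait indicator is `pH_opt`, the arg-max of the
fitted curve (`find_optimum()`), since communities are inhibited on both
sides of a pH optimum essentially everywhere.

Assumptions worth keeping in mind: growth responses are assumed unimodal
(or monotone) and smooth in the stressor; the assay levels are assumed to
bracket the transition (the salt design spans the control EC up to ~470
dS m⁻¹, the pH design pH 3–8 plus the unbuffered suspension); and
normalising by the *observed* maximum slightly underestimates `c_opt`
when no assay level sits exactly at the optimum.

### Model selection

Deciding visually whether growth falls off on both sides does not
reproduce; the package uses a deterministic surrogate
(`fit_salt_tolerance()`): both models are fitted by least squares, and
the double model is selected only if it (i) converges, (ii) improves AIC
by more than 2 (AIC computed from least-squares RSS with a floor of
`n · 1e-24`, so that two numerically perfect fits compare by parameter
count alone), (iii) places `a_low` above `min(x) − 1` — a low-side
transition pushed outside the observed range is evidence the single model
suffices — and (iv) keeps `a_low < a_high`. On noise-free
single-logistic data this rule provably selects the single model, which
the tests verify.

### Numerical choices

* Optimiser: Levenberg–Marquardt (`minpack.lm::nlsLM`) with parameter
  tolerance 1e-8, objective tolerance 1e-10, at most 10,000 residual
  evaluations.
* Initialisation: `c` (or `c_opt`) at the maximum normalised growth
  (i.e. 1); midpoints at the level whose growth is nearest half-max on
  each side of the observed optimum; slopes at ±4 per log10 unit.
* Bounds: midpoints within the observed `x` range ± 2; slopes bounded
  away from 0 (1e-6) and above by 100, with the sign fixed per side.
  These keep the sigmoid transition within about one decade of the data
  and prevent slope/midpoint trade-off into degeneracy.
* `find_optimum()` evaluates the fitted curve on a 0.01-step grid over
  the searched interval, then refines the best cell with `optimize()`
  (tolerance 1e-10). Ties break toward the lower stressor value. A flat
  curve returns the interval's lower bound flagged degenerate, as does a
  monotone curve whose maximum sits on the boundary.
* Unconverged fits carry `converged = FALSE` and a missing trait value;
  downstream stages keep the sample row and work on complete cases.

## 2. The synthetic-data generator

No public data set pairs community tolerance assays with amplicon tables,
so validation rests on simulation with known ground truth
(`simulate_study()`). The generator emulates the sampling design the
analysis is meant for: two gradients of 3 transects × 8 points (48
samples). The AG gradient spans soil EC 0.1–3 dS m⁻¹ (1:5 extract) with
pH drawn uniformly in 5.5–7.0; the NV gradient spans 0.2–9 dS m⁻¹ with pH
4.5–8.5 *decreasing* in log EC (noise SD 0.15 pH units), building in the
EC–pH confounding that makes the NV gradient the interesting test case
for the cross-trait bioindicator pattern. Soil EC is laid out
log-uniformly along points with 0.05 log-unit transect noise.

Each of the default 500 taxa carries a salt tolerance (per-taxon logIC50
on the suspension-EC axis) drawn from a mixture of salt-sensitive (70%,
mean 0.0) and halotolerant (30%, mean 1.1) components with SD 0.35 log
units; a Gaussian pH niche with optimum uniform in 4–9 and log-normal
breadth (median 1.2 pH units); and a log-normal base abundance.
Composition at a site weights base abundance by a decreasing logistic
filter of log10 soil EC (slope 3 per decade, centred on the taxon's
tolerance) and the Gaussian pH filter; OTU counts are multinomial at
12,000 reads per sample — above the 10,000-read rarefaction target, so
rarefaction is actually exercised. Assays aggregate per-taxon responses
(logistic in log EC with slope 4; Gaussian in pH) with the *same*
expected composition, then apply multiplicative log-normal noise with
mean 1 and CV 0.05 — growth rates stay positive and their spread scales
with their magnitude, which matches how radio-assay replicates behave.

Two deliberate modelling choices: per-taxon salt responses use the same
logistic form the fitting module assumes, so the model is well specified
at the taxon level but only *approximately* at the community level —
mixtures of logistics are not logistic — which makes parameter-recovery
tests a genuine robustness check rather than a tautology. And taxon-level
salt niches are one-sided; community-level low-EC inhibition emerges only
through composition, unless `niche_config(halophiles = TRUE)` makes the
halotolerant taxa obligate (their growth and abundance drop below a
midpoint two log-units under their tolerance), which produces
double-logistic salt curves at saline sites.

The control (no-salt) assay level needs a suspension EC to sit on the log
axis; it is set to `soil_ec / 10`, mirroring the dilution from the 1:5
extract into the assay suspension. This is a stand-in — real control
suspension ECs depend on soil chemistry — and is exposed in the level
design rather than hard-wired into the fitting.

Ground truth for every sample is computed from the noise-free aggregate
curve: the true logIC50 by 0.001-step grid search for the 50% crossing
refined by root finding, the true pH optimum by 0.001-step grid arg-max.

What the simulator does *not* emulate: sequencing error, PCR and primer
bias, OTU clustering artefacts, compositional zero-inflation beyond
multinomial sampling, spatial autocorrelation among transect points, and
any trait variation not driven by the two modelled niches. Passing tests
therefore demonstrate that the pipeline recovers the signal its models
describe, not that field data will be as kind.

## 3. OTU-table preparation

`prepare_otu_table()` applies, in order: removal of samples under 10,000
reads (inclusive threshold: exactly 10,000 is kept), rarefaction to
10,000 reads (without replacement, seeded), and removal of OTUs with
fewer than 10 reads total *on the rarefied table* — assessing rarity
after rarefaction keeps the criterion consistent with the table actually
analysed; both orderings are defensible and the choice is recorded here.
Counts removed at each step are logged. Diversity is the Shannon index in
natural logarithms (the `vegan` convention).

## 4. Linkage analyses

Community dissimilarity is Bray–Curtis on Hellinger-transformed counts
(square-root relative abundances; rows on the unit hypersphere), the
combination that behaves linearly enough for ordination of sparse count
data. PCoA is the double-centred eigendecomposition; axes with
eigenvalues above 1e-8 are retained and negative eigenvalues are
*excluded* rather than corrected (Lingoes/Cailliez), with their total
magnitude reported — the simplest defensible treatment, flagged to users.

The trait-constrained ordination is capscale-style dbRDA with logIC50,
pH_opt and a 0/1 gradient indicator as constraints, 10,000 permutations,
and **marginal** term tests (each constraint against the model holding
the others), which answers "does this trait explain composition beyond
the other constraints" — the question of interest when traits are
correlated. Mantel tests use Spearman rank correlation (average-rank
ties), 9,999 permutations, one-sided for positive association, since the
scientific hypotheses are directional. Distance-decay slopes are
descriptive OLS over unordered pairs; pairs are non-independent, so no
p-value accompanies them — inference stays with the Mantel test — and
their only inferential use is the ratio `slope_ph / slope_salt`, the
logIC50 change producing the same compositional shift as one pH unit.

The pH trait regression excludes samples below soil pH 5.5 (boundary
retained), where the pH_opt–soil pH relation flattens; the exclusion list
is returned, never silently applied. The per-gradient diversity
regression uses type II sums of squares (`car::Anova`): each term
adjusted for the other, appropriate under the built-in EC–pH correlation.
On zero-residual (noise-free) fits, where F tests are undefined, the SS
decomposition falls back to explicit nested-model residual differences
with missing F and p.

The bioindicator screen applies the abundance filter (≥ 1% in ≥ 1
sample) to rarefied relative abundances and classifies at |ρ| ≥ 0.5 with
no multiple-testing control — classification is by effect-size threshold,
not significance, and the report documents this caveat. Zero-variance
OTUs report ρ = 0 with a degenerate flag so the report stays rectangular.

## 5. Reproducibility

Every random component takes a seed; `run_pipeline()` derives per-stage
and per-sample seeds from one master seed with a counter scheme (48271/
69621 multipliers mod 2³¹−1), so stages are independent yet the whole run
is byte-reproducible, and the manifest records the configuration and
derived seeds. The test suite validates parameter recovery on 40–100
simulated assays at 5% noise, Mantel calibration on 200 null replicates
of 15 samples at 999 permutations, and exhaustive-enumeration agreement
at 5 samples; the full-design checks run one 48-sample, 500-taxon study.
These sizes give stable Monte-Carlo behaviour while keeping a complete
run in the order of a minute.

## 6. Known limitations

* IC50 confidence intervals (profile likelihood) and hierarchical slope
  sharing across samples are not implemented.
* The equivalence ratio is structural: its value depends on the
  simulator's niche geometry, and on real data it should be read as a
  descriptive exchange rate, not a universal constant.
* Mantel and dbRDA p-values inherit the usual caveats of distance-based
  permutation inference under spatial autocorrelation, which the
  simulator does not generate.
* The double-logistic fit can be weakly identified when the data contain
  no low-side inhibition; the selection rule then deliberately falls back
  to the single model rather than reporting an unstable `a_low`.
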