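---
title: "Total-error validation of untargeted HCP quantification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Total-error validation of untargeted HCP quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcpval)
```

## The measurand and the validation unit

Untargeted HCP proteomics reports an aggregate: the total host cell protein
mass per injection, summed over parsimony-inferred protein groups quantified
by Hi3. Because the analyte space is database- and inference-derived, the
validation characterises the *measurement system* — identification,
inference, filtering, quantification and aggregation — rather than individual
analytes. The statistical unit throughout is the replicate block: one
independent preparation's reportable result, defined as the arithmetic mean
of its technical injections. All validation statistics operate on the
replicate-block relative error `RE = 100 (Y − μ) / μ` against the nominal
spike amount μ.

The default design (`validation_design()`) is hierarchical: four independent
assay runs, one carrying a complete seven-level spike series at 20–80 ng and
three carrying five levels (L1, L2, L4, L6, L7), with three preparations in
technical triplicate at each included level. Levels present in all assays
yield twelve replicate blocks and between-assay degrees of freedom of three;
the two single-assay levels contribute repeatability information only.

## Error model and variance decomposition

At each level a one-way random-effects model with assay as the grouping
factor splits the relative-error variance into repeatability (σ_W, within
assay) and a between-assay component (σ_B), estimated by method of moments:
σ_B² = max((MS_between − MS_within)/m_h, 0) with harmonic-mean replication
m_h, truncated at zero (flagged) whenever MS_between ≤ MS_within. Total SD is
σ_T = √(σ_W² + σ_B²). With only three between-assay degrees of freedom, a
between-assay SD below roughly 1.41 σ_W is indistinguishable from zero at
usable power, so a truncated estimate means "not resolvable", not "absent".

Per-level total SDs are smoothed by the log–log model
log σ_T = a + b log μ, fitted by weighted least squares with weights
n_j − 1. The degrees-of-freedom reading of the weights is a deliberate
choice: it exactly reproduces the predicted-SD column of the emulated study's 
accuracy table from the printed per-level total SDs, which the alternative
1/n_j reading does not, and it downweights the df = 2 single-assay levels
appropriately. Predictions are invariant to the logarithm base.

## Tolerance intervals and acceptance

The β-expectation interval at level j is `Bias_j ± t_{(1+β)/2, ν_j} σ̂_pred,j`
with ν_j from the Welch–Satterthwaite combination of the ANOVA mean squares
(c_W = 1 − 1/m_h, c_B = 1/m_h), floored at 3. When the between component is
truncated or not estimable, ν falls back to the within df — this reproduces
the emulated study's accuracy-table df of 8 at the levels with truncated components, which
the raw Welch–Satterthwaite formula cannot yield without the unavailable raw
mean squares. A level validates when its interval lies inside the closed
±30 % acceptance band; the validated range must be contiguous, and its lowest
level is the LLOQ.

The parallel 95/95 content interval uses a hierarchical cluster bootstrap:
assays resampled with replacement, blocks resampled within each sampled
assay, bias and the variance model refitted per resample, then M simulated
future errors per level (`e* = Bias* + Z σ*_pred`, Z standard normal). The
inner half-width is the 95th percentile of |e* − Bias*|; the reported
half-width is the 95th percentile of inner half-widths over B iterations,
centred on the observed bias (the natural reading of the interval's
definition; the bootstrap-mean centre is not used). Defaults are B = 4000 and
M = 1000; both are configurable and seeded, and percentiles use the linear
interpolation convention throughout.

**Known limitation.** The content interval's confidence statement is
asymptotic in the number of assays. Under the four-assay study design the
cluster bootstrap understates parameter dispersion (resampled within-group
mean squares shrink by (n−1)/n at three blocks per cell) and the log-scale
smoothing is Jensen-biased low, so the empirical probability that the
interval contains 95 % of future errors is materially below 95 % — our
simulations place it near 60 % under the default generator. Under a
larger design (10 assays × 20 blocks) the construction is calibrated
(≈95 %). The acceptance property tests therefore check expected coverage of
the β-expectation interval under the study design, and the content
interval's confidence guarantee in the large-sample regime where it holds.
Practically: with few assays, the β-expectation interval is the decision
tool, and the content interval is corroborative.

## Synthetic-data generator

The generator is the package's study stand-in and its parameters are fixed
as study conditions, not tuned:

- Calibration `β₀ = 1.25` ng, `β₁ = 0.798` — the emulated study's compressed
  line (81–85 % recovery with a small positive offset).
- `σ_W = 2.3 %` — the median repeatability.
- `σ_B = 1.0 %` — a small positive between-assay component. The per-level
  method-of-moments estimates span 0–1.67 % with most values truncated to
  zero and REML indicating small positive components where truncation
  occurred; 1 % sits inside that envelope and below the ≈1.41 σ_W
  detectability floor.
- Stratum calibrations: slopes 1.0588 / 0.9906 / 0.9029 / 0.7986 with
  intercepts 0.26 / 0.81 / 3.71 / 29.57 ppm (Q1→Q4), the emulated
  study's stratified fits.
- Anchor-level abundances ~ LogNormal(log 20, 1.5) ppm, spanning ≈1.7–236 ppm
  between the 5th and 95th percentiles — consistent with reported
  abundance-aware limits of ≈3.6 ppm (LLOQ) and ≈233 ppm (ULOQ); per-protein
  observation noise 10 %.
- True peptide-level FDP 0.009 at the q = 0.01 operating threshold.

Noise is multiplicative on the measured value — `Y = (β₀ + β₁μ)(1 +
(u_a + e)/100)` with u_a shared across an assay — i.e. additive on the
relative-error scale on which the statistics operate. One consequence worth
stating: on the RE-versus-nominal scale the noise SD is scaled by the
recovery (1 + bias/100) ≈ 0.81–0.85, and simulation checks of interval
coverage must draw future errors from this same model.

What the generator does *not* emulate: stochastic precursor sampling,
peptide-level missingness correlated with abundance, retention-time drift,
inter-protein correlation structure, or matrix effects. Passing tests
demonstrate that the statistical machinery recovers known truth under the
declared hierarchical error model — not that a particular instrument
configuration meets the acceptance criteria.

## Identification-error calibration

Entrapment peptides are built either by shuffling internal residues of
target peptides while fixing the C-terminal residue (the tryptic cleavage
product's defining terminus; the N-terminal residue is a cleavage product of
the preceding peptide and may vary — a documented interpretation), or by
trimming a foreign peptidome against the target. The estimator
`FDP(τ) = N_E(τ)(1 + 1/r)/N_D(τ)` uses the achieved entrapment-to-target
ratio r after collisions and trimming, not the nominal design ratio.
Uncertainty comes from resampling unique stripped sequences (default
B = 1000) and, at the operating threshold, a Wilson score interval scaled by
(1 + 1/r). Protein-level propagation assumes peptide independence:
FDP³ ≈ 7×10⁻⁷ at FDP = 0.009 for the three concordant peptides Hi3 requires.

## Quantification chain choices

Filter order is fixed: single-hit exclusion (< 2 technical injections), TIC
normalization to the median run total, intensity-deviation screening (10×
from the peptide's cross-run median — our documented reading of "intensity
deviation screening"), modified Z-score outlier removal (cutoff 3.5; MAD
denominator with a scaled mean-absolute-deviation fallback when the MAD is
zero), then replicate CV filtering (20 %). Normalization precedes all
outlier statistics by design. All thresholds live in `filter_config()` and
are logged by the pipeline. Hi3 selects the three highest mean-intensity
peptides (lexicographic tie-break), converts intensity to fmol through the
median-ratio response factor of the spiked standards, and to mass through
the lead protein's average (not monoisotopic) molecular weight, the
convention for protein-level mass conversion.

Parsimony inference is a deterministic greedy set cover: select the
accession covering the most unassigned peptides (ties: most total peptides,
then lexicographically smallest accession); non-selected accessions whose
peptide sets are subsets of a selected set join as members; each peptide is
assigned to exactly one group (earliest selected). Groups left without a
unique peptide merge into the retained group sharing most peptides. The
tie-breaks are fixed here precisely so the output is order-invariant; the
pre-merge greedy cover size is kept as an attribute for comparison against
exhaustive minimal covers, where excess over the optimum is reported rather
than silently accepted.

## Stratified analysis

Strata are fixed once from anchor-level (L4) mean abundances at the
5/25/50/75/100 percentiles (linear interpolation; proteins below the 5th
percentile are excluded as unstable). Cell reportables are bootstrap
expectations over proteins within each (assay, level, block, stratum) cell
(default 10,000 resamples; configurable down for testing — the estimator's
Monte-Carlo noise shrinks as 1/√(nB)); cells under 30 proteins are excluded
with reason codes, and counts are conserved. Relative errors are computed on
the spike-ratio scale against the stratum anchor, which forces zero mean
bias at the anchor level by construction — stratified bias is deviation from
the anchor's systematic error, not from ground truth. The per-stratum
calibration regresses bootstrapped observed cell means on theoretical cell
abundances with the same HC3 machinery as the aggregate fit; for synthetic
data the generator emits the theoretical abundance alongside the observed
one, which is what makes the generator's stratum slopes identifiable (an
anchor-scaled observed abundance would confound slope and intercept).
Acceptance uses ±35 %, wider than the aggregate limit to absorb the extra
bootstrap-estimation variance of stratum-level reportables.

## Numerical and degenerate-input conventions

Zero empirical variance at a calibration level is an error unless variance
pooling is explicitly enabled (the minimum positive level variance is then
borrowed). Zero total SD excludes a level from the variance model with a
warning. Degenerate stratum cutpoints (tied percentiles) are an error rather
than silently collapsed strata. Acceptance bounds are closed. Every
stochastic routine takes an explicit integer seed and restores the caller's
RNG state, so generators and bootstraps are pure functions of (parameters,
seed).

## Simulation scale used by the test suite

The shipped tests run the property simulations at sizes chosen to exercise
the asymptotics they test while staying lightweight: 500 repetitions for
β-expectation coverage and calibration mean-recovery, 300 repetitions at
B = M = 500 for the content-interval confidence check (under the
10-assay × 20-block design discussed above), 200 seeds for FDP
unbiasedness, 100 repetitions for interval-recovery of generator truths,
and 1000 random instances for the parsimony-versus-exhaustive-cover
comparison.

## Known limitations

- HC3 sandwich intervals assume independent errors; under the generator's
  shared between-assay effect, replicate blocks are cluster-correlated and
  the intervals undercover scale parameters (slope coverage ≈0.80 at
  σ_B = 1 %, ≈0.95 at σ_B = 0). Any HC3-based analysis of such a design carries the same
  structural caveat. Cluster-robust alternatives would need more than four
  assays to be useful.
- The content tolerance interval's confidence guarantee is asymptotic in
  the assay count (see above).
- The abundance-stratified limits are anchor-relative and data-dependent;
  they are exercised against synthetic truth only.
- Protein-level FDP propagation assumes independent peptide-level errors;
  shared-sequence pathologies could violate it.
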