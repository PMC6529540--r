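---
title: "Methods: differentially methylated enhancer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentially methylated enhancer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
models, the assumptions behind them, the tunable parameters, the design
choices made where the design was genuinely open, and what the synthetic
validation does and does not establish.

# The data and its preprocessing

The observable is a per-cytosine, per-sample pair (methylated reads,
total reads) from targeted bisulfite sequencing over regulatory regions,
at both CpG and CpH (non-CpG) sites — the latter roughly 9-fold more
abundant in neuronal panels. Coordinates are 0-based half-open (BED
convention) throughout, and forward- and reverse-strand cytosines are
kept as distinct sites; nothing in the pipeline collapses strands.

Preprocessing is a fixed sequence of filters, each a function of its own:

* **Coverage** (`coverage_filter`, `min_depth = 30` reads): a call is
  only trusted when at least 30 reads span the cytosine; shallower calls
  become missing rather than noisy.
* **SNP masking** (`mask_snp_sites`): common variants create apparent
  methylation differences that are genotype, not epigenome; any site
  whose position intersects a supplied BED interval is dropped. Because
  both filters act site-wise, coverage filtering and SNP masking commute
  (a property the tests exercise).
* **Replicate merging** (`merge_replicates`): replicate columns collapse
  to their mean beta at each site, using the non-missing replicates only
  (maximising retention; a site is missing only when every replicate is
  missing). Depths are summed over the contributing replicates.
* **Missingness** (`missingness_filter`, `min_call_rate = 0.70`): a site
  must be called in at least 70% of samples; sites with beta exactly 0
  in every called sample carry no signal and are dropped too.
* **Sample QC** (`sample_qc`, `max_deviation = 0.10`): sample-level
  outliers are flagged by the mean absolute deviation of their betas
  from the per-site cohort median profile. A ">10% difference" criterion
  on inter-sample agreement is not a uniquely defined statistic; this
  package operationalises it as MAD-from-median > 0.10 beta units, a
  monotone and easily audited surrogate.

`conversion_efficiency` estimates bisulfite conversion from designated
unmethylated control samples (e.g. whole-genome-amplified DNA) as
1 − Σmeth/Σtotal; there is no automatic control detection.

# Site-level model

Betas are transformed to M-values, M = log2(β/(1−β)), with β clamped to
[1e-3, 1−1e-3]. The clamp keeps boundary sites finite while distorting
nothing in the interior: at 30-read depth the smallest nonzero beta is
1/30 ≈ 0.033, far above the clamp.

Each site is regressed on the design (intercept, Braak stage, age, sex,
postmortem interval, neuronal subtype proportion) by iteratively
reweighted least squares with Huber weights, tuning constant k = 1.345
(95% Gaussian efficiency), at most 50 iterations, coefficient tolerance
1e-8. Braak stage is coded numerically 1–6, treating severity as
ordinal-linear; `make_design(braak_stages = 1:4)` restricts to the
early-pathology stratum. Rows with a missing response are dropped per
site (complete-case, no imputation); sites with fewer than rank + 3
observations or a rank-deficient reduced design are flagged missing.

The robust residual variance divides the Huber-weighted residual sum of
squares by its Gaussian expectation, kappa = 2Φ(k) − 1 ≈ 0.821, times
the residual df. This keeps s² consistent for σ² when the data are clean
(so moderated p-values stay uniform under the null — a property test)
while capping each gross outlier's contribution to the variance.

**Empirical Bayes.** The variance ensemble is modelled as
s² | σ² ~ σ²χ²_d/d with a scaled-inverse-χ² prior (d0, s0²). Moment
matching on log s² (mean and variance of e = log s² − ψ(d/2) + log(d/2),
with a Newton inversion of the trigamma function) yields d0 and s0²;
the posterior variance s̃² = (d0 s0² + d s²)/(d0 + d) defines the
moderated t on d0 + d df. When the spread of log s² does not exceed its
χ² sampling noise the prior df is infinite and the common (geometric
mean) variance is used directly — in the exactly-degenerate case of
identical s² this returns that common value, so the moderated t reduces
to the ordinary t with inflated df.

Scan calibration is summarised by the genomic inflation factor
lambda = median(z²)/qchisq(0.5, 1) and the bias mean(z); values near 1
and 0 indicate an honest site-level test.

# From cytosines to regions

The region statistic deliberately separates *ranking* from *testing*:

1. **DMC selection** (`select_top_decile`): the top 10% of sites by
   p-value are flagged, rank ⌈0.10·m⌉ with ties broken by (chrom, pos)
   so the selected set has a deterministic size and content.
2. **Region chaining** (`group_regions`): single-linkage chaining joins
   consecutive sites on a chromosome whenever their gap is ≤ 1000 bp;
   the region spans [first site, last site + 1). Regions follow the
   probed sites, not annotated enhancer boundaries.
3. **Enrichment** (`region_enrichment`): each region's DMC count is
   tested against the profiled-cytosine universe by the inclusive
   hypergeometric upper tail P(X ≥ k), X ~ Hypergeom(N, K, n). The
   wording of a "top 10% background" admits a second parameterisation
   (conditioning within tested regions only); the (N, K, n, k) reading
   is implemented, and the tests pin it against exhaustive enumeration.
4. **Calling** (`call_dmrs`): BH across all chained regions — not only
   regions containing a DMC — then significance requires q < 0.05 *and*
   an absolute region effect ≥ 1 percentage point, where the region
   effect is the mean member-site difference of group mean betas,
   Braak 5–6 minus Braak 1–2. Direction (hyper/hypo) is the sign of
   that effect. Singleton regions are tested by default
   (`min_sites = 1`); a flag excludes them.

# Companion estimators

**Deconvolution.** Markers discriminate the two neuronal subtypes when
the paired t-test across reference individuals gives p ≤ 0.05, the mean
subtype difference is ≥ 0.05 beta, and the site shows no pathology
association (q ≥ 0.05 — "not different in disease" made concrete).
Proportions solve min ‖x − Rw‖² s.t. w ≥ 0, Σw = 1 per sample, via
Lawson–Hanson NNLS with a heavily weighted sum-to-one augmentation row
and final renormalisation; missing markers are dropped per sample.

**Epigenetic clock.** Elastic net (α = 0.5) of calibrated age on CpH
betas over an explicit 100-point log-spaced λ grid spanning six decades
below λ_max (glmnet's own path stops early once deviance saturates,
which would strand the fit far from the unpenalised end), with λ chosen
by seeded 10-fold CV (λ_min; λ_1se by flag). The age calibration is the
identity by default — the cohorts are all-adult — with the log-linear
young-age transform available. Betas, not M-values, are the predictors
by default (flag to switch).

Penalised regression at small n compresses predictions toward the
training mean, which attenuates genuine age shifts in a test stratum.
`fit_clock` therefore calibrates predictions through the prevalidated
fits: the cross-validated predictions of the training samples are
regressed on training age, and the inverse of that map is applied to new
predictions. The calibration is skipped (with a warning) when the CV fit
carries no usable age signal, in which case predictions fall back to the
shrunken estimates (and, in the λ → ∞ limit, to the training mean age).
Acceleration is tested by a two-sided paired t on predicted minus
chronological age; a zero-variance difference with nonzero mean is
reported as the p → 0 limit with a warning.

**Integration.** Interaction anchors annotate a region to a gene when
one anchor overlaps the region and the other overlaps the promoter
window [TSS − 2000, TSS + 2000) — half-open, strand-symmetric, and
invariant to anchor and row order. Expression goes through a strict
low-expression filter (CPM < 1 in *more than* 30% of samples), TMM
normalisation and log2-CPM (prior count 0.5, via edgeR), then the same
moderated robust engine with RIN added to the design. The coupling
statistic is the Pearson correlation, across enhancer–gene pairs, of the
two covariate-adjusted Braak coefficients (pair-level, not
sample-level — the other reading of an ambiguous contract). Set-overlap
questions use the same hypergeometric tail (`overlap_enrichment`).

# The synthetic cohort generator

`sim_config` fixes the study conditions; the generator is not a tuning
dial. Defaults: 101 donors; ages truncated-normal (mean 83.03, sd 9, range
54–105); Braak stages drawn so stage pairs 1–2/3–4/5–6 expect 38/32/31;
CpH fraction 1,085,436/1,207,507 ≈ 0.899 mirroring the assay
composition; negative-binomial depth (mean 60, size 8) truncated at 1;
binomial methylated counts at a logit-normal site mean; conversion
failure 0.0076 mixed in as p_obs = p* + (1 − p*)f; planted DMR effects
of 0.15 logit per Braak unit in 5% of regions, hypomethylating with
probability 0.7606; a CpH age slope of −0.01 logit/year with per-site
heterogeneity U(0.5, 1.5); a per-donor methylome-age offset
N(0, 3 years) emulating inter-individual epigenetic-aging variability;
covariate confounding hooks (sex, PMI, neuron proportion) defaulting to
0 so each adjustment can be tested in isolation. Baselines are
U(0.20, 0.80) at CpG and U(0.03, 0.15) at CpH sites — mid-range
regulatory CpG methylation versus the low single-digit-percent CpH
levels typical of neurons. Expression is negative-binomial with varying
library sizes; genes coupled to a region shift their log2 mean by
−sign × 0.3 per percentage point of that region's expected methylation
deviation. One master seed spawns fixed per-stage substreams, so each
stage is reproducible on its own.

What the generator does **not** emulate: spatial correlation of
methylation along a region beyond the shared planted effect; linked
SNP artefacts; batch or flow-cell structure; read-level errors;
realistic gene-length or GC effects in RNA-seq; more than two neuronal
subtypes. Passing the validation studies therefore demonstrates that the
estimators recover the structures they model — not that real cohorts
satisfy those models.

# Validation studies and their problem sizes

The `*_study` functions are seeded recovery experiments used by the test
suite and the acceptance script:

* `dmr_null_fdr_study`: 20 cohorts × (100 samples, 2000 regions, depth
  40), no planted effects; every significant region is a false
  discovery.
* `dmr_power_study`: the same geometry with 5% of regions planted at
  0.15 logit/Braak-unit; recall, precision, and direction agreement.
* `clock_recovery_study`: 38 training and 31 test donors sharing one
  age distribution (interleaved by age rank), test methylomes generated
  at age + Δ for Δ ∈ {0, 4, 8} years. This study plants a strong age
  signature (−0.06 logit/year, no methylome-age scatter, depth fixed at
  40): an information calculation (per-site beta slope ≈ slope·p(1−p)
  against binomial noise at depth 40, ~2500 CpH sites) shows the latent
  methylome age is estimable to about a year only under such a
  signature at n = 38, and with inter-individual scatter the paired t
  inherits shared train-cohort noise and becomes anticonservative
  regardless of method. The study is therefore designed to isolate the
  estimator: it verifies that planted shifts are recovered on the right
  scale and that no shift is detected when none is planted — not that
  any particular cohort's signal suffices.
* `deconvolution_recovery_study`: 500 mixtures, 200 markers, depth 40.
* `coupling_recovery_study`: 10 end-to-end cohorts (25 donors, 300
  regions, 500 genes) with inverse enhancer–gene coupling.

These sizes are scaled-down analogues of the motivating study chosen so
the whole suite runs in minutes on one CPU; the operating
characteristics they estimate (FDR, recall, precision, direction, shift
recovery, estimator accuracy, coupling sign) are size-stable.

# Numerical choices and degenerate inputs

* M-value clamp 1e-3; Huber k = 1.345, ≤50 iterations, tolerance 1e-8;
  IRLS scale = median absolute residual / 0.6745, with a clean fallback
  to OLS when the scale collapses to 0 (exact fits).
* Trigamma inversion by Newton with asymptotic guards at both ends.
* Hypergeometric tails via the stable `phyper` upper tail (inclusive,
  k − 1 convention); BH via `p.adjust`, pinned to the step-up definition
  by enumeration tests.
* NNLS tolerance 1e-10; the sum-to-one augmentation row weight 1e4,
  followed by exact renormalisation.
* Empty inputs return empty, typed results (empty call tables warn;
  empty interaction or truth tables yield empty pair tables); zero
  library sizes, constant ages, all-missing markers and
  zero-variance correlations raise immediate, specific errors or
  flagged missing values rather than propagating NaNs.

# Known limitations

* The sample-QC statistic is a surrogate for an under-specified
  agreement criterion; borderline samples may differ from other
  reasonable operationalisations.
* The region statistic tests DMC *enrichment*, not spatially coherent
  effect models; a region driven by one extreme site among many can
  reach significance only through the effect-size gate.
* The clock's prevalidated calibration restores scale but inflates
  variance when the training signal is weak; with weak signatures the
  honest behaviour is wide uncertainty, not accurate recovery.
* Deconvolution assumes the reference panel spans the mixture; an
  unmodelled cell type biases weights toward whichever profile it
  resembles.
* eRNA analysis is reduced to applying the expression contract to
  features located within enhancer regions; no read-level eRNA calling.
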