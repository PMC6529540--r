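# enhancerDMR

Analysis of DNA methylation at neuronal enhancers from targeted bisulfite
sequencing, for studies relating enhancer methylation to neurodegenerative
pathology. The package takes per-cytosine methylation calls (CpG and CpH),
covariate-annotated donor metadata, chromatin-interaction maps and RNA-seq
counts, and produces differentially methylated enhancer regions, neuronal
subtype proportions, epigenetic-age estimates, and enhancer→target-gene
integration — together with a synthetic-cohort generator with full ground
truth, so every stage can be validated without access to any study's raw
data.

## Who it is for

Groups analysing targeted bisulfite data (e.g. padlock-probe panels over
regulatory regions) in postmortem brain cohorts staged by neurofibrillary
tangle burden (Braak stage 1–6), and anyone who needs a tested, seeded
reference implementation of this analysis style for methods work.

## The statistics at its core

**Site-level model.** Beta values (methylated-read fractions) are mapped to
M-values, M = log2(β/(1−β)) with a clamp at 1e-3. Each cytosine is fit by
an iteratively reweighted least-squares regression with Huber weights
(k = 1.345) of M on Braak stage, adjusting for age, sex, postmortem
interval and neuronal subtype proportion. Residual variances are moderated
by empirical Bayes: prior df d0 and prior variance s0² are estimated by
moment matching on log s², the posterior variance is
s̃² = (d0·s0² + d·s²)/(d0 + d), and the moderated t = b/(s̃·√v) is referred
to a t distribution on d0 + d df, with Benjamini–Hochberg adjustment.

**Region-level statistic.** The top 10% of cytosines by p-value are flagged
as differentially methylated cytosines (DMCs). Cytosines within 1000 bp are
chained into regions, and each region's DMC content is tested by the
hypergeometric upper tail P(X ≥ k) with X ~ Hypergeom(N, K, n), where N is
all profiled cytosines and K all DMCs. Regions with BH q < 0.05 and an
absolute methylation change ≥ 1 percentage point between Braak 5–6 and
Braak 1–2 donors are called differentially methylated regions (DMRs).

**Companion estimators.** Neuronal glutamatergic:GABAergic proportions by
simplex-constrained least squares against a marker reference panel; a CpH
epigenetic clock (elastic net, α = 0.5, λ by seeded 10-fold CV, with
prevalidated calibration of predictions) trained on the Braak 1–2 stratum
and tested for age acceleration by paired t-test; enhancer targets
annotated through interaction anchors falling in ±2 kb promoter windows,
with expression analysed on TMM-normalised log2-CPM by the same moderated
robust engine.

## Worked example

```r
library(enhancerDMR)

cfg  <- sim_config(n_samples = 60, n_regions = 500, depth_mean = 40,
                   dmr_fraction = 0.05, dmr_effect_logit = 0.2, seed = 7)
meta <- generate_cohort(cfg)
sim  <- generate_methylation(meta, cfg)
sim$matrix
#> meth_matrix: 2503 sites x 60 samples
#>   contexts: CpG=248, CpH=2255
#>   missing beta: 0.0%

fit <- ebayes(fit_robust(beta_to_m(sim$matrix$beta), make_design(meta)))
fit
#> site_fit: 2503 features, 6 coefficients ( huber )
#>   empirical Bayes: d0 = 4.267 , s0^2 = 0.8315

dmc  <- select_top_decile(fit$p, sim$matrix$sites)
g    <- group_regions(sim$matrix$sites)
dmrs <- call_dmrs(g, dmc, delta_beta(sim$matrix, meta))
dmrs
#> dmr_result: 500 regions tested, 18 significant (q < 0.05 , |delta| >= 1 %)
#>   hypo: 16  hyper: 2
#>     region chrom  start    end  n k            p            q delta_beta_pct
#> 280    280  chr4 200081 200622 10 9 8.212564e-09 2.309772e-06      10.390778
#> 386    386  chr7  60031  60440  8 8 9.239087e-09 2.309772e-06      -5.530028
#> ...
```

The generator planted Braak-linked effects (mostly hypomethylating) in 5%
of the 500 regions; the pipeline recovers them as significant regions,
predominantly labelled `hypo`, with per-region effect sizes in percent
methylation change between the severe and no/mild pathology groups.
`inflation_factor(fit$t)` on this run gives lambda = 0.94 and bias = −0.06,
i.e. a well-calibrated site-level scan.

The same stages run end to end over plain TSV/BED artifacts with

```r
run_pipeline("all", pipeline_config(seed = 7), "out/")
```

or from a shell via `inst/scripts/run_pipeline.R`.

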