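# Seeded simulation studies validating the pipeline's operating
# characteristics. These are the package's own recovery experiments: each
# builds synthetic cohorts, runs the standard analysis path, and scores
# the calls against the generator's ground truth.

# map chained regions back to generator region ids via their first member
map_regions_to_truth <- function(grouping, truth) {
  first_site <- match(grouping$regions$region, grouping$site_region)
  truth$sites$region[first_site]
}

run_dmr_cohort <- function(cfg) {
  meta <- generate_cohort(cfg)
  sim <- generate_methylation(meta, cfg)
  design <- make_design(meta)
  fit <- ebayes(fit_robust(beta_to_m(sim$matrix$beta), design))
  dmc <- select_top_decile(fit$p, sim$matrix$sites)
  grouping <- group_regions(sim$matrix$sites)
  delta <- delta_beta(sim$matrix, meta)
  dmrs <- call_dmrs(grouping, dmc, delta)
  list(meta = meta, sim = sim, fit = fit, dmc = dmc,
       grouping = grouping, dmrs = dmrs,
       gen_region = map_regions_to_truth(grouping, sim$truth))
}

#' False-discovery control of the DMC-to-DMR pipeline under the null
#'
#' Runs the full site-model -> top-decile -> region-enrichment pipeline
#' on cohorts with no planted effects (100 samples, 2000 regions, read
#' depth 40) and reports the fraction of regions called significant —
#' all of which are false discoveries.
#'
#' @param n_replicates number of null cohorts (default 20).
#' @param seed master seed.
#' @return list with \code{fdr} (pooled fraction of significant regions),
#'   \code{per_replicate} counts, and the problem size.
#' @export
dmr_null_fdr_study <- function(n_replicates = 20, seed = 1) {
  sig <- integer(n_replicates)
  tested <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_samples = 100, n_regions = 2000,
                      sites_per_region = list(mean = 5, min = 1),
                      depth_mean = 40, dmr_fraction = 0,
                      age_slope_logit = 0,
                      seed = substream(seed, "pipeline") + r)
    res <- run_dmr_cohort(cfg)
    sig[r] <- sum(res$dmrs$significant)
    tested[r] <- nrow(res$dmrs)
  }
  list(fdr = sum(sig) / sum(tested), per_replicate = sig,
       n_regions_tested = sum(tested), n_replicates = n_replicates)
}

#' Power and precision for planted differentially methylated regions
#'
#' Plants Braak-linked logit effects (0.15 per Braak unit, mostly
#' hypomethylating) in 5% of 2000 regions at depth 40 with 100 samples,
#' runs the standard pipeline, and scores recall, precision, and
#' direction agreement of the significant calls against the truth.
#'
#' @param n_replicates cohorts to aggregate over (default 2).
#' @param seed master seed.
#' @return list with \code{recall}, \code{precision},
#'   \code{direction_correct} (fraction of recovered planted regions
#'   whose hyper/hypo label matches the planted sign), and counts.
#' @export
dmr_power_study <- function(n_replicates = 2, seed = 1) {
  tp <- fp <- fn <- 0
  dir_ok <- dir_all <- 0
  for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_samples = 100, n_regions = 2000,
                      sites_per_region = list(mean = 5, min = 1),
                      depth_mean = 40, dmr_fraction = 0.05,
                      dmr_effect_logit = 0.15,
                      seed = substream(seed, "qc") + 100 + r)
    res <- run_dmr_cohort(cfg)
    truth <- res$sim$truth
    planted <- truth$planted_dmr_ids
    sig_gen <- res$gen_region[res$dmrs$significant]
    tp <- tp + sum(planted %in% sig_gen)
    fp <- fp + sum(!sig_gen %in% planted)
    fn <- fn + sum(!planted %in% sig_gen)
    rec <- res$dmrs$significant & res$gen_region %in% planted
    signs <- truth$region_sign[res$gen_region[rec]]
    dir_ok <- dir_ok + sum(ifelse(signs < 0,
                                  res$dmrs$direction[rec] == "hypo",
                                  res$dmrs$direction[rec] == "hyper"))
    dir_all <- dir_all + sum(rec)
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       direction_correct = if (dir_all > 0) dir_ok / dir_all else NA_real_,
       n_true_positive = tp, n_false_positive = fp,
       n_replicates = n_replicates)
}

#' Recovery of planted epigenetic-age acceleration
#'
#' Trains the CpH clock on a 38-sample reference stratum and predicts a
#' 31-sample test stratum whose methylomes were generated at
#' chronological age + delta years, mirroring an accelerated-aging
#' cohort. Train and test strata share the age distribution (interleaved
#' by age rank). The planted per-site age signature is -0.06 logit/year
#' at CpH sites, with binomial noise at a fixed read depth of 40 and no
#' inter-individual methylome-age scatter — strong enough that the
#' latent methylome age is estimable to about a year from ~2500 sites.
#' The study thereby isolates the estimator: the recovery band and the
#' null size measure clock behaviour, not cohort sampling noise.
#'
#' @param deltas planted accelerations in years (default 0, 4, 8).
#' @param n_replicates cohorts per delta (default 5).
#' @param seed master seed.
#' @return data.frame with one row per (delta, replicate): estimated mean
#'   acceleration and paired-t p-value.
#' @export
clock_recovery_study <- function(deltas = c(0, 4, 8), n_replicates = 5,
                                 seed = 1) {
  out <- list()
  for (d in deltas) for (r in seq_len(n_replicates)) {
    cfg <- sim_config(n_samples = 69, n_regions = 800,
                      sites_per_region = list(mean = 5, min = 1),
                      depth_mean = 40, depth_dispersion = 1e6,
                      dmr_fraction = 0, age_slope_logit = -0.06,
                      age_scatter_years = 0,
                      seed = substream(seed, "folds") + 1000 * d + r)
    meta <- generate_cohort(cfg)
    test_ranks <- round(seq(1.5, 68.5, length.out = 31))
    braak <- rep(1, 69)
    braak[test_ranks] <- 6
    meta$braak <- braak[rank(meta$age, ties.method = "first")]
    gen_meta <- meta
    gen_meta$age <- gen_meta$age + ifelse(gen_meta$braak == 6, d, 0)
    sim <- generate_methylation(gen_meta, cfg)
    cph <- sim$matrix$sites$context == "CpH"
    B <- t(sim$matrix$beta[cph, , drop = FALSE])
    train <- meta$braak == 1
    model <- fit_clock(B[train, , drop = FALSE], meta$age[train],
                       seed = cfg$seed)
    pred <- predict(model, B[!train, , drop = FALSE])
    acc <- acceleration_test(pred, meta$age[!train])
    out[[length(out) + 1]] <- data.frame(
      delta = d, replicate = r,
      estimated = acc$mean_acceleration, p = acc$p)
  }
  do.call(rbind, out)
}

#' Deconvolution recovery under binomial read noise
#'
#' Estimates mixture weights for noisy two-subtype mixtures (200
#' markers, depth 40) and reports the fraction of estimates within 0.05
#' of the true weight plus the signed bias.
#'
#' @param n_mixtures total mixtures (default 500).
#' @param seed master seed.
#' @return list with \code{within_05}, \code{bias}, \code{errors}.
#' @export
deconvolution_recovery_study <- function(n_mixtures = 500, seed = 1) {
  per <- 100
  reps <- ceiling(n_mixtures / per)
  errs <- numeric(0)
  for (r in seq_len(reps)) {
    cfg <- sim_config(ref_markers = 200, ref_mixtures = per,
                      ref_depth = 40, seed = substream(seed, "reference") + r)
    ref <- generate_reference_panel(cfg)
    fit <- estimate_proportions(ref$mixtures, ref$panel)
    W <- as.matrix(fit$proportions[, colnames(ref$panel)])
    errs <- c(errs, W[, 1] - ref$weights[, 1])
  }
  errs <- errs[seq_len(n_mixtures)]
  list(within_05 = mean(abs(errs) < 0.05), bias = mean(errs),
       errors = errs)
}

#' Recovery of enhancer-gene inverse coupling
#'
#' Full coupled cohorts (methylation with planted effects, expression
#' inversely coupled through the truth record): correlates region-level
#' and gene-level Braak coefficients across the coupled pairs and
#' reports the per-run correlation and p-value.
#'
#' @param n_runs number of seeded cohorts (default 10).
#' @param seed master seed.
#' @return data.frame with r and p per run.
#' @export
coupling_recovery_study <- function(n_runs = 10, seed = 1) {
  out <- list()
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(n_samples = 25, n_regions = 300,
                      sites_per_region = list(mean = 5, min = 1),
                      dmr_fraction = 0.1, dmr_effect_logit = 0.3,
                      n_genes = 500, seed = substream(seed, "expression") + s)
    meta <- generate_cohort(cfg)
    sim <- generate_methylation(meta, cfg)
    expr <- generate_expression(meta, sim$truth, cfg)
    design <- make_design(meta)
    fit <- ebayes(fit_robust(beta_to_m(sim$matrix$beta), design))
    grouping <- group_regions(sim$matrix$sites)
    gen_region <- map_regions_to_truth(grouping, sim$truth)
    bsite <- fit$coefficients[, "braak"]
    meth_coef <- tapply(bsite, factor(grouping$site_region,
                                      levels = grouping$regions$region),
                        mean, na.rm = TRUE)
    names(meth_coef) <- gen_region
    counts <- filter_low_expression(expr$counts)
    de <- de_genes(tmm_logcpm(counts)$logcpm, meta)
    expr_coef <- de$coefficients[, "braak"]
    pairs <- sim$truth$enhancer_gene_truth
    res <- meth_expr_correlation(meth_coef, expr_coef,
                                 data.frame(region = pairs$region,
                                            gene = pairs$gene))
    out[[s]] <- data.frame(run = s, r = res$r, p = res$p, n = res$n)
  }
  do.call(rbind, out)
}
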