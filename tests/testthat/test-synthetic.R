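test_that("cohort generation is deterministic and honours Braak probabilities", {
  cfg <- small_config(seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  cfg1 <- small_config(seed = 3, braak_probs = c(1, 0, 0, 0, 0, 0))
  expect_true(all(generate_cohort(cfg1)$braak == 1))

  meta <- generate_cohort(small_config(seed = 5))
  expect_equal(nrow(meta), 40)
  expect_true(all(meta$age >= 54 & meta$age <= 105))
  expect_true(all(meta$braak %in% 1:6))
})

test_that("Braak stage-pair group sizes match the multinomial expectation", {
  # cohort split emulated: 38/32/31 over stage pairs in n = 101
  probs <- c(19, 19, 16, 16, 15.5, 15.5) / 101
  expected <- c(38, 32, 31)
  reps <- 200
  counts <- sapply(seq_len(reps), function(r) {
    meta <- generate_cohort(sim_config(n_samples = 101, seed = 1000 + r))
    pair <- (meta$braak + 1) %/% 2
    tabulate(pair, 3)
  })
  se <- sqrt(101 * (expected / 101) * (1 - expected / 101))
  expect_true(all(abs(rowMeans(counts) - expected) < se))
})

test_that("with no planted effects, Braak group differences stay within binomial noise", {
  cfg <- sim_config(n_samples = 80, n_regions = 60,
                    dmr_fraction = 0, age_slope_logit = 0,
                    noise_sd_logit = 0, conversion_failure = 0,
                    depth_mean = 60, seed = 21)
  meta <- generate_cohort(cfg)
  sim <- generate_methylation(meta, cfg)
  g1 <- meta$braak <= 3
  meth <- sim$calls$meth
  tot <- sim$calls$total
  m <- nrow(meth)
  pvals <- vapply(seq_len(m), function(i) {
    suppressWarnings(stats::prop.test(
      c(sum(meth[i, g1]), sum(meth[i, !g1])),
      c(sum(tot[i, g1]), sum(tot[i, !g1])))$p.value)
  }, numeric(1))
  expect_gt(min(pvals, na.rm = TRUE), 0.001 / m)
})

test_that("conversion failure shifts the observed mean by (1 - p*) * f", {
  f <- 0.01
  cfg <- sim_config(n_samples = 30, n_regions = 40, depth_mean = 10000,
                    depth_dispersion = 1e6, dmr_fraction = 0,
                    age_slope_logit = 0, noise_sd_logit = 0,
                    conversion_failure = f, seed = 8)
  meta <- generate_cohort(cfg)
  sim <- generate_methylation(meta, cfg)
  truth <- sim$truth
  # region-level expected truth holds E[p*]; observed = p* + (1 - p*) f
  rid <- truth$sites$region
  obs <- rowsum(sim$matrix$beta, rid) / tabulate(rid, cfg$n_regions)
  expected <- truth$region_meth + (1 - truth$region_meth) * f
  expect_lt(max(abs(obs - expected)), 0.01)
  # mean shift at near-unmethylated CpH sites approximates f itself
  low <- truth$sites$baseline < 0.05
  shift <- mean(sim$matrix$beta[low, ]) -
    mean(truth$sites$baseline[low])
  expect_lt(abs(shift - f * (1 - mean(truth$sites$baseline[low]))), 0.005)
})

test_that("generated betas and counts respect construction bounds", {
  cfg <- small_config(seed = 2)
  sim <- generate_methylation(generate_cohort(cfg), cfg)
  expect_true(all(sim$matrix$beta >= 0 & sim$matrix$beta <= 1))
  expect_true(all(sim$calls$meth <= sim$calls$total))
  expect_true(all(sim$calls$total >= 1))
  expect_identical(
    generate_methylation(generate_cohort(cfg), cfg)$matrix$beta,
    sim$matrix$beta)
})

test_that("planted logit effects reproduce the logistic prediction at high depth", {
  cfg <- sim_config(n_samples = 240, n_regions = 60, dmr_fraction = 0.2,
                    dmr_effect_logit = 0.3, dmr_hypo_prob = 1,
                    age_slope_logit = 0, noise_sd_logit = 0,
                    conversion_failure = 0, depth_mean = 10000,
                    depth_dispersion = 1e6,
                    braak_probs = c(.5, 0, 0, 0, 0, .5), seed = 31)
  meta <- generate_cohort(cfg)
  sim <- generate_methylation(meta, cfg)
  tr <- sim$truth$sites
  planted <- tr$effect != 0
  b1 <- rowMeans(sim$matrix$beta[planted, meta$braak == 1, drop = FALSE])
  b6 <- rowMeans(sim$matrix$beta[planted, meta$braak == 6, drop = FALSE])
  pred <- ilogit_test(logit_test(tr$baseline[planted]) + 6 * tr$effect[planted]) -
    ilogit_test(logit_test(tr$baseline[planted]) + 1 * tr$effect[planted])
  expect_lt(mean(abs((b6 - b1) - pred)), 0.005)
})

test_that("expression counts are inversely coupled to enhancer methylation", {
  cfg <- sim_config(n_samples = 30, n_regions = 60, dmr_fraction = 0.2,
                    dmr_effect_logit = 0.4, dmr_hypo_prob = 0.5,
                    coupling_log2_per_pct = 3, nb_size = 1e8,
                    n_genes = 300, seed = 41)
  for (s in 1:5) {
    cfg$seed <- 41 + s
    meta <- generate_cohort(cfg)
    sim <- generate_methylation(meta, cfg)
    expr <- generate_expression(meta, sim$truth, cfg)
    cp <- sim$truth$enhancer_gene_truth
    rho <- vapply(seq_len(nrow(cp)), function(i) {
      stats::cor(sim$truth$region_meth[cp$region[i], ] * cp$sign[i],
                 expr$counts[cp$gene[i], ], method = "spearman")
    }, numeric(1))
    expect_true(all(rho < 0))
  }
  # same seed -> identical counts
  e1 <- generate_expression(meta, sim$truth, cfg)
  expect_identical(e1$counts, expr$counts)
})

test_that("interaction pairs are cis and hit the coupled promoter window", {
  cfg <- small_config(seed = 51, dmr_fraction = 0.2)
  meta <- generate_cohort(cfg)
  sim <- generate_methylation(meta, cfg)
  expr <- generate_expression(meta, sim$truth, cfg)
  inter <- generate_interactions(sim$truth, expr$genes)
  expect_equal(nrow(inter), nrow(sim$truth$enhancer_gene_truth))
  expect_true(all(inter$chrom1 == inter$chrom2))
  gi <- match(sim$truth$enhancer_gene_truth$gene, expr$genes$gene)
  tss <- expr$genes$tss[gi]
  expect_true(all(inter$start2 >= tss - 2000 & inter$end2 <= tss + 2000))

  cfg0 <- small_config(seed = 52, dmr_fraction = 0)
  meta0 <- generate_cohort(cfg0)
  sim0 <- generate_methylation(meta0, cfg0)
  expr0 <- generate_expression(meta0, sim0$truth, cfg0)
  expect_equal(nrow(generate_interactions(sim0$truth, expr0$genes)), 0)
  expect_error(
    generate_interactions(sim$truth, expr$genes[-gi[1], , drop = FALSE]),
    "absent")
})

test_that("reference mixtures are convex combinations of the panel", {
  cfg <- small_config(seed = 61, ref_depth = Inf)
  ref <- generate_reference_panel(cfg)
  expect_true(all(abs(rowSums(ref$weights) - 1) < 1e-12))
  expected <- ref$panel %*% t(ref$weights)
  expect_equal(ref$mixtures, expected, tolerance = 1e-12)
  # subtype margins hold at every marker
  expect_true(all(abs(ref$panel[, 1] - ref$panel[, 2]) >= 0.0999 |
                    pmin(ref$panel[, 1], ref$panel[, 2]) <= 0.021 |
                    pmax(ref$panel[, 1], ref$panel[, 2]) >= 0.979))
})
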