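test_that("target annotation respects the half-open promoter window", {
  regions <- data.frame(region = 1L, chrom = "chr1",
                        start = 5000L, end = 5500L)
  genes <- data.frame(gene = "G1", chrom = "chr1", tss = 20000L)

  # one anchor in the region, the other exactly covering the TSS
  inter <- data.frame(chrom1 = "chr1", start1 = 5100L, end1 = 5200L,
                      chrom2 = "chr1", start2 = 19990L, end2 = 20010L)
  hit <- annotate_targets(regions, inter, genes)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$gene, "G1")

  # anchor ending exactly at TSS - 2000: half-open, no overlap
  inter2 <- data.frame(chrom1 = "chr1", start1 = 5100L, end1 = 5200L,
                       chrom2 = "chr1", start2 = 17900L, end2 = 18000L)
  expect_equal(nrow(annotate_targets(regions, inter2, genes)), 0)
  # one bp further does overlap
  inter3 <- transform(inter2, end2 = 18001L)
  expect_equal(nrow(annotate_targets(regions, inter3, genes)), 1)

  # anchor order must not matter
  swapped <- inter[, c(4:6, 1:3)]
  names(swapped) <- names(inter)
  expect_equal(annotate_targets(regions, swapped, genes)$gene, "G1")

  # row order must not matter
  both <- rbind(inter, inter3)
  expect_equal(annotate_targets(regions, both, genes),
               annotate_targets(regions, both[2:1, ], genes),
               ignore_attr = TRUE)

  expect_equal(nrow(annotate_targets(regions, inter[0, ], genes)), 0)
})

test_that("low-expression filtering uses a strict 30% rule", {
  n <- 10
  lib <- 1e6
  counts <- rbind(
    g_low31 = c(rep(0L, 3), rep(100L, 7)),     # CPM<1 in 30%? 3/10=30% kept
    g_keep = rep(50L, n),
    g_zero = rep(0L, n)
  )
  filler <- matrix(rep((lib - colSums(counts)) %/% 5, each = 5),
                   5, n, byrow = FALSE)
  rownames(filler) <- paste0("f", 1:5)
  mat <- rbind(counts, filler)
  kept <- filter_low_expression(mat)
  expect_true("g_low31" %in% rownames(kept))   # exactly 30%: kept
  expect_true("g_keep" %in% rownames(kept))
  expect_false("g_zero" %in% rownames(kept))

  mat31 <- mat
  mat31["g_low31", 4] <- 0L                     # now 4/10 = 40% low
  expect_false("g_low31" %in% rownames(filter_low_expression(mat31)))

  bad <- mat
  bad[, 1] <- 0L
  expect_error(filter_low_expression(bad), "zero library")
})

test_that("TMM log-CPM matches the normalization arithmetic", {
  set.seed(51)
  base <- matrix(rnbinom(2000, mu = 200, size = 5), 500, 4)
  rownames(base) <- paste0("g", 1:500)
  same <- base[, c(1, 1, 1)]
  colnames(same) <- paste0("S", 1:3)
  norm <- tmm_logcpm(same)
  expect_equal(norm$norm_factors, rep(1, 3), tolerance = 1e-9)

  # doubling a library without changing composition leaves its factor ~1
  doubled <- cbind(base, base[, 4] * 2L)
  nf <- tmm_logcpm(doubled)$norm_factors
  expect_equal(nf[5], nf[4], tolerance = 0.02)

  # log2-CPM arithmetic at a known count and library size
  x <- matrix(c(1000L, 999000L, 1000L, 999000L), 2, 2)
  rownames(x) <- c("a", "b")
  lc <- tmm_logcpm(x)$logcpm
  expect_equal(lc["a", 1], log2((1000 + 0.5) / (1e6 + 1) * 1e6),
               tolerance = 1e-3)
})

test_that("differential expression recovers planted fold changes and stays null-calibrated", {
  set.seed(52)
  n <- 25; ng <- 1000
  meta <- data.frame(sample = paste0("S", 1:n),
                     age = runif(n, 60, 100), sex = sample(c("F", "M"), n, TRUE),
                     pmi = runif(n, 10, 60),
                     braak = sample(1:6, n, TRUE),
                     neuron_glu_prop = runif(n, 0.7, 0.85),
                     rin = runif(n, 6, 9))
  mu <- matrix(200, ng, n)
  planted <- 1:50  # 5% of genes, 2-fold per Braak-pair step
  lfc_per_braak <- log2(2) / 2.5
  mu[planted, ] <- mu[planted, ] *
    2^(outer(rep(lfc_per_braak, 50), meta$braak - 3.5))
  counts <- matrix(rnbinom(ng * n, mu = as.vector(mu), size = 20), ng, n,
                   dimnames = list(paste0("g", 1:ng), meta$sample))
  norm <- tmm_logcpm(filter_low_expression(counts))
  de <- de_genes(norm$logcpm, meta)
  hits <- which(de$q < 0.05)
  expect_gte(length(intersect(hits, planted)) / length(planted), 0.5)

  # permuting Braak labels empties the discovery list
  meta_perm <- meta
  set.seed(53)
  meta_perm$braak <- sample(meta_perm$braak)
  de_perm <- de_genes(norm$logcpm[-planted, ], meta_perm)
  expect_lte(sum(de_perm$q < 0.05, na.rm = TRUE), 2)

  # null FDR
  counts0 <- matrix(rnbinom(ng * n, mu = 200, size = 20), ng, n,
                    dimnames = dimnames(counts))
  de0 <- de_genes(tmm_logcpm(counts0)$logcpm, meta)
  expect_lte(mean(de0$q < 0.05, na.rm = TRUE), 0.075)
})

test_that("methylation-expression coupling yields the expected correlations", {
  meth <- c(r1 = -0.4, r2 = -0.2, r3 = 0.1, r4 = 0.3)
  expr <- -2.5 * meth
  pairs <- data.frame(region = names(meth), gene = names(expr))
  names(expr) <- names(meth)
  out <- meth_expr_correlation(meth, expr, pairs)
  expect_equal(out$r, -1, tolerance = 1e-12)

  set.seed(54)
  small_r <- replicate(20, {
    m <- rnorm(500); e <- rnorm(500)
    names(m) <- names(e) <- paste0("x", 1:500)
    meth_expr_correlation(m, e, data.frame(region = names(m),
                                           gene = names(e)))$r
  })
  expect_gte(mean(abs(small_r) < 0.1), 0.95)

  expect_error(meth_expr_correlation(meth[1:2], expr[1:2], pairs[1:2, ]),
               "at least 3")
  cst <- c(a = 1, b = 1, c = 1)
  expect_warning(
    res0 <- meth_expr_correlation(cst, cst,
                                  data.frame(region = names(cst),
                                             gene = names(cst))),
    "zero variance")
  expect_true(is.na(res0$r))
})

test_that("genes behind hypomethylated enhancers surface as upregulated", {
  for (seed in c(611, 612, 613)) {
    cfg <- sim_config(n_samples = 25, n_regions = 300,
                      sites_per_region = list(mean = 5, min = 1),
                      dmr_fraction = 0.1, dmr_effect_logit = 0.3,
                      n_genes = 500, seed = seed)
    meta <- generate_cohort(cfg)
    sim <- generate_methylation(meta, cfg)
    expr <- generate_expression(meta, sim$truth, cfg)
    counts <- filter_low_expression(expr$counts)
    de <- de_genes(tmm_logcpm(counts)$logcpm, meta)
    up <- rownames(counts)[de$q < 0.05 & de$coefficients[, "braak"] > 0]
    tr <- sim$truth$enhancer_gene_truth
    hypo_genes <- tr$gene[sim$truth$region_sign[tr$region] < 0]
    res <- overlap_enrichment(hypo_genes[hypo_genes %in% rownames(counts)],
                              up, rownames(counts))
    expect_lt(res$p, 0.05)
  }
})

test_that("set-overlap enrichment equals enumeration and is symmetric", {
  u <- paste0("g", 1:1000)
  a <- u[1:10]; b <- u[1:10]
  expect_equal(overlap_enrichment(a, b, u)$p, 1 / choose(1000, 10))

  expect_equal(overlap_enrichment(u[1:5], u[6:10], u)$p, 1)

  u2 <- paste0("g", 1:100)
  res <- overlap_enrichment(u2[1:20], u2[c(1:6, 30:53)], u2)
  expect_equal(res$overlap, 6)
  expect_equal(res$p, hyper_tail_enum(6, 30, 20, 100), tolerance = 1e-12)
  expect_gt(res$p, 0.3); expect_lt(res$p, 0.7)

  expect_equal(overlap_enrichment(u2[1:20], u2[c(1:6, 30:53)], u2)$p,
               overlap_enrichment(u2[c(1:6, 30:53)], u2[1:20], u2)$p)
  expect_error(overlap_enrichment(c("nope"), u2[1:3], u2), "outside")
})
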