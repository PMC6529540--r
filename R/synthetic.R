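#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the
#' study conditions the pipeline is designed for: 101 donors with ages
#' centred near 83 years (range 54-105) split 38/32/31 across Braak stage
#' pairs 1-2/3-4/5-6, binomial read sampling at sequencing depths
#' averaging well above the 30-read call threshold, a ~9:1 CpH:CpG site
#' ratio, Braak-linked logit-scale effects at planted DMR regions (mostly
#' hypomethylation), an age-linked CpH methylation decline, and a small
#' bisulfite conversion failure rate.
#'
#' @param n_samples number of donors.
#' @param braak_probs probabilities of Braak stages 1-6 (sum to 1).
#' @param age_mean,age_sd,age_range normal age distribution, truncated.
#' @param n_regions number of regulatory regions probed.
#' @param sites_per_region list(mean, min): site count per region is
#'   min + Poisson(mean - min).
#' @param cph_fraction fraction of sites in CpH context.
#' @param depth_mean,depth_dispersion negative-binomial read depth
#'   (mean, size), truncated at 1.
#' @param dmr_fraction fraction of regions planted with a Braak effect.
#' @param dmr_effect_logit planted per-Braak-unit shift on the log-odds
#'   scale.
#' @param dmr_hypo_prob probability a planted region is hypomethylated in
#'   disease.
#' @param age_slope_logit mean per-year logit slope at CpH sites
#'   (negative: decline with age).
#' @param age_scatter_years standard deviation of the per-sample
#'   methylome-age offset: each donor's methylome reflects
#'   age + N(0, age_scatter_years), emulating the inter-individual
#'   epigenetic-aging variability clock studies report (default 3).
#' @param conversion_failure probability an unmethylated cytosine escapes
#'   bisulfite conversion and reads as methylated.
#' @param noise_sd_logit per site/sample Gaussian noise on the logit mean
#'   (beta-binomial-type overdispersion).
#' @param sex_effect_logit,pmi_effect_logit,neuron_effect_logit covariate
#'   confounding hooks (default 0 so tests can isolate each adjustment).
#' @param n_genes,nb_size,coupling_log2_per_pct expression generator:
#'   gene count, negative-binomial size, and log2 expression change per
#'   percentage point of enhancer methylation deviation for coupled pairs.
#' @param ref_markers,ref_mixtures,ref_depth deconvolution reference
#'   panel: marker count, mixture sample count, read depth of mixture
#'   noise (Inf = noise-free).
#' @param seed master seed; per-stage substreams are derived from it.
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_samples = 101,
                       braak_probs = c(19, 19, 16, 16, 15.5, 15.5) / 101,
                       age_mean = 83.03, age_sd = 9,
                       age_range = c(54, 105),
                       n_regions = 400,
                       sites_per_region = list(mean = 5, min = 1),
                       cph_fraction = 1085436 / 1207507,
                       depth_mean = 60, depth_dispersion = 8,
                       dmr_fraction = 0.05,
                       dmr_effect_logit = 0.15,
                       dmr_hypo_prob = 0.7606,
                       age_slope_logit = -0.01,
                       age_scatter_years = 3,
                       conversion_failure = 0.0076,
                       noise_sd_logit = 0.1,
                       sex_effect_logit = 0,
                       pmi_effect_logit = 0,
                       neuron_effect_logit = 0,
                       n_genes = 2000,
                       nb_size = 10,
                       coupling_log2_per_pct = 0.3,
                       ref_markers = 200,
                       ref_mixtures = 50,
                       ref_depth = 40,
                       seed = 1) {
  cfg <- as.list(environment())
  if (length(braak_probs) != 6 || any(braak_probs < 0) ||
      abs(sum(braak_probs) - 1) > 1e-9)
    stop2("braak_probs must be 6 nonnegative probabilities summing to 1")
  assert_prob(cph_fraction, "cph_fraction")
  assert_prob(dmr_fraction, "dmr_fraction")
  assert_prob(dmr_hypo_prob, "dmr_hypo_prob")
  assert_prob(conversion_failure, "conversion_failure")
  if (depth_mean < 1) stop2("depth_mean must be >= 1")
  if (depth_dispersion <= 0) stop2("depth_dispersion must be positive")
  if (noise_sd_logit < 0) stop2("noise_sd_logit must be nonnegative")
  if (n_samples < 1 || n_regions < 1) stop2("counts must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples,", x$n_regions, "regions,",
      "seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws donor metadata: truncated-normal ages, Braak stages from the
#' configured probabilities, sex, postmortem interval, RNA integrity, and
#' a true glutamatergic-neuron proportion in the 0.70-0.85 range typical
#' of prefrontal cortex.
#'
#' @param config a [sim_config()].
#' @return sample metadata data.frame (one row per donor).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  with_seed(substream(config$seed, "cohort"), {
    lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
    hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
    age <- stats::qnorm(stats::runif(n, lo, hi),
                        config$age_mean, config$age_sd)
    meta <- data.frame(
      sample = sprintf("S%03d", seq_len(n)),
      age = round(age, 1),
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(47, 54) / 101),
      pmi = round(stats::runif(n, 6, 72), 1),
      braak = sample(1:6, n, replace = TRUE, prob = config$braak_probs),
      neuron_glu_prop = round(stats::runif(n, 0.70, 0.85), 3),
      rin = round(stats::runif(n, 5.5, 9.5), 1),
      stringsAsFactors = FALSE
    )
    meta$replicate_group <- meta$sample
    meta$control_flag <- FALSE
    validate_metadata(meta)
    meta
  })
}

#' Generate synthetic methylation data with ground truth
#'
#' Lays regions along chromosomes with within-region site gaps well under
#' the 1000 bp chaining distance and between-region gaps well over it;
#' plants a Braak-linked logit effect in a random subset of regions
#' (hypomethylated with probability \code{dmr_hypo_prob}) and an
#' age-linked slope at CpH sites; then draws read depths from a truncated
#' negative binomial and methylated counts from a binomial whose success
#' probability is the logit-normal site mean mixed with the conversion
#' failure rate: \eqn{p_obs = p* + (1 - p*) f}.
#'
#' @param meta cohort metadata from [generate_cohort()].
#' @param config a [sim_config()].
#' @return list with \code{matrix} (a [meth_matrix()]), \code{calls} (the
#'   matching \code{meth_calls} count table) and \code{truth} (a
#'   \code{sim_truth} record: planted region ids and effects, per-site
#'   baselines and age slopes, per-sample true subtype proportions,
#'   expected per-region methylation, and enhancer-gene couplings).
#' @export
generate_methylation <- function(meta, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(meta) == 0) stop2("metadata is empty")
  with_seed(substream(config$seed, "methylation"), {
    spr <- config$sites_per_region
    n_sites_r <- spr$min + stats::rpois(config$n_regions,
                                        max(0, spr$mean - spr$min))
    n_regions <- config$n_regions
    # one chromosome block per ~40 regions; regions 10 kb apart
    chrom <- paste0("chr", 1 + (seq_len(n_regions) - 1) %/% 40)
    region_start <- 10000L * (((seq_len(n_regions) - 1) %% 40) + 1L)
    sites <- do.call(rbind, lapply(seq_len(n_regions), function(r) {
      k <- n_sites_r[r]
      gaps <- sample(2:120, k, replace = TRUE)
      data.frame(chrom = chrom[r],
                 pos = region_start[r] + cumsum(gaps),
                 region = r)
    }))
    ns <- nrow(sites)
    sites$strand <- sample(c("+", "-"), ns, replace = TRUE)
    sites$context <- ifelse(stats::runif(ns) < config$cph_fraction,
                            "CpH", "CpG")
    baseline <- ifelse(sites$context == "CpG",
                       stats::runif(ns, 0.20, 0.80),
                       stats::runif(ns, 0.03, 0.15))

    n_planted <- floor(config$dmr_fraction * n_regions)
    planted <- if (n_planted > 0) sort(sample(n_regions, n_planted))
               else integer(0)
    region_sign <- numeric(n_regions)
    region_sign[planted] <- ifelse(
      stats::runif(n_planted) < config$dmr_hypo_prob, -1, 1)
    effect <- config$dmr_effect_logit * region_sign[sites$region]

    age_slope <- ifelse(
      sites$context == "CpH",
      config$age_slope_logit * stats::runif(ns, 0.5, 1.5), 0)

    nsam <- nrow(meta)
    sexM <- as.numeric(meta$sex == "M")
    pmi_z <- (meta$pmi - mean(meta$pmi)) / max(stats::sd(meta$pmi), 1e-8)
    glu_c <- meta$neuron_glu_prop - mean(meta$neuron_glu_prop)
    # each donor's methylome age deviates from chronological age
    age_offset <- stats::rnorm(nsam, 0, config$age_scatter_years)
    age_c <- meta$age + age_offset - mean(meta$age)

    lin <- logit(baseline) +
      outer(effect, as.numeric(meta$braak)) +
      outer(age_slope, age_c) +
      outer(rep(1, ns), config$sex_effect_logit * sexM +
                          config$pmi_effect_logit * pmi_z +
                          config$neuron_effect_logit * glu_c)
    if (config$noise_sd_logit > 0)
      lin <- lin + matrix(stats::rnorm(ns * nsam, 0,
                                       config$noise_sd_logit), ns, nsam)
    p_star <- ilogit(lin)
    p_obs <- p_star + (1 - p_star) * config$conversion_failure

    depth <- matrix(stats::rnbinom(ns * nsam, mu = config$depth_mean,
                                   size = config$depth_dispersion),
                    ns, nsam)
    depth[depth < 1] <- 1L
    methc <- matrix(stats::rbinom(ns * nsam, as.vector(depth),
                                  as.vector(p_obs)), ns, nsam)
    colnames(depth) <- colnames(methc) <- meta$sample

    site_df <- sites[c("chrom", "pos", "strand", "context")]
    keys <- site_key(site_df$chrom, site_df$pos, site_df$strand)
    rownames(depth) <- rownames(methc) <- keys
    calls <- structure(
      list(sites = `rownames<-`(site_df, keys), meth = methc,
           total = depth, samples = meta$sample),
      class = "meth_calls")
    mm <- meth_matrix(methc / depth, depth, site_df)

    region_meth <- rowsum(p_star, sites$region) /
      tabulate(sites$region, nbins = n_regions)
    rownames(region_meth) <- paste0("region_", seq_len(n_regions))
    colnames(region_meth) <- meta$sample

    # sign = +1: inverse coupling (methylation down -> expression up)
    coupled <- if (n_planted > 0)
      data.frame(region = planted,
                 gene = sprintf("G%04d", planted),
                 sign = 1)
    else data.frame(region = integer(), gene = character(),
                    sign = numeric())

    truth <- structure(
      list(planted_dmr_ids = planted,
           region_sign = region_sign,
           sites = data.frame(key = keys, region = sites$region,
                              context = site_df$context,
                              baseline = baseline, effect = effect,
                              age_slope = age_slope),
           regions = data.frame(
             region = seq_len(n_regions), chrom = chrom,
             start = region_start,
             planted = seq_len(n_regions) %in% planted,
             sign = region_sign),
           true_neuron_proportions = data.frame(
             sample = meta$sample, GLU = meta$neuron_glu_prop,
             GABA = 1 - meta$neuron_glu_prop),
           methylome_age_offset = stats::setNames(age_offset, meta$sample),
           region_meth = region_meth,
           enhancer_gene_truth = coupled,
           config = config),
      class = "sim_truth")
    list(matrix = mm, calls = calls, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$sites), "sites in", nrow(x$regions),
      "regions;", length(x$planted_dmr_ids), "planted DMRs (",
      sum(x$region_sign < 0), "hypo )\n")
  invisible(x)
}

#' Generate RNA-seq counts coupled to enhancer methylation
#'
#' Negative-binomial gene counts with varying library sizes. Genes named
#' in the truth's enhancer-gene couplings get a log2 mean shifted by
#' \code{-sign * coupling_log2_per_pct} per percentage point that their
#' enhancer's expected methylation deviates from the cohort mean, so
#' hypomethylated enhancers up-regulate their targets.
#'
#' @param meta cohort metadata (the expression subset of the cohort).
#' @param truth \code{sim_truth} from [generate_methylation()].
#' @param config a [sim_config()].
#' @return list with \code{counts} (genes x samples integer matrix) and
#'   \code{genes} (gene, chrom, tss, strand), coupled genes placed in cis
#'   with their enhancer.
#' @export
generate_expression <- function(meta, truth, config) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(substream(config$seed, "expression"), {
    ng <- config$n_genes
    coupled <- truth$enhancer_gene_truth
    gene_ids <- sprintf("G%04d", seq_len(ng))
    # place coupled genes on their enhancer's chromosome, ~50 kb away
    reg <- truth$regions
    chrom <- sample(paste0("chr", 1:22), ng, replace = TRUE)
    tss <- as.integer(stats::runif(ng, 1e6, 5e7))
    ci <- match(coupled$gene, gene_ids)
    if (anyNA(ci)) stop2("coupled gene ids outside the gene table")
    chrom[ci] <- reg$chrom[coupled$region]
    tss[ci] <- reg$start[coupled$region] + 50000L
    genes <- data.frame(gene = gene_ids, chrom = chrom, tss = tss,
                        strand = sample(c("+", "-"), ng, replace = TRUE))

    nsam <- nrow(meta)
    log2mu <- matrix(stats::runif(ng, 3, 9), ng, nsam)
    if (nrow(coupled)) {
      mcols <- match(meta$sample, colnames(truth$region_meth))
      if (anyNA(mcols))
        stop2("expression samples absent from methylation truth")
      dev_pct <- 100 * (truth$region_meth[coupled$region, mcols,
                                          drop = FALSE] -
                          rowMeans(truth$region_meth[coupled$region, ,
                                                     drop = FALSE]))
      log2mu[ci, ] <- log2mu[ci, ] -
        config$coupling_log2_per_pct * coupled$sign * dev_pct
    }
    libfac <- stats::runif(nsam, 0.7, 1.4)
    mu <- t(t(2^log2mu) * libfac)
    counts <- matrix(stats::rnbinom(ng * nsam, mu = as.vector(mu),
                                    size = config$nb_size),
                     ng, nsam, dimnames = list(gene_ids, meta$sample))
    list(counts = counts, genes = genes)
  })
}

#' Generate enhancer-promoter interaction pairs
#'
#' Emits one interaction per enhancer-gene coupling in the truth record:
#' anchor 1 spans the source region, anchor 2 falls inside the +/- 2 kb
#' promoter window of the target gene's TSS, on the same chromosome
#' (cis).
#'
#' @param truth \code{sim_truth}.
#' @param genes gene table from [generate_expression()].
#' @param anchor_size anchor width in bp (default 1000).
#' @return BEDPE-like data.frame (chrom1, start1, end1, chrom2, start2,
#'   end2, score).
#' @export
generate_interactions <- function(truth, genes, anchor_size = 1000) {
  stopifnot(inherits(truth, "sim_truth"))
  coupled <- truth$enhancer_gene_truth
  if (nrow(coupled) == 0)
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      score = numeric()))
  gi <- match(coupled$gene, genes$gene)
  if (anyNA(gi))
    stop2("gene id absent from gene table: ",
          paste(coupled$gene[is.na(gi)], collapse = ", "))
  reg <- truth$regions[coupled$region, ]
  data.frame(
    chrom1 = reg$chrom,
    start1 = reg$start,
    end1 = reg$start + anchor_size,
    chrom2 = genes$chrom[gi],
    start2 = pmax(0L, genes$tss[gi] - 500L),
    end2 = genes$tss[gi] + 500L,
    score = 1
  )
}

#' Generate a two-subtype deconvolution reference panel
#'
#' Marker sites whose mean betas differ between glutamatergic and
#' GABAergic profiles by margins of 0.1-0.5, plus mixture samples that
#' are convex combinations of the two profiles with binomial read noise
#' at \code{ref_depth} (exact when \code{ref_depth = Inf}).
#'
#' @param config a [sim_config()].
#' @return list with \code{panel} (markers x 2 reference betas),
#'   \code{mixtures} (markers x mixtures betas) and \code{weights}
#'   (mixtures x 2 true proportions).
#' @export
generate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream(config$seed, "reference"), {
    m <- config$ref_markers
    r1 <- stats::runif(m, 0.1, 0.9)
    margin <- stats::runif(m, 0.1, 0.5) * sample(c(-1, 1), m, replace = TRUE)
    r2 <- pmin(0.98, pmax(0.02, r1 + margin))
    panel <- cbind(GLU = r1, GABA = r2)
    rownames(panel) <- sprintf("marker_%03d", seq_len(m))
    w_glu <- stats::runif(config$ref_mixtures, 0.55, 0.95)
    weights <- cbind(GLU = w_glu, GABA = 1 - w_glu)
    rownames(weights) <- sprintf("mix_%03d", seq_len(config$ref_mixtures))
    expect <- panel %*% t(weights)
    mixtures <- if (is.finite(config$ref_depth)) {
      matrix(stats::rbinom(length(expect), config$ref_depth,
                           as.vector(expect)) / config$ref_depth,
             nrow(expect), ncol(expect), dimnames = dimnames(expect))
    } else expect
    list(panel = panel, mixtures = mixtures, weights = weights)
  })
}

#' Write a synthetic truth record as structured text (JSON)
#' @param truth \code{sim_truth}.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  x <- truth
  x$config <- unclass(x$config)
  x$region_meth <- NULL  # large; reproducible from the seed
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
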