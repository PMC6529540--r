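#' Pipeline configuration
#'
#' All thresholds of the analysis in one record, with the defaults used
#' throughout: 30-read coverage, 70% call rate, top-decile DMC selection,
#' 1000 bp region chaining, q < 0.05 with >= 1% methylation change,
#' +/- 2 kb promoter windows, elastic-net alpha 0.5 with 10-fold CV.
#'
#' @param min_depth,call_rate,max_deviation preprocessing thresholds.
#' @param top_fraction,gap,q,min_change DMR thresholds.
#' @param promoter_window promoter half-width (bp).
#' @param alpha,folds clock hyperparameters.
#' @param snp_bed optional path to a SNP BED mask.
#' @param seed master seed.
#' @param sim simulation configuration ([sim_config()]) used by the
#'   simulate stage; defaults share the master seed.
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(min_depth = 30, call_rate = 0.70,
                            max_deviation = 0.10, top_fraction = 0.10,
                            gap = 1000, q = 0.05, min_change = 0.01,
                            promoter_window = 2000, alpha = 0.5,
                            folds = 10, snp_bed = NULL, seed = 1,
                            sim = sim_config(seed = seed)) {
  stopifnot(min_depth >= 1, call_rate >= 0, call_rate <= 1,
            top_fraction > 0, top_fraction <= 1, gap >= 0,
            q >= 0, q <= 1, min_change >= 0, promoter_window >= 0,
            alpha >= 0, alpha <= 1, folds >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages over a synthetic cohort: \code{simulate}
#' writes the raw inputs; \code{preprocess} applies the coverage, SNP,
#' replicate-merge, missingness and sample-QC filters; \code{dmc} runs
#' the site-level moderated robust regression; \code{dmr} calls
#' differentially methylated regions; \code{deconvolve} estimates subtype
#' proportions on the reference mixtures; \code{clock} trains the CpH age
#' model on Braak 1-2 and tests acceleration in Braak 5-6;
#' \code{integrate} links enhancers to genes and correlates methylation
#' and expression responses; \code{report} collates counts. \code{all}
#' runs everything. Every run writes a resolved-config copy and a
#' machine-readable filter-accounting log; outputs are plain TSV/BED.
#'
#' @param stage one of simulate, preprocess, dmc, dmr, deconvolve, clock,
#'   integrate, report, all.
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(stage = "all", config = pipeline_config(),
                         outdir = "pipeline_out") {
  stages <- c("simulate", "preprocess", "dmc", "dmr", "deconvolve",
              "clock", "integrate", "report", "all")
  stage <- match.arg(stage, stages)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_out <- unclass(config)
  cfg_out$sim <- unclass(cfg_out$sim)
  jsonlite::write_json(cfg_out, file.path(outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log <- list()
  note <- function(stage, metric, value) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, metric = metric,
                                          value = as.numeric(value))
  }
  res <- list()
  todo <- if (stage == "all") stages[1:8] else stage

  if ("simulate" %in% todo) {
    meta <- generate_cohort(config$sim)
    sim <- generate_methylation(meta, config$sim)
    expr <- generate_expression(meta, sim$truth, config$sim)
    inter <- generate_interactions(sim$truth, expr$genes)
    panel <- generate_reference_panel(config$sim)
    write_tsv(meta, file.path(outdir, "metadata.tsv"))
    write_methylation_calls(sim$calls, file.path(outdir, "calls.tsv"))
    write_tsv(data.frame(gene = rownames(expr$counts), expr$counts,
                         check.names = FALSE),
              file.path(outdir, "counts.tsv"))
    write_tsv(expr$genes, file.path(outdir, "genes.tsv"))
    utils::write.table(inter, file.path(outdir, "interactions.bedpe"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_tsv(data.frame(marker = rownames(panel$panel), panel$panel),
              file.path(outdir, "reference_panel.tsv"))
    write_tsv(data.frame(marker = rownames(panel$mixtures),
                         panel$mixtures, check.names = FALSE),
              file.path(outdir, "reference_mixtures.tsv"))
    write_truth(sim$truth, file.path(outdir, "truth.json"))
    note("simulate", "n_samples", nrow(meta))
    note("simulate", "n_sites", nrow(sim$matrix$beta))
    note("simulate", "n_planted_dmrs", length(sim$truth$planted_dmr_ids))
    res$meta <- meta; res$sim <- sim; res$expr <- expr
    res$inter <- inter; res$panel <- panel
  }
  if (any(c("preprocess", "dmc", "dmr", "clock", "integrate",
            "report") %in% todo)) {
    if (is.null(res$meta)) {
      res$meta <- read_tsv(file.path(outdir, "metadata.tsv"))
      calls <- read_methylation_calls(file.path(outdir, "calls.tsv"))
    } else calls <- res$sim$calls
  }
  if ("preprocess" %in% todo) {
    m <- coverage_filter(calls, config$min_depth)
    n0 <- nrow(m$beta)
    note("preprocess", "sites_in", n0)
    if (!is.null(config$snp_bed)) {
      m <- mask_snp_sites(m, config$snp_bed)
      note("preprocess", "sites_after_snp_mask", nrow(m$beta))
      note("preprocess", "sites_dropped_snp", n0 - nrow(m$beta))
    }
    m <- merge_replicates(m, res$meta)
    n1 <- nrow(m$beta)
    m <- missingness_filter(m, config$call_rate)
    note("preprocess", "sites_after_missingness", nrow(m$beta))
    note("preprocess", "sites_dropped_missingness", n1 - nrow(m$beta))
    qc <- sample_qc(m, config$max_deviation)
    note("preprocess", "samples_excluded", sum(qc$excluded$excluded))
    write_tsv(qc$excluded, file.path(outdir, "sample_qc.tsv"))
    write_meth_matrix(qc$matrix, file.path(outdir, "beta_matrix.tsv"))
    res$matrix <- qc$matrix
  }
  if (any(c("dmc", "dmr", "clock") %in% todo) && is.null(res$matrix))
    res$matrix <- read_meth_matrix(file.path(outdir, "beta_matrix.tsv"))
  if ("dmc" %in% todo) {
    meta_m <- res$meta[match(colnames(res$matrix$beta), res$meta$sample), ]
    design <- make_design(meta_m)
    fit <- ebayes(fit_robust(beta_to_m(res$matrix$beta), design))
    res$fit <- fit
    tab <- summary(fit)
    infl <- inflation_factor(fit$t)
    note("dmc", "lambda_inflation", infl$lambda)
    note("dmc", "bias", infl$bias)
    note("dmc", "n_sites_tested", sum(!is.na(fit$p)))
    write_tsv(tab, file.path(outdir, "site_results.tsv"))
  }
  if ("dmr" %in% todo) {
    if (is.null(res$fit)) stop2("dmr stage needs the dmc stage results; ",
                                "run stage='dmc' first (site_results in ",
                                outdir, ")")
    meta_m <- res$meta[match(colnames(res$matrix$beta), res$meta$sample), ]
    dmc <- select_top_decile(res$fit$p, res$matrix$sites,
                             config$top_fraction)
    grouping <- group_regions(res$matrix$sites, config$gap)
    delta <- delta_beta(res$matrix, meta_m)
    dmrs <- call_dmrs(grouping, dmc, delta, config$q, config$min_change)
    summ <- dmr_summary(dmrs, res$matrix$sites$context, dmc)
    res$dmc <- dmc; res$grouping <- grouping; res$dmrs <- dmrs
    res$dmr_summary <- summ
    note("dmr", "regions_tested", nrow(dmrs))
    note("dmr", "regions_significant", sum(dmrs$significant))
    write_tsv(as.data.frame(dmrs), file.path(outdir, "dmr_results.tsv"))
    write_dmr_bed(dmrs, file.path(outdir, "dmr_significant.bed"))
    jsonlite::write_json(summ, file.path(outdir, "dmr_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("deconvolve" %in% todo) {
    if (is.null(res$panel)) {
      pan <- read_tsv(file.path(outdir, "reference_panel.tsv"))
      mix <- read_tsv(file.path(outdir, "reference_mixtures.tsv"))
      res$panel <- list(
        panel = as.matrix(pan[, -1, drop = FALSE]),
        mixtures = as.matrix(mix[, -1, drop = FALSE]))
    }
    dec <- estimate_proportions(res$panel$mixtures, res$panel$panel)
    res$deconv <- dec
    write_tsv(dec$proportions, file.path(outdir, "proportions.tsv"))
    note("deconvolve", "n_mixtures", nrow(dec$proportions))
  }
  if ("clock" %in% todo) {
    meta_m <- res$meta[match(colnames(res$matrix$beta), res$meta$sample), ]
    cph <- res$matrix$sites$context == "CpH"
    B <- t(res$matrix$beta[cph, , drop = FALSE])
    train <- meta_m$braak %in% 1:2
    test <- meta_m$braak %in% 5:6
    Bc <- B[, colSums(is.na(B)) == 0, drop = FALSE]
    nfold <- max(3, min(config$folds, floor(sum(train) / 3)))
    model <- fit_clock(Bc[train, , drop = FALSE], meta_m$age[train],
                       alpha = config$alpha, folds = nfold,
                       seed = config$seed)
    pred <- predict(model, Bc[test, , drop = FALSE])
    acc <- acceleration_test(pred, meta_m$age[test])
    res$clock <- model; res$acceleration <- acc
    note("clock", "n_train", sum(train))
    note("clock", "n_test", sum(test))
    note("clock", "mean_acceleration", acc$mean_acceleration)
    write_tsv(data.frame(site = model$sites, coef = model$coefficients),
              file.path(outdir, "clock_model.tsv"))
    write_tsv(acc$samples, file.path(outdir, "clock_predictions.tsv"))
  }
  if ("integrate" %in% todo) {
    if (is.null(res$expr)) {
      cts <- read_tsv(file.path(outdir, "counts.tsv"))
      counts <- as.matrix(cts[, -1, drop = FALSE])
      rownames(counts) <- cts$gene
      genes <- read_tsv(file.path(outdir, "genes.tsv"))
      inter <- utils::read.table(file.path(outdir, "interactions.bedpe"),
                                 sep = "\t")
      names(inter)[1:6] <- c("chrom1", "start1", "end1",
                             "chrom2", "start2", "end2")
      res$expr <- list(counts = counts, genes = genes)
      res$inter <- inter
    }
    if (is.null(res$dmrs)) stop2("integrate stage needs dmr results")
    counts <- filter_low_expression(res$expr$counts)
    norm <- tmm_logcpm(counts)
    meta_e <- res$meta[match(colnames(counts), res$meta$sample), ]
    de <- de_genes(norm$logcpm, meta_e)
    # region-level methylation response: mean member-site Braak coefficient
    bsite <- res$fit$coefficients[, "braak"]
    rid_f <- factor(res$grouping$site_region,
                    levels = res$dmrs$region)
    meth_coef <- as.numeric(tapply(bsite, rid_f, mean, na.rm = TRUE))
    names(meth_coef) <- res$dmrs$region
    pairs <- annotate_targets(res$dmrs, res$inter, res$expr$genes,
                              config$promoter_window)
    expr_coef <- de$coefficients[, "braak"]
    names(expr_coef) <- rownames(counts)
    corr <- if (nrow(pairs) >= 3)
      meth_expr_correlation(meth_coef, expr_coef, pairs)
    else list(r = NA_real_, p = NA_real_, n = nrow(pairs))
    res$de <- de; res$pairs <- pairs; res$meth_expr <- corr
    note("integrate", "genes_tested", nrow(counts))
    note("integrate", "de_genes_q05", sum(de$q < 0.05, na.rm = TRUE))
    note("integrate", "pairs_annotated", nrow(pairs))
    write_tsv(summary(de), file.path(outdir, "de_results.tsv"))
    write_tsv(pairs, file.path(outdir, "enhancer_gene_pairs.tsv"))
    jsonlite::write_json(corr, file.path(outdir, "meth_expr_corr.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("report" %in% todo && length(log)) {
    report <- do.call(rbind, log)
    write_tsv(report, file.path(outdir, "pipeline_log.tsv"))
  } else if (length(log)) {
    write_tsv(do.call(rbind, log), file.path(outdir, "pipeline_log.tsv"))
  }
  invisible(res)
}

#' Write a methylation matrix as TSV (sites + beta and depth columns)
#' @param m a \code{meth_matrix}.
#' @param path output path.
#' @export
write_meth_matrix <- function(m, path) {
  stopifnot(inherits(m, "meth_matrix"))
  out <- cbind(m$sites,
               as.data.frame(m$beta),
               stats::setNames(as.data.frame(m$depth),
                               paste0("depth.", colnames(m$depth))))
  write_tsv(out, path)
}

#' Read a methylation matrix written by [write_meth_matrix()]
#' @param path TSV path.
#' @return a \code{meth_matrix}.
#' @export
read_meth_matrix <- function(path) {
  tab <- read_tsv(path)
  ann <- c("chrom", "pos", "strand", "context")
  depth_cols <- grep("^depth\\.", names(tab))
  beta_cols <- setdiff(seq_along(tab), c(match(ann, names(tab)), depth_cols))
  beta <- as.matrix(tab[, beta_cols, drop = FALSE])
  depth <- as.matrix(tab[, depth_cols, drop = FALSE])
  colnames(depth) <- sub("^depth\\.", "", colnames(depth))
  meth_matrix(beta, depth, tab[, ann])
}
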