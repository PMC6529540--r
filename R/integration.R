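#' Annotate enhancer target genes through chromatin interactions
#'
#' Emits a (region, gene) pair when one interaction anchor overlaps the
#' region and the other anchor overlaps the gene's promoter window
#' \code{[TSS - window, TSS + window)} (half-open; strand-symmetric).
#' Anchors are interchangeable, and the output is independent of
#' interaction row order.
#'
#' @param regions data.frame with \code{region}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), e.g. significant rows
#'   of a \code{dmr_result}.
#' @param interactions BEDPE-like data.frame (chrom1, start1, end1,
#'   chrom2, start2, end2).
#' @param genes gene table (gene, chrom, tss).
#' @param window promoter half-width in bp (default 2000).
#' @return data.frame of unique (region, gene) pairs plus
#'   \code{targets_per_region} attribute.
#' @export
annotate_targets <- function(regions, interactions, genes, window = 2000) {
  if (nrow(interactions) == 0 || nrow(regions) == 0)
    return(empty_pairs())
  a1 <- GenomicRanges::GRanges(
    interactions$chrom1,
    IRanges::IRanges(interactions$start1 + 1L, interactions$end1))
  a2 <- GenomicRanges::GRanges(
    interactions$chrom2,
    IRanges::IRanges(interactions$start2 + 1L, interactions$end2))
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  # promoter [tss - w, tss + w) half-open, 0-based -> 1-based closed
  prom_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(0L, genes$tss - window) + 1L,
                     genes$tss + window))
  pairs_one <- function(anchor_r, anchor_p) {
    hr <- GenomicRanges::findOverlaps(anchor_r, reg_gr)
    hp <- GenomicRanges::findOverlaps(anchor_p, prom_gr)
    rr <- split(S4Vectors::subjectHits(hr), S4Vectors::queryHits(hr))
    pp <- split(S4Vectors::subjectHits(hp), S4Vectors::queryHits(hp))
    common <- intersect(names(rr), names(pp))
    if (!length(common)) return(NULL)
    do.call(rbind, lapply(common, function(i)
      expand.grid(ri = rr[[i]], gi = pp[[i]])))
  }
  hits <- rbind(pairs_one(a1, a2), pairs_one(a2, a1))
  if (is.null(hits) || nrow(hits) == 0) return(empty_pairs())
  out <- unique(data.frame(region = regions$region[hits$ri],
                           gene = genes$gene[hits$gi]))
  out <- out[order(out$region, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "targets_per_region") <- table(out$region)
  out
}

empty_pairs <- function() {
  out <- data.frame(region = integer(), gene = character())
  attr(out, "targets_per_region") <- table(integer())
  out
}

#' Remove low-expressed genes
#'
#' Drops genes whose counts-per-million fall below \code{cpm_threshold}
#' in more than \code{max_fraction} of samples (strict inequality: a gene
#' low in exactly that fraction is kept).
#'
#' @param counts genes x samples nonnegative integer matrix.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param max_fraction tolerated fraction of low samples (default 0.30).
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  max_fraction = 0.30) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stop2("zero library size in sample(s): ",
                           paste(colnames(counts)[lib == 0], collapse = ", "))
  cpm <- t(t(counts) / lib) * 1e6
  low_frac <- rowMeans(cpm < cpm_threshold)
  counts[low_frac <= max_fraction, , drop = FALSE]
}

#' TMM normalization and log2-CPM
#'
#' Trimmed-mean-of-M-values scale factors (via edgeR) with factors, then
#' log2 counts-per-million on the effective library sizes with prior
#' count 0.5.
#'
#' @param counts filtered genes x samples count matrix.
#' @param prior_count prior added before the log (default 0.5).
#' @return list with \code{logcpm} matrix and \code{norm_factors}.
#' @export
tmm_logcpm <- function(counts, prior_count = 0.5) {
  counts <- as.matrix(counts)
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  logcpm <- edgeR::cpm(dge, log = TRUE, prior.count = prior_count)
  list(logcpm = logcpm, norm_factors = dge$samples$norm.factors)
}

#' Differential expression with the shared robust engine
#'
#' Per-gene covariate-adjusted robust fit with empirical-Bayes moderation
#' on log2-CPM values; identical contract to the methylation site scan,
#' with RIN included among the covariates.
#'
#' @param logcpm genes x samples matrix from [tmm_logcpm()].
#' @param meta sample metadata (must include \code{rin}).
#' @param covariates adjustment covariates (default adds rin).
#' @return a \code{site_fit} with moderated statistics for the Braak
#'   coefficient.
#' @export
de_genes <- function(logcpm, meta,
                     covariates = c("age", "sex", "pmi",
                                    "neuron_glu_prop", "rin")) {
  design <- make_design(meta, covariates = covariates)
  design <- design[match(colnames(logcpm), rownames(design)), ,
                   drop = FALSE]
  if (anyNA(design)) stop2("expression samples missing from metadata")
  fit <- fit_robust(logcpm, design)
  ebayes(fit, coef = "braak")
}

#' Correlate methylation and expression responses to pathology
#'
#' Pearson correlation, across enhancer-gene pairs, of the
#' covariate-adjusted Braak coefficient of enhancer methylation with the
#' Braak coefficient of target-gene expression; a negative correlation is
#' the signature of methylation-repressed targets.
#'
#' @param meth_coef named vector of region-level methylation Braak
#'   coefficients (names = region ids).
#' @param expr_coef named vector of gene-level expression Braak
#'   coefficients (names = gene ids).
#' @param pairs data.frame (region, gene) linking the two.
#' @return list with \code{r}, \code{p}, \code{n} (pairs used).
#' @export
meth_expr_correlation <- function(meth_coef, expr_coef, pairs) {
  x <- meth_coef[as.character(pairs$region)]
  y <- expr_coef[as.character(pairs$gene)]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop2("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("zero variance in coefficients; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Hypergeometric set-overlap enrichment
#'
#' P(X >= |A intersect B|) for X ~ Hypergeometric(|U|, |A|, |B|): the
#' chance of at least the observed overlap if B were drawn at random from
#' the universe. Symmetric in A and B.
#'
#' @param setA,setB character vectors (subsets of \code{universe}).
#' @param universe the background set.
#' @return list with \code{p}, \code{overlap}, \code{expected}.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB)
  out <- setdiff(c(setA, setB), universe)
  if (length(out))
    stop2("elements outside the universe: ",
          paste(utils::head(out, 5), collapse = ", "))
  N <- length(unique(universe))
  k <- length(intersect(setA, setB))
  p <- stats::phyper(k - 1, length(setA), N - length(setA), length(setB),
                     lower.tail = FALSE)
  list(p = p, overlap = k,
       expected = length(setA) * length(setB) / N)
}
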