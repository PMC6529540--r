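#' Flag top-decile differentially methylated cytosines
#'
#' Marks as DMCs the sites whose site-level p-value ranks in the smallest
#' \code{ceiling(fraction * m)} among the m sites with a non-missing p.
#' Ties are broken deterministically by (chrom, pos) order so the selected
#' set has exactly the required size.
#'
#' @param p per-site p-values (NA allowed; never selected).
#' @param sites site annotation data.frame (chrom, pos) aligned with
#'   \code{p}.
#' @param fraction selected fraction of sites (default 0.10).
#' @return logical DMC flag per site.
#' @export
select_top_decile <- function(p, sites, fraction = 0.10) {
  m <- sum(!is.na(p))
  if (m < 1) stop2("no sites with a p-value")
  n_sel <- ceiling(fraction * m)
  ord <- order(p, sites$chrom, sites$pos, na.last = TRUE)
  flag <- logical(length(p))
  flag[ord[seq_len(n_sel)]] <- TRUE
  flag
}

#' Group cytosines into regions by positional chaining
#'
#' Single-linkage chaining within a chromosome: consecutive sorted sites
#' join one region when their positional gap is at most \code{gap} bp.
#' Region span is half-open \code{[first site, last site + 1)}.
#'
#' @param sites data.frame with \code{chrom} and \code{pos} (0-based).
#' @param gap maximum gap joining consecutive sites (default 1000 bp).
#' @return list with \code{regions} (region, chrom, start, end, n) and
#'   \code{site_region} (region id per input site, input order).
#' @export
group_regions <- function(sites, gap = 1000) {
  n <- nrow(sites)
  ord <- order(sites$chrom, sites$pos)
  chrom <- sites$chrom[ord]
  pos <- sites$pos[ord]
  new_region <- c(TRUE, chrom[-1] != chrom[-n] | diff(pos) > gap)
  rid_sorted <- cumsum(new_region)
  site_region <- integer(n)
  site_region[ord] <- rid_sorted
  first <- which(new_region)
  last <- c(first[-1] - 1L, n)  # runs are contiguous in sorted order
  regions <- data.frame(
    region = seq_along(first),
    chrom = chrom[first],
    start = pos[first],
    end = pos[last] + 1L,
    n = last - first + 1L
  )
  rownames(regions) <- NULL
  list(regions = regions, site_region = site_region)
}

#' Hypergeometric enrichment of DMCs in one region
#'
#' Upper-tail (inclusive) probability of observing at least \code{k} DMCs
#' among the \code{n} cytosines of a region, when \code{K} of the \code{N}
#' profiled cytosines are DMCs: P(X >= k), X ~ Hypergeometric(N, K, n).
#'
#' @param k DMCs in the region.
#' @param n cytosines in the region.
#' @param K total DMCs among all profiled cytosines.
#' @param N total profiled cytosines.
#' @return the enrichment p-value.
#' @export
region_enrichment <- function(k, n, K, N) {
  if (any(k > n) || any(K > N) || any(k > K) || any(n > N))
    stop2("inconsistent hypergeometric counts (need k <= n, k <= K, ",
          "n <= N, K <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Call differentially methylated regions
#'
#' For every region: counts its member cytosines and DMCs, computes the
#' hypergeometric enrichment p against the profiled-cytosine universe,
#' BH-adjusts across all tested regions, averages the member-site beta
#' differences into a region-level effect (reported in %), and calls a
#' region significant when q < \code{q_threshold} and the absolute change
#' is at least \code{min_change}.
#'
#' @param grouping output of [group_regions()].
#' @param dmc logical DMC flag per site (same order as the sites passed to
#'   [group_regions()]).
#' @param delta per-site beta difference from [delta_beta()] (fractional).
#' @param q_threshold significance threshold on BH q (default 0.05).
#' @param min_change minimum absolute region beta change, fractional
#'   (default 0.01, i.e. 1 percentage point).
#' @param min_sites regions with fewer member sites are not tested
#'   (default 1: all regions tested).
#' @return data.frame of class \code{"dmr_result"}: region, chrom, start,
#'   end, n, k, p, q, delta_beta_pct, direction, significant.
#' @export
call_dmrs <- function(grouping, dmc, delta, q_threshold = 0.05,
                      min_change = 0.01, min_sites = 1) {
  regions <- grouping$regions
  rid <- grouping$site_region
  stopifnot(length(dmc) == length(rid), length(delta) == length(rid))
  N <- length(dmc)
  K <- sum(dmc)
  rid_f <- factor(rid, levels = regions$region)
  k <- as.integer(tapply(dmc, rid_f, sum))
  delta_r <- as.numeric(tapply(delta, rid_f, mean, na.rm = TRUE))
  keep <- regions$n >= min_sites
  res <- regions[keep, , drop = FALSE]
  res$k <- k[keep]
  res$p <- region_enrichment(res$k, res$n, K, N)
  res$q <- bh_adjust(res$p)
  res$delta_beta_pct <- 100 * delta_r[keep]
  res$direction <- ifelse(res$delta_beta_pct < 0, "hypo", "hyper")
  res$significant <- res$q < q_threshold &
    abs(res$delta_beta_pct) >= 100 * min_change &
    !is.na(res$delta_beta_pct)
  res$significant[is.na(res$significant)] <- FALSE
  attr(res, "universe") <- c(N = N, K = K)
  attr(res, "thresholds") <- c(q = q_threshold, min_change = min_change)
  class(res) <- c("dmr_result", "data.frame")
  res
}

#' @export
print.dmr_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("dmr_result:", nrow(x), "regions tested,",
      sum(x$significant), "significant (q <", th["q"], ", |delta| >=",
      100 * th["min_change"], "%)\n")
  sig <- x[x$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  hypo:", sum(sig$direction == "hypo"),
        " hyper:", sum(sig$direction == "hyper"), "\n")
    print(utils::head(as.data.frame(sig[order(sig$q), ]), 5))
  }
  invisible(x)
}

#' Summarise a DMR analysis
#'
#' Direction counts among significant regions (percentages to 2 decimals)
#' and, when site context and DMC flags are supplied, the CpG/CpH DMC
#' composition with the CpH:CpG fold ratio (1 decimal) and the fraction of
#' tested sites flagged per context.
#'
#' @param results a \code{dmr_result}.
#' @param context optional per-site context ("CpG"/"CpH").
#' @param dmc optional per-site DMC flag aligned with \code{context}.
#' @return list of summary counts and percentages.
#' @export
dmr_summary <- function(results, context = NULL, dmc = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  n_sig <- nrow(sig)
  n_hypo <- sum(sig$direction == "hypo")
  n_hyper <- n_sig - n_hypo
  out <- list(
    n_tested = nrow(results),
    n_significant = n_sig,
    n_hypo = n_hypo,
    n_hyper = n_hyper,
    pct_hypo = if (n_sig > 0) round(100 * n_hypo / n_sig, 2) else NA_real_,
    pct_hyper = if (n_sig > 0) round(100 * n_hyper / n_sig, 2) else NA_real_
  )
  if (!is.null(context) && !is.null(dmc)) {
    stopifnot(length(context) == length(dmc))
    cpg_dmc <- sum(dmc & context == "CpG")
    cph_dmc <- sum(dmc & context == "CpH")
    out$cpg_dmcs <- cpg_dmc
    out$cph_dmcs <- cph_dmc
    out$cph_cpg_fold <- if (cpg_dmc > 0) round(cph_dmc / cpg_dmc, 1)
                        else NA_real_
    out$pct_cpg_dmc <- round(100 * cpg_dmc / max(1, sum(context == "CpG")), 2)
    out$pct_cph_dmc <- round(100 * cph_dmc / max(1, sum(context == "CpH")), 2)
  }
  out
}

#' Write significant DMRs as a BED track
#'
#' name = region id, score = -log10(q) (capped at 1000).
#'
#' @param results a \code{dmr_result}.
#' @param path output BED path.
#' @export
write_dmr_bed <- function(results, path) {
  sig <- results[results$significant, , drop = FALSE]
  score <- round(-log10(sig$q), 2)
  score[score > 1000] <- 1000
  bed <- data.frame(chrom = sig$chrom, start = sig$start, end = sig$end,
                    name = sprintf("region_%s", sig$region),
                    score = score,
                    strand = rep(".", nrow(sig)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
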