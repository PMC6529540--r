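#' Read per-cytosine methylation calls
#'
#' Parses a bedMethyl-like TSV of per-cytosine, per-sample bisulfite calls
#' with columns \code{chrom}, \code{start}, \code{end}, \code{strand},
#' \code{context}, \code{sample}, \code{meth_reads}, \code{total_reads}
#' (0-based half-open coordinates) into a wide call table: one row per
#' cytosine site, one pair of count matrices across samples. Malformed rows
#' are rejected with their line numbers.
#'
#' @param path path to the TSV (gzip transparent via R connections).
#' @return An object of class \code{"meth_calls"}: list with \code{sites}
#'   (chrom, pos, strand, context), integer matrices \code{meth} and
#'   \code{total} (sites x samples), and \code{samples}.
#' @export
read_methylation_calls <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) stop2("cannot parse ", path, ": ", conditionMessage(e))
  )
  if (nrow(tab) == 0L) {
    warning("empty methylation call file: ", path)
    return(meth_calls(tab[0, , drop = FALSE]))
  }
  need <- c("chrom", "start", "end", "strand", "context",
            "sample", "meth_reads", "total_reads")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop2("call table missing columns: ", paste(miss, collapse = ", "))
  meth_calls(tab)
}

# Build the wide call table from long records; validates every row.
meth_calls <- function(tab) {
  if (nrow(tab) == 0L) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), context = character())
    return(structure(list(sites = sites,
                          meth = matrix(NA_integer_, 0, 0),
                          total = matrix(NA_integer_, 0, 0),
                          samples = character()),
                     class = "meth_calls"))
  }
  bad_ctx <- which(!tab$context %in% c("CpG", "CpH"))
  if (length(bad_ctx))
    stop2("unknown context at line(s) ",
          paste(utils::head(bad_ctx + 1L, 5), collapse = ", "),
          " (expected CpG or CpH)")
  bad_cnt <- which(tab$meth_reads > tab$total_reads |
                     tab$meth_reads < 0 | tab$total_reads < 0)
  if (length(bad_cnt))
    stop2("meth_reads > total_reads (or negative counts) at line(s) ",
          paste(utils::head(bad_cnt + 1L, 5), collapse = ", "))
  if (any(tab$start < 0)) stop2("negative start positions")

  keys <- site_key(tab$chrom, tab$start, tab$strand)
  ukey <- !duplicated(keys)
  sites <- data.frame(chrom = tab$chrom[ukey], pos = tab$start[ukey],
                      strand = tab$strand[ukey], context = tab$context[ukey],
                      stringsAsFactors = FALSE)
  skeys <- keys[ukey]
  samples <- unique(tab$sample)
  i <- match(keys, skeys)
  j <- match(tab$sample, samples)
  meth <- matrix(NA_integer_, length(skeys), length(samples),
                 dimnames = list(skeys, samples))
  total <- meth
  meth[cbind(i, j)] <- as.integer(tab$meth_reads)
  total[cbind(i, j)] <- as.integer(tab$total_reads)
  rownames(sites) <- skeys
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples),
            class = "meth_calls")
}

#' @export
print.meth_calls <- function(x, ...) {
  cat("meth_calls:", nrow(x$sites), "sites x", length(x$samples),
      "samples\n")
  invisible(x)
}

#' Write methylation calls as bedMethyl-like TSV
#'
#' Inverse of [read_methylation_calls()]; emits one row per covered
#' site/sample pair, 0-based half-open.
#'
#' @param calls a \code{meth_calls} object.
#' @param path output path.
#' @export
write_methylation_calls <- function(calls, path) {
  stopifnot(inherits(calls, "meth_calls"))
  cov <- which(!is.na(calls$total), arr.ind = TRUE)
  s <- calls$sites[cov[, 1], , drop = FALSE]
  out <- data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 1L,
                    strand = s$strand, context = s$context,
                    sample = calls$samples[cov[, 2]],
                    meth_reads = calls$meth[cov],
                    total_reads = calls$total[cov])
  out <- out[order(out$sample, out$chrom, out$start), ]
  write_tsv(out, path)
}

#' Coverage filter: calls to beta values
#'
#' Converts read counts to beta values (methylated fraction), keeping a call
#' only where the cytosine is spanned by at least \code{min_depth} reads;
#' calls below that depth become missing.
#'
#' @param calls a \code{meth_calls} object.
#' @param min_depth minimum spanning reads for a call to be retained
#'   (default 30).
#' @return a [meth_matrix()].
#' @export
coverage_filter <- function(calls, min_depth = 30) {
  stopifnot(inherits(calls, "meth_calls"))
  ok <- !is.na(calls$total) & calls$total >= min_depth
  beta <- ifelse(ok, calls$meth / calls$total, NA_real_)
  depth <- ifelse(ok, calls$total, NA_integer_)
  dimnames(beta) <- dimnames(depth) <- dimnames(calls$total)
  meth_matrix(beta, depth, calls$sites)
}

#' Drop cytosines overlapping SNP intervals
#'
#' Removes sites whose (0-based) position falls inside any interval of a BED
#' table of common SNPs (half-open \code{[start, end)}).
#'
#' @param m a \code{meth_matrix}.
#' @param snps data.frame with \code{chrom}, \code{start}, \code{end}, or a
#'   path to a BED file.
#' @return the filtered \code{meth_matrix}.
#' @export
mask_snp_sites <- function(m, snps) {
  stopifnot(inherits(m, "meth_matrix"))
  if (is.character(snps)) snps <- read_bed(snps)
  if (nrow(snps) == 0L) return(m)
  o <- order(snps$chrom, snps$start)
  if (!identical(o, seq_len(nrow(snps)))) {
    warning("SNP intervals not sorted; sorting internally")
    snps <- snps[o, , drop = FALSE]
  }
  # BED [start, end) half-open -> 1-based closed IRanges
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$start + 1L, snps$end))
  site_gr <- GenomicRanges::GRanges(
    m$sites$chrom, IRanges::IRanges(m$sites$pos + 1L, m$sites$pos + 1L))
  hit <- GenomicRanges::countOverlaps(site_gr, snp_gr) > 0
  subset_sites(m, !hit)
}

#' Merge replicate samples by mean beta
#'
#' Collapses columns sharing a \code{replicate_group} in the metadata to one
#' column per group: the mean of the non-missing replicate betas at each
#' site (missing only where every replicate is missing). Depths are summed
#' over the replicates contributing to the call.
#'
#' @param m a \code{meth_matrix}.
#' @param meta metadata with \code{sample} and \code{replicate_group}.
#' @return a \code{meth_matrix} with one column per replicate group.
#' @export
merge_replicates <- function(m, meta) {
  stopifnot(inherits(m, "meth_matrix"))
  if (is.null(meta$replicate_group))
    stop2("metadata has no replicate_group column")
  idx <- match(colnames(m$beta), meta$sample)
  if (anyNA(idx)) stop2("samples missing from metadata: ",
                        paste(colnames(m$beta)[is.na(idx)], collapse = ", "))
  grp <- meta$replicate_group[idx]
  groups <- unique(grp)
  beta <- matrix(NA_real_, nrow(m$beta), length(groups),
                 dimnames = list(rownames(m$beta), groups))
  depth <- beta
  for (g in seq_along(groups)) {
    cols <- which(grp == groups[g])
    if (!length(cols)) stop2("replicate group with zero samples: ", groups[g])
    b <- m$beta[, cols, drop = FALSE]
    d <- m$depth[, cols, drop = FALSE]
    beta[, g] <- rowMeans(b, na.rm = TRUE)
    depth[, g] <- rowSums(d * !is.na(b), na.rm = TRUE)
  }
  beta[is.nan(beta)] <- NA_real_
  depth[depth == 0] <- NA_real_
  meth_matrix(beta, depth, m$sites)
}

#' Site missingness filter
#'
#' Keeps sites with a methylation call in at least \code{min_call_rate} of
#' samples, and additionally drops sites whose beta is 0 in every sample
#' with a call (uninformative, fully unmethylated sites).
#'
#' @param m a \code{meth_matrix} (after replicate merging).
#' @param min_call_rate minimum fraction of samples with a call
#'   (default 0.70).
#' @return the filtered \code{meth_matrix}.
#' @export
missingness_filter <- function(m, min_call_rate = 0.70) {
  stopifnot(inherits(m, "meth_matrix"))
  called <- rowMeans(!is.na(m$beta))
  nonzero <- rowSums(m$beta > 0, na.rm = TRUE) > 0
  subset_sites(m, called >= min_call_rate & nonzero)
}

#' Flag outlier samples by deviation from the cohort profile
#'
#' Operationalises poor inter-sample agreement as the mean absolute
#' deviation of a sample's betas from the per-site cohort median profile;
#' samples deviating by more than \code{max_deviation} (beta units) are
#' excluded.
#'
#' @param m a \code{meth_matrix} with >= 3 samples.
#' @param max_deviation exclusion threshold on mean absolute deviation
#'   (default 0.10, i.e. a 10 percentage-point average difference).
#' @return list with \code{matrix} (retained samples) and \code{excluded}
#'   (data.frame sample/deviation for all samples, flagging exclusions).
#' @export
sample_qc <- function(m, max_deviation = 0.10) {
  stopifnot(inherits(m, "meth_matrix"))
  if (ncol(m$beta) < 3L) stop2("sample_qc needs at least 3 samples")
  med <- apply(m$beta, 1, stats::median, na.rm = TRUE)
  dev <- colMeans(abs(m$beta - med), na.rm = TRUE)
  report <- data.frame(sample = colnames(m$beta), deviation = dev,
                       excluded = dev > max_deviation, row.names = NULL)
  keep <- !report$excluded
  kept <- meth_matrix(m$beta[, keep, drop = FALSE],
                      m$depth[, keep, drop = FALSE], m$sites)
  list(matrix = kept, excluded = report)
}

#' Bisulfite conversion efficiency from unmethylated controls
#'
#' For designated control samples expected to be fully unmethylated (e.g.
#' whole-genome-amplified DNA), efficiency = 1 - sum(meth) / sum(total)
#' over all control calls.
#'
#' @param x a \code{meth_calls} object, or a numeric vector of methylated
#'   read counts.
#' @param controls control sample ids (when \code{x} is \code{meth_calls}).
#' @param total numeric vector of total read counts (when \code{x} is
#'   numeric).
#' @return conversion efficiency as a proportion in [0, 1].
#' @export
conversion_efficiency <- function(x, controls = NULL, total = NULL) {
  if (inherits(x, "meth_calls")) {
    if (is.null(controls)) stop2("control sample ids required")
    cols <- match(controls, x$samples)
    if (anyNA(cols)) stop2("unknown control sample(s)")
    meth <- sum(x$meth[, cols], na.rm = TRUE)
    tot <- sum(x$total[, cols], na.rm = TRUE)
  } else {
    meth <- sum(x)
    tot <- sum(total)
  }
  if (tot <= 0) stop2("zero total reads in control samples")
  1 - meth / tot
}

#' Read a BED3 file (0-based half-open)
#' @param path BED path.
#' @return data.frame chrom/start/end.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(tab[, 1:3], c("chrom", "start", "end"))
}
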