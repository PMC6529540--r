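#' Select subtype marker cytosines
#'
#' Keeps sites that discriminate the two neuronal subtypes and are stable
#' in disease: paired t-test p <= \code{p_max} between subtype profiles,
#' absolute subtype beta difference >= \code{min_delta}, and no
#' association with pathology (AD q >= \code{ad_q_min}).
#'
#' @param subtype1,subtype2 sites x individuals beta matrices of paired
#'   subtype measurements (same individuals, same site order).
#' @param ad_q per-site q-values from the pathology association scan.
#' @param p_max paired-t threshold (default 0.05).
#' @param min_delta minimum absolute subtype beta difference
#'   (default 0.05).
#' @param ad_q_min minimum AD q for a site to count as disease-stable
#'   (default 0.05).
#' @return integer indices of selected marker sites.
#' @export
select_markers <- function(subtype1, subtype2, ad_q, p_max = 0.05,
                           min_delta = 0.05, ad_q_min = 0.05) {
  stopifnot(all(dim(subtype1) == dim(subtype2)),
            nrow(subtype1) == length(ad_q))
  d <- subtype1 - subtype2
  n <- ncol(d)
  if (n < 2) stop2("paired t-test needs >= 2 paired measurements")
  dbar <- rowMeans(d)
  sd_d <- apply(d, 1, stats::sd)
  tstat <- dbar / (sd_d / sqrt(n))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 1)
  keep <- which(pval <= p_max & abs(dbar) >= min_delta & ad_q >= ad_q_min)
  if (!length(keep))
    stop2("no site passes the marker criteria; relax p_max/min_delta")
  keep
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||,
# x >= 0. Small dense problems only (deconvolution has 2-20 columns).
nnls_fit <- function(A, b, tol = 1e-10) {
  p <- ncol(A)
  x <- numeric(p)
  passive <- logical(p)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0
  while (any(!passive & w > tol) && iter < 30 * p) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(p)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Estimate neuronal-subtype proportions
#'
#' Simplex-constrained least squares: for each sample, finds the weight
#' vector w >= 0, sum(w) = 1 minimising ||x - R w|| over the marker betas,
#' where R is the reference panel (markers x subtypes). The sum constraint
#' is imposed through a heavily weighted augmentation row followed by
#' renormalisation. Markers missing in a sample are dropped for that
#' sample; a sample with fewer than (subtypes + 1) informative markers
#' gets missing proportions.
#'
#' @param betas markers x samples beta matrix (NA allowed).
#' @param panel markers x subtypes reference beta matrix (colnames =
#'   subtype names).
#' @return object of class \code{"deconv_fit"}: data.frame of per-sample
#'   weights and residual norm, plus the panel used.
#' @export
estimate_proportions <- function(betas, panel) {
  betas <- as.matrix(betas)
  panel <- as.matrix(panel)
  if (nrow(betas) != nrow(panel))
    stop2("betas and panel must share marker rows")
  if (ncol(panel) < 2) stop2("need >= 2 reference subtypes")
  if (nrow(panel) < 10) stop2("need >= 10 marker sites")
  k <- ncol(panel)
  nm <- colnames(panel) %||% paste0("subtype", seq_len(k))
  samples <- colnames(betas) %||% paste0("S", seq_len(ncol(betas)))
  big <- 1e4  # weight on the sum-to-one augmentation row
  W <- matrix(NA_real_, ncol(betas), k, dimnames = list(samples, nm))
  resid <- rep(NA_real_, ncol(betas))
  for (j in seq_len(ncol(betas))) {
    ok <- !is.na(betas[, j]) & rowSums(is.na(panel)) == 0
    if (sum(ok) < k + 1) next
    A <- rbind(panel[ok, , drop = FALSE], rep(big, k))
    b <- c(betas[ok, j], big)
    w <- nnls_fit(A, b)
    if (sum(w) <= 0) next
    w <- w / sum(w)
    W[j, ] <- w
    resid[j] <- sqrt(sum((betas[ok, j] -
                            panel[ok, , drop = FALSE] %*% w)^2))
  }
  out <- data.frame(sample = samples, W, residual = resid,
                    row.names = NULL, check.names = FALSE)
  structure(list(proportions = out, panel = panel), class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  pr <- x$proportions
  cat("deconv_fit:", nrow(pr), "samples,",
      ncol(x$panel), "subtypes,", nrow(x$panel), "markers\n")
  means <- colMeans(pr[, colnames(x$panel), drop = FALSE], na.rm = TRUE)
  cat("  mean proportions:",
      paste(names(means), sprintf("%.3f", means), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Average CpH methylation over gene bodies
#'
#' Utility for gene-signature deconvolution checks: mean beta of CpH sites
#' falling within each gene's body window (gene span +/- \code{flank}).
#'
#' @param m a \code{meth_matrix}.
#' @param genes data.frame with \code{gene}, \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param flank symmetric extension in bp (default 100000).
#' @return genes x samples matrix of mean CpH betas.
#' @export
gene_body_cph <- function(m, genes, flank = 1e5) {
  stopifnot(inherits(m, "meth_matrix"))
  cph <- m$sites$context == "CpH"
  site_gr <- GenomicRanges::GRanges(
    m$sites$chrom[cph],
    IRanges::IRanges(m$sites$pos[cph] + 1L, m$sites$pos[cph] + 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(0, genes$start - flank) + 1L, genes$end + flank))
  hits <- GenomicRanges::findOverlaps(gene_gr, site_gr)
  out <- matrix(NA_real_, nrow(genes), ncol(m$beta),
                dimnames = list(genes$gene, colnames(m$beta)))
  beta_cph <- m$beta[cph, , drop = FALSE]
  for (g in unique(S4Vectors::queryHits(hits))) {
    rows <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == g]
    out[g, ] <- colMeans(beta_cph[rows, , drop = FALSE], na.rm = TRUE)
  }
  out
}
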