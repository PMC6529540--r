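#' Methylation matrix container
#'
#' Holds per-cytosine beta values (methylated-read fraction) and read depths
#' for a set of sites across samples, together with site annotations. Sites
#' use 0-based positions (BED convention); a site is identified by
#' \code{chrom:pos:strand}. Missing beta values mark sites that were filtered
#' or not covered in a sample.
#'
#' @param beta numeric matrix, sites x samples, values in [0, 1] or NA.
#' @param depth integer matrix of read depths, same shape as \code{beta}.
#' @param sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{strand} (\code{"+"}/\code{"-"}) and \code{context}
#'   (\code{"CpG"}/\code{"CpH"}), one row per row of \code{beta}.
#'
#' @return An object of class \code{"meth_matrix"}.
#' @export
meth_matrix <- function(beta, depth, sites) {
  beta <- as.matrix(beta)
  depth <- as.matrix(depth)
  if (!all(dim(beta) == dim(depth)))
    stop2("beta and depth must have identical dimensions")
  if (nrow(beta) != nrow(sites))
    stop2("sites must have one row per row of beta")
  need <- c("chrom", "pos", "strand", "context")
  if (!all(need %in% names(sites)))
    stop2("sites must contain columns: ", paste(need, collapse = ", "))
  if (!all(sites$context %in% c("CpG", "CpH")))
    stop2("site context must be 'CpG' or 'CpH'")
  if (any(sites$pos < 0)) stop2("site positions must be >= 0")
  if (any(!is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop2("beta values must lie in [0, 1]")
  }
  keys <- site_key(sites$chrom, sites$pos, sites$strand)
  rownames(beta) <- rownames(depth) <- keys
  rownames(sites) <- keys
  structure(
    list(beta = beta, depth = depth, sites = sites,
         samples = colnames(beta) %||% paste0("S", seq_len(ncol(beta)))),
    class = "meth_matrix"
  )
}

#' @export
dim.meth_matrix <- function(x) dim(x$beta)

#' @export
print.meth_matrix <- function(x, ...) {
  d <- dim(x$beta)
  ctx <- table(x$sites$context)
  cat("meth_matrix:", d[1], "sites x", d[2], "samples\n")
  cat("  contexts:",
      paste(names(ctx), as.integer(ctx), sep = "=", collapse = ", "), "\n")
  cat("  missing beta:",
      sprintf("%.1f%%", 100 * mean(is.na(x$beta))), "\n")
  invisible(x)
}

# Row-subset keeping annotations aligned; used by every filter.
subset_sites <- function(m, keep) {
  stopifnot(inherits(m, "meth_matrix"))
  meth_matrix(m$beta[keep, , drop = FALSE],
              m$depth[keep, , drop = FALSE],
              m$sites[keep, , drop = FALSE])
}

#' Validate a sample metadata table
#'
#' Checks the covariate table used throughout the pipeline: one row per
#' sample with age (years), sex, postmortem interval (hours), Braak stage
#' (integer 1-6), glutamatergic-neuron proportion, and replicate group.
#'
#' @param meta data.frame with at least columns \code{sample}, \code{age},
#'   \code{sex}, \code{pmi}, \code{braak}; optional \code{neuron_glu_prop},
#'   \code{rin}, \code{replicate_group}, \code{control_flag}.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_metadata <- function(meta) {
  need <- c("sample", "age", "sex", "pmi", "braak")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop2("metadata missing columns: ", paste(miss, collapse = ", "))
  if (!all(meta$braak %in% 1:6))
    stop2("braak must be an integer in 1..6")
  if (!all(meta$sex %in% c("F", "M")))
    stop2("sex must be 'F' or 'M'")
  if (!is.null(meta$neuron_glu_prop))
    assert_prob(meta$neuron_glu_prop[!is.na(meta$neuron_glu_prop)],
                "neuron_glu_prop")
  if (anyDuplicated(meta$sample))
    stop2("duplicate sample ids in metadata")
  invisible(meta)
}
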