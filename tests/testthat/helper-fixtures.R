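# Shared fixture builders; everything is generated in code at test time.

small_config <- function(seed = 1, ...) {
  args <- list(n_samples = 40, n_regions = 60,
               sites_per_region = list(mean = 4, min = 1),
               n_genes = 200, ref_markers = 30, ref_mixtures = 10,
               seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# meth_matrix built directly from a beta matrix (depth = 50 everywhere)
mm_from_beta <- function(beta, context = "CpG", chrom = "chr1") {
  beta <- as.matrix(beta)
  if (is.null(colnames(beta)))
    colnames(beta) <- paste0("S", seq_len(ncol(beta)))
  sites <- data.frame(chrom = chrom, pos = seq_len(nrow(beta)) * 10L,
                      strand = "+",
                      context = rep_len(context, nrow(beta)))
  depth <- matrix(50, nrow(beta), ncol(beta),
                  dimnames = dimnames(beta))
  meth_matrix(beta, depth, sites)
}

# long-format call records for IO tests
calls_df <- function(n_sites = 5, samples = c("A", "B"), depth = 40,
                     meth = NULL) {
  grid <- expand.grid(site = seq_len(n_sites), sample = samples,
                      stringsAsFactors = FALSE)
  data.frame(chrom = "chr1", start = grid$site * 100L,
             end = grid$site * 100L + 1L, strand = "+",
             context = ifelse(grid$site %% 2 == 0, "CpH", "CpG"),
             sample = grid$sample,
             meth_reads = meth %||% pmin(depth, grid$site * 3L),
             total_reads = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logit_test <- function(p) log(p / (1 - p))
ilogit_test <- function(x) 1 / (1 + exp(-x))

write_tsv_helper <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

meth_calls_helper <- function(tab) enhancerDMR:::meth_calls(tab)

site_keys_helper <- function(chrom, pos, strand = "+")
  paste(chrom, pos, strand, sep = ":")

# exact hypergeometric upper tail by direct enumeration of the pmf
hyper_tail_enum <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# BH step-up by brute-force definition: q_i = min over p_(j) >= p_i of
# m p_(j) / j, capped at 1
bh_enum <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "max")
  sapply(seq_len(m), function(i) {
    js <- which(p[o] >= p[i] - 1e-15)
    min(1, min(m * p[o][js] / js))
  })
}
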