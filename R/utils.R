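# Internal helpers shared across the package.

logit <- function(p) log(p / (1 - p))
ilogit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop2(name, " must be a proportion in [0, 1]")
  invisible(x)
}

# Deterministic per-stage substream from a master seed; keeps every stage
# reproducible on its own while sharing one user-facing seed.
# Kept below 2^31 so it is always a valid R integer seed.
substream <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(
    cohort = 11L, methylation = 23L, expression = 37L, interactions = 41L,
    reference = 53L, folds = 67L, qc = 71L, pipeline = 83L
  )
  off <- offsets[[stage]] %||% 97L
  as.integer((abs(seed) * 1103L + off * 12289L) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
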