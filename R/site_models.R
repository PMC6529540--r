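#' Beta to M-value transform
#'
#' M = log2(beta / (1 - beta)) with beta clamped to
#' \code{[offset, 1 - offset]} so boundary values stay finite. Missing
#' values propagate.
#'
#' @param beta numeric vector/matrix of beta values in [0, 1] (NA allowed).
#' @param offset clamp distance from the boundaries (default 1e-3).
#' @return M-values, same shape as \code{beta}.
#' @export
beta_to_m <- function(beta, offset = 1e-3) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop2("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, offset), 1 - offset)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(out) <- dimnames(beta)
  out
}

#' Inverse of [beta_to_m()]
#' @param m M-values.
#' @return beta values in (0, 1).
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Build the covariate design matrix
#'
#' Columns: intercept, Braak stage coded numerically 1-6 (ordinal-linear
#' severity), then the requested covariates (sex coded M = 1).
#'
#' @param meta validated sample metadata.
#' @param covariates covariate column names to adjust for.
#' @param braak_stages restrict samples to these Braak stages (e.g.
#'   \code{1:4} for the early-pathology contrast); default all.
#' @return numeric design matrix with rownames = sample ids.
#' @export
make_design <- function(meta,
                        covariates = c("age", "sex", "pmi",
                                       "neuron_glu_prop"),
                        braak_stages = 1:6) {
  validate_metadata(meta)
  meta <- meta[meta$braak %in% braak_stages, , drop = FALSE]
  X <- cbind(intercept = 1, braak = as.numeric(meta$braak))
  for (cv in covariates) {
    if (is.null(meta[[cv]])) stop2("covariate absent from metadata: ", cv)
    v <- meta[[cv]]
    if (cv == "sex") v <- as.numeric(v == "M")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  rownames(X) <- meta$sample
  if (qr(X[stats::complete.cases(X), , drop = FALSE])$rank < ncol(X))
    stop2("design matrix is rank deficient")
  X
}

# Huber IRLS for one feature. Returns coefficients, robust residual
# variance, residual df and unscaled coefficient sd. The variance uses the
# weighted residual sum of squares divided by its Gaussian expectation
# kappa = 2*pnorm(k) - 1, so it is consistent for sigma^2 in the
# outlier-free regime while capping each gross residual's contribution.
fit_one_huber <- function(y, X, k = 1.345, maxit = 50, tol = 1e-8) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  w <- rep(1, length(y))
  for (it in seq_len(maxit)) {
    r <- as.vector(y - X %*% b)
    s <- stats::median(abs(r)) / 0.6745
    if (!is.finite(s) || s < 1e-12) break
    u <- abs(r) / s
    w <- ifelse(u <= k, 1, k / u)
    bn <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(bn - b)) < tol * max(1, max(abs(b)))) { b <- bn; break }
    b <- bn
  }
  r <- as.vector(y - X %*% b)
  df <- length(y) - ncol(X)
  kappa <- 2 * stats::pnorm(k) - 1
  s2 <- sum(w * r^2) / (kappa * df)
  R <- qr.R(qx)
  xtxinv_diag <- diag(chol2inv(R))
  list(coefficients = b, s2 = s2, df = df,
       stdev_unscaled = sqrt(xtxinv_diag), weights = w)
}

#' Per-feature robust linear model fits
#'
#' Fits, independently for every feature (cytosine M-values or gene
#' log-CPM), an iteratively reweighted least-squares regression with Huber
#' weights (tuning constant 1.345, at most 50 iterations, coefficient
#' tolerance 1e-8) of the feature on the design. Rows with a missing
#' response are dropped per feature (complete-case); features left with
#' fewer than rank + 3 observations, or a rank-deficient reduced design,
#' are flagged and reported as missing.
#'
#' @param Y features x samples numeric matrix (NA allowed).
#' @param design samples x coefficients design matrix from [make_design()].
#' @param method \code{"huber"} (default) or \code{"ols"}.
#' @return object of class \code{"site_fit"}: coefficient matrix,
#'   \code{s2}, \code{df}, \code{stdev_unscaled}, \code{n_used}.
#' @export
fit_robust <- function(Y, design, method = c("huber", "ols")) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(design))
    stop2("ncol(Y) must equal nrow(design)")
  p <- ncol(design)
  nf <- nrow(Y)
  coefs <- matrix(NA_real_, nf, p,
                  dimnames = list(rownames(Y), colnames(design)))
  unscaled <- coefs
  s2 <- rep(NA_real_, nf)
  df <- rep(NA_real_, nf)
  n_used <- integer(nf)

  for (i in seq_len(nf)) {
    y <- Y[i, ]
    keep <- !is.na(y) & rowSums(is.na(design)) == 0
    n <- sum(keep)
    n_used[i] <- n
    if (n < p + 3) next
    X <- design[keep, , drop = FALSE]
    qx <- qr(X)
    if (qx$rank < p) next
    if (method == "ols") {
      b <- qr.coef(qx, y[keep])
      r <- y[keep] - as.vector(X %*% b)
      fit <- list(coefficients = b, s2 = sum(r^2) / (n - p), df = n - p,
                  stdev_unscaled = sqrt(diag(chol2inv(qr.R(qx)))))
    } else {
      fit <- fit_one_huber(y[keep], X)
    }
    coefs[i, ] <- fit$coefficients
    unscaled[i, ] <- fit$stdev_unscaled
    s2[i] <- fit$s2
    df[i] <- fit$df
  }
  structure(list(coefficients = coefs, stdev_unscaled = unscaled,
                 s2 = s2, df = df, n_used = n_used, design = design,
                 method = method),
            class = "site_fit")
}

#' @export
coef.site_fit <- function(object, ...) object$coefficients

#' @export
print.site_fit <- function(x, ...) {
  cat("site_fit:", nrow(x$coefficients), "features,",
      ncol(x$coefficients), "coefficients (", x$method, ")\n")
  if (!is.null(x$ebayes))
    cat("  empirical Bayes: d0 =", format(x$ebayes$d0, digits = 4),
        ", s0^2 =", format(x$ebayes$s02, digits = 4), "\n")
  invisible(x)
}

# Newton inversion of the trigamma function (for prior-df estimation).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (it in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Empirical-Bayes variance squeezing
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' moment matching on log s^2 (the scaled-F marginal of sample variances),
#' and returns posterior variances
#' \eqn{\tilde s^2 = (d0 s0^2 + d s^2) / (d0 + d)}. If the observed spread
#' of log s^2 does not exceed its chi-square sampling noise, d0 is infinite
#' and all posterior variances equal s0^2.
#'
#' @param s2 per-feature residual variances.
#' @param df per-feature residual degrees of freedom.
#' @return list with \code{d0}, \code{s02}, \code{s2_post}.
#' @export
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & is.finite(df) & s2 > 0 & df > 0
  if (sum(ok) < 2) stop2("need at least 2 finite variances")
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s^2: infinite prior df; the prior variance
    # is the common (geometric mean) variance itself
    d0 <- Inf
    s02 <- exp(mean(log(s2[ok])))
  }
  s2_post <- rep(NA_real_, length(s2))
  if (is.infinite(d0)) {
    s2_post[ok] <- s02
  } else {
    s2_post[ok] <- (d0 * s02 + df[ok] * s2[ok]) / (d0 + df[ok])
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post)
}

#' Moderated t-statistics for a fitted coefficient
#'
#' Applies [squeeze_var()] to the residual variances of a [fit_robust()]
#' fit and computes, for the chosen coefficient, moderated t = b /
#' (s_tilde * unscaled sd) on d0 + d degrees of freedom, two-sided p, and
#' BH-adjusted q.
#'
#' @param fit a \code{site_fit}.
#' @param coef coefficient name to test (default \code{"braak"}).
#' @return the \code{site_fit} augmented with \code{ebayes} (d0, s02),
#'   \code{t}, \code{p}, \code{q}, \code{df_total}, and \code{tested_coef}.
#' @export
ebayes <- function(fit, coef = "braak") {
  stopifnot(inherits(fit, "site_fit"))
  if (!coef %in% colnames(fit$coefficients))
    stop2("no such coefficient: ", coef)
  sq <- squeeze_var(fit$s2, fit$df)
  b <- fit$coefficients[, coef]
  se <- sqrt(sq$s2_post) * fit$stdev_unscaled[, coef]
  tstat <- b / se
  df_total <- fit$df + sq$d0
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  fit$ebayes <- sq[c("d0", "s02")]
  fit$s2_post <- sq$s2_post
  fit$t <- tstat
  fit$p <- pval
  fit$q <- bh_adjust(pval)
  fit$df_total <- df_total
  fit$tested_coef <- coef
  fit
}

#' @export
summary.site_fit <- function(object, ...) {
  if (is.null(object$t))
    stop2("run ebayes() before summarising a site_fit")
  data.frame(feature = rownames(object$coefficients),
             b = object$coefficients[, object$tested_coef],
             t = object$t, p = object$p, q = object$q,
             n_used = object$n_used, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to \code{stats::p.adjust}); missing
#' p-values propagate.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE))
    stop2("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor and test-statistic bias
#'
#' lambda = median(z^2) / qchisq(0.5, 1); bias = mean(z). Values near 1 and
#' 0 respectively indicate a well-calibrated site-level test.
#'
#' @param z vector of z- or t-statistics (>= 100 recommended).
#' @return list with \code{lambda} and \code{bias}.
#' @export
inflation_factor <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 2) stop2("too few statistics")
  list(lambda = stats::median(z^2) / stats::qchisq(0.5, 1),
       bias = mean(z))
}

#' Per-site group methylation difference
#'
#' Difference of mean beta between the severe and the no/mild pathology
#' groups (Braak 5-6 minus Braak 1-2 by default), computed missing-aware;
#' a site with one group entirely missing gets NA.
#'
#' @param m a \code{meth_matrix}.
#' @param meta sample metadata matching the matrix columns.
#' @param low,high Braak stages defining the reference and severe groups.
#' @return named numeric vector of beta differences (high - low).
#' @export
delta_beta <- function(m, meta, low = c(1, 2), high = c(5, 6)) {
  stopifnot(inherits(m, "meth_matrix"))
  idx <- match(colnames(m$beta), meta$sample)
  if (anyNA(idx)) stop2("matrix samples missing from metadata")
  braak <- meta$braak[idx]
  lo <- m$beta[, braak %in% low, drop = FALSE]
  hi <- m$beta[, braak %in% high, drop = FALSE]
  if (ncol(lo) == 0 || ncol(hi) == 0) stop2("empty Braak group")
  rowMeans(hi, na.rm = TRUE) - rowMeans(lo, na.rm = TRUE)
}
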