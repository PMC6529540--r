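#' Fit a CpH epigenetic clock
#'
#' Elastic-net regression of (optionally calibrated) chronological age on
#' CpH beta values: standardized-predictor elastic net with mixing
#' parameter \code{alpha} over a log-spaced lambda grid, lambda chosen to
#' minimise the 10-fold cross-validated mean-squared error with a seeded
#' fold assignment. Sites with any missing training beta are dropped
#' before fitting.
#'
#' @param X samples x sites beta matrix (training stratum, e.g. Braak 1-2).
#' @param age chronological ages in years.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param folds cross-validation folds (default 10).
#' @param seed seed controlling the fold assignment.
#' @param transform age calibration: \code{"identity"} (default, adult
#'   cohorts) or \code{"log"} (log-linear below \code{adult_age}, linear
#'   above, for cohorts spanning childhood).
#' @param adult_age knot of the log transform (default 20).
#' @param lambda_rule \code{"min"} (default, CV-MSE minimiser) or
#'   \code{"1se"}.
#' @param calibrate when TRUE (default), rescale predictions through the
#'   prevalidated (cross-validated) fits: penalised regression at small n
#'   compresses predictions towards the training mean, so the training
#'   ages are regressed on their own CV predictions and the inverse map
#'   is applied at prediction time. This restores the scale of genuine
#'   age shifts; it is skipped (with a warning) when the CV fit carries
#'   no usable age signal.
#' @return object of class \code{"methyl_clock"}.
#' @export
fit_clock <- function(X, age, alpha = 0.5, folds = 10, seed = 1,
                      transform = c("identity", "log"), adult_age = 20,
                      lambda_rule = c("min", "1se"), calibrate = TRUE) {
  transform <- match.arg(transform)
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (nrow(X) != length(age)) stop2("nrow(X) must equal length(age)")
  if (stats::sd(age) == 0) stop2("age is constant; cannot fit a clock")
  if (nrow(X) < folds) stop2("need at least one sample per fold")
  keep <- colSums(is.na(X)) == 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) stop2("fewer than 2 complete sites for training")
  y <- calibrate_age(age, transform, adult_age)
  foldid <- with_seed(substream(seed, "folds"),
                      sample(rep_len(seq_len(folds), nrow(X))))
  # explicit log-spaced grid: glmnet's path otherwise stops early once
  # the deviance saturates, which leaves no near-unpenalised solutions
  lmax <- glmnet::glmnet(X, y, alpha = alpha, nlambda = 3)$lambda[1]
  grid <- exp(seq(log(lmax), log(lmax * 1e-6), length.out = 100))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE, family = "gaussian",
                          lambda = grid, keep = TRUE)
  lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = lam))
  cal <- c(a = 0, b = 1)
  if (calibrate) {
    preval <- cv$fit.preval[, which(cv$lambda == lam)]
    b <- stats::cov(preval, y) / stats::var(y)
    if (!is.finite(b) || b < 0.05) {
      warning("CV fit carries no usable age signal; ",
              "prediction calibration skipped")
    } else {
      cal <- c(a = mean(preval) - b * mean(y), b = b)
    }
  }
  structure(
    list(sites = colnames(X), coefficients = cf[-1, 1],
         intercept = cf[1, 1], calibration = cal,
         alpha = alpha, lambda = lam,
         lambda_rule = lambda_rule,
         cv_mse = data.frame(lambda = cv$lambda, mse = cv$cvm,
                             mse_sd = cv$cvsd),
         transform = transform, adult_age = adult_age, seed = seed,
         n_train = nrow(X)),
    class = "methyl_clock")
}

calibrate_age <- function(age, transform, adult_age) {
  if (transform == "identity") return(age)
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

uncalibrate_age <- function(y, transform, adult_age) {
  if (transform == "identity") return(y)
  ifelse(y <= 0,
         exp(y + log(adult_age + 1)) - 1,
         y * (adult_age + 1) + adult_age)
}

#' @export
print.methyl_clock <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("methyl_clock:", length(x$sites), "candidate sites,", nz,
      "with nonzero coefficients\n")
  cat(sprintf("  alpha = %.2f, lambda = %.4g (%s), trained on %d samples\n",
              x$alpha, x$lambda, x$lambda_rule, x$n_train))
  invisible(x)
}

#' @export
coef.methyl_clock <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Predict DNA methylation age
#'
#' @param object a \code{methyl_clock}.
#' @param newdata samples x sites beta matrix containing every model site
#'   (by column name).
#' @param ... unused.
#' @return predicted ages in years.
#' @export
predict.methyl_clock <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$sites, colnames(newdata))
  if (length(miss))
    stop2("model sites absent from input: ",
          paste(utils::head(miss, 5), collapse = ", "),
          if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  Xm <- newdata[, object$sites, drop = FALSE]
  y <- object$intercept + drop(Xm %*% object$coefficients)
  cal <- object$calibration %||% c(a = 0, b = 1)
  y <- (y - cal[["a"]]) / cal[["b"]]
  uncalibrate_age(y, object$transform, object$adult_age)
}

#' Epigenetic age acceleration test
#'
#' Paired two-sided t-test of predicted minus chronological age; reports
#' per-sample acceleration and the group mean with its standard error.
#'
#' @param predicted DNA-methylation ages.
#' @param chronological chronological ages (same samples, same order).
#' @return object of class \code{"acceleration_result"}.
#' @export
acceleration_test <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological))
  n <- length(predicted)
  if (n < 3) stop2("need at least 3 paired samples")
  d <- predicted - chronological
  m <- mean(d)
  s <- stats::sd(d)
  sem <- s / sqrt(n)
  if (s == 0) {
    tt <- list(statistic = if (m == 0) 0 else sign(m) * Inf,
               p.value = if (m == 0) 1 else 0)
    if (m != 0)
      warning("zero variance of paired differences with nonzero mean; ",
              "p reported as the 0 limit")
  } else {
    ht <- stats::t.test(predicted, chronological, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  structure(
    list(samples = data.frame(predicted = predicted,
                              chronological = chronological,
                              acceleration = d),
         mean_acceleration = m, sem = sem,
         mean_predicted = mean(predicted),
         mean_chronological = mean(chronological),
         t = tt$statistic, p = tt$p.value, n = n),
    class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf(
    "Epigenetic age acceleration: %.2f +/- %.2f years (n = %d)\n",
    x$mean_acceleration, x$sem, x$n))
  cat(sprintf("  chronological %.2f vs predicted %.2f years\n",
              x$mean_chronological, x$mean_predicted))
  cat(sprintf("  paired t = %.3f, p = %.3g\n", x$t, x$p))
  invisible(x)
}

#' Age trend of mean CpH methylation within a Braak stratum
#'
#' Regresses each sample's mean CpH methylation (in %) on age, adjusted
#' for sex, postmortem interval and neuronal subtype proportion, within
#' the requested Braak stages, using the package's robust fitting engine.
#'
#' @param m a \code{meth_matrix}.
#' @param meta sample metadata.
#' @param braak_stages stratum to analyse (default 1:6, i.e. all).
#' @param covariates adjustment covariates.
#' @return list: \code{slope} (% methylation per year), \code{p},
#'   \code{span_change} (% change over the stratum's age span), \code{n}.
#' @export
age_trend <- function(m, meta, braak_stages = 1:6,
                      covariates = c("sex", "pmi", "neuron_glu_prop")) {
  stopifnot(inherits(m, "meth_matrix"))
  idx <- match(colnames(m$beta), meta$sample)
  sub <- meta[idx, , drop = FALSE]
  keep <- sub$braak %in% braak_stages
  if (sum(keep) < 10) stop2("stratum has fewer than 10 samples")
  sub <- sub[keep, , drop = FALSE]
  cph <- m$sites$context == "CpH"
  pct <- 100 * colMeans(m$beta[cph, keep, drop = FALSE], na.rm = TRUE)
  X <- cbind(intercept = 1, age = sub$age)
  for (cv in covariates) {
    v <- sub[[cv]]
    if (is.null(v)) stop2("covariate absent from metadata: ", cv)
    if (cv == "sex") v <- as.numeric(v == "M")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  fit <- fit_robust(matrix(pct, 1), X)
  b <- fit$coefficients[1, "age"]
  se <- sqrt(fit$s2[1]) * fit$stdev_unscaled[1, "age"]
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), df = fit$df[1])
  list(slope = b, se = se, t = tstat, p = p,
       span_change = b * diff(range(sub$age)), n = nrow(sub))
}
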