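test_that("beta/M transform follows the clamped log-odds definition", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0), log2(1e-3 / (1 - 1e-3)))
  expect_true(is.finite(beta_to_m(1)))
  expect_equal(beta_to_m(c(0.25, NA)), c(log2(1 / 3), NA))
  expect_equal(m_to_beta(beta_to_m(0.37)), 0.37, tolerance = 1e-12)
  expect_error(beta_to_m(1.2), "lie in")
})

make_test_design <- function(n, seed = 1) {
  set.seed(seed)
  cbind(intercept = 1, braak = sample(1:6, n, TRUE),
        age = rnorm(n, 80, 8), sex = rbinom(n, 1, 0.5),
        pmi = runif(n, 10, 60))
}

test_that("robust fits interpolate exact linear data and track OLS under Gaussian noise", {
  X <- make_test_design(60, seed = 2)
  btrue <- c(1, 0.5, -0.02, 0.3, 0.01)
  y <- drop(X %*% btrue)
  fit <- fit_robust(matrix(y, 1), X)
  expect_equal(unname(fit$coefficients[1, ]), btrue, tolerance = 1e-8)

  set.seed(3)
  Y <- matrix(rep(y, each = 40), 40, byrow = FALSE,
              ncol = length(y)) + rnorm(40 * length(y), 0, 0.3)
  hub <- fit_robust(Y, X)
  ols <- fit_robust(Y, X, method = "ols")
  rel <- abs(hub$coefficients[, "braak"] - ols$coefficients[, "braak"]) /
    pmax(abs(ols$coefficients[, "braak"]), 0.1)
  expect_lt(stats::median(rel), 0.01)
  expect_lt(max(rel), 0.05)
})

test_that("Huber fits beat OLS on gross outliers in most simulations", {
  X <- make_test_design(50, seed = 4)
  btrue <- c(2, 0.4, 0, 0, 0)
  nrep <- 500
  set.seed(5)
  Y <- matrix(rep(drop(X %*% btrue), nrep), nrep, byrow = TRUE,
              ncol = nrow(X)) + rnorm(nrep * nrow(X), 0, 1)
  # plant the outlier at an extreme-Braak sample so it has leverage on
  # the coefficient under test
  out_col <- sample(which(X[, "braak"] %in% c(1, 6)), nrep, TRUE)
  Y[cbind(seq_len(nrep), out_col)] <-
    Y[cbind(seq_len(nrep), out_col)] + 25
  hub <- fit_robust(Y, X)$coefficients[, "braak"]
  ols <- fit_robust(Y, X, method = "ols")$coefficients[, "braak"]
  closer <- abs(hub - 0.4) < abs(ols - 0.4)
  expect_gte(mean(closer), 0.95)
})

test_that("Huber fits agree with the reference IRLS implementation", {
  skip_if_not_installed("MASS")
  X <- make_test_design(60, seed = 15)
  set.seed(16)
  Y <- matrix(rnorm(20 * 60, drop(X %*% c(1, 0.4, -0.01, 0.2, 0)), 1),
              20, byrow = TRUE, ncol = 60)
  Y[cbind(1:20, sample(60, 20, TRUE))] <- 15  # one outlier per feature
  fit <- fit_robust(Y, X)
  for (i in 1:20) {
    ref <- MASS::rlm(X, Y[i, ], psi = MASS::psi.huber, k = 1.345,
                     maxit = 50)
    expect_equal(unname(fit$coefficients[i, ]),
                 unname(coef(ref)), tolerance = 0.02)
  }
})

test_that("fit_robust is invariant to sample order and equivariant to rescaling", {
  X <- make_test_design(45, seed = 6)
  set.seed(7)
  Y <- matrix(rnorm(10 * 45, drop(X %*% c(1, .3, 0, 0, 0)), 1), 10,
              byrow = TRUE, ncol = 45)
  fit <- fit_robust(Y, X)
  perm <- sample(45)
  fit_p <- fit_robust(Y[, perm], X[perm, ])
  expect_equal(fit$coefficients, fit_p$coefficients, tolerance = 1e-6)

  X2 <- X
  X2[, "age"] <- X[, "age"] / 10
  fit_s <- fit_robust(Y, X2)
  expect_equal(fit_s$coefficients[, "age"],
               fit$coefficients[, "age"] * 10, tolerance = 1e-6)
  expect_equal(fit_s$coefficients[, "braak"],
               fit$coefficients[, "braak"], tolerance = 1e-6)

  # rank-deficiency after row deletion flags the feature as missing
  Xr <- X
  Xr[, "pmi"] <- Xr[, "braak"]
  expect_true(all(is.na(fit_robust(Y[1, , drop = FALSE],
                                   Xr)$coefficients)))
})

test_that("variance squeezing recovers known prior hyperparameters", {
  d0 <- 4; s02 <- 2; d <- 10
  set.seed(8)
  nfeat <- 20000
  sigma2 <- d0 * s02 / stats::rchisq(nfeat, d0)
  s2 <- sigma2 * stats::rchisq(nfeat, d) / d
  sq <- squeeze_var(s2, rep(d, nfeat))
  expect_lt(abs(sq$d0 - d0), 1)
  expect_lt(abs(sq$s02 - s02) / s02, 0.10)

  # identical variances: infinite prior df, posterior equals the common value
  sq2 <- squeeze_var(rep(1.7, 100), rep(12, 100))
  expect_true(is.infinite(sq2$d0))
  expect_equal(sq2$s02, 1.7)
  expect_equal(unique(sq2$s2_post), 1.7)
})

test_that("squeezed variances agree with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(9)
  s2 <- 1.5 * stats::rchisq(5000, 8) / 8 * (4 / stats::rchisq(5000, 4) * 4)
  sq <- squeeze_var(s2, rep(8, 5000))
  ref <- limma::squeezeVar(s2, df = 8)
  expect_equal(sq$d0, ref$df.prior, tolerance = 0.02)
  expect_equal(sq$s02, ref$var.prior, tolerance = 0.02)
  expect_equal(sq$s2_post, ref$var.post, tolerance = 1e-6)
})

test_that("moderated p-values are uniform under the null and control FDR", {
  X <- make_test_design(50, seed = 10)
  set.seed(11)
  Y <- matrix(rnorm(5000 * 50), 5000, 50)
  fit <- ebayes(fit_robust(Y, X))
  ks <- stats::ks.test(fit$p, "punif")
  expect_gt(ks$p.value, 0.01)

  # empirical FDR of q < 0.05 calls over null replicates
  set.seed(12)
  false_calls <- 0; total_feats <- 0
  for (r in 1:20) {
    Yr <- matrix(rnorm(400 * 50), 400, 50)
    fr <- ebayes(fit_robust(Yr, X))
    false_calls <- false_calls + sum(fr$q < 0.05, na.rm = TRUE)
    total_feats <- total_feats + 400
  }
  expect_lte(false_calls / total_feats, 0.075)
})

test_that("BH adjustment equals the step-up enumeration oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0, 0.5)), "lie in")

  set.seed(13)
  for (r in 1:50) {
    m <- sample(2:8, 1)
    p <- round(stats::runif(m, 0.01, 1), 3)
    expect_equal(bh_adjust(p), bh_enum(p), tolerance = 1e-12)
  }
})

test_that("inflation factor matches its chi-square definition", {
  z <- rep(c(-0.6745, 0.6745), 50)
  infl <- inflation_factor(z)
  expect_equal(infl$lambda, 0.6745^2 / stats::qchisq(0.5, 1),
               tolerance = 1e-4)
  expect_equal(infl$bias, 0)

  set.seed(14)
  z2 <- rnorm(1e5)
  i2 <- inflation_factor(z2)
  expect_true(i2$lambda > 0.97 && i2$lambda < 1.03)
  expect_true(abs(i2$bias) < 0.01)
  i3 <- inflation_factor(z2 * sqrt(2))
  expect_equal(i3$lambda, 2 * i2$lambda, tolerance = 1e-9)
})

test_that("delta_beta contrasts severe against reference Braak groups", {
  beta <- rbind(rep(0.5, 6),
                c(0.2, 0.2, 0.5, 0.5, 0.3, 0.3),
                c(0.1, 0.1, NA, NA, 0.4, 0.6))
  m <- mm_from_beta(beta)
  meta <- data.frame(sample = colnames(m$beta), age = 80, sex = "F",
                     pmi = 20, braak = c(1, 2, 3, 4, 5, 6))
  d <- delta_beta(m, meta)
  expect_equal(unname(d), c(0, 0.1, 0.4))
  d_swap <- delta_beta(m, meta, low = c(5, 6), high = c(1, 2))
  expect_equal(unname(d_swap), -unname(d))

  beta_na <- rbind(c(NA, NA, 0.5, 0.5, 0.3, 0.3))
  dna <- delta_beta(mm_from_beta(beta_na), meta)
  expect_true(is.na(dna))
})
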