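test_that("null model matches closed forms and the normal-equations oracle", {
  set.seed(21)
  e <- rnorm(40, 2, 1.5)
  # intercept only: mean and n-1 variance
  nm <- fit_null_model(e, matrix(1, 40, 1))
  expect_equal(unname(nm$alpha_hat), mean(e))
  expect_equal(nm$sigma2_hat, var(e))
  # random n = 30, p = 3 instance vs explicit inversion
  X <- cbind(1, rnorm(30), runif(30))
  y <- rnorm(30)
  nm2 <- fit_null_model(y, X)
  alpha_direct <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(nm2$alpha_hat), drop(alpha_direct), tolerance = 1e-10)
  expect_lt(max(abs(crossprod(X, nm2$residuals))),
            1e-8 * max(abs(crossprod(X, y))))
  # degenerate: e in the span of X
  expect_error(fit_null_model(X %*% c(1, 2, 3), X), "degenerate")
  # rank-deficient design names the collinear column
  Xr <- cbind(a = rep(1, 30), b = rnorm(30))
  Xr <- cbind(Xr, c = Xr[, "b"])
  expect_error(fit_null_model(y, Xr), "collinear.*c")
})

test_that("burden score test equals the squared refit z-statistic", {
  set.seed(22)
  n <- 50
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  s <- rnorm(n, 1, 0.8)
  e <- 0.3 * s + X %*% c(0.5, 0.5, 0.2) + rnorm(n)
  nm <- fit_null_model(e, X)
  st <- burden_score_test(nm, s)
  # brute-force refit: add s to the regression, square its z-statistic
  fit <- lm(e ~ 0 + X + s)
  # score test variance uses the null sigma2; rescale the refit z accordingly
  sm <- summary(fit)$coefficients
  z2_refit <- (sm["s", "Estimate"] / sm["s", "Std. Error"])^2
  sigma2_full <- sum(residuals(fit)^2) / (n - 4)
  z2_score_scale <- z2_refit * sigma2_full / nm$sigma2_hat
  expect_equal(st$statistic, z2_score_scale, tolerance = 1e-8)
  expect_equal(st$p_value, pchisq(st$statistic, 1, lower.tail = FALSE))
})

test_that("burden test is degenerate for collinear s and exact for s'r = 0", {
  set.seed(23)
  n <- 30
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  nm <- fit_null_model(e, X)
  expect_error(burden_score_test(nm, X[, 2]), class = "tlegene_degenerate_burden")
  # s orthogonal to the residuals: statistic 0, p = 1
  r <- nm$residuals
  s0 <- rnorm(n)
  s0 <- qr.resid(qr(cbind(X, r)), s0)  # orthogonal to X and r
  st <- burden_score_test(nm, s0)
  expect_equal(st$statistic, 0, tolerance = 1e-16)
  expect_equal(st$p_value, 1)
})

test_that("variance-component test handles degenerate G and m = 1", {
  set.seed(24)
  n <- 40
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  nm <- fit_null_model(e, X)
  # all-zero genotypes: statistic 0, p = 1
  z <- vc_score_test(nm, matrix(0, n, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # m = 1 reduces to the burden test with that column
  g1 <- rbinom(n, 2, 0.3)
  p_vc <- vc_score_test(nm, matrix(g1, ncol = 1))$p_value
  p_burden <- burden_score_test(nm, g1)$p_value
  expect_equal(p_vc, p_burden, tolerance = 1e-6)
  # G inside the design span: statistic 0, p = 1
  z2 <- vc_score_test(nm, cbind(X[, 2], 2 * X[, 2] + 3))
  expect_equal(z2$statistic, 0, tolerance = 1e-12)
  expect_equal(z2$p_value, 1)
})

test_that("variance-component p agrees with a Monte-Carlo null", {
  set.seed(25)
  n <- 50; m <- 5
  g <- make_genotypes(n = n, m = m, seed = 26, ld_rho = 0.4)
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  nm <- fit_null_model(e, X)
  res <- vc_score_test(nm, g$dosages)
  # resimulate residuals from N(0, sigma2 * P0) and recompute Q
  B <- 1e5
  qx <- nm$qr
  Z <- matrix(rnorm(n * B, 0, sqrt(nm$sigma2_hat)), n, B)
  R <- qr.resid(qx, Z)
  Qs <- colSums(crossprod(g$dosages, R)^2)
  p_mc <- mean(Qs >= res$statistic)
  se_mc <- sqrt(p_mc * (1 - p_mc) / B)
  expect_lt(abs(res$p_value - p_mc), 3 * se_mc + 1e-12)
})

test_that("mixture-of-chi-square tail matches closed forms and Monte Carlo", {
  # single weight: exact chi2_1 tail
  expect_equal(mixture_chisq_pvalue(3.841459, 1),
               pchisq(3.841459, 1, lower.tail = FALSE), tolerance = 1e-9)
  # equal weights c: chi2_3 tail at q / c
  expect_equal(mixture_chisq_pvalue(5, c(2, 2, 2)),
               pchisq(2.5, 3, lower.tail = FALSE), tolerance = 1e-8)
  # reference value for lambdas (2, 1, 0.5) at q = 5 computed by two
  # independent high-resolution inversions of the characteristic function
  expect_equal(mixture_chisq_pvalue(5, c(2, 1, 0.5)), 0.2264318,
               tolerance = 1e-6)
  # Monte-Carlo agreement
  set.seed(27)
  d <- 2 * rchisq(1e6, 1) + rchisq(1e6, 1) + 0.5 * rchisq(1e6, 1)
  p_mc <- mean(d > 5)
  expect_lt(abs(mixture_chisq_pvalue(5, c(2, 1, 0.5)) - p_mc),
            3 * sqrt(p_mc * (1 - p_mc) / 1e6))
  # guards
  expect_error(mixture_chisq_pvalue(5, c(1, -1)), "negative")
  expect_equal(mixture_chisq_pvalue(0, c(1, 2)), 1)
})

test_that("decorrelated pair reduces to the plain score test when gamma = 0", {
  set.seed(28)
  n <- 60
  g <- make_genotypes(n = n, m = 6, seed = 29)
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  pair <- decorrelated_pair(e, X, g$dosages, rep(0, 6))
  expect_true(pair$degenerate)
  expect_null(pair$s_theta)
  plain <- vc_score_test(fit_null_model(e, X), g$dosages)
  expect_equal(pair$q_tau$p_value, plain$p_value)
  # non-degenerate pair reports both tests
  pair2 <- decorrelated_pair(e, X, g$dosages, rnorm(6, 0, 0.3))
  expect_false(pair2$degenerate)
  expect_s3_class(pair2$s_theta, "score_result")
  # the burden vector is in the tau null design, so G projected there
  # loses the burden direction: q_tau differs from the plain Score
  expect_false(isTRUE(all.equal(pair2$q_tau$statistic, plain$statistic)))
})

test_that("component p-values are invariant to location and scale of e", {
  set.seed(30)
  n <- 50
  g <- make_genotypes(n = n, m = 5, seed = 31)
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  gam <- rnorm(5, 0, 0.3)
  p0 <- decorrelated_pair(e, X, g$dosages, gam)
  p1 <- decorrelated_pair(7 + 3 * e, X, g$dosages, gam)
  expect_equal(p0$s_theta$p_value, p1$s_theta$p_value, tolerance = 1e-8)
  expect_equal(p0$q_tau$p_value, p1$q_tau$p_value, tolerance = 1e-8)
})

test_that("q_tau is invariant to rescaling gamma", {
  set.seed(32)
  n <- 50
  g <- make_genotypes(n = n, m = 5, seed = 33)
  X <- cbind(1, rnorm(n))
  e <- rnorm(n)
  gam <- rnorm(5, 0, 0.3)
  a <- decorrelated_pair(e, X, g$dosages, gam)
  b <- decorrelated_pair(e, X, g$dosages, -2.5 * gam)
  expect_equal(a$q_tau$p_value, b$q_tau$p_value, tolerance = 1e-8)
  expect_equal(a$s_theta$statistic, b$s_theta$statistic, tolerance = 1e-8)
})
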