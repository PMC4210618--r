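test_that("row_lm reproduces exact fits and two-point variances", {
  groups <- rep(c("a", "b"), each = 3)
  design <- model.matrix(~0 + groups)
  fit <- row_lm(matrix(c(0, 0, 0, 1, 1, 1), 1, 6), design)
  expect_equal(drop(fit$coefficients %*% c(-1, 1)), 1)
  expect_equal(fit$sigma2, 0)

  fit2 <- row_lm(matrix(c(1, 3), 1, 2), matrix(1, 2, 1))
  expect_equal(unname(drop(fit2$coefficients)), 2)
  expect_equal(fit2$sigma2, 2)  # two-point sample variance
  expect_identical(fit2$df_residual, 1L)
})

test_that("row_lm agrees with per-row lm() on a random design", {
  set.seed(42)
  y <- matrix(rnorm(160), 20, 8)
  x1 <- rnorm(8); x2 <- runif(8)
  design <- cbind(1, x1, x2)
  fit <- row_lm(y, design)
  for (g in c(1, 7, 20)) {
    ref <- lm(y[g, ] ~ x1 + x2)
    expect_equal(unname(drop(fit$coefficients[g, ])), unname(coef(ref)),
                 tolerance = 1e-10)
    expect_equal(fit$sigma2[g], sum(resid(ref)^2) / ref$df.residual,
                 tolerance = 1e-10)
  }
  expect_equal(fit$hat, unname(hat(design)), tolerance = 1e-10)
  expect_error(row_lm(y, cbind(1, x1, x1)), "rank deficient")
})

test_that("trigamma_inverse matches a bisection oracle", {
  for (y in c(1e-4, 0.01, 0.105, 1.0, 5, 1e3)) {
    x <- trigamma_inverse(y)
    expect_equal(x, trigamma_inverse_bisect(y), tolerance = 1e-7)
    expect_equal(trigamma(x), y, tolerance = 1e-7 * y)
  }
  # the frozen spot value for psi'(x) = 1
  expect_equal(trigamma_inverse(1), 1.42625512, tolerance = 1e-6)
  expect_error(trigamma_inverse(-1), "positive")
})

test_that("equal variances give an infinite-df prior with near-identity scale", {
  d <- 98
  pr <- fit_var_prior(rep(0.5, 100), df = d)
  expect_identical(pr$d0, Inf)
  # exp(mean(e)) carries the exact digamma bias factor, ~1 for large df
  expect_equal(pr$s0_sq, 0.5 * exp(log(d / 2) - digamma(d / 2)))
  expect_equal(pr$s0_sq, 0.5, tolerance = 0.02)
})

test_that("prior estimation matches limma's fitFDist on shared data", {
  skip_if_not_installed("limma")
  set.seed(3)
  d <- 10
  s2 <- draw_variances(5000, d0 = 8, s0_sq = 0.3) * rchisq(5000, d) / d
  mine <- fit_var_prior(s2, df = d)
  ref <- limma::fitFDist(s2, df1 = d)
  expect_equal(mine$d0, ref$df2, tolerance = 1e-6)
  expect_equal(mine$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("zero variances are excluded from the prior but still squeezed", {
  s2 <- c(0, 0, rep(0.5, 50))
  pr <- fit_var_prior(s2, df = 10)
  expect_identical(pr$n_zero, 2L)
  post <- squeeze_var(s2, 10, pr$d0, pr$s0_sq)
  expect_length(post, 52)
  expect_true(all(post > 0))
  expect_error(fit_var_prior(c(0, 0), df = 10), "zero")
})

test_that("squeeze_var interpolates between data and prior", {
  expect_equal(squeeze_var(2, df = 5, d0 = 20, s0_sq = 1), 1.2)
  expect_equal(squeeze_var(c(0.3, 2), df = 7, d0 = Inf, s0_sq = 0.9),
               c(0.9, 0.9))
  expect_equal(squeeze_var(2, df = 5, d0 = 1e-9, s0_sq = 1), 2,
               tolerance = 1e-6)
  # convexity: posterior always between the variance and the prior
  set.seed(9)
  s2 <- rchisq(200, 3)
  post <- squeeze_var(s2, df = 6, d0 = 4.5, s0_sq = 1.1)
  expect_true(all(post >= pmin(s2, 1.1) - 1e-12))
  expect_true(all(post <= pmax(s2, 1.1) + 1e-12))
})

test_that("moderated t collapses to the classical pooled t when d0 = 0", {
  set.seed(11)
  groups <- rep(c("a", "b"), c(5, 7))
  design <- model.matrix(~0 + groups)
  y <- matrix(rnorm(12 * 50), 50, 12)
  fit <- row_lm(y, design)
  # d0 = 0 leaves each variance untouched: t must equal the textbook t
  mt <- moderated_t(fit, d0 = 0, s0_sq = 1, contrast = c(-1, 1))
  for (g in c(1, 25, 50)) {
    ref <- pooled_t_oracle(y[g, groups == "a"], y[g, groups == "b"])
    expect_equal(mt$t[g], ref$t, tolerance = 1e-10)
    expect_equal(mt$p[g], ref$p, tolerance = 1e-10)
  }
})

test_that("moderated t handles null centers and a fixed worked instance", {
  groups <- rep(c("a", "b"), each = 3)
  design <- model.matrix(~0 + groups)
  yc <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6)
  fit <- row_lm(yc, design)
  mt <- moderated_t(fit, d0 = 4, s0_sq = 1, contrast = c(-1, 1))
  expect_equal(mt$t, 0)
  expect_equal(mt$p, 1)

  # independent step-by-step formula evaluation, frozen
  y <- matrix(c(1, 2, 3, 4, 5, 9), 1, 6)
  fit <- row_lm(y, design)
  s2 <- fit$sigma2                       # pooled residual variance, df = 4
  post <- (4 * 1 + 4 * s2) / 8
  tref <- (6 - 2) / sqrt(post * (1 / 3 + 1 / 3))
  pref <- 2 * pt(-abs(tref), df = 8)
  mt <- moderated_t(fit, d0 = 4, s0_sq = 1, contrast = c(-1, 1))
  expect_equal(mt$t, tref, tolerance = 1e-12)
  expect_equal(mt$p, pref, tolerance = 1e-12)
  expect_equal(mt$df_total, 8)
})

test_that("moderation pipeline agrees with limma eBayes end to end", {
  skip_if_not_installed("limma")
  set.seed(21)
  groups <- rep(c("a", "b"), each = 6)
  design <- model.matrix(~0 + groups)
  y <- matrix(rnorm(12 * 300, sd = rep(sqrt(draw_variances(300)), 12)),
              300, 12)
  fit <- row_lm(y, design)
  pr <- fit_var_prior(fit$sigma2, fit$df_residual)
  mt <- moderated_t(fit, pr$d0, pr$s0_sq, c(-1, 1))
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(y, design), c(-1, 1)))
  expect_equal(pr$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(pr$s0_sq, eb$s2.prior, tolerance = 1e-8)
  expect_equal(mt$t, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(mt$p, unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("shrinkage towards a larger prior attenuates the statistic", {
  groups <- rep(c("a", "b"), each = 4)
  design <- model.matrix(~0 + groups)
  set.seed(5)
  y <- matrix(rnorm(8 * 20), 20, 8)
  fit <- row_lm(y, design)
  t1 <- abs(moderated_t(fit, 10, max(fit$sigma2) * 2, c(-1, 1))$t)
  t2 <- abs(moderated_t(fit, 10, max(fit$sigma2) * 4, c(-1, 1))$t)
  expect_true(all(t2 <= t1 + 1e-12))
})

test_that("bh_adjust matches its definition, oracles and invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  p <- runif(1000)
  q <- bh_adjust(p)
  expect_identical(q, bh_bruteforce(p))
  expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))       # monotone in raw p
  perm <- sample(1000)
  expect_identical(bh_adjust(p[perm]), q[perm])  # permutation equivariance
  # ties share adjusted values
  pt <- c(0.02, 0.02, 0.5)
  expect_equal(bh_adjust(pt)[1], bh_adjust(pt)[2])
})
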