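test_that("deviations carry the n/(n+1) leverage factor of the group design", {
  # group of 50: leverage 1/50, factor 50/51
  g <- factor(rep(c("a", "b"), each = 50))
  x <- matrix(rnorm(200), 2, 100)
  dev <- compute_deviations(x, groups = g, type = "abs")
  expect_equal(unique(round(dev$leverage, 12)), 50 / 51)

  # hand computation: groups {0,2} (h = 1/2) and {5,5,5,5} (h = 1/4)
  y <- matrix(c(0, 2, 5, 5, 5, 5), 1, 6)
  g2 <- factor(rep(c("a", "b"), c(2, 4)))
  dev2 <- compute_deviations(y, groups = g2, type = "abs")
  expect_equal(unname(dev2$z[1, 1:2]), c(1, 1) * 2 / 3)
  expect_equal(unname(dev2$z[1, 3:6]), rep(0, 4))
  expect_equal(unname(dev2$leverage), c(2/3, 2/3, 4/5, 4/5, 4/5, 4/5))

  # squared deviations: the factor multiplies the squared deviation once
  dev2s <- compute_deviations(y, groups = g2, type = "sq")
  expect_equal(unname(dev2s$z[1, 1:2]), c(1, 1) * 2 / 3)

  # a constant feature has an all-zero deviation row
  cst <- compute_deviations(matrix(3, 1, 6), groups = g2, type = "abs")
  expect_equal(unname(cst$z[1, ]), rep(0, 6))

  # a group of one has leverage 1: no variability information
  expect_error(compute_deviations(matrix(rnorm(3), 1, 3),
                                  design = diag(3)[, 1:2], type = "abs"),
               "leverage")
})

test_that("swapping group labels negates the effect and preserves p", {
  sim <- tiny_sim()
  f1 <- varfit(sim$M, groups = sim$groups)
  f2 <- varfit(sim$M, groups = factor(sim$groups,
                                      levels = c("group2", "group1")))
  expect_equal(f2$table$effect, -f1$table$effect, tolerance = 1e-12)
  expect_equal(f2$table$p_value, f1$table$p_value, tolerance = 1e-12)
})

test_that("absolute-deviation p-values are affine invariant", {
  sim <- tiny_sim(seed = 13)
  f1 <- varfit(sim$M, groups = sim$groups, type = "abs")
  shifted <- methyl_matrix(unclass(sim$M)[, ] * -2.5 + 7, scale = "M")
  f2 <- varfit(shifted, groups = sim$groups, type = "abs")
  expect_equal(f2$table$p_value, f1$table$p_value, tolerance = 1e-9)
  expect_equal(f2$table$effect, 2.5 * f1$table$effect, tolerance = 1e-9)
})

test_that("balanced designs make the leverage factor immaterial", {
  sim <- tiny_sim(seed = 17)
  fit <- varfit(sim$M, groups = sim$groups)
  # moderated t on the unscaled absolute deviations: same p (scale-free t)
  g <- sim$groups
  design <- stats::model.matrix(~0 + g)
  vals <- unclass(sim$M)[, ]
  r <- vals
  for (lev in levels(g))
    r[, g == lev] <- vals[, g == lev] - rowMeans(vals[, g == lev, drop = FALSE])
  zf <- row_lm(abs(r), design)
  pr <- fit_var_prior(zf$sigma2, zf$df_residual)
  mt <- moderated_t(zf, pr$d0, pr$s0_sq, c(-1, 1))
  expect_equal(fit$table$p_value, unname(mt$p), tolerance = 1e-10)
})

test_that("a single spread-out group is detected with the right sign", {
  y <- matrix(c(-1, 0, 1, -10, 0, 10), 1, 6)
  g <- factor(rep(c("a", "b"), each = 3))
  fit <- varfit(y, groups = g)
  expect_gt(fit$table$effect, 0)  # group b has the larger spread
  # independent re-evaluation: G = 1 forces the infinite-d0 prior fallback
  dev <- compute_deviations(y, groups = g, type = "abs")
  zf <- row_lm(dev$z, stats::model.matrix(~0 + g))
  e <- log(zf$sigma2) - digamma(zf$df_residual / 2) + log(zf$df_residual / 2)
  post <- exp(e)
  tref <- diff(tapply(dev$z[1, ], g, mean)) / sqrt(post * (1/3 + 1/3))
  pref <- 2 * pt(-abs(tref), 1e6)
  expect_equal(fit$prior$d0, Inf)
  expect_equal(fit$table$t, unname(tref), tolerance = 1e-10)
  expect_equal(fit$table$p_value, unname(pref), tolerance = 1e-10)
})

test_that("beta input is logit-transformed automatically", {
  sim <- tiny_sim(seed = 23)
  beta <- m_to_beta(sim$M)
  f_beta <- varfit(beta, groups = sim$groups)
  f_m <- varfit(sim$M, groups = sim$groups)
  expect_equal(f_beta$table$p_value, f_m$table$p_value, tolerance = 1e-9)
})

test_that("null p-values are near-uniform under the hierarchical model", {
  for (seed in 1:5) {
    sim <- simulate_methylation(n_features = 10000, n1 = 50, n2 = 50,
                                seed = 1000 + seed)
    fit <- varfit(sim$M, groups = sim$groups)
    ks <- suppressWarnings(ks.test(fit$table$p_value, "punif"))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("variability ratio uses the max/min convention with direction", {
  # variances 5 and 1 scaled into data: group a = sd sqrt(5), b = sd 1
  set.seed(31)
  x <- cbind(matrix(rnorm(50 * 20, sd = sqrt(5)), 50),
             matrix(rnorm(50 * 20), 50))
  g <- rep(c("a", "b"), each = 20)
  vr <- variability_ratio(x, g)
  expect_true(all(vr$var_ratio >= 1))
  expect_equal(mean(vr$var_ratio), 5, tolerance = 0.25 * 5)
  expect_true(mean(vr$direction == "a") > 0.9)

  # exactly equal variances give ratio 1
  y <- matrix(c(1, 2, 3, 4, 11, 12, 13, 14), 1, 8)
  vr2 <- variability_ratio(y, rep(c("a", "b"), each = 4))
  expect_equal(vr2$var_ratio, 1)

  # both variances zero: ratio defined as 1, logged
  expect_message(
    vr3 <- variability_ratio(matrix(1, 1, 8), rep(c("a", "b"), each = 4)),
    "zero variance")
  expect_equal(vr3$var_ratio, 1)
})

test_that("significant_dv applies the FDR and ratio filters jointly", {
  sim <- tiny_sim(seed = 37)
  fit <- varfit(sim$M, groups = sim$groups)
  # force known boundary rows
  fit$table$adj_p_value[1:3] <- c(0.01, 0.04, 0.2)
  fit$table$var_ratio[1:3] <- c(4.9, 6, 100)
  fit$table$adj_p_value[-(1:3)] <- 1
  sel <- significant_dv(fit, fdr = 0.05, ratio = 5)
  expect_identical(sel$probe_id, fit$table$probe_id[2])  # 0.04 & 6 only
  expect_named(attr(sel, "counts"), c("group1", "group2"))

  fit$table$adj_p_value[] <- 1
  expect_identical(nrow(significant_dv(fit)), 0L)
})

test_that("meanfit finds location shifts and nothing under identical groups", {
  set.seed(41)
  base <- matrix(rnorm(100 * 6, sd = 0.01), 100, 6)
  g <- rep(c("a", "b"), each = 3)
  same <- cbind(base[, 1:3], base[, 1:3])
  f0 <- meanfit(same, groups = g)
  expect_equal(f0$table$effect, rep(0, 100), tolerance = 1e-12)
  expect_equal(f0$table$p_value, rep(1, 100), tolerance = 1e-8)

  shifted <- base; shifted[, 4:6] <- shifted[, 4:6] + 1
  f1 <- meanfit(shifted, groups = g)
  expect_equal(f1$table$effect, rep(1, 100), tolerance = 0.05)
  expect_true(all(f1$table$adj_p_value < 0.01))
})

test_that("meanfit reports the group beta difference for filtering", {
  sim <- tiny_sim(seed = 43)
  fit <- meanfit(sim$M, groups = sim$groups)
  beta <- unclass(m_to_beta(sim$M))[, ]
  db <- rowMeans(beta[, sim$groups == "group2"]) -
    rowMeans(beta[, sim$groups == "group1"])
  expect_equal(fit$table$delta_beta, unname(db), tolerance = 1e-12)
  expect_true(all(abs(fit$table$delta_beta) <= 1))

  fit$table$adj_p_value[1:3] <- 0.01
  fit$table$delta_beta[1:3] <- c(0.09, 0.25, -0.3)
  fit$table$adj_p_value[-(1:3)] <- 1
  sel <- significant_dm(fit)
  expect_identical(sel$probe_id, fit$table$probe_id[2:3])
})

test_that("ranking overlap has the right envelopes and chance level", {
  ids <- paste0("f", 1:500)
  ov <- ranking_overlap(ids, ids, top_n = 50, universe = ids, n_random = 10)
  expect_equal(ov$overlap, 1:50)  # identical rankings: identity curve
  ov2 <- ranking_overlap(ids[1:100], ids[101:200], top_n = 100,
                         universe = ids, n_random = 10)
  expect_equal(ov2$overlap, rep(0, 100))  # disjoint top lists
  # chance baseline at rank k is about k^2 / universe
  set.seed(47)
  ov3 <- ranking_overlap(sample(ids), sample(ids), top_n = 200,
                         universe = ids, n_random = 200)
  expect_equal(ov3$random_median[200], 200^2 / 500, tolerance = 0.15)
  expect_error(ranking_overlap(ids, ids, top_n = 501, universe = ids),
               "universe")
})

test_that("varfit S3 surface behaves", {
  sim <- tiny_sim(seed = 53)
  fit <- varfit(sim$M, groups = sim$groups)
  expect_output(print(fit), "absolute deviations")
  expect_output(print(summary(fit)), "Top features")
  expect_length(coef(fit), nrow(sim$M))
  expect_identical(dim(residuals(fit)), dim(unclass(sim$M)[, ]))
  expect_identical(as.data.frame(fit), fit$table)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
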