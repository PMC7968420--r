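# Per-region features, change rates, and the two-group statistics.

test_that("sphere region features match the analytic oracles", {
  vol <- sphereVolumeFixture()
  rf <- regionFeatures(vol, "CA1")
  expect_lt(abs(rf$volume / (4 / 3 * pi * 1000) - 1), 0.02)
  expect_lt(abs(rf$surface_area / (4 * pi * 100) - 1), 0.05)
  # principal curvature means bracket the analytic 1/r = 0.1
  expect_gt(rf$curv_max, 0.1); expect_lt(rf$curv_min, 0.11)
  expect_gt(rf$curv_min, 0)
  # RPC >= 1 by construction; near-umbilic surfaces keep it far below the
  # values of strongly folded regions (ridge/valley vertices reach 1e8)
  expect_gte(rf$rpc, 1)
  expect_lt(rf$rpc, 3)
  # determinism
  expect_identical(rf, regionFeatures(vol, "CA1"))
  expect_error(regionFeatures(vol, "CA3"), "zero voxels|unknown")
})

test_that("change rate uses the second-visit denominator as defined", {
  expect_equal(changeRate(100, 100), 0)
  expect_equal(changeRate(443.964, 325.024), -0.36594, tolerance = 1e-5)
  expect_error(changeRate(1, 0), "non-zero")
  # asymmetric denominator: not antisymmetric under visit swap
  expect_false(isTRUE(all.equal(changeRate(80, 100), -changeRate(100, 80))))
})

test_that("Cohen's d matches printed group summaries and its invariances", {
  expect_equal(round(cohensD(-3.96, 6.13, -7.78, 5.81), 2), 0.64)
  expect_lt(abs(cohensD(4.23, 14.62, 3.61, 14.42) - 0.04254), 5e-4)
  expect_equal(cohensD(1, 2, 1, 3), 0)
  expect_equal(cohensD(-3.96, 6.13, -7.78, 5.81),
               cohensD(-7.78, 5.81, -3.96, 6.13))      # group-symmetric
  expect_equal(cohensD(-39.6, 61.3, -77.8, 58.1),
               cohensD(-3.96, 6.13, -7.78, 5.81))      # scale-invariant
  expect_equal(cohensD(3, 0, 3, 0), 0)
  expect_error(cohensD(1, 0, 2, 0), "infinite")
})

test_that("two-sample t behaves canonically and detects the printed effect", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  same <- twoSampleT(x, y)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  a <- c(0.3, 1.2, -0.5, 2); b <- c(1.4, 2.2, 3.1, 0.2)
  expect_equal(twoSampleT(a, b)$t, -twoSampleT(b, a)$t)
  expect_equal(twoSampleT(a, b)$p, twoSampleT(b, a)$p)
  expect_error(twoSampleT(1, y), "n >= 2")
  # power at the presubiculum volume effect size (d ~ 0.62, n = 89/group,
  # alpha = 0.01): closed-form noncentral-t oracle, checked within 3 MC SEs
  ncp <- 0.62 * sqrt(89 / 2)
  crit <- qt(0.995, df = 176)
  power <- 1 - pt(crit, 176, ncp) + pt(-crit, 176, ncp)  # ~ 0.936
  rej <- vapply(1:1000, function(s) {
    set.seed(s)
    twoSampleT(rnorm(89), rnorm(89, 0.62))$p < 0.01
  }, logical(1))
  se <- sqrt(power * (1 - power) / 1000)
  expect_lt(abs(mean(rej) - power), 3 * se)
  expect_gt(mean(rej), 0.9)
})

test_that("chi-square statistics reproduce the demographic comparisons", {
  expect_equal(chiSquareStat(rbind(c(53, 36), c(52, 37))), 0)  # Yates 2x2
  prop <- rbind(c(20, 40), c(10, 20))
  expect_equal(chiSquareStat(prop, yates = FALSE), 0)
  expect_gt(chiSquareStat(rbind(c(30, 10), c(10, 30)), yates = FALSE), 0)
  expect_error(chiSquareStat(rbind(c(0, 0), c(1, 2))), "zero expected")
  expect_equal(chi2Critical(1, 0.05), 3.841, tolerance = 5e-4)
  expect_equal(chi2Critical(4, 0.05), 9.488, tolerance = 5e-4)
  expect_error(chi2Critical(0, 0.05), "df")
  expect_error(chi2Critical(1, 1.5), "alpha")
})

test_that("Pearson correlation handles exact and null cases", {
  x <- 1:10
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_error(pearsonR(x, rep(1, 10)), "constant")
  expect_error(pearsonR(1:2, 2:3), "n >= 3")
  small <- vapply(1:200, function(s) {
    set.seed(s)
    abs(pearsonR(rnorm(178), rnorm(178))$r) < 0.2
  }, logical(1))
  expect_gt(mean(small), 0.9)
})

test_that("groupStats reproduces the group-summary layout over 45 features", {
  tab <- simulateCohort(nPerGroup = 30, seed = 21)
  gs <- groupStats(tab)
  expect_identical(gs$feature, featureInventory()$feature)
  expect_identical(nrow(gs), 45L)
  expect_true(all(gs$p_value >= 0 & gs$p_value <= 1))
  expect_true(all(gs$cohens_d >= 0))
  single <- tab[tab$group == 0, ]
  expect_error(groupStats(single), "two groups")
})

test_that("groupStats with zero-SD groups gives p ~ 0 and the closed-form d", {
  params <- subfieldCohortParams()[1:2, ]
  params$sd_stable <- 0; params$sd_converter <- 0
  params$mean_stable <- c(0, 1); params$mean_converter <- c(1, 1)
  tab <- simulateCohort(nPerGroup = 10, params = params, seed = 1)
  # add negligible jitter so the t statistic is defined
  tab[[params$feature[1]]] <- tab[[params$feature[1]]] +
    rnorm(20, 0, 1e-9)
  gs <- groupStats(tab[, c("subject_id", "group", params$feature[1])])
  expect_lt(gs$p_value, 1e-10)
  expect_gt(gs$cohens_d, 1e6)
})

test_that("presubiculum volume effect size is recovered across seeds", {
  # sampling SE of d at n = 89/group: sqrt(2/n + d^2/(4n)) ~ 0.153, so the
  # sample d should land within ~2 SE (0.31) of the population value 0.618 in
  # ~95% of seeds, and its average should be close to the population value
  params <- subfieldCohortParams()
  params <- params[params$feature == "presubiculum__volume", ]
  dTrue <- cohensD(params$mean_stable, params$sd_stable,
                   params$mean_converter, params$sd_converter)
  seD <- sqrt(2 / 89 + dTrue^2 / (4 * 89))
  ds <- vapply(1:100, function(s) {
    tab <- simulateCohort(nPerGroup = 89, params = params, seed = s)
    groupStats(tab)$cohens_d
  }, numeric(1))
  expect_gte(mean(abs(ds - dTrue) < 2 * seD), 0.90)
  expect_lt(abs(mean(ds) - dTrue), 3 * seD / sqrt(100))
})

test_that("label permutation makes groupStats p-values uniform", {
  tab <- simulateCohort(nPerGroup = 89, seed = 31)
  sub <- tab[, c("subject_id", "group", "subiculum__surface_area")]
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    sub$group <- sample(sub$group)
    groupStats(sub)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
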