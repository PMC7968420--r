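# Feature selection and the MLP conversion classifier.

test_that("univariate selection reproduces the published threshold counts", {
  uni <- univariateSelectionTable()
  expect_identical(nrow(uni), 30L)
  counts <- vapply(c(0.01, 0.05, 0.1), function(th)
    length(selectedFeatures(univariateSelect(uni, th))), integer(1))
  expect_identical(counts, c(19L, 21L, 25L))
  expect_identical(length(selectedFeatures(univariateSelect(uni, 1.0))), 30L)
  expect_error(univariateSelect(uni, 0), "pThreshold")
  expect_error(univariateSelect(uni, 1.5), "pThreshold")
})

test_that("univariate selection is monotone in the threshold", {
  uni <- univariateSelectionTable()
  prev <- character(0)
  for (th in c(0.001, 0.01, 0.05, 0.1, 0.5, 1)) {
    cur <- selectedFeatures(univariateSelect(uni, th))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # ranking is ascending in p
  r <- featureRanking(univariateSelect(uni, 0.05))
  expect_true(!is.unsorted(r$p_value))
})

test_that("univariate selection computes p-values from a cohort directly", {
  tab <- simulateCohort(nPerGroup = 89, seed = 41)
  sel <- univariateSelect(tab, 0.01)
  gs <- groupStats(tab)
  expect_identical(sort(selectedFeatures(sel)),
                   sort(gs$feature[gs$p_value < 0.01]))
})

test_that("forest importance ranks a planted signal feature first", {
  tab <- simulateCohort(nPerGroup = 89, seed = 51)
  set.seed(51)
  tab$planted <- tab$group + rnorm(nrow(tab), 0, 0.01)
  hits <- vapply(1:20, function(s) {
    fi <- forestImportance(tab, nForests = 5, nTrees = 20, topK = 1, seed = s)
    featureRanking(fi)$feature[1] == "planted"
  }, logical(1))
  expect_true(all(hits))
})

test_that("forest importance is deterministic, non-negative, and validated", {
  tab <- simulateCohort(nPerGroup = 30, seed = 61)
  a <- forestImportance(tab, nForests = 3, nTrees = 10, seed = 5)
  b <- forestImportance(tab, nForests = 3, nTrees = 10, seed = 5)
  expect_identical(featureRanking(a), featureRanking(b))
  expect_true(all(featureRanking(a)$score >= 0))
  # normalized importances: total score sums to the number of forests
  expect_equal(sum(featureRanking(a)$score), 3, tolerance = 1e-9)
  expect_error(forestImportance(tab, topK = 100), "topK")
  one <- tab[tab$group == 1, ]
  expect_error(forestImportance(one), "both classes")
})

test_that("planted-feature recovery improves with effect size", {
  base <- subfieldCohortParams()
  base$mean_stable <- 0; base$mean_converter <- 0
  base$sd_stable <- 1; base$sd_converter <- 1
  recov <- vapply(c(0.2, 0.5, 1.0, 3.0), function(d) {
    params <- base
    params$mean_converter[1] <- d  # plant the effect in feature 1
    mean(vapply(1:15, function(s) {
      tab <- simulateCohort(nPerGroup = 89, params = params, seed = s + 1000)
      fi <- forestImportance(tab, nForests = 3, nTrees = 20, topK = 1,
                             seed = s)
      featureRanking(fi)$feature[1] == params$feature[1]
    }, logical(1)))
  }, numeric(1))
  expect_true(!is.unsorted(recov))
  expect_gt(recov[4], recov[1])
})

test_that("classifier metrics follow their definitions", {
  expect_equal(evaluateClassifier(c(1, 0, 1, 0), c(1, 0, 1, 0)),
               c(accuracy = 100, sensitivity = 100, specificity = 100))
  expect_equal(evaluateClassifier(rep(1, 4), c(1, 1, 0, 0)),
               c(accuracy = 50, sensitivity = 100, specificity = 0))
  truth <- c(1, 1, 0, 0)
  expect_equal(evaluateClassifier(1 - truth, truth),
               c(accuracy = 0, sensitivity = 0, specificity = 0))
  expect_warning(m <- evaluateClassifier(c(0, 0), c(0, 0)), "sensitivity")
  expect_true(is.na(m["sensitivity"]))
  expect_error(evaluateClassifier(1, c(1, 0)), "length")
})

test_that("the MLP separates two well-separated Gaussian blobs", {
  set.seed(1)
  n <- 89
  blob <- data.frame(subject_id = sprintf("S%03d", 1:(2 * n)),
                     group = rep(0:1, each = n),
                     f1 = c(rnorm(n, 0), rnorm(n, 4)),
                     f2 = c(rnorm(n, 0), rnorm(n, 4)))
  rep1 <- trainMLP(blob, config = mlpConfig(repeats = 10, seed = 3))
  expect_gte(meanMetrics(rep1)["accuracy"], 95)
})

test_that("the MLP is at chance on permuted labels", {
  tab <- simulateCohort(nPerGroup = 89, seed = 71)
  set.seed(5)
  tab$group <- sample(tab$group)
  rep0 <- trainMLP(tab, config = mlpConfig(repeats = 20, seed = 13))
  acc <- meanMetrics(rep0)["accuracy"]
  expect_gte(acc, 40); expect_lte(acc, 60)
})

test_that("report bookkeeping: mean accuracy equals the mean of repeats", {
  tab <- simulateCohort(nPerGroup = 30, seed = 81)
  rep1 <- trainMLP(tab, config = mlpConfig(repeats = 5, maxIter = 100,
                                           seed = 2))
  pr <- perRepeatMetrics(rep1)
  expect_identical(nrow(pr), 5L)
  expect_equal(unname(meanMetrics(rep1)["accuracy"]), mean(pr$accuracy))
  expect_true(all(pr$accuracy >= 0 & pr$accuracy <= 100))
  # deterministic under a fixed root seed
  rep2 <- trainMLP(tab, config = mlpConfig(repeats = 5, maxIter = 100,
                                           seed = 2))
  expect_identical(perRepeatMetrics(rep2), pr)
})

test_that("trainMLP validates its inputs", {
  tab <- simulateCohort(nPerGroup = 10, seed = 91)
  expect_error(trainMLP(tab, subset = character(0)), "empty feature subset")
  expect_error(trainMLP(tab, subset = "nope"), "unknown features")
  one <- tab[tab$group == 0, ]
  expect_error(trainMLP(one), "single-class")
  expect_error(mlpConfig(splitFractions = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(mlpConfig(repeats = 0), "repeats")
})

test_that("early stopping with the validation split still learns", {
  set.seed(2)
  n <- 60
  blob <- data.frame(subject_id = sprintf("S%03d", 1:(2 * n)),
                     group = rep(0:1, each = n),
                     f1 = c(rnorm(n, 0), rnorm(n, 4)))
  rep1 <- trainMLP(blob, config = mlpConfig(repeats = 5, seed = 4,
                                            earlyStopping = TRUE))
  expect_gte(meanMetrics(rep1)["accuracy"], 90)
})
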