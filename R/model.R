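# Feature selection (univariate t-test p-values; repeated random-forest Gini
# importance) and the repeat-averaged MLP conversion classifier.

#' SelectionResult: a ranked feature list with a selected subset
#'
#' @slot method `"univariate"` or `"forest"`.
#' @slot ranking data.frame of (feature, score), sorted ascending by p-value
#'   (univariate) or descending by summed Gini importance (forest).
#' @slot selected character vector, the retained subset (in ranking order).
#' @slot criterion human-readable selection criterion.
#' @aliases SelectionResult
#' @export
setClass("SelectionResult",
  representation(method = "character", ranking = "data.frame",
                 selected = "character", criterion = "character"))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!object@method %in% c("univariate", "forest"))
    msg <- c(msg, "method must be 'univariate' or 'forest'")
  if (!all(object@selected %in% object@ranking$feature))
    msg <- c(msg, "selected features must appear in the ranking")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s, %s): %d of %d features selected\n",
              object@method, object@criterion, length(object@selected),
              nrow(object@ranking)))
  print(utils::head(object@ranking, 5))
})

#' @rdname SelectionResult-class
#' @param x a `SelectionResult`
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname SelectionResult-class
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @rdname SelectionResult-class
#' @export
setGeneric("featureRanking", function(x) standardGeneric("featureRanking"))
#' @rdname SelectionResult-class
#' @export
setMethod("featureRanking", "SelectionResult", function(x) x@ranking)

#' Univariate feature selection by two-sample t-test p-value
#'
#' Ranks features ascending by p-value and retains those with
#' `p < pThreshold` (strict). The input is either a change-rate table with a
#' `group` column (p-values computed by [groupStats()]) or a precomputed
#' data.frame with `feature` and `p_value` columns.
#'
#' @param x change-rate table or (feature, p_value) data.frame.
#' @param pThreshold selection threshold in (0, 1].
#' @return A [SelectionResult-class].
#' @examples
#' sel <- univariateSelect(univariateSelectionTable(), 0.01)
#' length(selectedFeatures(sel))  # 19
#' @export
univariateSelect <- function(x, pThreshold = 0.01) {
  if (pThreshold <= 0 || pThreshold > 1)
    stop("pThreshold must be in (0, 1]")
  df <- if (!is.null(x$p_value) && !is.null(x$feature)) {
    data.frame(feature = x$feature, p_value = x$p_value,
               stringsAsFactors = FALSE)
  } else {
    gs <- groupStats(x)
    data.frame(feature = gs$feature, p_value = gs$p_value,
               stringsAsFactors = FALSE)
  }
  df <- df[order(df$p_value, df$feature), ]
  rownames(df) <- NULL
  new("SelectionResult", method = "univariate", ranking = df,
      selected = df$feature[df$p_value < pThreshold],
      criterion = sprintf("p < %g", pThreshold))
}

#' Feature ranking by repeated random-forest Gini importance
#'
#' Fits `nForests` random forests of `nTrees` trees each on the classification
#' of group from the feature columns; each forest's Gini importances
#' (total Gini impurity reduction per feature) are normalized to sum to 1 and
#' summed across forests, and features are ranked by the summed importance.
#'
#' @param table change-rate table with a 0/1 `group` column.
#' @param nForests number of forests (default 100).
#' @param nTrees trees per forest (default 20).
#' @param topK number of top-ranked features to retain (default all).
#' @param seed root seed; per-forest seeds are derived deterministically.
#' @return A [SelectionResult-class] with `score` = summed normalized Gini
#'   importance.
#' @export
forestImportance <- function(table, nForests = 100L, nTrees = 20L,
                             topK = NULL, seed = 1L) {
  feats <- featureColumns(table)
  if (length(unique(table$group)) < 2L) stop("need both classes present")
  if (is.null(topK)) topK <- length(feats)
  if (topK > length(feats)) stop("topK exceeds the feature count")
  X <- as.matrix(table[, feats, drop = FALSE])
  y <- factor(table$group)
  total <- numeric(length(feats))
  for (f in seq_len(nForests)) {
    set.seed(.substreamSeed(seed, 0L, f))
    rf <- randomForest::randomForest(X, y, ntree = nTrees,
                                     importance = FALSE)
    imp <- rf$importance[, "MeanDecreaseGini"]
    s <- sum(imp)
    if (s > 0) total <- total + imp / s
  }
  df <- data.frame(feature = feats, score = total, stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$feature), ]
  rownames(df) <- NULL
  new("SelectionResult", method = "forest", ranking = df,
      selected = df$feature[seq_len(topK)],
      criterion = sprintf("top %d of %d forests x %d trees",
                          topK, nForests, nTrees))
}

# ---------------------------------------------------------------------------
# MLP classifier
# ---------------------------------------------------------------------------

#' MLP training configuration
#'
#' Defaults follow the study protocol: two 12-neuron ReLU hidden layers,
#' Adam with momentum 0.9 and adaptive learning rate, L2 penalty 1e-4, a
#' fixed budget of 800 iterations, random 60/30/10 train/test/validation
#' splits, and averaging over 100 training repeats. The validation split is
#' held out (optionally used for early stopping; off by default so training
#' runs the full iteration budget).
#'
#' @param hidden hidden layer sizes.
#' @param maxIter training iterations (full batch).
#' @param l2 L2 weight penalty.
#' @param learningRate Adam base learning rate.
#' @param beta1,beta2 Adam moment decay rates (`beta1` is the momentum).
#' @param splitFractions train/test/validation fractions, summing to 1.
#' @param repeats number of shuffled training repeats to average.
#' @param seed root seed; per-repeat seeds are derived deterministically.
#' @param earlyStopping stop when validation loss stops improving.
#' @return list of class `mlpConfig`.
#' @export
mlpConfig <- function(hidden = c(12L, 12L), maxIter = 800L, l2 = 1e-4,
                      learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      splitFractions = c(train = 0.6, test = 0.3,
                                         validation = 0.1),
                      repeats = 100L, seed = 1L, earlyStopping = FALSE) {
  if (abs(sum(splitFractions) - 1) > 1e-8)
    stop("splitFractions must sum to 1")
  if (repeats < 1L) stop("repeats must be >= 1")
  structure(list(hidden = hidden, maxIter = maxIter, l2 = l2,
                 learningRate = learningRate, beta1 = beta1, beta2 = beta2,
                 splitFractions = splitFractions, repeats = repeats,
                 seed = seed, earlyStopping = earlyStopping),
            class = "mlpConfig")
}

#' ClassifierReport: repeat-averaged classification performance
#'
#' @slot perRepeat data.frame with one row per training repeat: seed,
#'   accuracy, sensitivity, specificity (percent, test split only).
#' @slot features feature subset used.
#' @slot config the `mlpConfig` used.
#' @aliases ClassifierReport
#' @export
setClass("ClassifierReport",
  representation(perRepeat = "data.frame", features = "character",
                 config = "list"))

setValidity("ClassifierReport", function(object) {
  m <- as.matrix(object@perRepeat[, c("accuracy", "sensitivity",
                                      "specificity")])
  ok <- is.na(m) | (m >= 0 & m <= 100)
  if (!all(ok)) "metrics must lie in [0, 100] percent" else TRUE
})

setMethod("show", "ClassifierReport", function(object) {
  s <- meanMetrics(object)
  cat(sprintf(
    "ClassifierReport: %d repeats, %d features\n  accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    nrow(object@perRepeat), length(object@features),
    s["accuracy"], s["sensitivity"], s["specificity"]))
})

#' @rdname ClassifierReport-class
#' @param x a `ClassifierReport`
#' @export
setGeneric("meanMetrics", function(x) standardGeneric("meanMetrics"))

#' @describeIn ClassifierReport-class mean accuracy/sensitivity/specificity
#'   (percent) across repeats
#' @export
setMethod("meanMetrics", "ClassifierReport", function(x) {
  c(accuracy = mean(x@perRepeat$accuracy, na.rm = TRUE),
    sensitivity = mean(x@perRepeat$sensitivity, na.rm = TRUE),
    specificity = mean(x@perRepeat$specificity, na.rm = TRUE))
})

#' @rdname ClassifierReport-class
#' @export
setGeneric("perRepeatMetrics", function(x) standardGeneric("perRepeatMetrics"))
#' @rdname ClassifierReport-class
#' @export
setMethod("perRepeatMetrics", "ClassifierReport", function(x) x@perRepeat)

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Converter (label 1) is the positive class: sensitivity is converter
#' recall, specificity non-converter recall, both in percent. If the truth
#' contains no positives (or no negatives) the undefined metric is returned
#' as `NA` with a warning rather than silently 0.
#'
#' @param predicted,truth 0/1 label vectors of equal length.
#' @return named numeric: accuracy, sensitivity, specificity (percent).
#' @examples
#' evaluateClassifier(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 50, 50, 50
#' @export
evaluateClassifier <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!length(truth)) stop("empty input")
  pos <- truth == 1; neg <- truth == 0
  sens <- if (any(pos)) 100 * mean(predicted[pos] == 1) else {
    warning("no positive truth labels: sensitivity undefined"); NA_real_
  }
  spec <- if (any(neg)) 100 * mean(predicted[neg] == 0) else {
    warning("no negative truth labels: specificity undefined"); NA_real_
  }
  c(accuracy = 100 * mean(predicted == truth),
    sensitivity = sens, specificity = spec)
}

#' Train and evaluate the MLP conversion classifier
#'
#' For each repeat: shuffle, stratified 60/30/10 train/test/validation split,
#' standardize features with the train-split mean/SD, fit the MLP for the
#' full iteration budget, threshold the predicted converter probability at
#' 0.5, and score the test split. Metrics are reported per repeat and
#' averaged.
#'
#' @param table change-rate table with a 0/1 `group` column.
#' @param subset feature names to use (default: all feature columns).
#' @param config an [mlpConfig()].
#' @return A [ClassifierReport-class].
#' @examples
#' \donttest{
#' tab <- simulateCohort(nPerGroup = 30, seed = 2)
#' rep <- trainMLP(tab, config = mlpConfig(repeats = 3, maxIter = 200))
#' meanMetrics(rep)
#' }
#' @export
trainMLP <- function(table, subset = NULL, config = mlpConfig()) {
  if (is.null(subset)) subset <- featureColumns(table)
  if (!length(subset)) stop("empty feature subset")
  missing <- setdiff(subset, names(table))
  if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
  y <- table$group
  if (length(unique(y)) < 2L) stop("single-class data: cannot train")
  X <- as.matrix(table[, subset, drop = FALSE])

  rows <- lapply(seq_len(config$repeats), function(r) {
    rseed <- .substreamSeed(config$seed, 1L, r)
    sp <- .stratifiedSplit(y, config$splitFractions, rseed)
    mu <- colMeans(X[sp$train, , drop = FALSE])
    sg <- apply(X[sp$train, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0 | !is.finite(sg)] <- 1
    std <- function(M) sweep(sweep(M, 2L, mu), 2L, sg, "/")
    useVal <- isTRUE(config$earlyStopping) && length(sp$validation)
    net <- .mlpFit(std(X[sp$train, , drop = FALSE]), y[sp$train],
                   hidden = config$hidden, maxIter = config$maxIter,
                   l2 = config$l2, learningRate = config$learningRate,
                   beta1 = config$beta1, beta2 = config$beta2, seed = rseed,
                   Xval = if (useVal) std(X[sp$validation, , drop = FALSE]),
                   yval = if (useVal) y[sp$validation])
    prob <- .mlpPredict(net, std(X[sp$test, , drop = FALSE]))
    m <- evaluateClassifier(as.integer(prob >= 0.5), y[sp$test])
    data.frame(repeat_id = r, seed = rseed, accuracy = m["accuracy"],
               sensitivity = m["sensitivity"], specificity = m["specificity"],
               row.names = NULL)
  })
  new("ClassifierReport", perRepeat = do.call(rbind, rows),
      features = subset, config = unclass(config))
}
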