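# Synthetic two-group change-rate cohorts. The generator draws each of the 45
# subfield change-rate features from a per-group Gaussian whose means and SDs
# come from the published group summaries shipped in inst/extdata, so the
# simulated cohorts have the marginal statistical structure of the real
# converter / non-converter comparison (joint covariances are not published;
# features are independent by default, with an optional equicorrelation).

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "hippomorph", mustWork = FALSE)
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)  # pre-install
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' The 45-feature inventory (9 subfields x 5 morphological indices)
#'
#' Fixed ordering of the analyzed subfields (presubiculum, subiculum, CA1,
#' CA3, CA4, GC-ML-DG, molecular layer, hippocampal fissure, hippocampal
#' tail) crossed with the five indices (volume, surface_area, curv_max,
#' curv_min, rpc). Feature column names follow `<region>__<index>` with
#' non-alphanumeric region characters mapped to `_`.
#'
#' @return data.frame with columns `region`, `index`, `feature` (45 rows).
#' @examples
#' nrow(featureInventory())  # 45
#' @export
featureInventory <- function() {
  regions <- c("presubiculum", "subiculum", "CA1", "CA3", "CA4", "GC-ML-DG",
               "molecular layer", "hippocampal fissure", "hippocampal tail")
  indices <- c("volume", "surface_area", "curv_max", "curv_min", "rpc")
  df <- expand.grid(index = indices, region = regions,
                    stringsAsFactors = FALSE)[, c("region", "index")]
  df$feature <- featureName(df$region, df$index)
  rownames(df) <- NULL
  df
}

#' @rdname featureInventory
#' @param region,index character vectors of region and index names.
#' @export
featureName <- function(region, index) {
  paste0(gsub("[^A-Za-z0-9]+", "_", region), "__", index)
}

#' Published two-group change-rate summaries
#'
#' `changeRateSummaries()` returns the per-feature group means and SDs (in
#' percent), p-values and Cohen's d of the volume, surface-area and RPC
#' change rates for the nine analyzed subfields (27 rows).
#' `univariateSelectionTable()` returns the 30 ranked univariate-selection
#' p-values (values reported only as an upper bound are stored at the bound
#' with `p_censored = TRUE`).
#'
#' @return data.frame; see Details.
#' @export
changeRateSummaries <- function() {
  df <- .extdata("subfield_change_rates.tsv")
  df$feature <- featureName(df$region, df$index)
  df
}

#' @rdname changeRateSummaries
#' @export
univariateSelectionTable <- function() {
  df <- .extdata("univariate_selection.tsv")
  df$feature <- featureName(df$region, df$index)
  df
}

#' Default generator parameters for all 45 features
#'
#' Group means/SDs for volume, surface_area and rpc change rates come from the
#' published summaries. The published record gives no group means/SDs for the
#' curv_max / curv_min change rates -- only univariate p-values for 8 of the
#' 18; for those, the effect size is back-derived from the p-value
#' (|t| = qt(1 - p/2, 176), d = |t| / sqrt(89/2)) and expressed as a
#' converter-group mean shift of d * 8 percentage points around a stable-group
#' mean of 0 with SD 8% (comparable to the published RPC-change SDs). The 10
#' curvature features without a published p-value get a null effect (d = 0).
#'
#' @return data.frame with columns `region`, `index`, `feature`,
#'   `mean_stable`, `sd_stable`, `mean_converter`, `sd_converter` (45 rows,
#'   inventory order). Units are percent change.
#' @export
subfieldCohortParams <- function() {
  inv <- featureInventory()
  pub <- changeRateSummaries()
  uni <- univariateSelectionTable()
  sdCurv <- 8
  out <- inv
  out$mean_stable <- 0; out$sd_stable <- sdCurv
  out$mean_converter <- 0; out$sd_converter <- sdCurv
  m <- match(out$feature, pub$feature)
  has <- !is.na(m)
  out$mean_stable[has] <- pub$mean_stable[m[has]]
  out$sd_stable[has] <- pub$sd_stable[m[has]]
  out$mean_converter[has] <- pub$mean_converter[m[has]]
  out$sd_converter[has] <- pub$sd_converter[m[has]]
  cu <- uni[uni$index %in% c("curv_max", "curv_min"), ]
  mm <- match(cu$feature, out$feature)
  d <- stats::qt(1 - cu$p_value / 2, df = 176) / sqrt(89 / 2)
  out$mean_converter[mm] <- d * sdCurv
  out
}

.substreamSeed <- function(root, group, j) {
  as.integer((as.double(root) %% 1e6) * 2000 + group * 1000 + j)
}

#' Simulate a two-group change-rate cohort
#'
#' Draws `nPerGroup` subjects per group; each feature of each group is
#' Gaussian with that group's (mean, SD) from `params`. Group 0 is the
#' non-converter (stable) group, group 1 the converter (the positive class
#' throughout). Values are percent change rates, as in the published
#' summaries. Each (group, feature) pair uses its own deterministic
#' sub-stream of the root seed, so adding or reordering features does not
#' perturb the draws of other columns. An optional equicorrelation `rho`
#' mixes in a per-subject common factor, giving every feature pair
#' within-subject correlation `rho`.
#'
#' @param nPerGroup subjects per group (default 89).
#' @param params parameter table as from [subfieldCohortParams()]; must have
#'   columns feature, mean_stable, sd_stable, mean_converter, sd_converter
#'   with non-negative SDs.
#' @param correlation within-subject feature correlation in `[0, 1)`.
#' @param seed integer root seed.
#' @return data.frame ("ChangeRateTable"): `subject_id`, `group` (0/1), then
#'   one numeric column per feature.
#' @examples
#' tab <- simulateCohort(nPerGroup = 10, seed = 1)
#' dim(tab)  # 20 x 47
#' @export
simulateCohort <- function(nPerGroup = 89L, params = subfieldCohortParams(),
                           correlation = 0, seed = 1L) {
  if (nPerGroup < 1L) stop("nPerGroup must be >= 1")
  if (!nrow(params)) stop("empty feature list")
  need <- c("feature", "mean_stable", "sd_stable", "mean_converter",
            "sd_converter")
  if (!all(need %in% names(params))) stop("params lacks required columns")
  if (anyDuplicated(params$feature)) stop("duplicate features in params")
  if (any(params$sd_stable < 0) || any(params$sd_converter < 0))
    stop("SDs must be >= 0")
  if (correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)")

  nf <- nrow(params)
  out <- matrix(0, 2L * nPerGroup, nf)
  grp <- rep(c(0L, 1L), each = nPerGroup)
  for (g in 0:1) {
    rows <- which(grp == g)
    mu <- if (g == 0L) params$mean_stable else params$mean_converter
    sdv <- if (g == 0L) params$sd_stable else params$sd_converter
    zc <- if (correlation > 0) {
      set.seed(.substreamSeed(seed, g, 0L))
      stats::rnorm(nPerGroup)
    } else numeric(nPerGroup)
    for (j in seq_len(nf)) {
      set.seed(.substreamSeed(seed, g, j))
      z <- stats::rnorm(nPerGroup)
      if (correlation > 0)
        z <- sqrt(correlation) * zc + sqrt(1 - correlation) * z
      out[rows, j] <- mu[j] + sdv[j] * z
    }
  }
  colnames(out) <- params$feature
  cbind(data.frame(subject_id = sprintf("S%04d", seq_len(2L * nPerGroup)),
                   group = grp, stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Feature columns of a change-rate table
#'
#' @param table a change-rate data.frame as from [simulateCohort()].
#' @return character vector of feature column names.
#' @export
featureColumns <- function(table) {
  setdiff(names(table), c("subject_id", "group"))
}

#' Read/write a change-rate cohort as delimited text
#'
#' Tab-separated, one header row: subject_id, group, then one column per
#' feature.
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @return `writeCohort` returns `path` invisibly; `readCohort` the
#'   data.frame.
#' @export
writeCohort <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject_id", "group") %in% names(df)))
    stop("not a cohort table: missing subject_id/group columns")
  df
}
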