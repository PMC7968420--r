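# Per-region morphometric features, longitudinal change rates, and the
# two-group statistics used to compare converter and non-converter cohorts.

#' Morphometric features of one labelled region
#'
#' Composes the geometric pipeline for a single region: binary mask ->
#' iso-surface reconstruction -> Laplacian smoothing -> curvature field ->
#' per-vertex means. The `volume` feature is the voxel count times the voxel
#' volume (segmentation volumetry convention); `mesh_volume` (the enclosed
#' volume of the smoothed surface) is also reported for geometric validation.
#'
#' @param vol a [LabelVolume-class].
#' @param region region name (see [extractMask()]).
#' @param smoothIterations,smoothStep smoothing parameters, see
#'   [laplacianSmooth()].
#' @param mode curvature mode, see [curvatureField()].
#' @param winsorize if `TRUE`, per-vertex RPC values are capped at their 99th
#'   percentile before averaging (off by default; the mean of RPC is sensitive
#'   to near-parabolic vertices).
#' @return data.frame with one row: region, volume (mm^3), surface_area
#'   (mm^2), curv_max, curv_min, rpc, mesh_volume (mm^3), n_vertices,
#'   clamp_count.
#' @export
regionFeatures <- function(vol, region, smoothIterations = 50L,
                           smoothStep = 0.5,
                           mode = c("area_normalized", "as_written"),
                           winsorize = FALSE) {
  mode <- match.arg(mode)
  mask <- extractMask(vol, region)
  voxvol <- prod(spacing(vol))
  mesh <- marchingCubes(mask, spacing(vol))
  mesh <- laplacianSmooth(mesh, smoothIterations, smoothStep)
  cf <- curvatureField(mesh, mode)
  rpc <- cf@rpc
  if (winsorize) rpc <- pmin(rpc, stats::quantile(rpc, 0.99, names = FALSE))
  data.frame(region = paste(region, collapse = "+"),
             volume = sum(mask) * voxvol,
             surface_area = meshArea(mesh),
             curv_max = mean(cf@cmax, na.rm = TRUE),
             curv_min = mean(cf@cmin, na.rm = TRUE),
             rpc = mean(rpc, na.rm = TRUE),
             mesh_volume = meshVolume(mesh),
             n_vertices = nrow(vertices(mesh)),
             clamp_count = clampCount(cf),
             stringsAsFactors = FALSE)
}

#' Longitudinal change rate of a morphological index
#'
#' \eqn{C_f = (f_{second} - f_{first}) / f_{second}}: the relative difference
#' between two visits, normalized by the *second* visit's value (note the
#' asymmetric denominator; implemented exactly as defined). Returned as a
#' fraction; multiply by 100 for percent.
#'
#' @param fFirst,fSecond index values at the first and second visit
#'   (vectorized). `fSecond` must be non-zero.
#' @return numeric change rate(s).
#' @examples
#' changeRate(443.964, 325.024)  # -0.36594, i.e. -36.59%
#' @export
changeRate <- function(fFirst, fSecond) {
  if (any(fSecond == 0)) stop("fSecond must be non-zero")
  (fSecond - fFirst) / fSecond
}

#' Cohen's d from group summaries
#'
#' Absolute standardized mean difference with the equal-n pooled SD:
#' \eqn{d = |m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}}.
#'
#' @param m1,s1,m2,s2 group means and SDs (s1, s2 >= 0, not both 0 unless the
#'   means agree).
#' @return non-negative effect size d.
#' @examples
#' cohensD(-3.96, 6.13, -7.78, 5.81)  # ~ 0.64
#' @export
cohensD <- function(m1, s1, m2, s2) {
  if (any(s1 < 0) || any(s2 < 0)) stop("SDs must be >= 0")
  pooled <- sqrt((s1^2 + s2^2) / 2)
  if (any(pooled == 0 & m1 != m2))
    stop("zero variance with differing means: infinite effect size")
  ifelse(pooled == 0, 0, abs(m1 - m2) / pooled)
}

#' Two-sample t-test
#'
#' Pooled-variance (Student) two-sample t by default, Welch optionally; the
#' two-sided p-value comes from the t distribution.
#'
#' @param groupA,groupB numeric vectors (n >= 2 each).
#' @param variant `"pooled"` or `"welch"`.
#' @return list with `t`, `p`, `df`.
#' @export
twoSampleT <- function(groupA, groupB, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs n >= 2")
  ht <- stats::t.test(groupA, groupB, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Pearson chi-square statistic and critical value
#'
#' `chiSquareStat` computes the Pearson statistic for an r x c count table,
#' with the Yates continuity correction applied to 2 x 2 tables when
#' `yates = TRUE` (the default, matching the demographic comparisons).
#' `chi2Critical` returns the upper critical value of the chi-square
#' distribution, i.e. the 5% significance bound when `alpha = 0.05`.
#'
#' @param table matrix of non-negative counts.
#' @param yates apply the continuity correction for 2 x 2 tables.
#' @return `chiSquareStat`: the statistic (numeric). `chi2Critical`: the
#'   critical value.
#' @examples
#' chiSquareStat(rbind(c(53, 36), c(52, 37)))  # 0 with Yates correction
#' chi2Critical(1, 0.05)                       # 3.841
#' @export
chiSquareStat <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be >= 0")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(E == 0)) stop("zero expected cell count")
  correct <- yates && all(dim(table) == 2L)
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  unname(ht$statistic)
}

#' @rdname chiSquareStat
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @export
chi2Critical <- function(df, alpha = 0.05) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(alpha <= 0) || any(alpha >= 1)) stop("alpha must be in (0, 1)")
  stats::qchisq(1 - alpha, df)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r` and `p`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Per-feature two-group statistics of a change-rate table
#'
#' For every feature column: group means and SDs, pooled two-sample t and
#' two-sided p, and Cohen's d -- one row per feature, mirroring the published
#' group-comparison layout. Group 0 is the stable (non-converter) group.
#'
#' @param table change-rate data.frame with a 0/1 `group` column (see
#'   [simulateCohort()]).
#' @param variant t-test variant, see [twoSampleT()].
#' @return data.frame with columns feature, mean_stable, sd_stable,
#'   mean_converter, sd_converter, t, p_value, cohens_d.
#' @export
groupStats <- function(table, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  feats <- featureColumns(table)
  if (!length(feats)) stop("no feature columns")
  g <- table$group
  if (length(unique(g)) != 2L) stop("need exactly two groups")
  rows <- lapply(feats, function(f) {
    a <- table[[f]][g == 0L]; b <- table[[f]][g == 1L]
    tt <- twoSampleT(a, b, variant)
    data.frame(feature = f,
               mean_stable = mean(a), sd_stable = stats::sd(a),
               mean_converter = mean(b), sd_converter = stats::sd(b),
               t = tt$t, p_value = tt$p,
               cohens_d = cohensD(mean(a), stats::sd(a), mean(b), stats::sd(b)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
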