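# Discrete curvature operators on closed triangle meshes.
#
# Gaussian curvature comes from the Gauss-Bonnet angle deficit at each vertex
# (2*pi minus the sum of incident interior angles); mean curvature from edge
# lengths times signed dihedral angles accumulated around each vertex. Two
# modes are exposed:
#   as_written       - the raw quantities: K = angle deficit (radians),
#                      H = mean over incident edges of s(e)*psi(e) (mm rad).
#   area_normalized  - dimensionally consistent pointwise estimators:
#                      K = deficit / A_v (1/mm^2),
#                      H = sum s(e)*psi(e) / (4 A_v) (1/mm),
#                      with A_v the barycentric vertex area (one third of the
#                      incident triangle areas).
# Principal curvatures are the roots cmax/cmin = H +/- sqrt(H^2 - K), with a
# negative discriminant clamped to zero (counted). The ratio of principal
# curvatures RPC = max(|cmax|,|cmin|) / min(|cmax|,|cmin|) >= 1 is the folding
# biomarker: 1 at umbilic (locally spherical) points, large on ridges/valleys.

# per-face unit normals, areas, and interior angles at the three corners
.faceGeometry <- function(mesh) {
  V <- vertices(mesh); f <- faces(mesh)
  p1 <- V[f[, 1], , drop = FALSE]
  p2 <- V[f[, 2], , drop = FALSE]
  p3 <- V[f[, 3], , drop = FALSE]
  e12 <- p2 - p1; e13 <- p3 - p1; e23 <- p3 - p2
  cr <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
              e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
              e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  a2 <- sqrt(rowSums(cr^2))            # twice the face area
  area <- a2 / 2
  nrm <- cr / ifelse(a2 > 0, a2, 1)
  l12 <- sqrt(rowSums(e12^2)); l13 <- sqrt(rowSums(e13^2))
  l23 <- sqrt(rowSums(e23^2))
  ang <- function(u, v, lu, lv) {
    cs <- rowSums(u * v) / (lu * lv)
    acos(pmin(1, pmax(-1, cs)))
  }
  a1 <- ang(e12, e13, l12, l13)        # angle at corner 1
  a2c <- ang(-e12, e23, l12, l23)      # at corner 2
  a3 <- pi - a1 - a2c                  # at corner 3
  list(normal = nrm, area = area, angles = cbind(a1, a2c, a3))
}

.vertexAreas <- function(mesh, geo = .faceGeometry(mesh)) {
  f <- faces(mesh)
  nv <- nrow(vertices(mesh))
  av <- numeric(nv)
  third <- geo$area / 3
  for (c3 in 1:3) {
    s <- rowsum(third, f[, c3])
    av[as.integer(rownames(s))] <- av[as.integer(rownames(s))] + s[, 1]
  }
  av
}

#' Discrete Gaussian curvature (Gauss-Bonnet angle deficit)
#'
#' Per vertex, `as_written` returns the raw angle deficit
#' \eqn{K(v) = 2\pi - \sum_i \beta_i} in radians, where the \eqn{\beta_i} are
#' the interior angles at `v` of its incident triangles; `area_normalized`
#' divides by the barycentric vertex area, giving 1/mm^2. Over any closed
#' genus-0 mesh the deficits sum to exactly \eqn{4\pi} (discrete Gauss-Bonnet
#' / Descartes). Vertices touched by a zero-area triangle are returned as
#' `NA` with a warning.
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @param mode `"as_written"` (default) or `"area_normalized"`.
#' @return numeric vector of per-vertex K.
#' @examples
#' sph <- icosphereMesh(10, 3)
#' sum(gaussianCurvature(sph)) / (4 * pi)  # 1
#' @export
gaussianCurvature <- function(mesh, mode = c("as_written", "area_normalized")) {
  mode <- match.arg(mode)
  geo <- .faceGeometry(mesh)
  f <- faces(mesh)
  nv <- nrow(vertices(mesh))
  angsum <- numeric(nv)
  for (c3 in 1:3) {
    s <- rowsum(geo$angles[, c3], f[, c3])
    angsum[as.integer(rownames(s))] <- angsum[as.integer(rownames(s))] + s[, 1]
  }
  K <- 2 * pi - angsum
  if (any(geo$area == 0)) {
    bad <- unique(as.vector(f[geo$area == 0, ]))
    K[bad] <- NA_real_
    warning(length(bad), " vertex/vertices incident to a degenerate triangle; K set to NA")
  }
  if (mode == "area_normalized") K <- K / .vertexAreas(mesh, geo)
  K
}

# signed dihedral angles: for each undirected edge of a closed oriented mesh,
# psi = atan2((nA x nB) . u, nA . nB) with u the edge direction as wound in
# face A; positive on convex edges (w.r.t. outward normals).
.edgeDihedrals <- function(mesh, geo = .faceGeometry(mesh)) {
  V <- vertices(mesh); f <- faces(mesh)
  nf <- nrow(f)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), times = 3L)
  nv <- as.double(nrow(V))
  key <- (pmin(he[, 1], he[, 2]) - 1) * nv + pmax(he[, 1], he[, 2])
  o <- order(key, he[, 1])
  key <- key[o]; he <- he[o, , drop = FALSE]; fid <- fid[o]
  n <- length(key)
  if (n %% 2L != 0L || any(key[seq(1, n, 2)] != key[seq(2, n, 2)]))
    stop("mesh has boundary or non-manifold edges; a closed mesh is required")
  i1 <- seq(1, n, 2); i2 <- seq(2, n, 2)
  a <- he[i1, 1]; b <- he[i1, 2]
  fa <- fid[i1]; fb <- fid[i2]
  u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
  len <- sqrt(rowSums(u^2))
  u <- u / len
  nA <- geo$normal[fa, , drop = FALSE]
  nB <- geo$normal[fb, , drop = FALSE]
  cr <- cbind(nA[, 2] * nB[, 3] - nA[, 3] * nB[, 2],
              nA[, 3] * nB[, 1] - nA[, 1] * nB[, 3],
              nA[, 1] * nB[, 2] - nA[, 2] * nB[, 1])
  psi <- atan2(rowSums(cr * u), rowSums(nA * nB))
  list(i = a, j = b, length = len, psi = psi)
}

#' Discrete mean curvature from edge dihedral angles
#'
#' Per vertex, `as_written` returns \eqn{H(v) = (1/N) \sum_e s(e) \psi(e)}
#' over the N edges incident to `v`, with `s(e)` the edge length and
#' \eqn{\psi(e)} the signed dihedral angle (positive where the surface is
#' convex with respect to the outward normal). `area_normalized` returns the
#' standard pointwise estimator \eqn{H(v) = \sum_e s(e)\psi(e) / (4 A_v)}
#' in 1/mm. Reversing the mesh orientation flips the sign of H everywhere.
#'
#' @inheritParams gaussianCurvature
#' @return numeric vector of per-vertex H.
#' @examples
#' sph <- icosphereMesh(10, 3)
#' median(meanCurvature(sph, "area_normalized")) * 10  # ~ 1
#' @export
meanCurvature <- function(mesh, mode = c("as_written", "area_normalized")) {
  mode <- match.arg(mode)
  geo <- .faceGeometry(mesh)
  ed <- .edgeDihedrals(mesh, geo)
  nv <- nrow(vertices(mesh))
  w <- ed$length * ed$psi
  acc <- numeric(nv); deg <- numeric(nv)
  for (side in list(ed$i, ed$j)) {
    s <- rowsum(w, side)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
    d <- rowsum(rep(1, length(side)), side)
    deg[as.integer(rownames(d))] <- deg[as.integer(rownames(d))] + d[, 1]
  }
  if (mode == "as_written") acc / deg else acc / (4 * .vertexAreas(mesh, geo))
}

#' Principal curvatures from K and H
#'
#' \eqn{c_{max} = H + \sqrt{H^2 - K}}, \eqn{c_{min} = H - \sqrt{H^2 - K}}.
#' A negative discriminant (possible for discrete estimates) is clamped to
#' zero, making the vertex umbilic; the number of clamped vertices is
#' reported.
#'
#' @param K,H numeric vectors of equal length.
#' @return list with `cmax`, `cmin` (cmax >= cmin everywhere) and integer
#'   `clampCount`.
#' @examples
#' principalCurvatures(K = 0.75, H = 1)  # cmax 1.5, cmin 0.5
#' @export
principalCurvatures <- function(K, H) {
  if (length(K) != length(H)) stop("K and H must have the same length")
  disc <- H^2 - K
  clamped <- !is.na(disc) & disc < 0
  sq <- sqrt(pmax(disc, 0))
  list(cmax = H + sq, cmin = H - sq, clampCount = sum(clamped))
}

#' Ratio of principal curvatures (RPC)
#'
#' \eqn{RPC = \max(|c_{max}|, |c_{min}|) / \min(|c_{max}|, |c_{min}|)}.
#' The denominator is floored at `eps` so the ratio stays finite near
#' parabolic points; the result is >= 1, equals 1 at umbilic points, and is
#' symmetric in its two arguments and invariant to global scaling of the
#' surface.
#'
#' @param cmax,cmin numeric vectors of equal length.
#' @param eps positive denominator floor (default 1e-8).
#' @return numeric vector of per-vertex RPC values (>= 1).
#' @examples
#' rpcIndex(2, 1)     # 2
#' rpcIndex(0.3, 0.3) # 1 (umbilic)
#' @export
rpcIndex <- function(cmax, cmin, eps = 1e-8) {
  if (eps <= 0) stop("eps must be > 0")
  if (length(cmax) != length(cmin)) stop("cmax and cmin must have the same length")
  a <- abs(cmax); b <- abs(cmin)
  num <- pmax(a, b)
  den <- pmax(pmin(a, b), eps)
  pmax(num, den) / den
}

#' Compute the full per-vertex curvature field of a mesh
#'
#' Composes [gaussianCurvature()], [meanCurvature()], [principalCurvatures()]
#' and [rpcIndex()] into a [CurvatureField-class].
#'
#' @inheritParams gaussianCurvature
#' @param eps RPC denominator floor, passed to [rpcIndex()].
#' @return A [CurvatureField-class].
#' @examples
#' curvatureField(icosphereMesh(10, 2), mode = "area_normalized")
#' @export
curvatureField <- function(mesh, mode = c("as_written", "area_normalized"),
                           eps = 1e-8) {
  mode <- match.arg(mode)
  K <- gaussianCurvature(mesh, mode)
  H <- meanCurvature(mesh, mode)
  pc <- principalCurvatures(K, H)
  new("CurvatureField", K = K, H = H, cmax = pc$cmax, cmin = pc$cmin,
      rpc = rpcIndex(pc$cmax, pc$cmin, eps), mode = mode,
      clampCount = as.integer(pc$clampCount))
}

# ---------------------------------------------------------------------------
# Folding-pattern classification
# ---------------------------------------------------------------------------

#' FoldingHistogram: distribution of local folding patterns
#'
#' Counts and fractions of surface vertices in each of six folding classes
#' (cap, ridge, flat, valley, cup, saddle), together with the curvature
#' threshold `tau` that defined "flat".
#'
#' @slot counts named integer vector over the six classes.
#' @slot fractions named numeric vector, sums to 1.
#' @slot tau threshold used.
#' @aliases FoldingHistogram
#' @export
setClass("FoldingHistogram",
  representation(counts = "integer", fractions = "numeric", tau = "numeric"))

setValidity("FoldingHistogram", function(object) {
  msg <- character()
  cls <- c("cap", "ridge", "flat", "valley", "cup", "saddle")
  if (!identical(names(object@counts), cls))
    msg <- c(msg, "counts must be named by the six folding classes")
  if (sum(object@counts) > 0 &&
      abs(sum(object@fractions) - 1) > 1e-12)
    msg <- c(msg, "fractions must sum to 1")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FoldingHistogram", function(object) {
  cat(sprintf("FoldingHistogram (tau = %.4g), %d vertices\n",
              object@tau, sum(object@counts)))
  print(round(object@fractions, 4))
})

#' Classify local folding patterns from principal curvatures
#'
#' Each vertex is assigned one of six shape classes by thresholding its
#' principal curvatures at `tau`: flat (both |c| <= tau), ridge
#' (cmax > tau, |cmin| <= tau), valley (|cmax| <= tau, cmin < -tau), cap
#' (both > tau), cup (both < -tau), saddle (cmax > tau, cmin < -tau). Because
#' cmax >= cmin these six classes are exhaustive. When `tau` is `NULL` it
#' defaults to the 25th percentile of |curvature| pooled over cmax and cmin;
#' the threshold actually used is always recorded in the histogram.
#'
#' @param cmax,cmin numeric vectors of principal curvatures.
#' @param tau positive threshold, or `NULL` for the adaptive default.
#' @return list with `class` (factor over the six classes, one per vertex)
#'   and `histogram` (a [FoldingHistogram-class]).
#' @examples
#' classifyFolding(c(0.5, 0.5), c(0.4, 0), tau = 0.1)$class  # cap, ridge
#' @export
classifyFolding <- function(cmax, cmin, tau = NULL) {
  stopifnot(length(cmax) == length(cmin))
  if (is.null(tau)) {
    tau <- stats::quantile(c(abs(cmax), abs(cmin)), 0.25, names = FALSE)
    if (tau <= 0) tau <- .Machine$double.eps
  }
  if (tau <= 0) stop("tau must be > 0")
  bucket <- function(x) (x > tau) - (x < -tau)
  bmax <- bucket(cmax); bmin <- bucket(cmin)
  cls <- rep(NA_character_, length(cmax))
  cls[bmax == 0 & bmin == 0] <- "flat"
  cls[bmax == 1 & bmin == 0] <- "ridge"
  cls[bmax == 0 & bmin == -1] <- "valley"
  cls[bmax == 1 & bmin == 1] <- "cap"
  cls[bmax == -1 & bmin == -1] <- "cup"
  cls[bmax == 1 & bmin == -1] <- "saddle"
  lev <- c("cap", "ridge", "flat", "valley", "cup", "saddle")
  cls <- factor(cls, levels = lev)
  counts <- table(cls)
  n <- length(cls)
  hist <- new("FoldingHistogram",
              counts = structure(as.integer(counts), names = lev),
              fractions = structure(as.numeric(counts) / max(n, 1L), names = lev),
              tau = as.numeric(tau))
  list(class = cls, histogram = hist)
}

#' Export per-vertex curvature values as delimited text
#'
#' Writes vertex_id, K, H, cmax, cmin, rpc (and folding class when supplied)
#' as a TSV.
#'
#' @param field a [CurvatureField-class].
#' @param path output file.
#' @param class optional per-vertex folding class (factor/character).
#' @return `path`, invisibly.
#' @export
writeCurvatureTSV <- function(field, path, class = NULL) {
  df <- curvatureValues(field)
  if (!is.null(class)) df$class <- as.character(class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
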