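# Synthetic label volumes of known analytic geometry. These stand in for
# segmented subfield masks so that every geometric stage (reconstruction,
# smoothing, curvature) can be validated against closed-form oracles.

#' Rasterize an analytic shape into a label volume
#'
#' Voxelizes a sphere, ellipsoid, torus or two-lobe (two overlapping spheres)
#' shape on a regular grid. A voxel carries `labelId` iff its *centre* lies
#' strictly inside the analytic surface, so the labelled voxel count times the
#' voxel volume converges to the analytic volume as spacing decreases. The
#' shape is centred in the grid and padded with `margin` background voxels on
#' every side, guaranteeing that [marchingCubes()] yields a closed surface.
#'
#' @param kind `"sphere"`, `"ellipsoid"`, `"torus"` or `"two_lobe"`.
#' @param radius sphere/lobe radius in mm (sphere, two_lobe).
#' @param semiAxes numeric(3) ellipsoid semi-axes in mm (ellipsoid).
#' @param majorRadius,minorRadius torus centre-line radius and tube radius in
#'   mm (torus; the torus axis is z).
#' @param separation centre-to-centre distance of the two lobes in mm
#'   (two_lobe; must be < 2 * radius so the lobes overlap into one component).
#' @param spacing voxel edge length(s) in mm, length 1 or 3.
#' @param labelId positive integer label for foreground voxels.
#' @param margin background padding in voxels (>= 1).
#' @param labelMap label dictionary attached to the result; defaults to a
#'   single entry naming the shape.
#' @return A [LabelVolume-class].
#' @examples
#' vol <- rasterizeShape("sphere", radius = 5, spacing = 1)
#' sum(labelGrid(vol) != 0) # ~ 4/3 pi 5^3
#' @export
rasterizeShape <- function(kind = c("sphere", "ellipsoid", "torus", "two_lobe"),
                           radius = NULL, semiAxes = NULL,
                           majorRadius = NULL, minorRadius = NULL,
                           separation = NULL,
                           spacing = c(1, 1, 1), labelId = 1L, margin = 2L,
                           labelMap = NULL) {
  kind <- match.arg(kind)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (margin < 1L) stop("margin must be >= 1 voxel")
  if (labelId < 1L) stop("labelId must be a positive integer")

  pos <- function(x, what) {
    if (is.null(x) || any(!is.finite(x)) || any(x <= 0))
      stop("invalid shape spec: ", what, " must be positive")
    x
  }
  half <- switch(kind,
    sphere = rep(pos(radius, "radius"), 3L),
    ellipsoid = {
      a <- pos(semiAxes, "semiAxes"); stopifnot(length(a) == 3L); a
    },
    torus = {
      R <- pos(majorRadius, "majorRadius"); r <- pos(minorRadius, "minorRadius")
      if (r >= R) stop("invalid shape spec: minorRadius must be < majorRadius")
      c(R + r, R + r, r)
    },
    two_lobe = {
      r <- pos(radius, "radius"); s <- pos(separation, "separation")
      if (s >= 2 * r) stop("invalid shape spec: lobes must overlap (separation < 2*radius)")
      c(s / 2 + r, r, r)
    })

  n <- 2L * as.integer(ceiling(half / spacing)) + 1L + 2L * as.integer(margin)
  ctr <- (n + 1) / 2
  x <- (seq_len(n[1]) - ctr[1]) * spacing[1]
  y <- (seq_len(n[2]) - ctr[2]) * spacing[2]
  z <- (seq_len(n[3]) - ctr[3]) * spacing[3]
  X <- array(rep(x, times = n[2] * n[3]), n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), n)
  Z <- array(rep(z, each = n[1] * n[2]), n)

  inside <- switch(kind,
    sphere = X^2 + Y^2 + Z^2 < radius^2,
    ellipsoid = (X / semiAxes[1])^2 + (Y / semiAxes[2])^2 +
      (Z / semiAxes[3])^2 < 1,
    torus = (sqrt(X^2 + Y^2) - majorRadius)^2 + Z^2 < minorRadius^2,
    two_lobe = pmin((X - separation / 2)^2, (X + separation / 2)^2) +
      Y^2 + Z^2 < radius^2)

  if (is.null(labelMap))
    labelMap <- structure(as.integer(labelId), names = kind)
  LabelVolume(array(as.integer(inside) * as.integer(labelId), n),
              spacing = spacing, labelMap = labelMap)
}

# signed volume (no abs): positive when faces are wound outward
.signedVolume <- function(V, f) {
  p1 <- V[f[, 1], , drop = FALSE]
  p2 <- V[f[, 2], , drop = FALSE]
  p3 <- V[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Icosphere test mesh
#'
#' Regular icosahedron subdivided `subdivisions` times with vertices projected
#' onto the sphere of the requested radius. A near-uniform triangulation of
#' the sphere: the standard analytic oracle for curvature estimators
#' (K = 1/r^2, H = 1/r, umbilic everywhere so RPC ~ 1).
#'
#' @param radius sphere radius in mm.
#' @param subdivisions number of 1-to-4 triangle subdivisions (>= 0).
#' @param center sphere centre, numeric(3).
#' @return A [SurfaceMesh-class] with outward orientation.
#' @export
icosphereMesh <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    ek <- key(e[, 1], e[, 2])
    mids <- (V[e[, 1], , drop = FALSE] + V[e[, 2], , drop = FALSE]) / 2
    midId <- nrow(V) + seq_len(nrow(e))
    names(midId) <- ek
    V <- rbind(V, mids)
    m12 <- midId[key(f[, 1], f[, 2])]
    m23 <- midId[key(f[, 2], f[, 3])]
    m31 <- midId[key(f[, 3], f[, 1])]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  V <- V / sqrt(rowSums(V^2)) * radius
  if (.signedVolume(V, f) < 0) f <- f[, c(1, 3, 2)]
  V <- sweep(V, 2L, center, "+")
  SurfaceMesh(V, f)
}
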