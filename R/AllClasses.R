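#' @import methods
NULL

#' The twelve hippocampal subfields
#'
#' Canonical subfield names and integer label codes used throughout the
#' package, in the conventional atlas order. Three subfields (parasubiculum,
#' HATA, fimbria) are too small to be resolved reliably at typical MRI
#' resolution and are excluded from feature analysis.
#'
#' @return `hippocampusSubfields()` returns a named integer vector mapping the
#'   12 subfield names to label codes; `analyzedSubfields()` returns the
#'   character vector of the 9 subfields retained for morphometric analysis.
#' @examples
#' hippocampusSubfields()
#' analyzedSubfields()
#' @export
hippocampusSubfields <- function() {
  c(
    "parasubiculum"       = 1L,
    "presubiculum"        = 2L,
    "subiculum"           = 3L,
    "CA1"                 = 4L,
    "CA3"                 = 5L,
    "CA4"                 = 6L,
    "GC-ML-DG"            = 7L,
    "HATA"                = 8L,
    "fimbria"             = 9L,
    "molecular layer"     = 10L,
    "hippocampal fissure" = 11L,
    "hippocampal tail"    = 12L
  )
}

#' @rdname hippocampusSubfields
#' @export
analyzedSubfields <- function() {
  setdiff(names(hippocampusSubfields()),
          c("parasubiculum", "HATA", "fimbria"))
}

# ---------------------------------------------------------------------------
# LabelVolume
# ---------------------------------------------------------------------------

#' LabelVolume: a 3-D integer label image with voxel spacing
#'
#' Container for a labelled segmentation volume: a 3-D array of non-negative
#' integer labels (0 = background), per-axis voxel spacing in mm, and a label
#' dictionary mapping region names to label codes. The voxel at array index
#' (i, j, k) has its centre at physical position ((i-1) sx, (j-1) sy, (k-1) sz)
#' mm; no further affine/orientation handling is done.
#'
#' @slot grid 3-D integer array of labels.
#' @slot spacing numeric(3), voxel edge lengths in mm (all > 0).
#' @slot labelMap named integer vector, region name -> label code.
#'
#' @aliases LabelVolume
#' @export
setClass("LabelVolume",
  representation(grid = "array", spacing = "numeric", labelMap = "integer"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  g <- object@grid
  if (any(g < 0)) msg <- c(msg, "labels must be >= 0")
  if (any(g != round(g))) msg <- c(msg, "labels must be integer-valued")
  if (length(object@labelMap) &&
      (is.null(names(object@labelMap)) || anyDuplicated(names(object@labelMap))))
    msg <- c(msg, "labelMap must have unique names")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#'
#' @param grid 3-D numeric or integer array of labels (integer-valued; float
#'   storage that is losslessly castable is accepted).
#' @param spacing voxel spacing in mm; a single value is recycled to 3 axes.
#' @param labelMap named integer vector mapping region names to label codes;
#'   defaults to [hippocampusSubfields()].
#' @return A [LabelVolume-class] object.
#' @examples
#' g <- array(0L, c(4, 4, 4)); g[2:3, 2:3, 2:3] <- 1L
#' LabelVolume(g, spacing = 1, labelMap = c(blob = 1L))
#' @export
LabelVolume <- function(grid, spacing = c(1, 1, 1),
                        labelMap = hippocampusSubfields()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(grid != round(grid)))
    stop("label grid is not integer-valued")
  storage.mode(grid) <- "integer"
  new("LabelVolume", grid = grid, spacing = as.numeric(spacing),
      labelMap = structure(as.integer(labelMap), names = names(labelMap)))
}

#' @describeIn LabelVolume-class label grid accessor
#' @param x,object a `LabelVolume`
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))
#' @rdname LabelVolume-class
#' @export
setMethod("labelGrid", "LabelVolume", function(x) x@grid)

#' @rdname LabelVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname LabelVolume-class
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)

#' @rdname LabelVolume-class
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname LabelVolume-class
#' @export
setMethod("labelMap", "LabelVolume", function(x) x@labelMap)

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@grid)
  labs <- sort(unique(as.vector(object@grid)))
  labs <- labs[labs != 0L]
  cat(sprintf("LabelVolume %d x %d x %d, spacing %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  %d foreground voxel(s), labels present: %s\n",
              sum(object@grid != 0L),
              if (length(labs)) paste(labs, collapse = ", ") else "none"))
  known <- names(object@labelMap)[match(labs, object@labelMap)]
  if (any(is.na(known)))
    cat(sprintf("  warning: %d label value(s) not in labelMap\n", sum(is.na(known))))
})

# ---------------------------------------------------------------------------
# SurfaceMesh
# ---------------------------------------------------------------------------

#' SurfaceMesh: a triangle mesh in mm coordinates
#'
#' Triangle surface mesh with vertices in physical (mm) coordinates and faces
#' as 1-based vertex index triples wound counter-clockwise when seen from
#' outside (outward normals). Meshes produced by [marchingCubes()] are closed
#' 2-manifolds; [checkMesh()] verifies closedness, edge-manifoldness and
#' consistent orientation.
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3), 1-based vertex indices.
#'
#' @aliases SurfaceMesh
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(f) != 3L) msg <- c(msg, "faces must be m x 3")
  if (nrow(f)) {
    if (min(f) < 1L || max(f) > nrow(v))
      msg <- c(msg, "face indices out of range")
    degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
    if (any(degen)) msg <- c(msg, "degenerate faces (repeated vertex index)")
  }
  if (any(!is.finite(v))) msg <- c(msg, "non-finite vertex coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct a SurfaceMesh
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param faces matrix (m x 3) of 1-based vertex index triples.
#' @return A [SurfaceMesh-class] object.
#' @export
SurfaceMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  new("SurfaceMesh", vertices = vertices, faces = faces)
}

#' @rdname SurfaceMesh-class
#' @param x,object a `SurfaceMesh`
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname SurfaceMesh-class
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname SurfaceMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname SurfaceMesh-class
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)

setMethod("show", "SurfaceMesh", function(object) {
  nv <- nrow(object@vertices); nf <- nrow(object@faces)
  ne <- if (nf) nrow(meshEdges(object)) else 0L
  cat(sprintf("SurfaceMesh: %d vertices, %d edges, %d faces (Euler chi = %d)\n",
              nv, ne, nf, nv - ne + nf))
})

# ---------------------------------------------------------------------------
# CurvatureField
# ---------------------------------------------------------------------------

#' CurvatureField: per-vertex curvature indices of a surface
#'
#' Holds per-vertex discrete Gaussian curvature K, mean curvature H, principal
#' curvatures cmax >= cmin, and the ratio of principal curvatures
#' RPC = max(|cmax|, |cmin|) / min(|cmax|, |cmin|) >= 1. `mode` records whether
#' the raw formulas were used (`as_written`: K in radians, H in mm radians) or
#' the dimensionally consistent area-normalized estimators (`area_normalized`:
#' K in 1/mm^2, H in 1/mm). `clampCount` is the number of vertices whose
#' discriminant H^2 - K was negative and clamped to zero before taking the
#' square root.
#'
#' @slot K,H,cmax,cmin,rpc numeric vectors, one value per mesh vertex.
#' @slot mode `"as_written"` or `"area_normalized"`.
#' @slot clampCount integer, vertices with clamped discriminant.
#'
#' @aliases CurvatureField
#' @export
setClass("CurvatureField",
  representation(K = "numeric", H = "numeric", cmax = "numeric",
                 cmin = "numeric", rpc = "numeric", mode = "character",
                 clampCount = "integer"))

setValidity("CurvatureField", function(object) {
  msg <- character()
  n <- length(object@K)
  if (length(object@H) != n || length(object@cmax) != n ||
      length(object@cmin) != n || length(object@rpc) != n)
    msg <- c(msg, "K, H, cmax, cmin, rpc must have equal length")
  if (!object@mode %in% c("as_written", "area_normalized"))
    msg <- c(msg, "mode must be 'as_written' or 'area_normalized'")
  if (any(object@cmax < object@cmin))
    msg <- c(msg, "cmax must be >= cmin at every vertex")
  if (any(object@rpc < 1 - 1e-12))
    msg <- c(msg, "rpc must be >= 1 everywhere")
  if (object@clampCount < 0L || object@clampCount > n)
    msg <- c(msg, "clampCount out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CurvatureField", function(object) {
  cat(sprintf("CurvatureField (%s): %d vertices, %d clamped discriminant(s)\n",
              object@mode, length(object@K), object@clampCount))
  cat(sprintf("  median K = %.4g, median H = %.4g, median RPC = %.4g\n",
              stats::median(object@K), stats::median(object@H),
              stats::median(object@rpc)))
})

#' @rdname CurvatureField-class
#' @param x a `CurvatureField`
#' @export
setGeneric("curvatureValues", function(x) standardGeneric("curvatureValues"))

#' @describeIn CurvatureField-class all per-vertex fields as a data.frame with
#'   columns vertex_id, K, H, cmax, cmin, rpc
#' @export
setMethod("curvatureValues", "CurvatureField", function(x) {
  data.frame(vertex_id = seq_along(x@K), K = x@K, H = x@H,
             cmax = x@cmax, cmin = x@cmin, rpc = x@rpc)
})

#' @rdname CurvatureField-class
#' @export
setGeneric("clampCount", function(x) standardGeneric("clampCount"))
#' @rdname CurvatureField-class
#' @export
setMethod("clampCount", "CurvatureField", function(x) x@clampCount)

# ---------------------------------------------------------------------------
# RigidTransform
# ---------------------------------------------------------------------------

#' RigidTransform: a rotation + translation with registration residual
#'
#' Result of rigid point-set registration: `y = R x + t`. The rotation is a
#' proper orthonormal matrix (det +1); `rms` is the final root-mean-square
#' nearest-neighbour distance achieved.
#'
#' @slot rotation 3 x 3 rotation matrix.
#' @slot translation numeric(3).
#' @slot rms final RMS registration residual (mm).
#' @slot iterations number of ICP iterations performed.
#' @slot rmsHistory RMS after each iteration (non-increasing).
#'
#' @aliases RigidTransform
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 rms = "numeric", iterations = "integer",
                 rmsHistory = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation is not orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must have determinant +1")
  }
  if (length(object@translation) != 3L)
    msg <- c(msg, "translation must be length 3")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%s), RMS %.3g (%d iter)\n",
              ang * 180 / pi,
              paste(sprintf("%.3f", object@translation), collapse = ", "),
              object@rms, object@iterations))
})

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param points n x 3 matrix of coordinates.
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(transform, points) {
  stopifnot(is(transform, "RigidTransform"))
  points <- as.matrix(points)
  sweep(points %*% t(transform@rotation), 2L, transform@translation, "+")
}
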