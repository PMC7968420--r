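# Surface reconstruction and mesh utilities.
#
# Surfaces are extracted from binary voxel masks at iso-level 0.5 using a
# tetrahedral decomposition of each grid cell (the marching-tetrahedra variant
# of marching cubes): every cell between 8 voxel centres is split into 6
# tetrahedra around the main diagonal, and each tetrahedron contributes 0-2
# triangles with vertices at cut-edge midpoints. Unlike the classic 256-case
# cube table, this decomposition has no ambiguous configurations, so the
# output is always a closed, edge-manifold, consistently oriented surface --
# which the downstream curvature operators require.

#' Extract a binary region mask from a label volume
#'
#' @param vol a [LabelVolume-class].
#' @param region a region name in `labelMap(vol)`, a character vector of such
#'   names (union), or `"whole hippocampus"` / `"whole"` for the union of all
#'   mapped labels.
#' @return 3-D integer array with 1 inside the region and 0 elsewhere.
#' @examples
#' g <- array(0L, c(5, 5, 5)); g[2:4, 2:4, 2:4] <- 4L
#' vol <- LabelVolume(g, spacing = 1)
#' sum(extractMask(vol, "CA1"))
#' @export
extractMask <- function(vol, region) {
  stopifnot(is(vol, "LabelVolume"))
  lm <- labelMap(vol)
  if (length(region) == 1L && region %in% c("whole", "whole hippocampus")) {
    labs <- unname(lm)
  } else {
    unknown <- setdiff(region, names(lm))
    if (length(unknown))
      stop("unknown region name(s): ", paste(unknown, collapse = ", "))
    labs <- unname(lm[region])
  }
  mask <- array(as.integer(labelGrid(vol) %in% labs), dim(labelGrid(vol)))
  if (!any(mask == 1L))
    stop("region '", paste(region, collapse = "+"), "' has zero voxels")
  mask
}

# --- marching-tetrahedra case table ---------------------------------------
# Cube corners (0/1 offsets), 1-based ids 1..8; six tetrahedra share the main
# diagonal corner1-corner7 so that face diagonals of adjacent cells agree.
.mtCache <- new.env(parent = emptyenv())

.mtTable <- function() {
  if (!is.null(.mtCache$tbl)) return(.mtCache$tbl)
  C8 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
              c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- list(c(1L, 2L, 3L, 7L), c(1L, 3L, 4L, 7L), c(1L, 4L, 8L, 7L),
               c(1L, 8L, 5L, 7L), c(1L, 5L, 6L, 7L), c(1L, 6L, 2L, 7L))
  cases <- vector("list", 6L)
  for (t in seq_len(6L)) {
    Ct <- C8[tets[[t]], , drop = FALSE]
    percode <- vector("list", 14L)
    for (code in 1:14) {
      ins <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
      out <- setdiff(1:4, ins)
      tris <- if (length(ins) == 1L) {
        list(cbind(rep(ins, 3L), out))
      } else if (length(ins) == 3L) {
        list(cbind(rep(out, 3L), ins))
      } else {
        i1 <- ins[1]; i2 <- ins[2]; o1 <- out[1]; o2 <- out[2]
        list(rbind(c(i1, o1), c(i1, o2), c(i2, o2)),
             rbind(c(i1, o1), c(i2, o2), c(i2, o1)))
      }
      # orient: triangle normal must point away from the inside corners
      cin <- colMeans(Ct[ins, , drop = FALSE])
      tris <- lapply(tris, function(tr) {
        p <- (Ct[tr[, 1], , drop = FALSE] + Ct[tr[, 2], , drop = FALSE]) / 2
        e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
        nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
                 e1[3] * e2[1] - e1[1] * e2[3],
                 e1[1] * e2[2] - e1[2] * e2[1])
        s <- sum(nrm * (colMeans(p) - cin))
        stopifnot(abs(s) > 1e-12)
        if (s < 0) tr[c(1L, 3L, 2L), , drop = FALSE] else tr
      })
      percode[[code]] <- tris
    }
    cases[[t]] <- percode
  }
  .mtCache$tbl <- list(tets = tets, cases = cases)
  .mtCache$tbl
}

#' Reconstruct a closed triangle surface from a binary mask
#'
#' Extracts the 0.5 iso-surface separating foreground from background voxels,
#' placing triangle vertices at midpoints between adjacent voxel centres.
#' Voxel index (i, j, k) maps to physical coordinates
#' ((i-1) sx, (j-1) sy, (k-1) sz) mm. Only the largest connected surface
#' component is retained. The result always passes [checkMesh()].
#'
#' @param mask binary 3-D array (or a [LabelVolume-class], in which case all
#'   non-zero voxels are foreground). Foreground must not touch the array
#'   boundary: pad with at least one background voxel.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param keepLargest retain only the largest connected component
#'   (default `TRUE`).
#' @return A [SurfaceMesh-class] with outward-oriented faces.
#' @examples
#' m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
#' mesh <- marchingCubes(m, spacing = 1)
#' checkMesh(mesh)
#' @export
marchingCubes <- function(mask, spacing = c(1, 1, 1), keepLargest = TRUE) {
  if (is(mask, "LabelVolume")) {
    spacing <- spacing(mask)
    mask <- labelGrid(mask) != 0L
  }
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3-D array")
  m <- array(as.integer(mask != 0), d)
  if (!any(m == 1L)) stop("empty mask: no foreground voxels")
  if (any(m[c(1L, d[1]), , ] == 1L) || any(m[, c(1L, d[2]), ] == 1L) ||
      any(m[, , c(1L, d[3])] == 1L))
    stop("mask touches the volume boundary; pad with >= 1 background voxel")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))

  nx <- d[1]; ny <- d[2]; nz <- d[3]
  np <- as.double(nx) * ny * nz
  if (np > 9e7) stop("grid too large for exact edge keying")
  corner <- list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
                 c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  ix <- seq_len(nx - 1L); iy <- seq_len(ny - 1L); iz <- seq_len(nz - 1L)
  cv <- lapply(corner, function(o) m[ix + o[1], iy + o[2], iz + o[3]])
  s <- Reduce(`+`, cv)
  mixed <- which(s > 0L & s < 8L)
  ncx <- nx - 1L; ncy <- ny - 1L
  ci <- ((mixed - 1L) %% ncx) + 1L
  cj <- (((mixed - 1L) %/% ncx) %% ncy) + 1L
  ck <- ((mixed - 1L) %/% (ncx * ncy)) + 1L
  orig <- as.double(ci) + (as.double(cj) - 1) * nx + (as.double(ck) - 1) * nx * ny
  offs <- vapply(corner, function(o) o[1] + o[2] * as.double(nx) +
                   o[3] * as.double(nx) * ny, numeric(1))
  V8 <- vapply(seq_len(8L), function(c8) cv[[c8]][mixed],
               integer(length(mixed)))
  if (length(mixed) == 1L) V8 <- matrix(V8, nrow = 1L)

  tbl <- .mtTable()
  batches <- list(); nb <- 0L
  for (t in seq_len(6L)) {
    tc <- tbl$tets[[t]]
    code <- V8[, tc[1]] + 2L * V8[, tc[2]] + 4L * V8[, tc[3]] + 8L * V8[, tc[4]]
    for (cd in 1:14) {
      idx <- which(code == cd)
      if (!length(idx)) next
      for (tr in tbl$cases[[t]][[cd]]) {
        A <- matrix(0, length(idx), 3L); B <- A
        for (r in 1:3) {
          A[, r] <- orig[idx] + offs[tc[tr[r, 1]]]
          B[, r] <- orig[idx] + offs[tc[tr[r, 2]]]
        }
        nb <- nb + 1L
        batches[[nb]] <- list(A = A, B = B)
      }
    }
  }
  if (!nb) stop("no interface cells found")
  A <- do.call(rbind, lapply(batches, `[[`, "A"))
  B <- do.call(rbind, lapply(batches, `[[`, "B"))
  kmin <- pmin(A, B); kmax <- pmax(A, B)
  key <- (kmin - 1) * np + kmax
  ukey <- sort(unique(as.vector(key)))
  fmat <- matrix(match(as.vector(key), ukey), ncol = 3L)
  pmax_ <- ((ukey - 1) %% np) + 1
  pmin_ <- (ukey - 1) %/% np + 1
  coordOf <- function(p) {
    i <- ((p - 1) %% nx)
    j <- ((p - 1) %/% nx) %% ny
    k <- (p - 1) %/% (as.double(nx) * ny)
    cbind(i * spacing[1], j * spacing[2], k * spacing[3])
  }
  verts <- (coordOf(pmin_) + coordOf(pmax_)) / 2
  mesh <- SurfaceMesh(verts, fmat)
  if (keepLargest) mesh <- largestComponent(mesh)
  mesh
}

#' Keep only the largest connected component of a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return a [SurfaceMesh-class] restricted to the largest vertex-connected
#'   component, vertices re-indexed.
#' @export
largestComponent <- function(mesh) {
  f <- faces(mesh)
  e <- meshEdges(mesh)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices(mesh)) - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(mesh)
  big <- which.max(comp$csize)
  keepV <- which(comp$membership == big)
  keepF <- f[, 1] %in% keepV  # faces are whole within a component
  newid <- integer(nrow(vertices(mesh)))
  newid[keepV] <- seq_along(keepV)
  SurfaceMesh(vertices(mesh)[keepV, , drop = FALSE],
              matrix(newid[f[keepF, ]], ncol = 3L))
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a [SurfaceMesh-class].
#' @return integer matrix (n_edges x 2), each row `i < j`.
#' @export
meshEdges <- function(mesh) {
  f <- faces(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Validate mesh topology and orientation
#'
#' A watertight surface suitable for curvature analysis must be edge-manifold
#' (every undirected edge shared by exactly two faces), closed (no boundary
#' edges) and consistently oriented (each directed half-edge used exactly
#' once). For a single genus-0 component the Euler characteristic
#' V - E + F equals 2.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return list with logical elements `closed`, `manifold`, `oriented`, and
#'   integer `eulerChar`.
#' @export
checkMesh <- function(mesh) {
  f <- faces(mesh)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ue <- cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  ukey <- paste(ue[, 1], ue[, 2])
  cnt <- table(ukey)
  manifold <- all(cnt <= 2L)
  closed <- all(cnt == 2L)
  dkey <- paste(he[, 1], he[, 2])
  oriented <- !anyDuplicated(dkey)
  nE <- length(cnt)
  list(closed = closed, manifold = manifold, oriented = oriented,
       eulerChar = nrow(vertices(mesh)) - nE + nrow(f))
}

#' Laplacian (umbrella) mesh smoothing
#'
#' Each iteration moves every vertex toward the unweighted mean of its 1-ring
#' neighbours by a fraction `step`; connectivity is never altered. Pure
#' umbrella smoothing shrinks closed surfaces without bound, which would bias
#' area and curvature features by an amount that depends on mesh resolution,
#' so by default each pass ends with a uniform rescale about the centroid
#' restoring the enclosed volume (`volumeConstraint = TRUE`, the convention of
#' mainstream mesh-processing toolkits); staircase noise is still removed, but
#' the surface no longer collapses. Set `volumeConstraint = FALSE` for the
#' uncompensated operator, or `taubin = TRUE` for the Taubin lambda/mu
#' band-pass variant (its own shrinkage compensation; the volume constraint is
#' then not applied).
#'
#' @param mesh a [SurfaceMesh-class].
#' @param iterations number of smoothing passes (default 50).
#' @param step relaxation factor in (0, 1] (default 0.5).
#' @param taubin logical; alternate `step` with a compensating negative step
#'   (mu = -step - 0.03) after each pass.
#' @param volumeConstraint rescale to preserve enclosed volume after each
#'   pass (default `TRUE`; requires a closed mesh, silently skipped
#'   otherwise).
#' @return smoothed [SurfaceMesh-class] with identical faces.
#' @export
laplacianSmooth <- function(mesh, iterations = 50L, step = 0.5,
                            taubin = FALSE, volumeConstraint = !taubin) {
  if (iterations < 0) stop("iterations must be >= 0")
  stopifnot(step > 0, step <= 1)
  if (iterations == 0L) return(mesh)
  V <- vertices(mesh)
  f <- faces(mesh)
  e <- meshEdges(mesh)
  n <- nrow(V)
  Adj <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                              x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(Adj)
  if (any(deg == 0)) stop("isolated vertex: cannot smooth")
  W <- Adj / deg
  mu <- -step - 0.03
  if (volumeConstraint && !checkMesh(mesh)$closed) volumeConstraint <- FALSE
  v0 <- if (volumeConstraint) abs(.signedVolume(V, f)) else NA_real_
  for (it in seq_len(iterations)) {
    V <- V + step * (as.matrix(W %*% V) - V)
    if (taubin) V <- V + mu * (as.matrix(W %*% V) - V)
    if (volumeConstraint) {
      vi <- abs(.signedVolume(V, f))
      if (vi > 0) {
        ctr <- colMeans(V)
        V <- sweep(sweep(V, 2L, ctr) * (v0 / vi)^(1 / 3), 2L, ctr, "+")
      }
    }
  }
  SurfaceMesh(V, f)
}

#' Surface area and enclosed volume of a triangle mesh
#'
#' `meshArea` sums triangle areas. `meshVolume` sums signed tetrahedron
#' volumes against the origin (divergence theorem) and returns the absolute
#' value, so the result does not depend on global winding direction; it
#' requires a closed mesh.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return area in mm^2, volume in mm^3.
#' @examples
#' sph <- icosphereMesh(10, subdivisions = 3)
#' meshArea(sph) / (4 * pi * 100)   # ~ 1
#' @export
meshArea <- function(mesh) {
  V <- vertices(mesh); f <- faces(mesh)
  a <- V[f[, 2], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  b <- V[f[, 3], , drop = FALSE] - V[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' @rdname meshArea
#' @export
meshVolume <- function(mesh) {
  chk <- checkMesh(mesh)
  if (!chk$closed) stop("mesh is not closed: enclosed volume undefined")
  V <- vertices(mesh); f <- faces(mesh)
  p1 <- V[f[, 1], , drop = FALSE]
  p2 <- V[f[, 2], , drop = FALSE]
  p3 <- V[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

#' Export a mesh as ASCII PLY or OFF
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file path.
#' @param scalars optional data.frame of per-vertex scalar attributes written
#'   as extra float properties (PLY only).
#' @return `path`, invisibly.
#' @export
writeMeshPLY <- function(mesh, path, scalars = NULL) {
  V <- vertices(mesh); f <- faces(mesh)
  props <- c("property float x", "property float y", "property float z")
  vtab <- V
  if (!is.null(scalars)) {
    stopifnot(nrow(scalars) == nrow(V))
    props <- c(props, paste("property float", names(scalars)))
    vtab <- cbind(V, as.matrix(scalars))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(V)), props,
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(vtab, trim = TRUE, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMeshPLY
#' @export
writeMeshOFF <- function(mesh, path) {
  V <- vertices(mesh); f <- faces(mesh)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("OFF", paste(nrow(V), nrow(f), 0L)), con)
  utils::write.table(format(V, trim = TRUE, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
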