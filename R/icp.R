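# Rigid point-set registration (iterative closest point) and nearest-vertex
# label transfer between registered surfaces.

# squared cross-distance matrix, chunked over rows of a to bound memory
.nearestNeighbour <- function(a, b, chunk = 2048L) {
  na <- nrow(a)
  idx <- integer(na); d2 <- numeric(na)
  bb <- rowSums(b^2)
  for (s in seq(1L, na, by = chunk)) {
    e <- min(s + chunk - 1L, na)
    blk <- a[s:e, , drop = FALSE]
    D <- outer(rowSums(blk^2), bb, "+") - 2 * blk %*% t(b)
    j <- max.col(-D, ties.method = "first")
    idx[s:e] <- j
    # recompute the matched distances exactly: the expansion above suffers
    # catastrophic cancellation near zero
    d2[s:e] <- rowSums((blk - b[j, , drop = FALSE])^2)
  }
  list(index = idx, dist2 = d2)
}

# closed-form rigid fit (Kabsch/SVD): find R, t minimizing ||R a + t - b||
.kabsch <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  H <- crossprod(sweep(a, 2L, ca), sweep(b, 2L, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cb - R %*% ca))
}

.checkPointSet <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop(what, " must be an n x 3 matrix")
  if (nrow(p) < 3L) stop(what, " must contain at least 3 points")
  s <- svd(sweep(p, 2L, colMeans(p)))$d
  if (s[2] < 1e-9 * max(s[1], 1))
    stop(what, " is degenerate (collinear points)")
  p
}

#' Rigid registration by iterative closest point (ICP)
#'
#' Point-to-point ICP: alternate nearest-neighbour correspondence from source
#' to target with a closed-form (SVD) rigid update, until the RMS
#' nearest-neighbour distance changes by less than `tol` or `maxIter` is
#' reached. The per-iteration RMS sequence is non-increasing.
#'
#' @param source,target n x 3 point matrices (or [SurfaceMesh-class] objects,
#'   whose vertices are used). Need >= 3 non-collinear points each.
#' @param maxIter maximum iterations (default 100).
#' @param tol RMS-change convergence tolerance (default 1e-6).
#' @return A [RigidTransform-class] mapping source onto target; its
#'   `rmsHistory` slot holds the RMS after each iteration.
#' @examples
#' cloud <- vertices(icosphereMesh(5, 1))
#' icpRegister(cloud, cloud)  # identity, RMS 0
#' @export
icpRegister <- function(source, target, maxIter = 100L, tol = 1e-6) {
  if (is(source, "SurfaceMesh")) source <- vertices(source)
  if (is(target, "SurfaceMesh")) target <- vertices(target)
  src <- .checkPointSet(source, "source")
  tgt <- .checkPointSet(target, "target")
  # initialize by centroid alignment: point-to-point ICP from a raw identity
  # start is easily trapped by a large translation offset
  R <- diag(3); tr <- colMeans(tgt) - colMeans(src)
  cur <- sweep(src, 2L, tr, "+")
  hist <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    nn <- .nearestNeighbour(cur, tgt)
    fit <- .kabsch(cur, tgt[nn$index, , drop = FALSE])
    cur <- sweep(cur %*% t(fit$R), 2L, fit$t, "+")
    R <- fit$R %*% R
    tr <- as.numeric(fit$R %*% tr + fit$t)
    rms <- sqrt(mean(.nearestNeighbour(cur, tgt)$dist2))
    hist <- c(hist, rms)
    if (abs(prev - rms) < tol) break
    prev <- rms
  }
  new("RigidTransform", rotation = R, translation = tr,
      rms = hist[length(hist)], iterations = length(hist),
      rmsHistory = hist)
}

#' Transfer subfield labels onto a whole-structure surface
#'
#' Assigns every vertex of the whole surface the name of its nearest vertex
#' among the (already registered) subfield surfaces. Distance ties are broken
#' deterministically: within a subfield the lowest vertex index wins, across
#' subfields the lexicographically first region name wins.
#'
#' @param whole a [SurfaceMesh-class] (or n x 3 point matrix).
#' @param subfields named list of [SurfaceMesh-class] objects or point
#'   matrices, one per region, registered to the whole surface.
#' @return character vector of region names, one per whole-surface vertex.
#' @export
transferLabels <- function(whole, subfields) {
  if (is(whole, "SurfaceMesh")) whole <- vertices(whole)
  whole <- as.matrix(whole)
  if (!length(subfields)) stop("empty subfield set")
  if (is.null(names(subfields)) || any(!nzchar(names(subfields))))
    stop("subfields must be a named list")
  best <- rep(Inf, nrow(whole))
  lab <- rep(NA_character_, nrow(whole))
  for (nm in sort(names(subfields))) {
    p <- subfields[[nm]]
    if (is(p, "SurfaceMesh")) p <- vertices(p)
    nn <- .nearestNeighbour(whole, as.matrix(p))
    better <- nn$dist2 < best   # strict: earlier name keeps ties
    lab[better] <- nm
    best[better] <- nn$dist2[better]
  }
  lab
}
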