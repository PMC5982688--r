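# Internal numerical helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so results are reproducible given their seed argument and
# never perturb user code.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# round half away from zero (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

# Rotation about the x axis by angle a (radians), mapping the gravity frame
# (x right, y down, z forward-horizontal) into a camera pitched down by a.
rotX <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

rotZ <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Signed distances of points (n x 3) to a PlaneModel.
planeDistance <- function(plane, pts) {
  drop(pts %*% plane@normal) + plane@offset
}

# Mean distance of every point to its k nearest neighbors; exact, via
# the compiled voxel-hash search.
knnMeanDistance <- function(pts, k) {
  storage.mode(pts) <- "double"
  .knnMeanDistanceCpp(pts, as.integer(k))
}

# Nearest-neighbor distance from each query point to a reference set.
nearestDistance <- function(query, ref, block = 512L) {
  n <- nrow(query)
  sqr <- rowSums(ref^2)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    idx <- i0:i1
    d2 <- outer(rowSums(query[idx, , drop = FALSE]^2), sqr, "+") -
      2 * tcrossprod(query[idx, , drop = FALSE], ref)
    out[idx] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

# Exact single-linkage Euclidean components with linkage radius r, via
# the compiled voxel-hash BFS. Labels are numbered by first appearance.
euclideanComponents <- function(pts, radius) {
  if (nrow(pts) == 0L) return(integer(0))
  storage.mode(pts) <- "double"
  .euclideanComponentsCpp(pts, radius)
}

# Shoelace area of a closed polygon given as an m x 2 matrix of vertices.
polygonArea <- function(v) {
  m <- nrow(v)
  if (m < 3) return(0)
  j <- c(2:m, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygonPerimeter <- function(v) {
  m <- nrow(v)
  if (m < 2) return(0)
  j <- c(2:m, 1L)
  sum(sqrt(rowSums((v[j, , drop = FALSE] - v)^2)))
}

# Which of the query points (m x 2) lie inside or on a convex polygon
# (vertices k x 2, any orientation). Exact half-plane test.
pointsInConvexPolygon <- function(query, poly, eps = 1e-9) {
  k <- nrow(poly)
  if (k == 1)
    return(abs(query[, 1] - poly[1, 1]) < eps &
           abs(query[, 2] - poly[1, 2]) < eps)
  a <- polygonSignedArea(poly)
  if (a < 0) poly <- poly[k:1, , drop = FALSE]   # force counter-clockwise
  inside <- rep(TRUE, nrow(query))
  j <- c(2:k, 1L)
  for (e in seq_len(k)) {
    ex <- poly[j[e], 1] - poly[e, 1]
    ey <- poly[j[e], 2] - poly[e, 2]
    cr <- ex * (query[, 2] - poly[e, 2]) - ey * (query[, 1] - poly[e, 1])
    if (k == 2) inside <- inside & abs(cr) < eps else
      inside <- inside & cr >= -eps
  }
  inside
}

polygonSignedArea <- function(v) {
  m <- nrow(v)
  j <- c(2:m, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

stopDegenerate <- function(msg) stop(msg, call. = FALSE)
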