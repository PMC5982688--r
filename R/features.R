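# The 19-component shape descriptor f1..f19 computed from a segmented
# person cloud: frontal-mesh volume and surface, point counts, scatter
# matrix eigenvalues with the derived sphericity/flatness/linearity ratios,
# statistical moments of the centered point distances, sensor distance,
# silhouette contour and convex-hull measures, and gender.

#' Eigenvalues of the point-cloud scatter matrix
#'
#' Computes the eigenvalues of the 3 x 3 scatter matrix
#' \eqn{S = \sum_j (p_j - \bar p)(p_j - \bar p)^T} (unnormalized sum, in
#' m^2 times point count), sorted in descending order. The eigenvalues are
#' invariant under rigid transformations of the cloud.
#'
#' @param x a [PointCloud-class] or an n x 3 coordinate matrix with at
#'   least 3 valid points.
#' @return numeric 3-vector (lambda1 >= lambda2 >= lambda3 >= 0).
#' @export
scatterEigenvalues <- function(x) {
  pts <- if (is(x, "PointCloud")) validCoords(x) else as.matrix(x)
  if (nrow(pts) < 3)
    stopDegenerate("scatter matrix needs at least 3 points")
  s <- crossprod(sweep(pts, 2, colMeans(pts)))
  ev <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  pmax(ev, 0)
}

#' Eigenvalue shape ratios: sphericity, flatness, linearity
#'
#' sphericity = lambda3 / sum(lambda),
#' flatness = 2 (lambda2 - lambda3) / sum(lambda),
#' linearity = (lambda1 - lambda2) / sum(lambda).
#' All three lie in [0, 1]; an isotropic cloud gives (1/3, 0, 0), a
#' perfect line (0, 0, 1).
#'
#' @param lambda1 largest eigenvalue, or a 3-vector of all three.
#' @param lambda2,lambda3 remaining eigenvalues when given separately.
#' @return named numeric 3-vector (sphericity, flatness, linearity).
#' @examples
#' eigenShapeFeatures(4.7e3, 3.9e2, 7.1e1)
#' @export
eigenShapeFeatures <- function(lambda1, lambda2 = NULL, lambda3 = NULL) {
  l <- if (is.null(lambda2)) lambda1 else c(lambda1, lambda2, lambda3)
  stopifnot(length(l) == 3)
  if (any(diff(l) > 1e-9 * max(l, 1)) || any(l < 0))
    stop("eigenvalues must satisfy lambda1 >= lambda2 >= lambda3 >= 0",
         call. = FALSE)
  s <- sum(l)
  if (s <= 0) stopDegenerate("eigenvalue sum must be positive")
  c(sphericity = l[3] / s,
    flatness = 2 * (l[2] - l[3]) / s,
    linearity = (l[1] - l[2]) / s)
}

#' Triangulate the frontal surface of an organized person cloud
#'
#' Builds two triangles per 2 x 2 pixel quad whose four points are valid
#' and whose depth discontinuities stay below \code{jumpThreshold} (to
#' avoid bridging jumping-edge artifacts). Degenerate (zero-area)
#' triangles are skipped.
#'
#' @param person organized [PointCloud-class].
#' @param jumpThreshold maximal depth difference between neighboring
#'   pixels in a quad, meters.
#' @return a [FrontalMesh-class].
#' @export
computeFrontalMesh <- function(person, jumpThreshold = 0.05) {
  if (!isOrganized(person))
    stop("frontal mesh requires an organized cloud", call. = FALSE)
  w <- person@width; h <- person@height
  co <- person@coords
  valid <- rowSums(is.finite(co)) == 3L
  idx <- function(u, v) v * w + u + 1L            # 0-based pixel
  u <- rep(0:(w - 2L), times = h - 1L)
  v <- rep(0:(h - 2L), each = w - 1L)
  a <- idx(u, v); b <- idx(u, v + 1L)
  c_ <- idx(u + 1L, v); d <- idx(u + 1L, v + 1L)
  ok <- valid[a] & valid[b] & valid[c_] & valid[d]
  z <- co[, 3]
  jump <- pmax(abs(z[a] - z[b]), abs(z[a] - z[c_]), abs(z[d] - z[b]),
               abs(z[d] - z[c_]), abs(z[b] - z[c_]))
  ok <- ok & jump <= jumpThreshold
  tri <- rbind(cbind(a[ok], b[ok], c_[ok]),
               cbind(c_[ok], b[ok], d[ok]))
  if (nrow(tri) == 0)
    return(new("FrontalMesh"))
  # drop zero-area triangles
  e1 <- co[tri[, 2], , drop = FALSE] - co[tri[, 1], , drop = FALSE]
  e2 <- co[tri[, 3], , drop = FALSE] - co[tri[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  tri <- tri[area2 > 1e-14, , drop = FALSE]
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(co))
  remap[used] <- seq_along(used)
  tri2 <- matrix(remap[tri], ncol = 3)
  storage.mode(tri2) <- "integer"
  new("FrontalMesh", vertices = co[used, , drop = FALSE],
      triangles = tri2)
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas by the cross-product formula; an empty mesh has
#' area 0.
#'
#' @param mesh a [FrontalMesh-class].
#' @return area in m^2.
#' @export
computeSurface <- function(mesh) {
  if (nrow(mesh@triangles) == 0) return(0)
  v <- mesh@vertices
  t1 <- mesh@triangles
  e1 <- v[t1[, 2], , drop = FALSE] - v[t1[, 1], , drop = FALSE]
  e2 <- v[t1[, 3], , drop = FALSE] - v[t1[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Volume between the frontal surface and a back plane
#'
#' The invisible back of the person is modeled by a single plane (the
#' stretcher surface). The volume is the sum of triangular prisms: for each
#' mesh triangle, its area projected onto the plane times the mean signed
#' distance of its vertices to the plane. The result is clamped at >= 0.
#'
#' @param mesh a [FrontalMesh-class] whose vertices lie on the sensor side
#'   of the plane.
#' @param backPlane a [PlaneModel-class].
#' @return volume in m^3.
#' @export
computeVolume <- function(mesh, backPlane) {
  if (nrow(mesh@triangles) == 0) return(0)
  v <- mesh@vertices
  n <- backPlane@normal
  dist <- planeDistance(backPlane, v)
  if (mean(dist) < 0) dist <- -dist             # orient toward the sensor
  q <- v - outer(planeDistance(backPlane, v), n)  # orthogonal projection
  t1 <- mesh@triangles
  e1 <- q[t1[, 2], , drop = FALSE] - q[t1[, 1], , drop = FALSE]
  e2 <- q[t1[, 3], , drop = FALSE] - q[t1[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  aproj <- sqrt(rowSums(cr^2)) / 2
  dmean <- (dist[t1[, 1]] + dist[t1[, 2]] + dist[t1[, 3]]) / 3
  max(sum(aproj * dmean), 0)
}

#' Statistical moment features of the centered point distances
#'
#' compactness (f11) is the root-mean-square distance to the centroid;
#' kurtosis (f12) the plain sum of distances to the centroid; alternative
#' compactness (f13) the mean fourth power of the distances divided by the
#' flatness ratio f9 (unavailable when flatness is zero or not supplied).
#' All three are invariant under rigid transformations.
#'
#' @param x a [PointCloud-class] or n x 3 coordinate matrix with at least
#'   2 valid points.
#' @param flatness the f9 flatness ratio used by f13; NULL marks f13
#'   unavailable.
#' @return named numeric 3-vector (compactness, kurtosis,
#'   alt_compactness); f13 is NA when unavailable.
#' @export
statisticalFeatures <- function(x, flatness = NULL) {
  pts <- if (is(x, "PointCloud")) validCoords(x) else as.matrix(x)
  n <- nrow(pts)
  if (n < 2)
    stopDegenerate("statistical features need at least 2 points")
  r <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
  alt <- if (!is.null(flatness) && is.finite(flatness) && flatness > 0)
    mean(r^4) / flatness else NA_real_
  c(compactness = sqrt(mean(r^2)), kurtosis = sum(r),
    alt_compactness = alt)
}

#' Distance from the sensor to the person
#'
#' Euclidean distance from the sensor origin to the centroid of the person
#' points (default), or to the nearest person point.
#'
#' @param person a non-empty [PointCloud-class].
#' @param method "centroid" or "nearest".
#' @return meters.
#' @export
distanceToPerson <- function(person, method = c("centroid", "nearest")) {
  method <- match.arg(method)
  pts <- validCoords(person)
  if (nrow(pts) == 0)
    stopDegenerate("cannot compute distance to an empty cloud")
  if (method == "centroid") sqrt(sum(colMeans(pts)^2))
  else min(sqrt(rowSums(pts^2)))
}

# Moore-neighbor boundary tracing (8-connected) of the largest blob in a
# binary mask given as mask[x + 1, y + 1]. Returns the border polygon
# through pixel centers (m x 2, 0-based pixel coordinates) in tracing
# order. Jacob's stopping criterion.
traceBoundary <- function(mask) {
  w <- nrow(mask); h <- ncol(mask)
  at <- function(x, y) x >= 0 && x < w && y >= 0 && y < h &&
    mask[x + 1, y + 1] > 0
  start <- NULL
  for (y in 0:(h - 1)) {
    xs <- which(mask[, y + 1] > 0)
    if (length(xs)) { start <- c(xs[1] - 1L, y); break }
  }
  if (is.null(start)) return(matrix(numeric(0), 0, 2))
  # clockwise Moore neighborhood starting west
  nb <- matrix(c(-1, 0, -1, -1, 0, -1, 1, -1, 1, 0, 1, 1, 0, 1, -1, 1),
               ncol = 2, byrow = TRUE)
  contour <- matrix(start, 1, 2)
  searchDir <- 0L                        # begin looking west of the start
  cur <- start
  entryDir <- -1L
  repeat {
    found <- FALSE
    for (k in 0:7) {
      dir <- (searchDir + k) %% 8L
      nx <- cur[1] + nb[dir + 1, 1]; ny <- cur[2] + nb[dir + 1, 2]
      if (at(nx, ny)) {
        if (entryDir < 0L) entryDir <- dir
        else if (all(cur == start) && dir == entryDir &&
                 nrow(contour) > 1) return(contour[-nrow(contour), ,
                                                   drop = FALSE])
        cur <- c(nx, ny)
        contour <- rbind(contour, cur)
        searchDir <- (dir + 5L) %% 8L    # one step past the backtrack
        found <- TRUE
        break
      }
    }
    if (!found) return(contour)          # isolated pixel
    if (nrow(contour) > 4L * (w * h)) return(contour)   # safety
  }
}

#' Silhouette contour and convex-hull features
#'
#' Rasterizes the person cloud into a binary mask on the sensor grid (the
#' organized grid when available, otherwise by pinhole projection with the
#' given intrinsics), keeps the largest 8-connected blob, fills holes, and
#' traces the outer border polygon through pixel centers. Contour length is
#' the closed polygon perimeter (pixels); contour area is the enclosed
#' pixel count; hull length/area are the perimeter of the convex hull of
#' the contour vertices and the count of pixel centers inside or on it.
#'
#' @param person a [PointCloud-class].
#' @param intr [Intrinsics-class] with width/height; required when the
#'   cloud is not organized.
#' @return named numeric 4-vector (contour_length, contour_area,
#'   hull_length, hull_area).
#' @export
silhouetteFeatures <- function(person, intr = NULL) {
  if (isOrganized(person)) {
    w <- person@width; h <- person@height
    mask <- matrix(0L, w, h)
    vm <- validMask(person)
    if (any(vm)) {
      pix <- which(vm) - 1L
      mask[cbind(pix %% w + 1L, pix %/% w + 1L)] <- 1L
    }
  } else {
    if (is.null(intr) || intr@width <= 0L || intr@height <= 0L)
      stop("unorganized cloud: intrinsics with image size required",
           call. = FALSE)
    w <- intr@width; h <- intr@height
    pts <- validCoords(person)
    pts <- pts[pts[, 3] > 0, , drop = FALSE]
    uv <- round(projectPoints(pts, intr))
    keep <- uv[, 1] >= 0 & uv[, 1] <= w - 1 & uv[, 2] >= 0 &
      uv[, 2] <= h - 1
    mask <- matrix(0L, w, h)
    mask[uv[keep, , drop = FALSE] + 1L] <- 1L
  }
  if (!any(mask > 0))
    stopDegenerate("empty silhouette mask")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(as.integer(lab[lab > 0]))
  blob <- (lab == which.max(sizes)) * 1
  blob <- EBImage::fillHull(blob)
  contour <- traceBoundary(blob)
  clen <- if (nrow(contour) >= 2) polygonPerimeter(contour) else 0
  carea <- sum(blob > 0)
  hIdx <- grDevices::chull(contour[, 1], contour[, 2])
  hull <- contour[hIdx, , drop = FALSE]
  hlen <- if (nrow(hull) >= 2) polygonPerimeter(hull) else 0
  bb <- cbind(range(hull[, 1]), range(hull[, 2]))
  grid <- as.matrix(expand.grid(x = bb[1, 1]:bb[2, 1],
                                y = bb[1, 2]:bb[2, 2]))
  harea <- sum(pointsInConvexPolygon(grid, hull))
  c(contour_length = clen, contour_area = as.numeric(carea),
    hull_length = hlen, hull_area = as.numeric(harea))
}

#' Construct a FeatureVector
#' @param values named or unnamed numeric 19-vector (f1..f19).
#' @param available logical 19-vector; defaults to \code{!is.na(values)}.
#' @export
featureVector <- function(values, available = !is.na(values)) {
  nm <- weightFeatureNames()
  values <- as.numeric(values)
  names(values) <- nm
  names(available) <- nm
  new("FeatureVector", values = values, available = available)
}

#' @rdname FeatureVector-class
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

#' @rdname FeatureVector-class
#' @export
setMethod("featureAvailable", "FeatureVector", function(x) x@available)

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector (f1..f19):\n")
  v <- signif(object@values, 4)
  v[!object@available] <- NA
  print(v)
})

#' Stack feature vectors into a data frame
#'
#' @param fvs list of [FeatureVector-class] objects.
#' @return data.frame with one row per frame and the 19 named feature
#'   columns; unavailable features are NA.
#' @export
featureTable <- function(fvs) {
  m <- t(vapply(fvs, function(f) {
    v <- f@values
    v[!f@available] <- NA_real_
    v
  }, numeric(19)))
  as.data.frame(m)
}

#' Compute the full f1..f19 descriptor of a segmented person
#'
#' Composes all feature operations. Volume (f1) requires both an organized
#' person cloud and a back plane; the mesh surface (f2) requires
#' organization; silhouette features (f15-f18) require an organized cloud
#' or intrinsics with image size; gender (f19) is passed through, never
#' inferred. Unavailable features are flagged, not errors.
#'
#' @param person segmented person [PointCloud-class] (non-empty).
#' @param scene the full scene cloud (for the density feature f4); NULL
#'   marks f4 unavailable.
#' @param plane optional back [PlaneModel-class] (the stretcher) enabling
#'   the volume feature.
#' @param intr optional [Intrinsics-class] for silhouette rasterization of
#'   unorganized clouds.
#' @param gender optional "female"/"male" (or 0/1).
#' @param jumpThreshold mesh depth-discontinuity threshold, meters.
#' @return a [FeatureVector-class].
#' @export
extractFeatures <- function(person, scene = NULL, plane = NULL,
                            intr = NULL, gender = NULL,
                            jumpThreshold = 0.05) {
  nP <- nValidPoints(person)
  if (nP == 0) stopDegenerate("person cloud is empty")
  v <- rep(NA_real_, 19)
  names(v) <- weightFeatureNames()

  if (isOrganized(person)) {
    mesh <- computeFrontalMesh(person, jumpThreshold)
    v["surface"] <- computeSurface(mesh)
    if (!is.null(plane))
      v["volume"] <- computeVolume(mesh, plane)
  }
  v["n_person"] <- nP
  if (!is.null(scene)) v["density"] <- nP / nValidPoints(scene)

  if (nP >= 3) {
    ev <- scatterEigenvalues(person)
    v[c("lambda1", "lambda2", "lambda3")] <- ev
    if (sum(ev) > 0)
      v[c("sphericity", "flatness", "linearity")] <- eigenShapeFeatures(ev)
  }
  if (nP >= 2) {
    v[c("compactness", "kurtosis", "alt_compactness")] <-
      statisticalFeatures(person, flatness = v[["flatness"]])
  }
  v["distance"] <- distanceToPerson(person)
  sil <- tryCatch(silhouetteFeatures(person, intr), error = function(e) NULL)
  if (!is.null(sil))
    v[c("contour_length", "contour_area", "hull_length", "hull_area")] <- sil
  if (!is.null(gender)) {
    v["gender"] <- if (is.numeric(gender)) as.numeric(gender != 0)
                   else as.numeric(tolower(gender) %in% c("m", "male"))
  }
  featureVector(v)
}
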