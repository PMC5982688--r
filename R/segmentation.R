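# Scene segmentation: split a scene cloud P into the person's points Pp and
# the environment PE (P = Pp + PE over valid points). Two recipes are
# provided, one for the clinical lying scenario (region crop, stretcher
# plane by RANSAC, thermal threshold, largest Euclidean component,
# morphological cleanup) and one for standing/walking subjects (background
# subtraction against a reference frame, floor plane removal, statistical
# outlier filter, largest component).

#' Segmentation parameters with documented defaults
#'
#' @param thermalMin temperature threshold separating skin (~33-36 C) from
#'   room surfaces (~20-25 C); default 30 C.
#' @param backgroundDistThreshold distance threshold for background
#'   subtraction, default 5 cm (3-5x typical depth noise at 2-4 m).
#' @param ransacTolerance plane inlier tolerance, default 1.5 cm.
#' @param ransacIterations number of 3-point hypotheses, default 500.
#' @param ransacSeed RNG seed for the hypothesis draws.
#' @param roi axis-aligned crop box (list with \code{min}, \code{max}
#'   3-vectors, camera frame) marking the floor-marker range in the lying
#'   scenario.
#' @param morphRadius disc radius (pixels) for morphological opening.
#' @param outlierK,outlierSigma neighbor count and sd multiplier of the
#'   statistical outlier filter.
#' @param linkRadius Euclidean-clustering linkage radius, default 5 cm.
#' @param keepLargest keep only the largest connected component.
#' @param floorAxis expected floor-normal direction (camera frame) used as
#'   an axis hint when fitting the floor so the background wall cannot win;
#'   NULL disables the hint.
#' @param planeAxisTolDeg angular tolerance of the axis hint, degrees.
#' @return named list of parameters.
#' @export
segmentationConfig <- function(thermalMin = 30,
                               backgroundDistThreshold = 0.05,
                               ransacTolerance = 0.015,
                               ransacIterations = 500L,
                               ransacSeed = 1L,
                               roi = list(min = c(-1.1, -0.6, 0.5),
                                          max = c(1.1, 0.6, 2.1)),
                               morphRadius = 1L,
                               outlierK = 8L,
                               outlierSigma = 5,
                               linkRadius = 0.05,
                               keepLargest = TRUE,
                               floorAxis = c(0, 1, 0),
                               planeAxisTolDeg = 30) {
  list(thermalMin = thermalMin,
       backgroundDistThreshold = backgroundDistThreshold,
       ransacTolerance = ransacTolerance,
       ransacIterations = as.integer(ransacIterations),
       ransacSeed = as.integer(ransacSeed),
       roi = roi, morphRadius = as.integer(morphRadius),
       outlierK = as.integer(outlierK), outlierSigma = outlierSigma,
       linkRadius = linkRadius, keepLargest = keepLargest,
       floorAxis = floorAxis, planeAxisTolDeg = planeAxisTolDeg)
}

#' Crop a cloud to an axis-aligned region of interest
#'
#' Keeps points inside the closed box; in organized clouds removed points
#' become invalid (NaN) so the grid layout is preserved.
#'
#' @param cloud a [PointCloud-class].
#' @param roi list with \code{min} and \code{max} 3-vectors (meters).
#' @export
cropROI <- function(cloud, roi) {
  stopifnot(all(roi$max > roi$min))
  co <- cloud@coords
  keep <- validMask(cloud) &
    co[, 1] >= roi$min[1] & co[, 1] <= roi$max[1] &
    co[, 2] >= roi$min[2] & co[, 2] <= roi$max[2] &
    co[, 3] >= roi$min[3] & co[, 3] <= roi$max[3]
  keep[is.na(keep)] <- FALSE
  keepPoints(cloud, keep)
}

# Core RANSAC plane fit on an n x 3 coordinate matrix. Returns the inlier
# mask and the (normalized, origin-positive-side) plane. Vectorized over
# hypothesis blocks; ties between equal-inlier hypotheses are broken by the
# lower iteration index (which.max).
fitPlaneRANSAC <- function(pts, tol, iters, seed, axis = NULL,
                           axisTolDeg = 30) {
  n <- nrow(pts)
  if (n < 3) stopDegenerate("plane fit needs at least 3 valid points")
  draws <- withSeed(seed, {
    matrix(sample.int(n, 3L * iters, replace = TRUE), ncol = 3)
  })
  p1 <- pts[draws[, 1], , drop = FALSE]
  e1 <- pts[draws[, 2], , drop = FALSE] - p1
  e2 <- pts[draws[, 3], , drop = FALSE] - p1
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nl <- sqrt(nx^2 + ny^2 + nz^2)
  ok <- nl > 1e-12                      # skip collinear samples
  nx <- nx / nl; ny <- ny / nl; nz <- nz / nl
  if (!is.null(axis)) {
    axis <- axis / sqrt(sum(axis^2))
    ca <- abs(nx * axis[1] + ny * axis[2] + nz * axis[3])
    ok <- ok & ca >= cos(axisTolDeg * pi / 180)
  }
  if (!any(ok)) stopDegenerate("no admissible plane hypothesis found")
  normals <- cbind(nx, ny, nz)
  d <- -(p1[, 1] * nx + p1[, 2] * ny + p1[, 3] * nz)
  counts <- rep(-1L, iters)
  block <- 128L
  idx <- which(ok)
  for (i0 in seq(1L, length(idx), by = block)) {
    ii <- idx[i0:min(i0 + block - 1L, length(idx))]
    dist <- abs(sweep(pts %*% t(normals[ii, , drop = FALSE]), 2, d[ii],
                      "+"))
    counts[ii] <- colSums(dist <= tol)
  }
  best <- which.max(counts)
  nrm <- normals[best, ]
  off <- d[best]
  if (off < 0) { nrm <- -nrm; off <- -off }   # camera origin on + side
  inl <- abs(drop(pts %*% nrm) + off) <= tol
  list(inliers = inl,
       plane = new("PlaneModel", normal = nrm, offset = off,
                   tolerance = tol))
}

#' Remove the dominant plane from a cloud by RANSAC
#'
#' Fits the maximum-inlier 3-point plane hypothesis over \code{iters}
#' random draws (deterministic given \code{seed}), removes its inliers
#' (distance <= \code{tol}) and returns both the remainder and the plane
#' model for downstream volume computation.
#'
#' @param cloud a [PointCloud-class] with at least 3 valid points.
#' @param tol inlier tolerance in meters.
#' @param iters number of hypotheses.
#' @param seed RNG seed.
#' @param axis optional 3-vector; only hypotheses whose normal is within
#'   \code{axisTolDeg} degrees of this axis are considered.
#' @param axisTolDeg angular tolerance of the axis hint.
#' @return list with \code{remainder} (PointCloud) and \code{plane}
#'   ([PlaneModel-class]).
#' @export
removePlaneRANSAC <- function(cloud, tol = 0.015, iters = 500L,
                              seed = 1L, axis = NULL, axisTolDeg = 30) {
  vm <- validMask(cloud)
  fit <- fitPlaneRANSAC(cloud@coords[vm, , drop = FALSE], tol, iters,
                        seed, axis, axisTolDeg)
  keep <- vm
  keep[vm] <- !fit$inliers
  list(remainder = keepPoints(cloud, keep), plane = fit$plane)
}

#' Threshold a cloud by temperature
#'
#' Keeps points whose temperature is at least \code{tMin}; points without
#' a temperature sample are dropped.
#'
#' @param cloud a [PointCloud-class] carrying a temperature channel.
#' @param tMin threshold in degrees Celsius.
#' @export
thermalSegment <- function(cloud, tMin = 30) {
  if (!hasTemperature(cloud))
    stop("cloud has no temperature channel", call. = FALSE)
  keep <- validMask(cloud) & !is.na(cloud@temperature) &
    cloud@temperature >= tMin
  keepPoints(cloud, keep)
}

#' Subtract a person-free reference frame from a scene
#'
#' Keeps scene points whose distance to the corresponding reference point
#' (organized clouds on the same grid) or to the nearest reference point
#' (unorganized clouds) exceeds the threshold. Scene points where the
#' reference is invalid are kept (new geometry occludes nothing).
#'
#' @param scene,reference [PointCloud-class] objects; either both organized
#'   on the same grid or both unorganized.
#' @param distThreshold threshold in meters.
#' @export
subtractBackground <- function(scene, reference, distThreshold = 0.05) {
  orgS <- isOrganized(scene); orgR <- isOrganized(reference)
  if (orgS != orgR)
    stop("scene and reference must both be organized or both unorganized",
         call. = FALSE)
  vs <- validMask(scene)
  if (orgS) {
    if (scene@width != reference@width ||
        scene@height != reference@height)
      stop("organized grids differ in size", call. = FALSE)
    vr <- validMask(reference)
    d <- sqrt(rowSums((scene@coords - reference@coords)^2))
    keep <- vs & (!vr | (d > distThreshold))
    keep[is.na(keep)] <- FALSE
  } else {
    keep <- vs
    dd <- nearestDistance(scene@coords[vs, , drop = FALSE],
                          validCoords(reference))
    keep[vs] <- dd > distThreshold
  }
  keepPoints(scene, keep)
}

#' Keep the largest Euclidean connected component
#'
#' Exact single-linkage clustering with the given linkage radius; the
#' component with the most points survives. Ties are broken toward the
#' component whose centroid is closest to the sensor origin.
#'
#' @param cloud a [PointCloud-class].
#' @param linkRadius linkage radius in meters.
#' @export
largestComponent <- function(cloud, linkRadius = 0.05) {
  vm <- validMask(cloud)
  if (!any(vm)) return(keepPoints(cloud, vm))
  pts <- cloud@coords[vm, , drop = FALSE]
  lab <- euclideanComponents(pts, linkRadius)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    cdist <- vapply(best, function(b) {
      sqrt(sum(colMeans(pts[lab == b, , drop = FALSE])^2))
    }, numeric(1))
    best <- best[which.min(cdist)]
  }
  keep <- vm
  keep[vm] <- lab == best
  keepPoints(cloud, keep)
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a disc structuring element; removes
#' speckles smaller than the element while preserving large regions.
#'
#' @param mask binary (0/1 or logical) matrix.
#' @param radius disc radius in pixels.
#' @return binary integer matrix of the same shape.
#' @export
morphologicalClean <- function(mask, radius = 1L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (radius < 1L) return(m)
  kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- EBImage::opening(m, kern)
  matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
}

#' Statistical outlier removal
#'
#' Computes each point's mean distance to its k nearest neighbors and
#' removes points whose statistic exceeds mean + sigma * sd of that
#' statistic over the cloud.
#'
#' @param cloud a [PointCloud-class] with more than \code{k} valid points.
#' @param k neighbor count.
#' @param sigma standard-deviation multiplier.
#' @export
statisticalOutlierFilter <- function(cloud, k = 8L, sigma = 3) {
  vm <- validMask(cloud)
  if (sum(vm) <= k)
    stopDegenerate("statistical outlier filter needs more points than k")
  md <- knnMeanDistance(cloud@coords[vm, , drop = FALSE], k)
  thr <- mean(md) + sigma * stats::sd(md)
  keep <- vm
  keep[vm] <- md <= thr
  keepPoints(cloud, keep)
}

# Apply morphological opening to the person's validity mask of an
# organized cloud; returns the cleaned keep-mask over point indices.
morphCleanOrganized <- function(cloud, keep, radius) {
  if (!isOrganized(cloud) || radius < 1L) return(keep)
  m <- matrix(as.numeric(keep), nrow = cloud@width, ncol = cloud@height)
  m <- morphologicalClean(m, radius)          # width x height = x by y
  as.vector(m) > 0L
}

finishScene <- function(scene, personKeep, plane) {
  if (!any(personKeep))
    stop("empty segmentation: no person points survived", call. = FALSE)
  new("SegmentedScene",
      person = keepPoints(scene, personKeep),
      environment = keepPoints(scene, validMask(scene) & !personKeep),
      supportPlane = plane)
}

#' Segment a patient lying on a stretcher
#'
#' Clinical recipe: crop to the floor-marker region; fit the stretcher
#' surface by RANSAC on the cropped scene (while the stretcher is still
#' the dominant plane) and drop its inliers; apply the thermal threshold
#' when a temperature channel exists; keep the largest Euclidean component;
#' morphologically clean the organized validity mask. The stretcher plane
#' is returned as the support plane for volume computation.
#'
#' @param scene a [PointCloud-class] from the over-stretcher viewpoint.
#' @param cfg a [segmentationConfig()] list.
#' @return a [SegmentedScene-class].
#' @export
segmentLying <- function(scene, cfg = segmentationConfig()) {
  n <- nrow(scene@coords)
  co <- scene@coords
  inroi <- validMask(scene) &
    co[, 1] >= cfg$roi$min[1] & co[, 1] <= cfg$roi$max[1] &
    co[, 2] >= cfg$roi$min[2] & co[, 2] <= cfg$roi$max[2] &
    co[, 3] >= cfg$roi$min[3] & co[, 3] <= cfg$roi$max[3]
  inroi[is.na(inroi)] <- FALSE
  if (sum(inroi) < 3)
    stop("empty segmentation: region of interest holds no points",
         call. = FALSE)
  fit <- fitPlaneRANSAC(co[inroi, , drop = FALSE], cfg$ransacTolerance,
                        cfg$ransacIterations, cfg$ransacSeed,
                        axis = c(0, 0, 1),
                        axisTolDeg = cfg$planeAxisTolDeg)
  keep <- inroi
  keep[inroi] <- !fit$inliers
  if (hasTemperature(scene)) {
    warm <- !is.na(scene@temperature) & scene@temperature >= cfg$thermalMin
    keep <- keep & warm
  }
  if (cfg$keepLargest && any(keep)) {
    pts <- co[keep, , drop = FALSE]
    lab <- euclideanComponents(pts, cfg$linkRadius)
    sizes <- tabulate(lab)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      cdist <- vapply(best, function(b)
        sqrt(sum(colMeans(pts[lab == b, , drop = FALSE])^2)), numeric(1))
      best <- best[which.min(cdist)]
    }
    keep[keep] <- lab == best
  }
  keep <- keep & morphCleanOrganized(scene, keep, cfg$morphRadius)
  finishScene(scene, keep, fit$plane)
}

#' Segment a standing or walking person
#'
#' Background subtraction against a person-free reference frame, floor
#' plane removal (the floor is fit on the full scene with the configured
#' axis hint and its inliers are dropped from the candidates), statistical
#' outlier filtering and largest-component selection. The floor plane is
#' returned as the support plane.
#'
#' @param scene a [PointCloud-class] containing the person.
#' @param reference a person-free [PointCloud-class] of the same scene.
#' @param cfg a [segmentationConfig()] list.
#' @return a [SegmentedScene-class].
#' @export
segmentStanding <- function(scene, reference,
                            cfg = segmentationConfig()) {
  orgS <- isOrganized(scene)
  vs <- validMask(scene)
  if (orgS) {
    if (!isOrganized(reference) || scene@width != reference@width ||
        scene@height != reference@height)
      stop("organized scene and reference grids differ", call. = FALSE)
    vr <- validMask(reference)
    d <- sqrt(rowSums((scene@coords - reference@coords)^2))
    keep <- vs & (!vr | (d > cfg$backgroundDistThreshold))
    keep[is.na(keep)] <- FALSE
  } else {
    keep <- vs
    keep[vs] <- nearestDistance(scene@coords[vs, , drop = FALSE],
                                validCoords(reference)) >
      cfg$backgroundDistThreshold
  }
  # floor plane, fit where it is still dominant (the full scene)
  plane <- NULL
  fit <- tryCatch(
    fitPlaneRANSAC(scene@coords[vs, , drop = FALSE],
                   cfg$ransacTolerance, cfg$ransacIterations,
                   cfg$ransacSeed, axis = cfg$floorAxis,
                   axisTolDeg = cfg$planeAxisTolDeg),
    error = function(e) NULL)
  if (!is.null(fit)) {
    plane <- fit$plane
    keep[vs] <- keep[vs] & !fit$inliers
  }
  if (sum(keep) > cfg$outlierK) {
    md <- knnMeanDistance(scene@coords[keep, , drop = FALSE],
                          cfg$outlierK)
    keep[keep] <- md <= mean(md) + cfg$outlierSigma * stats::sd(md)
  }
  if (cfg$keepLargest && any(keep)) {
    pts <- scene@coords[keep, , drop = FALSE]
    lab <- euclideanComponents(pts, cfg$linkRadius)
    sizes <- tabulate(lab)
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      cdist <- vapply(best, function(b)
        sqrt(sum(colMeans(pts[lab == b, , drop = FALSE])^2)), numeric(1))
      best <- best[which.min(cdist)]
    }
    keep[keep] <- lab == best
  }
  finishScene(scene, keep, plane)
}

#' @rdname SegmentedScene-class
#' @export
setMethod("personCloud", "SegmentedScene", function(x) x@person)

#' @rdname SegmentedScene-class
#' @export
setMethod("environmentCloud", "SegmentedScene",
          function(x) x@environment)

#' @rdname SegmentedScene-class
#' @export
setMethod("supportPlane", "SegmentedScene", function(x) x@supportPlane)

setMethod("show", "SegmentedScene", function(object) {
  cat("SegmentedScene: person", nValidPoints(object@person),
      "pts / environment", nValidPoints(object@environment), "pts\n")
  if (!is.null(object@supportPlane))
    cat("  support plane normal:",
        signif(object@supportPlane@normal, 3), " offset:",
        signif(object@supportPlane@offset, 4), "\n")
})
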