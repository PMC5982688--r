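# Pinhole projection, rectification, depth-image back-projection and
# depth/thermal sensor fusion. Coordinate conventions: right-handed camera
# frame with x right, y down, z forward along the optical axis; continuous
# pixel coordinates (u, v), pixel centers at integers, 0-based.

#' Construct camera intrinsics
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels.
#' @param dist distortion coefficients (k1, k2, k3, p1, p2).
#' @param width,height sensor resolution (optional, needed by silhouette
#'   rasterization and [depthToCloud()] consumers).
#' @export
intrinsics <- function(fx, fy, cx, cy, dist = c(0, 0, 0, 0, 0),
                       width = 0L, height = 0L) {
  new("Intrinsics", fx = fx, fy = fy, cx = cx, cy = cy,
      dist = as.numeric(dist), width = as.integer(width),
      height = as.integer(height))
}

#' Construct a rigid extrinsic transform
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector, meters.
#' @export
extrinsics <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("Extrinsics", rotation = rotation,
      translation = as.numeric(translation))
}

#' Project 3D points onto the sensor plane
#'
#' Distortion-free pinhole model: u = cx + fx x / z, v = cy + fy y / z.
#' Rectification is assumed to have been applied to the images beforehand.
#'
#' @param pts numeric 3-vector or n x 3 matrix of camera-frame points; all
#'   depths must be positive.
#' @param intr an [Intrinsics-class].
#' @return n x 2 matrix of (u, v) pixel coordinates.
#' @export
projectPoints <- function(pts, intr) {
  if (is.null(dim(pts))) pts <- matrix(pts, 1, 3)
  if (any(pts[, 3] <= 0))
    stop("cannot project points with non-positive depth", call. = FALSE)
  cbind(u = intr@cx + intr@fx * pts[, 1] / pts[, 3],
        v = intr@cy + intr@fy * pts[, 2] / pts[, 3])
}

#' Apply the Brown distortion polynomial to pixel coordinates
#'
#' Evaluates the radial (k1, k2, k3) and tangential (p1, p2) terms in
#' normalized coordinates. With all coefficients zero this is the identity;
#' a pixel on the principal point is always unchanged.
#'
#' @param q 2-vector or n x 2 matrix of (u, v) pixels.
#' @param intr an [Intrinsics-class] carrying the coefficients.
#' @return pixels of the same shape as the input.
#' @export
rectifyPixel <- function(q, intr) {
  vec <- is.null(dim(q))
  if (vec) q <- matrix(q, 1, 2)
  k1 <- intr@dist[1]; k2 <- intr@dist[2]; k3 <- intr@dist[3]
  p1 <- intr@dist[4]; p2 <- intr@dist[5]
  xn <- (q[, 1] - intr@cx) / intr@fx
  yn <- (q[, 2] - intr@cy) / intr@fy
  r2 <- xn^2 + yn^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- xn * radial + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
  out <- cbind(u = intr@cx + intr@fx * xd, v = intr@cy + intr@fy * yd)
  if (vec) out[1, ] else out
}

#' Back-project a depth image into an organized point cloud
#'
#' Inverse of [projectPoints()] per pixel. The depth image is indexed
#' \code{depth[v + 1, u + 1]} (rows are image rows). Pixels with
#' non-positive or missing depth become invalid (NaN) points so the grid
#' layout is preserved.
#'
#' @param depth numeric H x W matrix of depths along the optical axis,
#'   meters.
#' @param intr an [Intrinsics-class].
#' @return an organized [PointCloud-class] of size W x H.
#' @export
depthToCloud <- function(depth, intr) {
  h <- nrow(depth); w <- ncol(depth)
  u <- rep(seq_len(w) - 1, each = 1)
  # row-major point order: index = v * width + u
  uu <- rep(seq_len(w) - 1, times = h)
  vv <- rep(seq_len(h) - 1, each = w)
  z <- as.numeric(t(depth))
  bad <- !is.finite(z) | z <= 0
  z[bad] <- NaN
  co <- cbind((uu - intr@cx) / intr@fx * z,
              (vv - intr@cy) / intr@fy * z,
              z)
  pointCloud(co, width = w, height = h)
}

#' Fuse a thermal image onto a point cloud
#'
#' Transforms each point into the thermal camera frame, projects it with
#' the thermal intrinsics and samples the nearest pixel. Points projecting
#' outside the image (or behind the thermal camera) get no temperature
#' (NA). Coordinates are never modified.
#'
#' @param cloud a [PointCloud-class] in the reference (depth-sensor) frame.
#' @param thermalImage numeric H x W matrix, degrees Celsius.
#' @param intrT thermal camera [Intrinsics-class].
#' @param extrT [Extrinsics-class] mapping reference-frame points into the
#'   thermal camera frame.
#' @return the cloud with a temperature channel attached.
#' @export
fuseThermal <- function(cloud, thermalImage, intrT,
                        extrT = extrinsics()) {
  h <- nrow(thermalImage); w <- ncol(thermalImage)
  co <- cloud@coords
  tt <- rep(NA_real_, nrow(co))
  ok <- rowSums(is.finite(co)) == 3L
  if (any(ok)) {
    p <- co[ok, , drop = FALSE] %*% t(extrT@rotation)
    p <- sweep(p, 2, extrT@translation, "+")
    front <- p[, 3] > 0
    u <- round(intrT@cx + intrT@fx * p[, 1] / p[, 3])
    v <- round(intrT@cy + intrT@fy * p[, 2] / p[, 3])
    inimg <- front & u >= 0 & u <= w - 1 & v >= 0 & v <= h - 1
    vals <- rep(NA_real_, nrow(p))
    vals[inimg] <- thermalImage[cbind(v[inimg] + 1, u[inimg] + 1)]
    tt[ok] <- vals
  }
  new("PointCloud", coords = cloud@coords, color = cloud@color,
      temperature = tt, width = cloud@width, height = cloud@height,
      meta = cloud@meta)
}

#' Read a calibration config file
#'
#' Consumes a plain-text JSON file with one intrinsics block per sensor and
#' one extrinsic transform per non-reference sensor, e.g.
#' \preformatted{
#' {"sensors": {"depth": {"fx":...,"fy":...,"cx":...,"cy":...,
#'                        "dist":[...], "width":..., "height":...},
#'              "thermal": {..., "rotation":[[...]], "translation":[...]}}}
#' }
#'
#' @param path path to the JSON config.
#' @return named list per sensor with \code{intr} ([Intrinsics-class]) and,
#'   where present, \code{extr} ([Extrinsics-class]).
#' @export
readCalibrationConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$sensors))
    stop("calibration config must contain a 'sensors' object",
         call. = FALSE)
  lapply(cfg$sensors, function(s) {
    out <- list(intr = intrinsics(
      fx = s$fx, fy = s$fy, cx = s$cx, cy = s$cy,
      dist = if (is.null(s$dist)) numeric(5) else s$dist,
      width = if (is.null(s$width)) 0L else s$width,
      height = if (is.null(s$height)) 0L else s$height))
    if (!is.null(s$rotation))
      out$extr <- extrinsics(matrix(unlist(s$rotation), 3, 3,
                                    byrow = TRUE),
                             s$translation)
    out
  })
}
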