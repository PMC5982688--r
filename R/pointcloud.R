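#' Construct a PointCloud
#'
#' @param coords numeric n x 3 matrix of x, y, z in meters (camera frame).
#' @param color optional n x 3 integer matrix (r, g, b in 0..255).
#' @param temperature optional numeric vector, degrees Celsius (NA where no
#'   sample exists).
#' @param width,height grid dimensions for organized clouds (both 0 for
#'   unorganized clouds). Organized clouds are stored row-major: point
#'   index = v * width + u + 1 for 0-based pixel (u, v).
#' @param meta optional list of frame metadata.
#' @return a [PointCloud-class] object.
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), 10, 3))
#' nPoints(pc)
#' @export
pointCloud <- function(coords, color = NULL, temperature = NULL,
                       width = 0L, height = 0L, meta = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (is.null(color)) color <- matrix(integer(0), 0, 3)
  color <- as.matrix(color)
  storage.mode(color) <- "integer"
  colnames(color) <- c("r", "g", "b")
  if (is.null(temperature)) temperature <- numeric(0)
  new("PointCloud", coords = coords, color = color,
      temperature = as.numeric(temperature),
      width = as.integer(width), height = as.integer(height), meta = meta)
}

#' @rdname PointCloud-class
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname PointCloud-class
#' @export
setMethod("temperature", "PointCloud", function(x) x@temperature)

#' @rdname PointCloud-class
#' @export
setMethod("pointColors", "PointCloud", function(x) x@color)

#' @rdname PointCloud-class
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname PointCloud-class
#' @export
setMethod("validMask", "PointCloud", function(x) {
  rowSums(is.finite(x@coords)) == 3L
})

#' @rdname PointCloud-class
#' @export
setMethod("nValidPoints", "PointCloud", function(x) sum(validMask(x)))

#' @rdname PointCloud-class
#' @export
setMethod("isOrganized", "PointCloud",
          function(x) x@width > 0L && x@height > 0L)

#' @rdname PointCloud-class
#' @export
setMethod("hasTemperature", "PointCloud",
          function(x) length(x@temperature) > 0L)

#' @rdname PointCloud-class
#' @export
setMethod("hasColor", "PointCloud", function(x) nrow(x@color) > 0L)

#' @rdname PointCloud-class
#' @export
setMethod("frameMeta", "PointCloud", function(x) x@meta)

setMethod("show", "PointCloud", function(object) {
  cat("PointCloud:", nrow(object@coords), "points (",
      nValidPoints(object), "valid )\n")
  if (isOrganized(object))
    cat("  organized", object@width, "x", object@height, "\n")
  cat("  channels: xyz", if (hasColor(object)) "rgb",
      if (hasTemperature(object)) "t", "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(object@meta),
                         sep = "=", collapse = ", "), "\n")
})

# Keep the points indexed by a logical mask. Organized clouds preserve
# their grid layout (removed points become NaN); unorganized clouds drop
# rows. Channels follow the coordinates.
keepPoints <- function(cloud, keep) {
  stopifnot(length(keep) == nrow(cloud@coords))
  if (isOrganized(cloud)) {
    co <- cloud@coords
    co[!keep, ] <- NaN
    tt <- cloud@temperature
    if (length(tt)) tt[!keep] <- NA_real_
    new("PointCloud", coords = co, color = cloud@color, temperature = tt,
        width = cloud@width, height = cloud@height, meta = cloud@meta)
  } else {
    new("PointCloud", coords = cloud@coords[keep, , drop = FALSE],
        color = if (nrow(cloud@color)) cloud@color[keep, , drop = FALSE]
                else cloud@color,
        temperature = if (length(cloud@temperature))
          cloud@temperature[keep] else numeric(0),
        width = 0L, height = 0L, meta = cloud@meta)
  }
}

# Coordinates of valid points only.
validCoords <- function(cloud) {
  cloud@coords[validMask(cloud), , drop = FALSE]
}
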