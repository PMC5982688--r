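#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Point cloud with optional color and thermal channels
#'
#' The central data carrier of the package: a set of 3D points in the sensor
#' (camera) frame, in meters, optionally carrying 8-bit RGB color and a
#' per-point temperature in degrees Celsius. A cloud may be \emph{organized},
#' i.e. laid out on the sensor's pixel grid (row-major, \code{width} columns
#' by \code{height} rows); invalid pixels are encoded as \code{NaN}
#' coordinates and are excluded from all statistics.
#'
#' @slot coords numeric matrix, n x 3 (x, y, z in meters). Camera frame:
#'   x right, y down, z forward along the optical axis.
#' @slot color integer matrix, n x 3 (r, g, b in 0..255) or 0 x 3 when the
#'   cloud has no color channel.
#' @slot temperature numeric vector of length n (degrees Celsius, \code{NA}
#'   for points without a temperature sample) or length 0 when the cloud has
#'   no thermal channel.
#' @slot width,height integer; grid dimensions for organized clouds, both 0
#'   for unorganized clouds.
#' @slot meta list; optional frame metadata (see [parseDatasetFilename()]).
#'
#' @seealso [pointCloud()], [readPCD()], [writePCD()]
#' @export
setClass("PointCloud",
  representation(
    coords = "matrix",
    color = "matrix",
    temperature = "numeric",
    width = "integer",
    height = "integer",
    meta = "list"
  ),
  prototype(
    coords = matrix(numeric(0), 0, 3),
    color = matrix(integer(0), 0, 3),
    temperature = numeric(0),
    width = 0L, height = 0L,
    meta = list()
  )
)

setValidity("PointCloud", function(object) {
  msg <- character(0)
  if (ncol(object@coords) != 3)
    msg <- c(msg, "coords must have 3 columns (x, y, z)")
  n <- nrow(object@coords)
  if (nrow(object@color) != 0 && nrow(object@color) != n)
    msg <- c(msg, "color must have one row per point or zero rows")
  if (length(object@temperature) != 0 && length(object@temperature) != n)
    msg <- c(msg, "temperature must have one value per point or length zero")
  organized <- object@width > 0L && object@height > 0L
  if (organized && as.numeric(object@width) * as.numeric(object@height) != n)
    msg <- c(msg, "organized cloud: width * height must equal the point count")
  if (!organized && (object@width != 0L || object@height != 0L))
    msg <- c(msg, "width and height must both be positive or both zero")
  if (length(msg)) msg else TRUE
})

#' Infinite plane model
#'
#' A plane \eqn{\{p : n \cdot p + d = 0\}} with unit normal \eqn{n} and
#' offset \eqn{d} in meters, as recovered by RANSAC for the stretcher
#' surface or the floor. The inlier tolerance used during fitting is kept
#' for provenance.
#'
#' @slot normal unit 3-vector.
#' @slot offset numeric scalar, meters.
#' @slot tolerance numeric scalar, inlier distance used at fit time (meters).
#' @export
setClass("PlaneModel",
  representation(normal = "numeric", offset = "numeric",
                 tolerance = "numeric"),
  prototype(normal = c(0, 0, 1), offset = 0, tolerance = 0.015)
)

setValidity("PlaneModel", function(object) {
  if (length(object@normal) != 3)
    return("normal must be a 3-vector")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must have unit length (within 1e-9)")
  TRUE
})

setClassUnion("PlaneModelOrNULL", c("PlaneModel", "NULL"))

#' Pinhole camera intrinsics
#'
#' @slot fx,fy focal lengths in pixels (> 0).
#' @slot cx,cy principal point in pixels (continuous coordinates, pixel
#'   centers at integers, 0-based).
#' @slot dist numeric 5-vector (k1, k2, k3, p1, p2): radial and tangential
#'   distortion coefficients of the Brown model.
#' @slot width,height sensor resolution in pixels (0 when unknown).
#' @export
setClass("Intrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", dist = "numeric",
                 width = "integer", height = "integer"),
  prototype(dist = numeric(5), width = 0L, height = 0L)
)

setValidity("Intrinsics", function(object) {
  if (object@fx <= 0 || object@fy <= 0)
    return("focal lengths fx and fy must be positive")
  if (length(object@dist) != 5)
    return("dist must be a 5-vector (k1, k2, k3, p1, p2)")
  TRUE
})

#' Rigid sensor-to-sensor transform
#'
#' Maps points from the reference (depth-sensor) frame into another sensor's
#' frame: \eqn{p' = R p + t}.
#'
#' @slot rotation 3 x 3 rotation matrix (determinant +1 within 1e-9).
#' @slot translation 3-vector, meters.
#' @export
setClass("Extrinsics",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = numeric(3))
)

setValidity("Extrinsics", function(object) {
  if (!all(dim(object@rotation) == c(3, 3)))
    return("rotation must be 3 x 3")
  if (abs(det(object@rotation) - 1) > 1e-9)
    return("rotation determinant must be +1 within 1e-9")
  if (length(object@translation) != 3)
    return("translation must be a 3-vector")
  TRUE
})

#' Triangulated frontal surface of a segmented person
#'
#' @slot vertices numeric matrix m x 3 (meters).
#' @slot triangles integer matrix k x 3 of vertex indices (1-based).
#' @export
setClass("FrontalMesh",
  representation(vertices = "matrix", triangles = "matrix"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            triangles = matrix(integer(0), 0, 3))
)

setValidity("FrontalMesh", function(object) {
  if (ncol(object@vertices) != 3) return("vertices must have 3 columns")
  if (ncol(object@triangles) != 3) return("triangles must have 3 columns")
  if (nrow(object@triangles) > 0 &&
      (max(object@triangles) > nrow(object@vertices) ||
       min(object@triangles) < 1))
    return("triangle indices out of range")
  TRUE
})

#' The 19-component body-shape descriptor of one person frame
#'
#' Holds the feature values f1..f19 (volume, surface, point counts, scatter
#' eigenvalues and the derived sphericity/flatness/linearity, statistical
#' moments, distance, silhouette contour and convex-hull measures, gender)
#' together with per-feature availability flags. Volume (f1) is available
#' only when a supporting back plane exists; gender (f19) only when it was
#' supplied as an input.
#'
#' @slot values named numeric 19-vector (f1..f19); \code{NA} when
#'   unavailable.
#' @slot available named logical 19-vector.
#' @seealso [extractFeatures()], [featureTable()]
#' @export
setClass("FeatureVector",
  representation(values = "numeric", available = "logical")
)

#' Names and order of the feature descriptor components
#' @return character vector of length 19 (f1..f19 short names).
#' @export
weightFeatureNames <- function() {
  c("volume", "surface", "n_person", "density",
    "lambda1", "lambda2", "lambda3",
    "sphericity", "flatness", "linearity",
    "compactness", "kurtosis", "alt_compactness",
    "distance",
    "contour_length", "contour_area", "hull_length", "hull_area",
    "gender")
}

setValidity("FeatureVector", function(object) {
  if (length(object@values) != 19 || length(object@available) != 19)
    return("values and available must have length 19")
  TRUE
})

#' Trained three-layer feed-forward weight estimator
#'
#' A fully connected network with one hidden layer of \code{tanh} units and
#' a single linear output neuron emitting body weight in kilograms, trained
#' by resilient propagation (iRPROP-) with weight decay and validation-based
#' early stopping. Inputs are standardized with the training-set mean and
#' standard deviation stored in the model.
#'
#' @slot w1 hidden-layer weights (nHidden x nFeatures).
#' @slot b1 hidden-layer biases.
#' @slot w2 output weights (length nHidden).
#' @slot b2 output bias (scalar).
#' @slot center,scale per-feature standardization parameters.
#' @slot featureMask logical 19-vector: which of f1..f19 the model consumes.
#' @slot config list; training configuration snapshot.
#' @slot history list; training/validation error traces.
#' @seealso [trainWeightNet()], [predictWeight()]
#' @export
setClass("WeightNet",
  representation(w1 = "matrix", b1 = "numeric", w2 = "numeric",
                 b2 = "numeric", center = "numeric", scale = "numeric",
                 featureMask = "logical", config = "list",
                 history = "list")
)

setValidity("WeightNet", function(object) {
  p <- ncol(object@w1)
  h <- nrow(object@w1)
  if (length(object@b1) != h || length(object@w2) != h)
    return("hidden-layer dimensions inconsistent")
  if (length(object@center) != p || length(object@scale) != p)
    return("standardization parameters inconsistent with input width")
  if (any(object@scale <= 0))
    return("standardization scales must be positive")
  if (sum(object@featureMask) != p)
    return("featureMask must select exactly ncol(w1) features")
  TRUE
})

#' Result of splitting a scene into person and environment
#'
#' @slot person PointCloud of the segmented person (organized layout is
#'   preserved; removed points become NaN).
#' @slot environment PointCloud of everything else.
#' @slot supportPlane the stretcher (lying) or floor (standing) plane, or
#'   NULL when none was fit.
#' @export
setClass("SegmentedScene",
  representation(person = "PointCloud", environment = "PointCloud",
                 supportPlane = "PlaneModelOrNULL")
)

#' Parametric synthetic humanoid with analytic ground-truth weight
#'
#' A union of ten pairwise-disjoint ellipsoids (head, torso, two upper and
#' lower arms, two thighs and shins). Because the segments are disjoint the
#' body volume is the exact sum of ellipsoid volumes and the ground-truth
#' weight is \eqn{\rho \cdot V} with no hidden noise on the label.
#'
#' @slot segments list of body segments; each a list with \code{center}
#'   (body frame, meters), \code{semi} (semi-axes), \code{rot} (3 x 3).
#' @slot density tissue density in kg/m^3.
#' @slot gender "female" or "male".
#' @slot posture list of posture parameters (arm abduction, leg stance,
#'   arms-crossed and backpack flags, arm swing).
#' @slot heightM standing height in meters.
#' @slot analyticVolume body volume in m^3.
#' @slot groundTruthKg exact weight, density * analyticVolume.
#' @slot id integer subject identifier.
#' @seealso [samplePopulation()], [renderScene()]
#' @export
setClass("SyntheticSubject",
  representation(segments = "list", density = "numeric",
                 gender = "character", posture = "list",
                 heightM = "numeric", analyticVolume = "numeric",
                 groundTruthKg = "numeric", id = "integer")
)

setValidity("SyntheticSubject", function(object) {
  if (object@groundTruthKg <= 0) return("ground-truth weight must be > 0")
  if (object@analyticVolume <= 0) return("analytic volume must be > 0")
  TRUE
})

#' Synthetic scene description
#'
#' Everything the renderer needs besides the subject: sensor intrinsics,
#' camera mounting (height and downward pitch for standing/walking; straight
#' overhead view for lying), scene geometry, depth noise, and the thermal
#' contrast between body and background.
#'
#' @slot mode "lying", "standing" or "walking".
#' @slot intr sensor [Intrinsics-class].
#' @slot cameraHeightM camera height above the floor (standing/walking) or
#'   above the stretcher plane (lying), meters.
#' @slot pitchRad downward pitch of the optical axis (standing/walking).
#' @slot subjectDistanceM distance camera-to-subject along the ground,
#'   meters (standing; start distance for walking).
#' @slot noiseSigma along-ray Gaussian depth noise, meters.
#' @slot bodyTempC,backgroundTempC temperatures attached to body and
#'   environment points, degrees Celsius.
#' @slot withThermal logical; attach a temperature channel at all.
#' @slot clutter list; optional extras (\code{bystander = TRUE} adds a cool
#'   blob next to the subject, \code{backpack = TRUE} a box behind the
#'   torso).
#' @export
setClass("SceneSpec",
  representation(mode = "character", intr = "Intrinsics",
                 cameraHeightM = "numeric", pitchRad = "numeric",
                 subjectDistanceM = "numeric", noiseSigma = "numeric",
                 bodyTempC = "numeric", backgroundTempC = "numeric",
                 withThermal = "logical", clutter = "list")
)

setValidity("SceneSpec", function(object) {
  if (!object@mode %in% c("lying", "standing", "walking"))
    return("mode must be lying, standing or walking")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})
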