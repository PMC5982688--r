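#' @rdname PointCloud-class
#' @param object,x a PointCloud
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointCloud-class
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' @rdname PointCloud-class
#' @export
setGeneric("pointColors", function(x) standardGeneric("pointColors"))

#' @rdname PointCloud-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname PointCloud-class
#' @export
setGeneric("nValidPoints", function(x) standardGeneric("nValidPoints"))

#' @rdname PointCloud-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname PointCloud-class
#' @export
setGeneric("isOrganized", function(x) standardGeneric("isOrganized"))

#' @rdname PointCloud-class
#' @export
setGeneric("hasTemperature", function(x) standardGeneric("hasTemperature"))

#' @rdname PointCloud-class
#' @export
setGeneric("hasColor", function(x) standardGeneric("hasColor"))

#' @rdname PointCloud-class
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))

#' @rdname FeatureVector-class
#' @param x a FeatureVector
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureVector-class
#' @export
setGeneric("featureAvailable",
           function(x) standardGeneric("featureAvailable"))

#' @rdname SegmentedScene-class
#' @param x a SegmentedScene
#' @export
setGeneric("personCloud", function(x) standardGeneric("personCloud"))

#' @rdname SegmentedScene-class
#' @export
setGeneric("environmentCloud",
           function(x) standardGeneric("environmentCloud"))

#' @rdname SegmentedScene-class
#' @export
setGeneric("supportPlane", function(x) standardGeneric("supportPlane"))

#' @rdname SyntheticSubject-class
#' @param x a SyntheticSubject
#' @export
setGeneric("groundTruthKg", function(x) standardGeneric("groundTruthKg"))

#' @rdname SyntheticSubject-class
#' @export
setGeneric("analyticVolume", function(x) standardGeneric("analyticVolume"))
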