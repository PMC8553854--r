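#' Accessor generics
#'
#' Small accessor layer over the S4 containers so user code never touches
#' slots directly.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("erpData", function(object) standardGeneric("erpData"))

#' @rdname accessors
#' @export
setGeneric("montage", function(object) standardGeneric("montage"))

#' @rdname accessors
#' @export
setGeneric("timesMs", function(object) standardGeneric("timesMs"))

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("innerDistanceSum",
           function(object) standardGeneric("innerDistanceSum"))

#' @rdname accessors
#' @export
setGeneric("microstates", function(object) standardGeneric("microstates"))

#' @rdname accessors
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("nullDistribution",
           function(object) standardGeneric("nullDistribution"))

setMethod("erpData", "EpochSet", function(object) object@data)
setMethod("erpData", "ERPMatrix", function(object) object@data)
setMethod("montage", "EpochSet", function(object) object@montage)
setMethod("montage", "ERPMatrix", function(object) object@montage)
setMethod("timesMs", "EpochSet", function(object) object@timesMs)
setMethod("timesMs", "ERPMatrix", function(object) object@timesMs)
setMethod("timesMs", "Segmentation", function(object) object@timesMs)
setMethod("isNormalized", "ERPMatrix", function(object) object@normalized)
setMethod("nEpochs", "EpochSet", function(object) dim(object@data)[1])
setMethod("centroids", "ClusterModel", function(object) object@centroids)
setMethod("clusterLabels", "ClusterModel", function(object) object@labels)
setMethod("innerDistanceSum", "ClusterModel",
          function(object) object@innerDistanceSum)
setMethod("microstates", "Segmentation", function(object) object@microstates)
setMethod("templates", "TemplateSet", function(object) object@templates)
setMethod("resultTable", "TanovaResult", function(object) object@table)
setMethod("resultTable", "PosthocTable", function(object) object@table)
setMethod("nullDistribution", "TanovaResult", function(object) object@null)
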