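# Accessor generics. Slot access stays internal; user code goes through
# these.

#' @rdname accessors
#' @param object an object from this package
#' @export
setGeneric("dataArray", function(object) standardGeneric("dataArray"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("categoryLabels",
           function(object) standardGeneric("categoryLabels"))

#' @rdname accessors
#' @export
setGeneric("depictionLabels",
           function(object) standardGeneric("depictionLabels"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("conditionIds", function(object) standardGeneric("conditionIds"))

#' @rdname accessors
#' @export
setGeneric("rdmValues", function(object) standardGeneric("rdmValues"))

#' @rdname accessors
#' @export
setGeneric("accuracyValues",
           function(object) standardGeneric("accuracyValues"))

#' @rdname accessors
#' @export
setGeneric("chanceLevel", function(object) standardGeneric("chanceLevel"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))

#' @rdname accessors
#' @export
setGeneric("peakLatency", function(object) standardGeneric("peakLatency"))

#' @rdname accessors
#' @export
setGeneric("peakCI", function(object) standardGeneric("peakCI"))
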