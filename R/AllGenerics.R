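#' Accessors for hazelmap classes
#'
#' `calls()` returns the markers-by-individuals call matrix, `markerInfo()`
#' the per-marker metadata, `individuals()` the individual ids,
#' `nMarkers()`/`nIndividuals()` the dimensions, and `markerFunnel()` the
#' QC funnel counts. For [GeneticMap-class], `mapTable()` returns the
#' ordered marker table and `mapSummary()` the per-group summary
#' statistics. For [ArmSet-class], `arms()` returns the marker
#' memberships.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname accessors
#' @export
setGeneric("markerFunnel", function(x) standardGeneric("markerFunnel"))

#' @rdname accessors
#' @export
setGeneric("mapTable", function(x) standardGeneric("mapTable"))

#' @rdname accessors
#' @export
setGeneric("mapSummary", function(x) standardGeneric("mapSummary"))

#' @rdname accessors
#' @export
setGeneric("linkageGroups", function(x) standardGeneric("linkageGroups"))

#' @rdname accessors
#' @export
setGeneric("arms", function(x) standardGeneric("arms"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
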