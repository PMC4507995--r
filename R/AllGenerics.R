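#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Accessors for the core data classes: photon counts, time axis,
#' per-channel curve values and fitted parameter maps.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot contents; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x, ...) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x, ...) standardGeneric("timeAxis"))

#' @rdname accessors
#' @export
setGeneric("curveValues", function(x, ...) standardGeneric("curveValues"))

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x, ...) standardGeneric("pixelPitch"))

#' @rdname accessors
#' @export
setGeneric("resultMap", function(x, name, ...) standardGeneric("resultMap"))

#' @rdname accessors
#' @export
setGeneric("mapNames", function(x, ...) standardGeneric("mapNames"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(x, ...) standardGeneric("subjects"))
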