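#' @title Generics for telemetry containers
#' @description Accessor generics for the S4 containers of the package.
#' @param x an object.
#' @name chronotel-generics
NULL

#' @rdname chronotel-generics
#' @export
setGeneric("lma", function(x) standardGeneric("lma"))

#' @rdname chronotel-generics
#' @export
setGeneric("tb", function(x) standardGeneric("tb"))

#' @rdname chronotel-generics
#' @export
setGeneric("seriesMask", function(x) standardGeneric("seriesMask"))

#' @rdname chronotel-generics
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname chronotel-generics
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname chronotel-generics
#' @export
setGeneric("spanHours", function(x) standardGeneric("spanHours"))

#' @rdname chronotel-generics
#' @export
setGeneric("timeHours", function(x) standardGeneric("timeHours"))

#' @rdname chronotel-generics
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname chronotel-generics
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname chronotel-generics
#' @export
setGeneric("relativeAmplitude", function(x) standardGeneric("relativeAmplitude"))

#' @rdname chronotel-generics
#' @export
setGeneric("peakPower", function(x) standardGeneric("peakPower"))

#' @rdname chronotel-generics
#' @export
setGeneric("tauHours", function(x) standardGeneric("tauHours"))
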