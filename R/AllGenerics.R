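#' @rdname MotMetrics-class
#' @param object,x a PenTrack S4 object.
#' @export
setGeneric("mota", function(x) standardGeneric("mota"))

#' @rdname MotMetrics-class
#' @export
setGeneric("motp", function(x) standardGeneric("motp"))

#' @rdname MotMetrics-class
#' @export
setGeneric("motCounts", function(x) standardGeneric("motCounts"))

#' @rdname PrCurve-class
#' @export
setGeneric("averagePrecisionValue",
           function(x) standardGeneric("averagePrecisionValue"))

#' @rdname PenSimulation-class
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname PenSimulation-class
#' @export
setGeneric("pathLengths", function(x) standardGeneric("pathLengths"))

#' @rdname PenSimulation-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname TrackSet-class
#' @export
setGeneric("trackRecords", function(x) standardGeneric("trackRecords"))

#' @rdname TrackSet-class
#' @export
setGeneric("nTracks", function(x) standardGeneric("nTracks"))

#' @rdname PerceptualHash-class
#' @export
setGeneric("hashBits", function(x) standardGeneric("hashBits"))

#' @rdname PerceptualHash-class
#' @export
setGeneric("hashHex", function(x) standardGeneric("hashHex"))
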