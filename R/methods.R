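## accessors and show methods

#' @rdname MotMetrics-class
#' @aliases mota motp motCounts
#' @exportMethod mota
setMethod("mota", "MotMetrics", function(x) x@mota)

#' @rdname MotMetrics-class
#' @exportMethod motp
setMethod("motp", "MotMetrics", function(x) x@motp)

#' @rdname MotMetrics-class
#' @exportMethod motCounts
setMethod("motCounts", "MotMetrics", function(x) x@counts)

#' @rdname PrCurve-class
#' @exportMethod averagePrecisionValue
setMethod("averagePrecisionValue", "PrCurve", function(x) x@ap)

#' @rdname PenSimulation-class
#' @exportMethod occupancy
setMethod("occupancy", "PenSimulation", function(x) x@occupancy)

#' @rdname PenSimulation-class
#' @exportMethod pathLengths
setMethod("pathLengths", "PenSimulation", function(x) x@pathLength)

#' @rdname PenSimulation-class
#' @exportMethod groundTruth
setMethod("groundTruth", "PenSimulation", function(x) x@states)

#' @rdname TrackSet-class
#' @exportMethod trackRecords
setMethod("trackRecords", "TrackSet", function(x) x@records)

#' @rdname TrackSet-class
#' @exportMethod nTracks
setMethod("nTracks", "TrackSet",
          function(x) length(unique(x@records$track_id)))

#' @rdname PerceptualHash-class
#' @exportMethod hashBits
setMethod("hashBits", "PerceptualHash", function(x) as.integer(x@bits))

#' @rdname PerceptualHash-class
#' @exportMethod hashHex
setMethod("hashHex", "PerceptualHash", function(x) {
    nib <- vapply(seq(1, 64, by = 4), function(i)
        sum(as.integer(x@bits[i:(i + 3)]) * c(8L, 4L, 2L, 1L)), numeric(1))
    paste(format.hexmode(as.integer(nib)), collapse = "")
})

setMethod("show", "PerceptualHash", function(object)
    cat("PerceptualHash <", hashHex(object), ">\n", sep = ""))

setMethod("show", "MotMetrics", function(object) {
    cts <- object@counts
    cat(sprintf("MotMetrics: MOTA = %.4f, MOTP = %.4f (%s)\n",
                object@mota, object@motp, object@metric))
    cat(sprintf("  GT %d | FN %d | FP %d | IDSW %d over %d frames\n",
                sum(cts$gt), sum(cts$fn), sum(cts$fp), sum(cts$idsw),
                nrow(cts)))
})

setMethod("show", "PrCurve", function(object)
    cat(sprintf("PrCurve [%s]: AP = %.4f (%d detections, %d GT)\n",
                object@label, object@ap, length(object@tp), object@nGt)))

setMethod("show", "PenSimulation", function(object) {
    p <- object@param
    cat(sprintf(
        "PenSimulation: %d pigs, %d frames (%g s @ %g FPS), %gx%g px\n",
        p@nAnimals, length(unique(object@states$frame)),
        p@duration, p@fps, p@width, p@height))
    cat("  occupancy (mean over pigs):",
        paste(sprintf("%s %.2f", colnames(object@occupancy),
                      colMeans(object@occupancy)), collapse = ", "), "\n")
})

setMethod("show", "TrackSet", function(object) {
    cat(sprintf("TrackSet: %d tracks over %d frames (%d records)\n",
                nTracks(object), object@nFrames, nrow(object@records)))
})
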