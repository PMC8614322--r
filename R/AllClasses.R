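#' @import methods
#' @importFrom stats median rnorm runif rpois rbinom sd setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Posture class labels
#'
#' The closed three-class posture set used throughout the package:
#' \code{standing_pig} (feet/snout contact only), \code{sl_pig} (sternal
#' lying: belly and folded limbs on the floor) and \code{ll_pig} (lateral
#' lying: side trunk and extended limbs).
#'
#' @return Character vector of the three valid labels, in canonical order.
#' @export
#' @examples
#' postureLabels()
postureLabels <- function() c("standing_pig", "sl_pig", "ll_pig")

.checkPosture <- function(label) {
    bad <- setdiff(unique(as.character(label)), postureLabels())
    if (length(bad))
        stop("unknown posture label(s) ", paste(sQuote(bad), collapse = ", "),
             "; valid labels are ", paste(postureLabels(), collapse = ", "))
    invisible(TRUE)
}

## ---- parameter classes -----------------------------------------------------

#' @rdname trackerParam
#' @export
setClass("TrackerParam", representation(
    maxAge = "integer", iouGate = "numeric", clipLength = "numeric",
    fps = "numeric", posWeight = "numeric", velWeight = "numeric",
    appearanceWeight = "numeric"),
    prototype(maxAge = 50L, iouGate = 0.3, clipLength = 60, fps = 5,
              posWeight = 1 / 20, velWeight = 1 / 160, appearanceWeight = 0))

setValidity("TrackerParam", function(object) {
    msg <- NULL
    if (object@maxAge < 1L) msg <- c(msg, "maxAge must be >= 1")
    if (object@iouGate <= 0 || object@iouGate >= 1)
        msg <- c(msg, "iouGate must lie in (0, 1)")
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (object@appearanceWeight < 0 || object@appearanceWeight > 1)
        msg <- c(msg, "appearanceWeight must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Tracker configuration
#'
#' Parameters of the tracking-by-detection loop: a track is retired after
#' \code{maxAge} consecutive unmatched frames (50 in the source study);
#' assignments with IoU below \code{iouGate} are severed; clips are
#' \code{clipLength} seconds at \code{fps} frames per second (1-min clips at
#' 5 FPS by default). \code{posWeight}/\code{velWeight} scale the Kalman
#' noise standard deviations relative to box height.
#'
#' @param maxAge integer; frames a track survives without a match.
#' @param iouGate minimum IoU for a valid track/detection match.
#' @param clipLength clip length in seconds.
#' @param fps frames per second of the detection stream.
#' @param posWeight,velWeight Kalman noise scales (fraction of box height).
#' @param appearanceWeight weight in [0,1] given to an appearance cost hook
#'   (see \code{\link{runClip}}); 0 uses pure IoU/motion cost.
#' @return A \code{TrackerParam} object.
#' @export
#' @examples
#' trackerParam(maxAge = 50, fps = 5)
trackerParam <- function(maxAge = 50L, iouGate = 0.3, clipLength = 60,
                         fps = 5, posWeight = 1 / 20, velWeight = 1 / 160,
                         appearanceWeight = 0) {
    new("TrackerParam", maxAge = as.integer(maxAge), iouGate = iouGate,
        clipLength = clipLength, fps = fps, posWeight = posWeight,
        velWeight = velWeight, appearanceWeight = appearanceWeight)
}

#' @rdname activityParam
#' @export
setClass("ActivityParam", representation(
    walkThreshold = "numeric", fps = "numeric"),
    prototype(walkThreshold = 4, fps = 5))

setValidity("ActivityParam", function(object) {
    msg <- NULL
    if (object@walkThreshold <= 0) msg <- c(msg, "walkThreshold must be > 0")
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Activity-scoring configuration
#'
#' A standing pig whose centroid moves more than \code{walkThreshold} pixels
#' between consecutive frames is scored as walking (4 px at the working
#' 640x640 resolution by default; the threshold is exposed because the
#' original frame space is a convention, not a law).
#'
#' @param walkThreshold centroid displacement (pixels) above which a
#'   standing pig counts as walking.
#' @param fps frames per second, used to convert distances to speeds.
#' @return An \code{ActivityParam} object.
#' @export
#' @examples
#' activityParam(walkThreshold = 4, fps = 5)
activityParam <- function(walkThreshold = 4, fps = 5)
    new("ActivityParam", walkThreshold = walkThreshold, fps = fps)

#' @rdname penParam
#' @export
setClass("PenParam", representation(
    width = "numeric", height = "numeric", nAnimals = "integer",
    fps = "numeric", duration = "numeric", transition = "matrix",
    walkSpeedMean = "numeric", walkSpeedSd = "numeric", headingSd = "numeric",
    feeder = "numeric", boxSizes = "matrix", initPosture = "character",
    seed = "integer"))

.defaultTransition <- function() {
    ## slow per-frame switching at 5 FPS; stationary mass concentrates on the
    ## lying states, echoing the dominance of lying in housed fattening pigs
    m <- matrix(c(
        0.970, 0.020, 0.010,
        0.010, 0.970, 0.020,
        0.004, 0.016, 0.980), nrow = 3, byrow = TRUE)
    dimnames(m) <- list(postureLabels(), postureLabels())
    m
}

.defaultBoxSizes <- function() {
    ## top-view footprint (width, height) per posture; lateral lying is the
    ## widest silhouette (extended limbs), standing the most compact
    m <- matrix(c(80, 40, 100, 56, 120, 72), nrow = 3, byrow = TRUE)
    dimnames(m) <- list(postureLabels(), c("w", "h"))
    m
}

setValidity("PenParam", function(object) {
    msg <- NULL
    if (object@nAnimals < 1L) msg <- c(msg, "nAnimals must be >= 1")
    if (object@width <= 0 || object@height <= 0)
        msg <- c(msg, "arena dimensions must be positive")
    tm <- object@transition
    if (!all(dim(tm) == c(3L, 3L)) || any(tm < 0) ||
        any(abs(rowSums(tm) - 1) > 1e-8))
        msg <- c(msg, "transition must be a 3x3 row-stochastic matrix")
    if (length(object@feeder) && length(object@feeder) != 4L)
        msg <- c(msg, "feeder must be numeric(0) or (x_min,y_min,x_max,y_max)")
    if (length(object@feeder) == 4L) {
        f <- object@feeder
        if (f[1] < 0 || f[2] < 0 || f[3] > object@width ||
            f[4] > object@height || f[3] <= f[1] || f[4] <= f[2])
            msg <- c(msg, "feeder rectangle must lie inside the arena")
    }
    if (is.null(msg)) TRUE else msg
})

#' Pen-simulation configuration
#'
#' World model for the synthetic top-view pen: \code{nAnimals} pigs in a
#' \code{width} x \code{height} pixel arena (640x640 by default, the working
#' frame size), posture evolving as a per-frame Markov chain over
#' \code{\link{postureLabels}}, standing pigs taking heading-persistent
#' Gaussian random-walk steps, lying pigs stationary. Pigs whose centre falls
#' inside the \code{feeder} rectangle are invisible (the study pen had a
#' large feeder that hid pigs from the ceiling camera); pass
#' \code{feeder = NULL} for an unoccluded pen.
#'
#' @param width,height arena size in pixels.
#' @param nAnimals number of pigs (5 in the source study).
#' @param fps frames per second.
#' @param duration clip duration in seconds.
#' @param transition 3x3 row-stochastic per-frame posture transition matrix
#'   (rows/cols in \code{postureLabels()} order).
#' @param walkSpeedMean,walkSpeedSd step-length distribution (pixels/frame)
#'   of standing pigs.
#' @param headingSd per-frame heading diffusion (radians) of the walk.
#' @param feeder occlusion rectangle \code{c(x_min, y_min, x_max, y_max)} or
#'   \code{NULL}; the default covers ~15\% of the arena.
#' @param boxSizes 3x2 matrix of box (width, height) per posture.
#' @param initPosture \code{NULL} to draw initial postures from the
#'   chain's stationary distribution, or a single posture label forced on
#'   every pig at frame 1.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return A \code{PenParam} object.
#' @export
#' @examples
#' penParam(nAnimals = 5, duration = 60, seed = 1)
penParam <- function(width = 640, height = 640, nAnimals = 5L, fps = 5,
                     duration = 60, transition = .defaultTransition(),
                     walkSpeedMean = 3, walkSpeedSd = 1, headingSd = 0.5,
                     feeder = c(480, 0, 640, 384),
                     boxSizes = .defaultBoxSizes(), initPosture = NULL,
                     seed = 1L) {
    if (is.null(feeder)) feeder <- numeric(0)
    if (is.null(initPosture)) initPosture <- character(0)
    if (length(initPosture)) .checkPosture(initPosture)
    new("PenParam", width = width, height = height,
        nAnimals = as.integer(nAnimals), fps = fps, duration = duration,
        transition = transition, walkSpeedMean = walkSpeedMean,
        walkSpeedSd = walkSpeedSd, headingSd = headingSd,
        feeder = as.numeric(feeder), boxSizes = boxSizes,
        initPosture = as.character(initPosture), seed = as.integer(seed))
}

#' @rdname noiseParam
#' @export
setClass("NoiseParam", representation(
    missRate = "numeric", fpRate = "numeric", jitterSd = "numeric",
    labelFlipRate = "numeric", seed = "integer"),
    prototype(missRate = 0, fpRate = 0, jitterSd = 0, labelFlipRate = 0,
              seed = 1L))

setValidity("NoiseParam", function(object) {
    msg <- NULL
    if (object@missRate < 0 || object@missRate > 1)
        msg <- c(msg, "missRate must lie in [0, 1]")
    if (object@labelFlipRate < 0 || object@labelFlipRate > 1)
        msg <- c(msg, "labelFlipRate must lie in [0, 1]")
    if (object@fpRate < 0) msg <- c(msg, "fpRate must be >= 0")
    if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Detector noise model
#'
#' Imperfections of the (simulated) detector: each visible pig is missed
#' independently with probability \code{missRate}; box centre and size are
#' jittered with Gaussian sd \code{jitterSd} pixels; \code{fpRate} spurious
#' boxes per frame are added (Poisson); labels flip to a random other
#' posture with probability \code{labelFlipRate}.
#'
#' @param missRate per-detection miss probability in [0,1].
#' @param fpRate expected false positives per frame.
#' @param jitterSd coordinate jitter sd in pixels.
#' @param labelFlipRate posture mislabelling probability in [0,1].
#' @param seed integer seed for the noise draws.
#' @return A \code{NoiseParam} object.
#' @export
#' @examples
#' noiseParam(missRate = 0.05, seed = 7)
noiseParam <- function(missRate = 0, fpRate = 0, jitterSd = 0,
                       labelFlipRate = 0, seed = 1L)
    new("NoiseParam", missRate = missRate, fpRate = fpRate,
        jitterSd = jitterSd, labelFlipRate = labelFlipRate,
        seed = as.integer(seed))

## ---- data containers -------------------------------------------------------

#' PerceptualHash class
#'
#' A 64-bit visual fingerprint of a frame: the 8x8 low-frequency block of
#' the image's 2-D DCT, ravelled row-major and thresholded at its median.
#'
#' @slot bits logical vector of exactly 64 bits.
#' @seealso \code{\link{computePhash}}, \code{\link{hammingDistance}}
#' @export
setClass("PerceptualHash", representation(bits = "logical"))

setValidity("PerceptualHash", function(object) {
    if (length(object@bits) != 64L) "a perceptual hash has exactly 64 bits"
    else if (anyNA(object@bits)) "hash bits must not be NA"
    else TRUE
})

#' PenSimulation class
#'
#' Ground truth produced by \code{\link{simulatePen}}: per-(frame, animal)
#' state (centre, box, posture, visibility), per-animal path length under
#' the walking rule, and per-animal posture occupancy fractions.
#'
#' @slot param the \code{PenParam} used.
#' @slot states data.frame with one row per (frame, animal).
#' @slot pathLength numeric, per-animal walking distance in pixels.
#' @slot occupancy animals x 3 matrix of posture occupancy fractions
#'   (rows sum to 1).
#' @export
setClass("PenSimulation", representation(
    param = "PenParam", states = "data.frame", pathLength = "numeric",
    occupancy = "matrix"))

setValidity("PenSimulation", function(object) {
    msg <- NULL
    need <- c("frame", "animal", "cx", "cy", "posture", "visible",
              "x_min", "y_min", "x_max", "y_max")
    if (!all(need %in% names(object@states)))
        msg <- c(msg, "states is missing required columns")
    if (nrow(object@occupancy) &&
        any(abs(rowSums(object@occupancy) - 1) > 1e-8))
        msg <- c(msg, "occupancy fractions must sum to 1 per animal")
    if (any(object@pathLength < 0)) msg <- c(msg, "path lengths must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' TrackSet class
#'
#' The output of \code{\link{runClip}}: identity-preserving tracks over one
#' clip, stored as a long data.frame of per-frame records (frame, track_id,
#' box corners, posture label, confidence). Retired tracks are included.
#'
#' @slot records data.frame of per-frame track records.
#' @slot param the \code{TrackerParam} used.
#' @slot nFrames number of frames the clip spans.
#' @export
setClass("TrackSet", representation(
    records = "data.frame", param = "TrackerParam", nFrames = "integer"))

setValidity("TrackSet", function(object) {
    need <- c("frame", "track_id", "x_min", "y_min", "x_max", "y_max",
              "label", "confidence")
    if (!all(need %in% names(object@records)))
        "records is missing required columns"
    else TRUE
})

#' MotMetrics class
#'
#' CLEAR-MOT evaluation result: MOTA = 1 - (FN + FP + IDSW) / GT, and MOTP =
#' mean match quality (IoU by default, higher is better; optionally centre
#' distance, lower is better), with the per-frame accumulator table.
#'
#' @slot mota multi-object tracking accuracy (at most 1; can be negative).
#' @slot motp multi-object tracking precision.
#' @slot counts per-frame data.frame of gt, fn, fp, idsw, matches, sum_d.
#' @slot metric "iou" or "center".
#' @export
setClass("MotMetrics", representation(
    mota = "numeric", motp = "numeric", counts = "data.frame",
    metric = "character"))

setValidity("MotMetrics", function(object) {
    msg <- NULL
    if (object@mota > 1 + 1e-12) msg <- c(msg, "MOTA cannot exceed 1")
    cts <- object@counts
    if (nrow(cts)) {
        if (any(cts$fn > cts$gt)) msg <- c(msg, "FN_i cannot exceed GT_i")
        if (any(cts$matches > cts$gt))
            msg <- c(msg, "matches cannot exceed GT_i")
        if (any(cts$fn < 0 | cts$fp < 0 | cts$idsw < 0 | cts$gt < 0))
            msg <- c(msg, "counts must be nonnegative")
    }
    if (is.null(msg)) TRUE else msg
})

#' PrCurve class
#'
#' Ranked precision-recall curve of one detection class with its
#' all-point-interpolated average precision.
#'
#' @slot label posture class evaluated.
#' @slot confidence detection confidences in ranked (descending) order.
#' @slot tp logical; whether each ranked detection is a true positive.
#' @slot precision,recall cumulative precision/recall along the ranking.
#' @slot ap average precision in [0, 1].
#' @slot nGt number of ground-truth boxes of the class.
#' @export
setClass("PrCurve", representation(
    label = "character", confidence = "numeric", tp = "logical",
    precision = "numeric", recall = "numeric", ap = "numeric",
    nGt = "integer"))

setValidity("PrCurve", function(object) {
    msg <- NULL
    if (object@ap < -1e-12 || object@ap > 1 + 1e-12)
        msg <- c(msg, "AP must lie in [0, 1]")
    if (length(object@recall) > 1 && any(diff(object@recall) < -1e-12))
        msg <- c(msg, "recall must be nondecreasing along the ranking")
    if (is.null(msg)) TRUE else msg
})
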