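## ethogram read-outs: walking, distance, speed, posture scores, phases

#' Walking classification for one frame pair
#'
#' A standing pig whose centroid moved more than the walking threshold
#' (4 px between consecutive frames by default) is considered walking; the
#' rule never fires for lying pigs, whatever their displacement (detector
#' jitter on a resting pig is not locomotion).
#'
#' @param prev,cur centroids \code{c(cx, cy)} at the earlier/later frame.
#' @param prevPosture,curPosture posture labels at the two frames.
#' @param param an \code{\link{activityParam}}.
#' @return List with \code{walking} (logical) and \code{dd}, the Euclidean
#'   centroid displacement in pixels.
#' @export
#' @examples
#' classifyWalking(c(10, 10), c(13, 14), "standing_pig", "standing_pig")
classifyWalking <- function(prev, cur, prevPosture, curPosture,
                            param = activityParam()) {
    dd <- centroidDistance(prev, cur)
    walking <- identical(prevPosture, "standing_pig") &&
        identical(curPosture, "standing_pig") && dd > param@walkThreshold
    list(walking = walking, dd = dd)
}

.trackSplit <- function(x) {
    records <- if (is(x, "TrackSet")) trackRecords(x) else x
    split(records, records$track_id)
}

#' Locomotion summary per track
#'
#' Sums the supra-threshold standing displacements of each track into a
#' total distance, and derives two speeds: \code{speed_walking}, distance
#' over the time actually spent walking (the headline value), and
#' \code{speed_overall}, distance over the clip's wall-clock span. Sums
#' restricted to walking pairs keep sub-threshold detector jitter out of
#' the distance budget; the unfiltered sum is also returned as
#' \code{raw_displacement} for comparison.
#'
#' @param x a \code{\linkS4class{TrackSet}} or its records data.frame.
#' @param param an \code{\link{activityParam}}.
#' @return data.frame with one row per track: \code{track_id},
#'   \code{total_distance} (px), \code{walking_pairs},
#'   \code{speed_walking} and \code{speed_overall} (px/s),
#'   \code{raw_displacement} (px).
#' @export
locomotionSummary <- function(x, param = activityParam()) {
    perTrack <- lapply(.trackSplit(x), function(tr) {
        tr <- tr[order(tr$frame), ]
        n <- nrow(tr)
        if (n < 2L)
            return(data.frame(track_id = tr$track_id[1],
                              total_distance = 0, walking_pairs = 0L,
                              speed_walking = 0, speed_overall = 0,
                              raw_displacement = 0))
        dx <- diff(tr$x_min + tr$x_max) / 2
        dy <- diff(tr$y_min + tr$y_max) / 2
        dd <- sqrt(dx^2 + dy^2)
        consecutive <- diff(tr$frame) == 1L
        standing <- tr$label[-n] == "standing_pig" &
            tr$label[-1L] == "standing_pig"
        walking <- consecutive & standing & dd > param@walkThreshold
        total <- sum(dd[walking])
        nw <- sum(walking)
        span <- (tr$frame[n] - tr$frame[1]) / param@fps
        data.frame(track_id = tr$track_id[1], total_distance = total,
                   walking_pairs = as.integer(nw),
                   speed_walking = if (nw) total / (nw / param@fps) else 0,
                   speed_overall = if (span > 0) total / span else 0,
                   raw_displacement = sum(dd[consecutive]))
    })
    out <- do.call(rbind, perTrack)
    rownames(out) <- NULL
    out
}

#' Individual posture/activity score
#'
#' The fraction of a clip's frames in which pig i shows activity a:
#' P_i(a) = sum_k AF_k / n, with AF_k the indicator that frame k shows the
#' activity and n the clip's total frame count. Frames in which the pig is
#' undetected (occluded or missed) contribute 0 to the numerator but stay
#' in the denominator, so heavy occlusion depresses all of a pig's scores
#' rather than silently renormalising them.
#'
#' @param x a \code{\linkS4class{TrackSet}} or records data.frame (one
#'   track's records, or several — scores are computed per track).
#' @param activity one of \code{postureLabels()} or \code{"walking"}.
#' @param nFrames total frames n of the clip.
#' @param param an \code{\link{activityParam}} (used for walking).
#' @return data.frame with \code{track_id}, \code{activity}, \code{score}
#'   in [0, 1] and \code{n_frames}.
#' @export
#' @examples
#' recs <- data.frame(frame = 1:10, track_id = 1, x_min = 0, y_min = 0,
#'                    x_max = 10, y_max = 10, label = "ll_pig",
#'                    confidence = 1)
#' postureScoreIndividual(recs, "ll_pig", nFrames = 10)$score
postureScoreIndividual <- function(x, activity, nFrames,
                                   param = activityParam()) {
    stopifnot(nFrames >= 1)
    if (!activity %in% c(postureLabels(), "walking"))
        stop("activity must be one of ",
             paste(c(postureLabels(), "walking"), collapse = ", "))
    perTrack <- lapply(.trackSplit(x), function(tr) {
        tr <- tr[order(tr$frame), ]
        hits <- if (activity == "walking") .walkingFrames(tr, param)
                else sum(tr$label == activity)
        data.frame(track_id = tr$track_id[1], activity = activity,
                   score = hits / nFrames, n_frames = as.integer(nFrames))
    })
    out <- do.call(rbind, perTrack)
    rownames(out) <- NULL
    out
}

## frames credited as walking: a frame counts when it participates in a
## supra-threshold standing pair with its predecessor
.walkingFrames <- function(tr, param) {
    n <- nrow(tr)
    if (n < 2L) return(0L)
    dx <- diff(tr$x_min + tr$x_max) / 2
    dy <- diff(tr$y_min + tr$y_max) / 2
    dd <- sqrt(dx^2 + dy^2)
    walking <- (diff(tr$frame) == 1L) &
        tr$label[-n] == "standing_pig" & tr$label[-1L] == "standing_pig" &
        dd > param@walkThreshold
    sum(walking)
}

#' Group posture/activity score
#'
#' The average number of pigs per frame showing an activity: the sum over
#' frames of the per-frame count, divided by the clip's frame count. Equals
#' the sum of the individual scores over pigs, and ranges from 0 to the
#' group size.
#'
#' @inheritParams postureScoreIndividual
#' @return data.frame with \code{subject = "group"}, \code{activity},
#'   \code{score} and \code{n_frames}.
#' @export
postureScoreGroup <- function(x, activity, nFrames,
                              param = activityParam()) {
    ind <- postureScoreIndividual(x, activity, nFrames, param)
    data.frame(subject = "group", activity = activity,
               score = sum(ind$score), n_frames = as.integer(nFrames))
}

#' Full activity score table for a clip
#'
#' Individual and group scores for the three postures plus walking, in one
#' tidy table. Walking overlaps standing (it is a sub-state), so scores
#' over the three postures sum to the detected fraction, while walking is
#' reported alongside.
#'
#' @inheritParams postureScoreIndividual
#' @return data.frame with columns \code{subject}, \code{activity},
#'   \code{score}, \code{n_frames}.
#' @export
activityScores <- function(x, nFrames, param = activityParam()) {
    acts <- c(postureLabels(), "walking")
    rows <- lapply(acts, function(a) {
        ind <- postureScoreIndividual(x, a, nFrames, param)
        rbind(data.frame(subject = as.character(ind$track_id),
                         activity = a, score = ind$score,
                         n_frames = ind$n_frames),
              data.frame(subject = "group", activity = a,
                         score = sum(ind$score),
                         n_frames = as.integer(nFrames)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Aggregate hourly scores into treatment-phase profiles
#'
#' Summarises per-hour activity scores across replicate days for each
#' (session, phase, activity) cell — sessions are the daily treatment
#' windows (e.g. morning/day/night) and phases the hours before, during
#' and after the ventilation-closure treatment. Reports the mean and
#' sample sd across days; a cell observed on a single day gets sd 0 and is
#' flagged \code{insufficient_replicates}; absent cells are simply not
#' reported.
#'
#' @param hourly data.frame with columns \code{day}, \code{session},
#'   \code{phase}, \code{activity}, \code{score} (one row per replicate
#'   hour).
#' @return data.frame with \code{session}, \code{phase}, \code{activity},
#'   \code{mean}, \code{sd}, \code{n_days},
#'   \code{insufficient_replicates}.
#' @export
#' @examples
#' h <- expand.grid(day = 1:3, session = "morning", phase = "before",
#'                  activity = "standing_pig")
#' h$score <- c(0.2, 0.4, 0.6)
#' phaseAggregate(h)
phaseAggregate <- function(hourly) {
    need <- c("day", "session", "phase", "activity", "score")
    if (!all(need %in% names(hourly)))
        stop("hourly table needs columns ", paste(need, collapse = ", "))
    key <- interaction(hourly$session, hourly$phase, hourly$activity,
                       drop = TRUE)
    cells <- lapply(split(hourly, key), function(cell) {
        n <- nrow(cell)
        data.frame(session = as.character(cell$session[1]),
                   phase = as.character(cell$phase[1]),
                   activity = as.character(cell$activity[1]),
                   mean = mean(cell$score),
                   sd = if (n > 1L) stats::sd(cell$score) else 0,
                   n_days = n,
                   insufficient_replicates = n < 2L)
    })
    out <- do.call(rbind, cells)
    rownames(out) <- NULL
    out[order(out$session, out$phase, out$activity), ]
}
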