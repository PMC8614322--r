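## tracking-by-detection: predict -> associate -> update / spawn / retire

.newTrack <- function(id, box, label, confidence, frame, param) {
    list(id = as.integer(id),
         state = kalmanInit(box, param@posWeight, param@velWeight),
         label = label, confidence = confidence,
         timeSinceUpdate = 0L, status = "active",
         history = list(data.frame(
             frame = as.integer(frame), track_id = as.integer(id),
             x_min = box[1], y_min = box[2], x_max = box[3], y_max = box[4],
             label = label, confidence = confidence)))
}

.rasterOrder <- function(dets) order(dets$y_min, dets$x_min)

#' Associate tracks with detections
#'
#' Minimum-total-cost assignment between the tracks' predicted boxes and
#' the current frame's detections, with cost 1 - IoU (optionally blended
#' with a user appearance cost). Assigned pairs whose IoU falls below
#' \code{iouGate} are severed and reported unmatched, so a cheap global
#' assignment cannot force a geometrically absurd match.
#'
#' @param predBoxes data.frame/matrix of predicted track boxes (may have 0
#'   rows).
#' @param detections data.frame of detection boxes (may have 0 rows).
#' @param iouGate minimum IoU for a valid pair.
#' @param costMatrix optional precomputed cost matrix overriding 1 - IoU.
#' @return List with \code{matches} (2-column matrix of track row, detection
#'   row), \code{unmatchedTracks} and \code{unmatchedDetections} (integer row
#'   indices).
#' @export
associateDetections <- function(predBoxes, detections, iouGate = 0.3,
                                costMatrix = NULL) {
    nT <- if (is.null(predBoxes)) 0L else nrow(as.data.frame(predBoxes))
    nD <- if (is.null(detections)) 0L else nrow(as.data.frame(detections))
    if (!nT || !nD)
        return(list(matches = matrix(integer(0), ncol = 2),
                    unmatchedTracks = seq_len(nT),
                    unmatchedDetections = seq_len(nD)))
    iou <- iouMatrix(predBoxes, detections)
    cost <- if (is.null(costMatrix)) 1 - iou else costMatrix
    sol <- solveAssignment(cost)
    matches <- cbind(track = seq_len(nT), det = sol$assignment)
    matches <- matches[!is.na(matches[, 2]), , drop = FALSE]
    keep <- iou[matches] >= iouGate
    matches <- matches[keep, , drop = FALSE]
    list(matches = matches,
         unmatchedTracks = setdiff(seq_len(nT), matches[, 1]),
         unmatchedDetections = setdiff(seq_len(nD), matches[, 2]))
}

#' Advance the tracker by one frame
#'
#' One cycle of the tracking loop: all active tracks are predicted one
#' frame ahead; predicted boxes are associated with the frame's detections
#' (Hungarian on 1 - IoU, gated); matched tracks take a Kalman measurement
#' update, adopt the detection's posture label and reset their missing-frame
#' counter; unmatched tracks coast and are retired once they have been
#' missing for more than \code{maxAge} frames; unmatched detections spawn
#' new tracks with fresh ids (in raster order, for determinism).
#'
#' @param tracks list of track objects (as built by \code{\link{runClip}}).
#' @param detections data.frame of the frame's detections
#'   (\code{\link{boundingBoxes}} columns); may have 0 rows.
#' @param frame integer frame index.
#' @param param a \code{\link{trackerParam}}.
#' @param appearance optional function(track, detectionRow) -> cost in
#'   [0, 1], blended with weight \code{param@appearanceWeight}.
#' @return The updated list of tracks.
#' @export
trackStep <- function(tracks, detections, frame, param = trackerParam(),
                      appearance = NULL) {
    ids <- vapply(tracks, `[[`, integer(1), "id")
    if (anyDuplicated(ids)) stop("internal error: duplicate track ids")
    active <- which(vapply(tracks, `[[`, character(1), "status") == "active")
    ## time update for every live track
    for (i in active)
        tracks[[i]]$state <- kalmanPredict(tracks[[i]]$state,
                                           param@posWeight, param@velWeight)
    predBoxes <- if (length(active))
        do.call(rbind, lapply(tracks[active],
                              function(tr) kalmanBox(tr$state)))
    else NULL
    if (!is.null(predBoxes)) {
        predBoxes <- as.data.frame(predBoxes)
        ## a coasting track can drift to a degenerate box; clamp minimally
        predBoxes$x_max <- pmax(predBoxes$x_max, predBoxes$x_min + 1e-6)
        predBoxes$y_max <- pmax(predBoxes$y_max, predBoxes$y_min + 1e-6)
    }
    cost <- NULL
    w <- param@appearanceWeight
    if (!is.null(appearance) && w > 0 && length(active) &&
        !is.null(detections) && nrow(detections)) {
        iou <- iouMatrix(predBoxes, detections)
        app <- matrix(0, length(active), nrow(detections))
        for (i in seq_along(active))
            for (j in seq_len(nrow(detections)))
                app[i, j] <- appearance(tracks[[active[i]]],
                                        detections[j, , drop = FALSE])
        cost <- (1 - w) * (1 - iou) + w * app
    }
    asc <- associateDetections(predBoxes, detections, param@iouGate,
                               costMatrix = cost)
    for (k in seq_len(nrow(asc$matches))) {
        ti <- active[asc$matches[k, 1]]
        dj <- asc$matches[k, 2]
        det <- detections[dj, ]
        box <- as.numeric(det[c("x_min", "y_min", "x_max", "y_max")])
        tracks[[ti]]$state <- kalmanUpdate(tracks[[ti]]$state, box,
                                           param@posWeight)
        tracks[[ti]]$label <- det$label
        tracks[[ti]]$confidence <- det$confidence
        tracks[[ti]]$timeSinceUpdate <- 0L
        tracks[[ti]]$history[[length(tracks[[ti]]$history) + 1L]] <-
            data.frame(frame = as.integer(frame),
                       track_id = tracks[[ti]]$id,
                       x_min = box[1], y_min = box[2],
                       x_max = box[3], y_max = box[4],
                       label = det$label, confidence = det$confidence)
    }
    for (k in asc$unmatchedTracks) {
        ti <- active[k]
        tracks[[ti]]$timeSinceUpdate <- tracks[[ti]]$timeSinceUpdate + 1L
        if (tracks[[ti]]$timeSinceUpdate > param@maxAge)
            tracks[[ti]]$status <- "retired"
    }
    if (length(asc$unmatchedDetections)) {
        newDets <- detections[asc$unmatchedDetections, , drop = FALSE]
        newDets <- newDets[.rasterOrder(newDets), , drop = FALSE]
        nextId <- if (length(ids)) max(ids) + 1L else 1L
        for (j in seq_len(nrow(newDets))) {
            det <- newDets[j, ]
            box <- as.numeric(det[c("x_min", "y_min", "x_max", "y_max")])
            tracks[[length(tracks) + 1L]] <-
                .newTrack(nextId, box, det$label, det$confidence, frame,
                          param)
            nextId <- nextId + 1L
        }
    }
    tracks
}

#' Track one clip of detections
#'
#' Runs the full tracking-by-detection loop over a clip: pigs in the first
#' frame receive ids 1..k in raster order (sorted by y_min, then x_min);
#' subsequent frames are linked by \code{\link{trackStep}}. Frames with no
#' detections still advance time, so occluded pigs age toward retirement;
#' a pig that reappears within \code{maxAge} frames keeps its id. Ids are
#' seeded per clip — cross-clip identity stitching is out of scope.
#'
#' @param detections data.frame with \code{frame} plus
#'   \code{\link{boundingBoxes}} columns; frame indices need not be
#'   contiguous but must span at most \code{clipLength * fps} frames.
#' @param param a \code{\link{trackerParam}}.
#' @param appearance optional appearance-cost hook, see
#'   \code{\link{trackStep}}.
#' @return A \code{\linkS4class{TrackSet}} (including retired tracks).
#' @export
#' @examples
#' dets <- boundingBoxes(c(0, 100), c(0, 100), c(50, 160), c(40, 150),
#'                       label = "sl_pig", frame = c(1, 1))
#' dets <- rbind(dets, transform(dets, frame = 2L))
#' nTracks(runClip(dets))
runClip <- function(detections, param = trackerParam(), appearance = NULL) {
    if (is.null(detections) || !nrow(detections)) {
        empty <- data.frame(frame = integer(0), track_id = integer(0),
                            x_min = numeric(0), y_min = numeric(0),
                            x_max = numeric(0), y_max = numeric(0),
                            label = character(0), confidence = numeric(0))
        return(new("TrackSet", records = empty, param = param,
                   nFrames = 0L))
    }
    .checkPosture(detections$label)
    frames <- seq(min(detections$frame), max(detections$frame))
    if (length(frames) > param@clipLength * param@fps)
        stop("stream spans ", length(frames), " frames; a clip holds at most ",
             param@clipLength * param@fps)
    first <- detections[detections$frame == frames[1L], , drop = FALSE]
    first <- first[.rasterOrder(first), , drop = FALSE]
    tracks <- list()
    for (j in seq_len(nrow(first))) {
        det <- first[j, ]
        box <- as.numeric(det[c("x_min", "y_min", "x_max", "y_max")])
        tracks[[j]] <- .newTrack(j, box, det$label, det$confidence,
                                 frames[1L], param)
    }
    for (f in frames[-1L]) {
        dets <- detections[detections$frame == f, , drop = FALSE]
        tracks <- trackStep(tracks, dets, f, param, appearance)
    }
    records <- do.call(rbind, unlist(lapply(tracks, `[[`, "history"),
                                     recursive = FALSE))
    records <- records[order(records$frame, records$track_id), ]
    rownames(records) <- NULL
    new("TrackSet", records = records, param = param,
        nFrames = length(frames))
}
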