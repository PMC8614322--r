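## detection and tracking quality against ground truth

#' Match ground-truth and hypothesis boxes in one frame
#'
#' Hungarian assignment maximising total IoU between the two box sets;
#' pairs whose IoU falls below \code{iouThreshold} are severed afterwards.
#'
#' @param gt,hyp data.frames of boxes (\code{\link{boundingBoxes}}
#'   columns); either may be empty.
#' @param iouThreshold minimum IoU for a valid match (0.5 by default; the
#'   localization criterion of the source study uses 0.6).
#' @return List with \code{matches} (columns gt, hyp, iou),
#'   \code{unmatchedGt}, \code{unmatchedHyp} (row indices).
#' @export
matchFrame <- function(gt, hyp, iouThreshold = 0.5) {
    nG <- if (is.null(gt)) 0L else nrow(gt)
    nH <- if (is.null(hyp)) 0L else nrow(hyp)
    if (!nG || !nH)
        return(list(matches = data.frame(gt = integer(0), hyp = integer(0),
                                         iou = numeric(0)),
                    unmatchedGt = seq_len(nG), unmatchedHyp = seq_len(nH)))
    iou <- iouMatrix(gt, hyp)
    sol <- solveAssignment(1 - iou)      # max total IoU
    m <- cbind(gt = seq_len(nG), hyp = sol$assignment)
    m <- m[!is.na(m[, 2]), , drop = FALSE]
    ious <- iou[m]
    keep <- ious >= iouThreshold
    matches <- data.frame(gt = m[keep, 1], hyp = m[keep, 2],
                          iou = ious[keep])
    list(matches = matches,
         unmatchedGt = setdiff(seq_len(nG), matches$gt),
         unmatchedHyp = setdiff(seq_len(nH), matches$hyp))
}

#' CLEAR-MOT evaluation of a tracking hypothesis
#'
#' Frame-by-frame accounting of misses (FN), false positives (FP) and
#' identity switches (IDSW) against identity-labelled ground truth,
#' yielding MOTA = 1 - (FN + FP + IDSW) / GT and MOTP, the mean match
#' quality. Matching is sticky, per the CLEAR-MOT protocol: a ground-truth
#' object keeps its previous hypothesis as long as their overlap stays
#' above threshold, and only unmatched objects enter the per-frame
#' Hungarian step; an IDSW is counted when a matched object's hypothesis id
#' differs from the last id it ever carried.
#'
#' @param gt,hyp data.frames with columns \code{frame}, \code{id} and box
#'   corners; \code{hyp} is typically \code{trackRecords(runClip(...))}
#'   with \code{track_id} renamed to \code{id} (done automatically).
#' @param iouThreshold match gate (0.5 by default).
#' @param metric \code{"iou"} (MOTP = mean IoU of matches, higher better)
#'   or \code{"center"} (mean centroid distance, lower better).
#' @return A \code{\linkS4class{MotMetrics}} object.
#' @export
#' @examples
#' gt <- boundingBoxes(0, 0, 50, 40, label = "sl_pig",
#'                     frame = rep(1:10, each = 1), id = 1)
#' evaluateMot(gt, gt)  # perfect: MOTA 1, MOTP 1
evaluateMot <- function(gt, hyp, iouThreshold = 0.5,
                        metric = c("iou", "center")) {
    metric <- match.arg(metric)
    if (is.null(gt) || !nrow(gt)) stop("MOTA is undefined for empty ground truth")
    if (!"id" %in% names(gt)) stop("ground truth needs an id column")
    if (!"id" %in% names(hyp) && "track_id" %in% names(hyp))
        names(hyp)[names(hyp) == "track_id"] <- "id"
    frames <- sort(unique(c(gt$frame, hyp$frame)))
    lastHyp <- integer(0)                # gt id -> last hypothesis id seen
    carried <- integer(0)                # gt id -> hyp id matched last frame
    rows <- vector("list", length(frames))
    for (fi in seq_along(frames)) {
        f <- frames[fi]
        g <- gt[gt$frame == f, , drop = FALSE]
        h <- hyp[hyp$frame == f, , drop = FALSE]
        nG <- nrow(g); nH <- nrow(h)
        matchedG <- integer(0); matchedH <- integer(0); dvals <- numeric(0)
        idswf <- 0L
        ## sticky continuation of last frame's pairs
        if (nG && nH && length(carried)) {
            for (gid in names(carried)) {
                gi <- match(as.integer(gid), g$id)
                hi <- match(carried[[gid]], h$id)
                if (!is.na(gi) && !is.na(hi)) {
                    ov <- boxIoU(g[gi, ], h[hi, ])
                    if (ov >= iouThreshold) {
                        matchedG <- c(matchedG, gi)
                        matchedH <- c(matchedH, hi)
                        dvals <- c(dvals, if (metric == "iou") ov else
                            centroidDistance(boxCentroid(g[gi, ]),
                                             boxCentroid(h[hi, ])))
                    }
                }
            }
        }
        ## Hungarian on the remainder
        restG <- setdiff(seq_len(nG), matchedG)
        restH <- setdiff(seq_len(nH), matchedH)
        if (length(restG) && length(restH)) {
            mf <- matchFrame(g[restG, , drop = FALSE],
                             h[restH, , drop = FALSE], iouThreshold)
            if (nrow(mf$matches)) {
                gi <- restG[mf$matches$gt]
                hi <- restH[mf$matches$hyp]
                matchedG <- c(matchedG, gi)
                matchedH <- c(matchedH, hi)
                dvals <- c(dvals, if (metric == "iou") mf$matches$iou else
                    mapply(function(a, b) centroidDistance(
                        boxCentroid(g[a, ]), boxCentroid(h[b, ])), gi, hi))
            }
        }
        ## identity bookkeeping
        newCarried <- integer(0)
        for (k in seq_along(matchedG)) {
            gid <- as.character(g$id[matchedG[k]])
            hid <- h$id[matchedH[k]]
            prev <- if (gid %in% names(lastHyp)) lastHyp[[gid]]
                    else NA_integer_
            if (!is.na(prev) && prev != hid) idswf <- idswf + 1L
            lastHyp[gid] <- hid
            newCarried[gid] <- hid
        }
        carried <- newCarried
        rows[[fi]] <- data.frame(
            frame = f, gt = nG, fn = nG - length(matchedG),
            fp = nH - length(matchedH), idsw = idswf,
            matches = length(matchedG), sum_d = sum(dvals))
    }
    counts <- do.call(rbind, rows)
    totGT <- sum(counts$gt)
    if (totGT == 0) stop("MOTA is undefined for empty ground truth")
    mota <- 1 - (sum(counts$fn) + sum(counts$fp) + sum(counts$idsw)) / totGT
    nMatch <- sum(counts$matches)
    motp <- if (nMatch) sum(counts$sum_d) / nMatch else NA_real_
    new("MotMetrics", mota = mota, motp = motp, counts = counts,
        metric = metric)
}

#' Average precision of one detection class
#'
#' Pascal-VOC style evaluation of ranked detections: detections of the
#' class are sorted by descending confidence and matched greedily to the
#' unconsumed ground-truth box of the same frame with the highest IoU; a
#' detection is a true positive when that IoU reaches \code{iouThreshold},
#' otherwise a false positive (including duplicate hits on an already
#' consumed box). AP is the all-point-interpolated area under the
#' precision-recall curve.
#'
#' @param detections data.frame with \code{frame}, box corners,
#'   \code{label}, \code{confidence}.
#' @param gt data.frame with \code{frame}, box corners, \code{label}.
#' @param label the posture class to evaluate.
#' @param iouThreshold localization gate (0.5 by default, as in the
#'   headline mAP of the source study; 0.6 is its stricter localization
#'   criterion).
#' @return A \code{\linkS4class{PrCurve}}.
#' @export
averagePrecision <- function(detections, gt, label,
                             iouThreshold = 0.5) {
    det <- detections[detections$label == label, , drop = FALSE]
    gtc <- gt[gt$label == label, , drop = FALSE]
    nGt <- nrow(gtc)
    if (!nrow(det))
        return(new("PrCurve", label = label, confidence = numeric(0),
                   tp = logical(0), precision = numeric(0),
                   recall = numeric(0), ap = 0, nGt = as.integer(nGt)))
    ## deterministic ranking: confidence desc, then frame, then x_min
    ord <- order(-det$confidence, det$frame, det$x_min)
    det <- det[ord, , drop = FALSE]
    consumed <- rep(FALSE, nGt)
    tp <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
        cand <- which(gtc$frame == det$frame[i] & !consumed)
        if (!length(cand)) next
        ious <- vapply(cand, function(j) boxIoU(det[i, ], gtc[j, ]),
                       numeric(1))
        best <- which.max(ious)
        if (ious[best] >= iouThreshold) {
            tp[i] <- TRUE
            consumed[cand[best]] <- TRUE
        }
    }
    cumTp <- cumsum(tp)
    precision <- cumTp / seq_along(tp)
    recall <- if (nGt) cumTp / nGt else rep(0, length(tp))
    ap <- if (nGt) .apAllPoint(recall, precision) else 0
    new("PrCurve", label = label, confidence = det$confidence, tp = tp,
        precision = precision, recall = recall, ap = ap,
        nGt = as.integer(nGt))
}

## all-point interpolation (VOC 2010+): area under the monotone envelope
.apAllPoint <- function(recall, precision) {
    mrec <- c(0, recall, 1)
    mpre <- c(0, precision, 0)
    for (i in rev(seq_len(length(mpre) - 1L)))
        mpre[i] <- max(mpre[i], mpre[i + 1L])
    idx <- which(mrec[-1L] != mrec[-length(mrec)])
    sum((mrec[idx + 1L] - mrec[idx]) * mpre[idx + 1L])
}

#' Mean average precision over classes
#'
#' @param curves a list of \code{\linkS4class{PrCurve}} objects, or the
#'   \code{detections}/\code{gt} pair to evaluate all of
#'   \code{postureLabels()}.
#' @param gt,iouThreshold see \code{\link{averagePrecision}}; used only
#'   when \code{curves} is a detection table.
#' @return Unweighted mean of the class APs.
#' @export
#' @examples
#' gt <- boundingBoxes(0, 0, 50, 40, label = "ll_pig", frame = 1)
#' det <- transform(gt, confidence = 0.9)
#' meanAveragePrecision(det, gt)
meanAveragePrecision <- function(curves, gt = NULL, iouThreshold = 0.5) {
    if (is.data.frame(curves)) {
        stopifnot(!is.null(gt))
        labs <- intersect(postureLabels(), unique(gt$label))
        curves <- lapply(labs, function(l)
            averagePrecision(curves, gt, l, iouThreshold))
    }
    if (!length(curves)) stop("need at least one class")
    mean(vapply(curves, averagePrecisionValue, numeric(1)))
}
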