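## box algebra in the continuous corner convention:
## width = x_max - x_min (no +1), origin top-left, y downward

.asBox <- function(b) {
    if (is.data.frame(b)) b <- unlist(b[1, c("x_min", "y_min", "x_max", "y_max")])
    b <- as.numeric(b)[1:4]
    if (anyNA(b)) stop("box coordinates must be numeric and non-missing")
    if (b[3] <= b[1] || b[4] <= b[2])
        stop("degenerate box: require x_max > x_min and y_max > y_min")
    b
}

#' Bounding-box table constructor
#'
#' Builds the canonical detection/annotation table used across the package:
#' one row per box with continuous corner coordinates (origin at the image
#' top-left, x rightward, y downward), a posture label from
#' \code{\link{postureLabels}} and a confidence in [0, 1] (1 for ground
#' truth).
#'
#' @param x_min,y_min,x_max,y_max box corners in pixels.
#' @param label posture label(s).
#' @param confidence detection confidence(s) in [0, 1].
#' @param frame optional frame index column.
#' @param id optional identity column (ground-truth / track id).
#' @return A data.frame with one row per box.
#' @export
#' @examples
#' boundingBoxes(0, 0, 10, 10, label = "standing_pig")
boundingBoxes <- function(x_min, y_min, x_max, y_max,
                          label = "standing_pig", confidence = 1,
                          frame = NULL, id = NULL) {
    df <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                     x_max = as.numeric(x_max), y_max = as.numeric(y_max),
                     label = as.character(label),
                     confidence = as.numeric(confidence))
    if (!is.null(frame)) df <- cbind(frame = as.integer(frame), df)
    if (!is.null(id)) df <- cbind(df, id = as.integer(id))
    if (nrow(df)) {
        if (any(df$x_max <= df$x_min) || any(df$y_max <= df$y_min))
            stop("degenerate box: require x_max > x_min and y_max > y_min")
        .checkPosture(df$label)
        if (any(df$confidence < 0 | df$confidence > 1))
            stop("confidence must lie in [0, 1]")
    }
    df
}

#' Intersection over union of two boxes
#'
#' The localization score of detection evaluation: intersection area divided
#' by union area. Symmetric, bounded in [0, 1], 0 for disjoint boxes and 1
#' iff the boxes coincide.
#'
#' @param a,b boxes as \code{c(x_min, y_min, x_max, y_max)} or 1-row
#'   data.frames with those columns.
#' @return IoU in [0, 1].
#' @export
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 1/7
boxIoU <- function(a, b) {
    a <- .asBox(a); b <- .asBox(b)
    iw <- min(a[3], b[3]) - max(a[1], b[1])
    ih <- min(a[4], b[4]) - max(a[2], b[2])
    if (iw <= 0 || ih <= 0) return(0)
    inter <- iw * ih
    union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) -
        inter
    inter / union
}

#' Pairwise IoU matrix
#'
#' @param A,B matrices or data.frames of boxes (columns
#'   \code{x_min, y_min, x_max, y_max}), one row per box.
#' @return \code{nrow(A)} x \code{nrow(B)} matrix of IoU values.
#' @export
iouMatrix <- function(A, B) {
    cols <- c("x_min", "y_min", "x_max", "y_max")
    A <- as.matrix(as.data.frame(A)[, cols, drop = FALSE])
    B <- as.matrix(as.data.frame(B)[, cols, drop = FALSE])
    nA <- nrow(A); nB <- nrow(B)
    out <- matrix(0, nA, nB)
    if (!nA || !nB) return(out)
    if (any(A[, 3] <= A[, 1]) || any(A[, 4] <= A[, 2]) ||
        any(B[, 3] <= B[, 1]) || any(B[, 4] <= B[, 2]))
        stop("degenerate box: require x_max > x_min and y_max > y_min")
    areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
    areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
    ## row loop is fine: nA, nB are group-sized (a handful of pigs)
    for (i in seq_len(nA)) {
        w <- pmin(A[i, 3], B[, 3]) - pmax(A[i, 1], B[, 1])
        h <- pmin(A[i, 4], B[, 4]) - pmax(A[i, 2], B[, 2])
        inter <- pmax(w, 0) * pmax(h, 0)
        out[i, ] <- inter / (areaA[i] + areaB - inter)
    }
    out
}

#' Box centroid and centroid distance
#'
#' \code{boxCentroid} returns the centre \code{((x_min+x_max)/2,
#' (y_min+y_max)/2)} of a box; \code{centroidDistance} the Euclidean
#' distance between two centres, the displacement used by the walking rule.
#'
#' @param box a box (see \code{\link{boxIoU}}).
#' @return \code{boxCentroid}: numeric \code{c(cx, cy)}.
#' @export
#' @examples
#' centroidDistance(c(10, 10), c(13, 14))  # 5
boxCentroid <- function(box) {
    b <- .asBox(box)
    c(cx = (b[1] + b[3]) / 2, cy = (b[2] + b[4]) / 2)
}

#' @rdname boxCentroid
#' @param a,b centroids as numeric \code{c(cx, cy)}.
#' @return \code{centroidDistance}: nonnegative Euclidean distance.
#' @export
centroidDistance <- function(a, b) {
    a <- as.numeric(a)[1:2]; b <- as.numeric(b)[1:2]
    sqrt(sum((a - b)^2))
}
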