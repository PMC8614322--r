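## independent oracles used across the suite; deliberately naive

## brute-force orthonormal 2-D type-II DCT by explicit cosine sums (O(N^4)),
## followed by the same ravel/zap/median/threshold rule as the hash
bruteForcePhashBits <- function(img) {
    N <- nrow(img)
    a <- function(k) if (k == 0) sqrt(1 / N) else sqrt(2 / N)
    C <- numeric(64)
    k <- 0L
    for (u in 0:7) {
        for (v in 0:7) {
            k <- k + 1L
            s <- 0
            for (x in 0:(N - 1)) {
                for (y in 0:(N - 1)) {
                    s <- s + img[x + 1, y + 1] *
                        cos(pi * (2 * x + 1) * u / (2 * N)) *
                        cos(pi * (2 * y + 1) * v / (2 * N))
                }
            }
            C[k] <- a(u) * a(v) * s
        }
    }
    C[abs(C) < 1e-10 * max(1, abs(C))] <- 0
    as.integer(C >= median(C))
}

## exhaustive-permutation minimum assignment cost (rectangular allowed)
allPerms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in allPerms(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

bruteAssignmentCost <- function(cost) {
    n <- nrow(cost); m <- ncol(cost)
    best <- Inf
    if (n <= m) {
        for (p in allPerms(seq_len(m)))
            best <- min(best, sum(cost[cbind(seq_len(n), p[seq_len(n)])]))
    } else {
        for (p in allPerms(seq_len(n)))
            best <- min(best, sum(cost[cbind(p[seq_len(m)], seq_len(m))]))
    }
    best
}

## exhaustive-permutation maximum-total-IoU matching value
bruteMaxIouSum <- function(iou) {
    -bruteAssignmentCost(-iou)
}

## matrix-free position/velocity Kalman filter for one coordinate, with the
## same height-scaled noise magnitudes as the tracker's filter
scalarKalmanTrace <- function(meas, h, posWeight = 1 / 20,
                              velWeight = 1 / 160) {
    F <- matrix(c(1, 0, 1, 1), 2)
    H <- matrix(c(1, 0), 1)
    q <- diag(c((posWeight * h)^2, (velWeight * h)^2))
    r <- (posWeight * h)^2
    x <- c(meas[1], 0)
    P <- diag(c((2 * posWeight * h)^2, (10 * velWeight * h)^2))
    out <- numeric(length(meas))
    out[1] <- x[1]
    for (i in seq_along(meas)[-1]) {
        x <- as.vector(F %*% x)
        P <- F %*% P %*% t(F) + q
        S <- (H %*% P %*% t(H))[1] + r
        K <- (P %*% t(H)) / S
        x <- x + as.vector(K) * (meas[i] - x[1])
        P <- (diag(2) - K %*% H) %*% P
        out[i] <- x[1]
    }
    out
}

## ground-truth table (visible rows only) in evaluator layout
simToGt <- function(sim) {
    st <- groundTruth(sim)
    st <- st[st$visible, , drop = FALSE]
    data.frame(frame = st$frame, id = st$animal,
               x_min = st$x_min, y_min = st$y_min,
               x_max = st$x_max, y_max = st$y_max,
               label = st$posture, confidence = 1)
}

## map track ids to ground-truth animals by first-frame centre proximity
matchTracksToAnimals <- function(sim, trackSet) {
    st <- groundTruth(sim)
    recs <- trackRecords(trackSet)
    f1 <- min(recs$frame)
    gt1 <- st[st$frame == f1, ]
    tr1 <- recs[recs$frame == f1, ]
    map <- integer(0)
    for (i in seq_len(nrow(tr1))) {
        cxy <- c((tr1$x_min[i] + tr1$x_max[i]) / 2,
                 (tr1$y_min[i] + tr1$y_max[i]) / 2)
        d <- sqrt((gt1$cx - cxy[1])^2 + (gt1$cy - cxy[2])^2)
        map[as.character(tr1$track_id[i])] <- gt1$animal[which.min(d)]
    }
    map
}

randomHash <- function() new("PerceptualHash", bits = runif(64) > 0.5)

flipBits <- function(h, idx) {
    b <- h@bits
    b[idx] <- !b[idx]
    new("PerceptualHash", bits = b)
}
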