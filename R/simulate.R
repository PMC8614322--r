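## seeded top-view pen simulator: the ground-truth substrate that stands in
## for annotated barn video

.stationaryDist <- function(P) {
    ## left eigenvector of the transition matrix at eigenvalue 1
    e <- eigen(t(P))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v / sum(v)
}

#' Simulate a pen of pigs
#'
#' Generates ground truth for one clip: each pig's posture evolves as a
#' per-frame Markov chain over \code{\link{postureLabels}}; standing pigs
#' take heading-persistent Gaussian random-walk steps (reflected at the
#' walls), lying pigs stay put; each pig carries a posture-dependent
#' bounding box; pigs whose centre falls inside the feeder rectangle are
#' invisible to the camera. Initial postures are drawn from the chain's
#' stationary distribution and initial positions from a jittered grid, so
#' pigs start well separated as they do in a real pen. Everything is
#' reproducible from \code{param@seed}.
#'
#' The returned ground truth includes each pig's true walking path length,
#' defined by the same supra-threshold displacement rule the activity
#' module applies (standing at both frames and moving more than 4 px), so
#' recovery tests compare like with like.
#'
#' @param param a \code{\link{penParam}}.
#' @param walkThreshold pixels; the walking definition used for the true
#'   path length (default 4).
#' @return A \code{\linkS4class{PenSimulation}}.
#' @export
#' @examples
#' sim <- simulatePen(penParam(nAnimals = 2, duration = 4, seed = 3))
#' occupancy(sim)
simulatePen <- function(param = penParam(), walkThreshold = 4) {
    validObject(param)
    nF <- as.integer(round(param@duration * param@fps))
    nA <- param@nAnimals
    labs <- postureLabels()
    withr::with_seed(param@seed, {
        posture <- matrix(0L, nF, nA)
        posture[1L, ] <- if (length(param@initPosture))
            rep(match(param@initPosture[1L], postureLabels()), nA)
        else sample.int(3L, nA, replace = TRUE,
                        prob = .stationaryDist(param@transition))
        ## jittered grid start, clear of the walls
        side <- ceiling(sqrt(nA))
        gx <- ((seq_len(nA) - 1L) %% side + 0.5) / side * param@width * 0.8 +
            param@width * 0.1
        gy <- ((seq_len(nA) - 1L) %/% side + 0.5) / side * param@height *
            0.8 + param@height * 0.1
        cx <- matrix(0, nF, nA); cy <- matrix(0, nF, nA)
        cx[1L, ] <- gx + rnorm(nA, 0, 5)
        cy[1L, ] <- gy + rnorm(nA, 0, 5)
        heading <- runif(nA, 0, 2 * pi)
        for (f in seq_len(nF)[-1L]) {
            for (a in seq_len(nA)) {
                p <- posture[f - 1L, a]
                posture[f, a] <- sample.int(3L, 1L,
                                            prob = param@transition[p, ])
                if (posture[f - 1L, a] == 1L && posture[f, a] == 1L) {
                    heading[a] <- heading[a] + rnorm(1, 0, param@headingSd)
                    step <- abs(rnorm(1, param@walkSpeedMean,
                                      param@walkSpeedSd))
                    nx <- cx[f - 1L, a] + step * cos(heading[a])
                    ny <- cy[f - 1L, a] + step * sin(heading[a])
                    ## reflect at a wall margin so boxes stay inside
                    mW <- max(param@boxSizes[, "w"]) / 2
                    mH <- max(param@boxSizes[, "h"]) / 2
                    if (nx < mW || nx > param@width - mW) {
                        heading[a] <- pi - heading[a]
                        nx <- min(max(nx, mW), param@width - mW)
                    }
                    if (ny < mH || ny > param@height - mH) {
                        heading[a] <- -heading[a]
                        ny <- min(max(ny, mH), param@height - mH)
                    }
                    cx[f, a] <- nx; cy[f, a] <- ny
                } else {
                    cx[f, a] <- cx[f - 1L, a]
                    cy[f, a] <- cy[f - 1L, a]
                }
            }
        }
    })
    w <- param@boxSizes[posture, "w"]
    h <- param@boxSizes[posture, "h"]
    states <- data.frame(
        frame = rep(seq_len(nF), nA),
        animal = rep(seq_len(nA), each = nF),
        cx = as.vector(cx), cy = as.vector(cy),
        posture = labs[as.vector(posture)],
        visible = TRUE,
        x_min = as.vector(cx) - as.vector(matrix(w, nF, nA)) / 2,
        y_min = as.vector(cy) - as.vector(matrix(h, nF, nA)) / 2,
        x_max = as.vector(cx) + as.vector(matrix(w, nF, nA)) / 2,
        y_max = as.vector(cy) + as.vector(matrix(h, nF, nA)) / 2)
    if (length(param@feeder) == 4L) {
        f <- param@feeder
        states$visible <- !(states$cx >= f[1] & states$cx <= f[3] &
                            states$cy >= f[2] & states$cy <= f[4])
    }
    occ <- t(vapply(seq_len(nA), function(a)
        tabulate(posture[, a], 3L) / nF, numeric(3)))
    dimnames(occ) <- list(seq_len(nA), labs)
    path <- vapply(seq_len(nA), function(a) {
        dd <- sqrt(diff(cx[, a])^2 + diff(cy[, a])^2)
        standing <- posture[-nF, a] == 1L & posture[-1L, a] == 1L
        sum(dd[standing & dd > walkThreshold])
    }, numeric(1))
    new("PenSimulation", param = param, states = states,
        pathLength = path, occupancy = occ)
}

#' Emit noisy detections from ground truth
#'
#' The detector stand-in: every visible pig is emitted with probability
#' 1 - \code{missRate}, with centre and size jittered by Gaussian noise,
#' its label flipped to a random other posture with probability
#' \code{labelFlipRate}; Poisson(\code{fpRate}) spurious boxes per frame
#' are added. Identities are dropped (a detector does not know them).
#' With an all-zero noise model the detections are exactly the visible
#' ground-truth boxes with confidence 1.
#'
#' @param sim a \code{\linkS4class{PenSimulation}}.
#' @param noise a \code{\link{noiseParam}}.
#' @return data.frame of detections: \code{frame}, box corners,
#'   \code{label}, \code{confidence}.
#' @export
#' @examples
#' sim <- simulatePen(penParam(nAnimals = 2, duration = 4, seed = 3))
#' dets <- emitDetections(sim, noiseParam())
#' nrow(dets) == sum(groundTruth(sim)$visible)
emitDetections <- function(sim, noise = noiseParam()) {
    validObject(noise)
    st <- groundTruth(sim)[groundTruth(sim)$visible, , drop = FALSE]
    param <- sim@param
    labs <- postureLabels()
    withr::with_seed(noise@seed, {
        keep <- runif(nrow(st)) >= noise@missRate
        st <- st[keep, , drop = FALSE]
        n <- nrow(st)
        if (noise@jitterSd > 0 && n) {
            dcx <- rnorm(n, 0, noise@jitterSd)
            dcy <- rnorm(n, 0, noise@jitterSd)
            dw <- rnorm(n, 0, noise@jitterSd)
            dh <- rnorm(n, 0, noise@jitterSd)
            w <- pmax(st$x_max - st$x_min + dw, 8)
            h <- pmax(st$y_max - st$y_min + dh, 8)
            ncx <- (st$x_min + st$x_max) / 2 + dcx
            ncy <- (st$y_min + st$y_max) / 2 + dcy
            st$x_min <- ncx - w / 2; st$x_max <- ncx + w / 2
            st$y_min <- ncy - h / 2; st$y_max <- ncy + h / 2
        }
        label <- st$posture
        conf <- if (n) runif(n, 0.6, 1) else numeric(0)
        if (noise@labelFlipRate > 0 && n) {
            flip <- runif(n) < noise@labelFlipRate
            label[flip] <- vapply(label[flip], function(l)
                sample(setdiff(labs, l), 1L), character(1))
        }
        if (noise@missRate == 0 && noise@jitterSd == 0 &&
            noise@labelFlipRate == 0)
            conf <- rep(1, n)
        out <- data.frame(frame = st$frame, x_min = st$x_min,
                          y_min = st$y_min, x_max = st$x_max,
                          y_max = st$y_max, label = label,
                          confidence = conf)
        nFP <- if (noise@fpRate > 0)
            rpois(length(unique(groundTruth(sim)$frame)), noise@fpRate)
        else integer(0)
        if (sum(nFP)) {
            frames <- rep(sort(unique(groundTruth(sim)$frame)), nFP)
            m <- length(frames)
            w <- runif(m, 40, 130); h <- runif(m, 30, 80)
            fcx <- runif(m, w / 2, param@width - w / 2)
            fcy <- runif(m, h / 2, param@height - h / 2)
            fp <- data.frame(frame = frames, x_min = fcx - w / 2,
                             y_min = fcy - h / 2, x_max = fcx + w / 2,
                             y_max = fcy + h / 2,
                             label = sample(labs, m, replace = TRUE),
                             confidence = runif(m, 0.3, 0.8))
            out <- rbind(out, fp)
        }
    })
    out <- out[order(out$frame, out$y_min, out$x_min), ]
    rownames(out) <- NULL
    out
}

#' Render one frame of the simulation
#'
#' Draws the pen as a grayscale intensity matrix (rows = y, columns = x):
#' uniform light-grey floor, dark feeder rectangle, each visible pig a
#' filled ellipse inscribed in its box with a posture-specific shade.
#' Deterministic; the substrate for perceptual-hash tests and demos.
#'
#' @param sim a \code{\linkS4class{PenSimulation}}.
#' @param frame frame index to render.
#' @param scale optional down-scale factor for speed (e.g. 0.25).
#' @return Numeric matrix in [0, 1] of size height x width.
#' @export
renderFrame <- function(sim, frame, scale = 1) {
    st <- groundTruth(sim)
    if (!frame %in% st$frame) stop("frame ", frame, " is out of range")
    param <- sim@param
    W <- as.integer(round(param@width * scale))
    H <- as.integer(round(param@height * scale))
    img <- matrix(0.25, H, W)
    xs <- (seq_len(W) - 0.5) / scale
    ys <- (seq_len(H) - 0.5) / scale
    if (length(param@feeder) == 4L) {
        f <- param@feeder
        img[ys >= f[2] & ys <= f[4], xs >= f[1] & xs <= f[3]] <- 0.05
    }
    shade <- c(standing_pig = 0.95, sl_pig = 0.75, ll_pig = 0.55)
    rows <- st[st$frame == frame & st$visible, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
        r <- rows[i, ]
        a <- (r$x_max - r$x_min) / 2
        b <- (r$y_max - r$y_min) / 2
        xi <- which(abs(xs - r$cx) <= a)
        yi <- which(abs(ys - r$cy) <= b)
        if (!length(xi) || !length(yi)) next
        ell <- outer((ys[yi] - r$cy)^2 / b^2, (xs[xi] - r$cx)^2 / a^2,
                     `+`) <= 1
        sub <- img[yi, xi, drop = FALSE]
        sub[ell] <- shade[[r$posture]]
        img[yi, xi] <- sub
    }
    img
}

#' Visibility histogram of a simulation
#'
#' Tabulates, over frames, how many pigs are simultaneously visible — the
#' shape of this distribution (right-skewed toward the group size, with a
#' tail caused by the feeder blind spot) mirrors what a ceiling camera
#' sees over a real pen with a large feeder.
#'
#' @param sim a \code{\linkS4class{PenSimulation}}.
#' @return Named integer vector: frames with 0, 1, ..., n pigs visible.
#' @export
visibilityHistogram <- function(sim) {
    st <- groundTruth(sim)
    perFrame <- tapply(st$visible, st$frame, sum)
    tab <- tabulate(perFrame + 1L, nbins = sim@param@nAnimals + 1L)
    setNames(tab, 0:sim@param@nAnimals)
}
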