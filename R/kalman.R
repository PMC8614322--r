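## constant-velocity Kalman filter on the (cx, cy, aspect, height) box
## parameterisation, the SORT/Deep-SORT convention: noise standard
## deviations scale with box height so big (near) pigs tolerate more jitter

.boxToMeas <- function(box) {
    b <- .asBox(box)
    w <- b[3] - b[1]; h <- b[4] - b[2]
    c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2, w / h, h)
}

.measToBox <- function(z) {
    h <- z[4]; w <- z[3] * h
    c(x_min = z[1] - w / 2, y_min = z[2] - h / 2,
      x_max = z[1] + w / 2, y_max = z[2] + h / 2)
}

#' Initialise a Kalman state from a first detection
#'
#' State is the 8-vector (cx, cy, aspect = width/height, height) plus their
#' per-frame velocities, with a diagonal covariance scaled by box height.
#'
#' @param box the first observed box.
#' @param posWeight,velWeight noise scales as fractions of box height.
#' @return A list with \code{mean} (length 8) and \code{cov} (8x8).
#' @export
#' @examples
#' st <- kalmanInit(c(90, 90, 110, 130))
#' st$mean[1:2]
kalmanInit <- function(box, posWeight = 1 / 20, velWeight = 1 / 160) {
    z <- .boxToMeas(box)
    h <- z[4]
    std <- c(2 * posWeight * h, 2 * posWeight * h, 1e-2, 2 * posWeight * h,
             10 * velWeight * h, 10 * velWeight * h, 1e-5, 10 * velWeight * h)
    list(mean = c(z, rep(0, 4)), cov = diag(std^2))
}

#' Kalman time update (one frame ahead)
#'
#' Constant-velocity propagation: positions advance by their velocities,
#' covariance grows by process noise proportional to box height.
#'
#' @param state list with \code{mean}, \code{cov} (see
#'   \code{\link{kalmanInit}}).
#' @param posWeight,velWeight process-noise scales.
#' @return The predicted state (same structure).
#' @export
#' @examples
#' st <- kalmanInit(c(90, 90, 110, 130))
#' st$mean[5] <- 5  # 5 px/frame rightward
#' kalmanPredict(st)$mean[1]
kalmanPredict <- function(state, posWeight = 1 / 20, velWeight = 1 / 160) {
    F <- diag(8)
    F[cbind(1:4, 5:8)] <- 1
    h <- state$mean[4]
    std <- c(posWeight * h, posWeight * h, 1e-2, posWeight * h,
             velWeight * h, velWeight * h, 1e-5, velWeight * h)
    list(mean = as.vector(F %*% state$mean),
         cov = F %*% state$cov %*% t(F) + diag(std^2))
}

#' Kalman measurement update
#'
#' Standard linear-Gaussian update of the predicted state with an observed
#' box; the posterior covariance trace never exceeds the prior's.
#'
#' @param state predicted state.
#' @param box observed box.
#' @param posWeight measurement-noise scale.
#' @return The posterior state.
#' @export
#' @examples
#' st <- kalmanPredict(kalmanInit(c(90, 90, 110, 130)))
#' kalmanUpdate(st, c(92, 90, 112, 130))$mean[1:2]
kalmanUpdate <- function(state, box, posWeight = 1 / 20) {
    z <- .boxToMeas(box)
    H <- cbind(diag(4), matrix(0, 4, 4))
    h <- state$mean[4]
    rstd <- c(posWeight * h, posWeight * h, 1e-1, posWeight * h)
    R <- diag(rstd^2)
    S <- H %*% state$cov %*% t(H) + R
    K <- state$cov %*% t(H) %*% solve(S)
    innov <- z - as.vector(H %*% state$mean)
    mean <- state$mean + as.vector(K %*% innov)
    cov <- (diag(8) - K %*% H) %*% state$cov
    cov <- (cov + t(cov)) / 2            # keep symmetric
    list(mean = mean, cov = cov)
}

#' Predicted box of a Kalman state
#'
#' @param state a Kalman state.
#' @return Named numeric \code{c(x_min, y_min, x_max, y_max)}.
#' @export
kalmanBox <- function(state) .measToBox(state$mean[1:4])
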