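## perceptual hashing: 32x32 bilinear resize -> orthonormal 2-D DCT-II ->
## top-left 8x8 block ravelled row-major -> threshold at the median

.dctMatrix <- function(n) {
    ## orthonormal type-II DCT basis: D %*% x gives the 1-D transform
    k <- seq_len(n) - 1
    D <- sqrt(2 / n) * cos(outer(k, 2 * k + 1) * pi / (2 * n))
    D[1, ] <- sqrt(1 / n)
    D
}

.toGray <- function(image) {
    if (is.matrix(image)) return(image)
    d <- dim(image)
    if (length(d) == 3L && d[3] >= 3L)  # ITU-R BT.601 luminance
        return(0.299 * image[, , 1] + 0.587 * image[, , 2] +
               0.114 * image[, , 3])
    if (length(d) == 3L && d[3] == 1L) return(image[, , 1])
    stop("image must be a 2-D grayscale matrix or an HxWx3 RGB array")
}

#' Perceptual hash of a frame
#'
#' Computes the 64-bit pHash fingerprint of an image: the frame is reduced
#' to 32x32 by bilinear interpolation, transformed with the orthonormal 2-D
#' type-II DCT, and the top-left 8x8 low-frequency coefficient block is
#' ravelled row-major into C_1..C_64. With m the median of those 64
#' coefficients, bit i is 1 when C_i >= m and 0 otherwise (the DC
#' coefficient is included in both the median and the bits). Near-duplicate
#' frames of an almost static pen differ in few bits, so streams can be
#' thinned by Hamming distance before annotation.
#'
#' @param image numeric matrix of intensities (rows = y, columns = x) or an
#'   HxWx3 RGB array; at least 8x8 pixels, nonnegative.
#' @param size side length of the pre-DCT resize (default 32).
#' @return A \code{\linkS4class{PerceptualHash}} object.
#' @seealso \code{\link{hammingDistance}}, \code{\link{dedupStream}}
#' @export
#' @examples
#' h <- computePhash(matrix(1, 32, 32))
#' sum(hashBits(h))  # constant image: all 64 bits set
computePhash <- function(image, size = 32L) {
    img <- .toGray(image)
    if (!is.matrix(img) || min(dim(img)) < 8L)
        stop("image must be at least 8x8 pixels")
    if (anyNA(img) || any(img < 0)) stop("intensities must be nonnegative")
    if (!all(dim(img) == c(size, size)))
        img <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
    D <- .dctMatrix(size)
    coef <- D %*% img %*% t(D)
    block <- coef[1:8, 1:8]
    C <- as.vector(t(block))           # ravel row-major
    ## coefficients that are zero up to floating-point noise are treated as
    ## exact zeros, so the >= median comparison is stable (a constant image
    ## must hash to all ones, not to rounding noise)
    C[abs(C) < 1e-10 * max(1, abs(C))] <- 0
    m <- stats::median(C)
    new("PerceptualHash", bits = C >= m)
}

#' Hamming distance between two perceptual hashes
#'
#' @param h1,h2 \code{\linkS4class{PerceptualHash}} objects (or logical
#'   64-bit vectors).
#' @return Integer number of differing bit positions, in [0, 64].
#' @export
#' @examples
#' h <- computePhash(matrix(1:1024, 32, 32))
#' hammingDistance(h, h)  # 0
hammingDistance <- function(h1, h2) {
    b1 <- if (is(h1, "PerceptualHash")) h1@bits else as.logical(h1)
    b2 <- if (is(h2, "PerceptualHash")) h2@bits else as.logical(h2)
    if (length(b1) != length(b2))
        stop("hash length mismatch: ", length(b1), " vs ", length(b2))
    sum(b1 != b2)
}

#' Near-duplicate filtering of a frame stream
#'
#' Walks an ordered stream and keeps a frame only when its hash differs
#' from the most recently *kept* frame's hash by more than
#' \code{maxDistance} bits (comparing to the last kept frame, not the
#' immediate predecessor, so an unbounded run of slowly drifting
#' near-duplicates cannot leak through). The first frame is always kept;
#' the default threshold of 1 drops only frames that are visually almost
#' identical.
#'
#' @param frames a list of images, or a list of
#'   \code{\linkS4class{PerceptualHash}} objects if hashes are precomputed.
#' @param maxDistance keep a frame iff its Hamming distance to the last
#'   kept frame exceeds this (default 1).
#' @return Integer vector of kept frame indices (1-based, strictly
#'   increasing, always starting at 1).
#' @export
#' @examples
#' frames <- replicate(5, matrix(1, 32, 32), simplify = FALSE)
#' dedupStream(frames)  # identical frames: keeps only the first
dedupStream <- function(frames, maxDistance = 1L) {
    if (!length(frames)) stop("empty frame stream")
    hashes <- lapply(frames, function(f)
        if (is(f, "PerceptualHash")) f else computePhash(f))
    kept <- 1L
    lastKept <- hashes[[1L]]
    for (i in seq_along(hashes)[-1L]) {
        if (hammingDistance(lastKept, hashes[[i]]) > maxDistance) {
            kept <- c(kept, i)
            lastKept <- hashes[[i]]
        }
    }
    kept
}
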