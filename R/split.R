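#' Random train/test split of labelled items
#'
#' Seeded uniform partition of item identifiers into a training and a test
#' set at a fixed ratio, as used to hold out annotated frames (a 90:10
#' split of 6680 frames gives 6012 training and 668 test items). The train
#' size is \code{floor(ratio * N)}; the split is a seeded shuffle followed
#' by a prefix cut, so it is reproducible and independent of input order.
#'
#' @param ids vector of item identifiers (length >= 2, no duplicates).
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return A list with elements \code{train}, \code{test} (disjoint subsets
#'   of \code{ids} whose union is \code{ids}), \code{ratio} and \code{seed}.
#' @export
#' @examples
#' sp <- splitDataset(sprintf("frame%04d", 1:100), ratio = 0.9, seed = 1)
#' lengths(sp[c("train", "test")])
splitDataset <- function(ids, ratio = 0.9, seed = 1L) {
    if (length(ids) < 2L) stop("need at least 2 items to split")
    if (anyDuplicated(ids)) stop("item identifiers must be unique")
    if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)")
    n <- length(ids)
    ## epsilon guards exactly-representable products (0.9*6680 = 6012)
    ## against downward rounding in binary floating point
    nTrain <- floor(ratio * n + 1e-9)
    perm <- withr::with_seed(as.integer(seed), sample.int(n))
    ord <- order(as.character(ids))  # order-independence: shuffle a canon
    canon <- ids[ord]
    take <- perm[seq_len(nTrain)]
    list(train = canon[sort(take)], test = canon[sort(setdiff(perm, take))],
         ratio = ratio, seed = as.integer(seed))
}
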