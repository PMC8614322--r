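#' Minimum-cost linear assignment
#'
#' Solves the rectangular linear assignment problem by the O(n^3) shortest
#' augmenting path (Hungarian) algorithm with row/column potentials: every
#' row of the cost matrix (if rows <= columns; otherwise every column) is
#' assigned to a distinct column so that the total cost is minimal. This is
#' the association engine behind track/detection matching and CLEAR-MOT
#' frame matching.
#'
#' @param cost numeric matrix of finite costs.
#' @return A list with \code{assignment} — integer vector of length
#'   \code{nrow(cost)}, \code{assignment[i]} the column assigned to row i
#'   (\code{NA} for unassigned rows when rows > columns) — and \code{cost},
#'   the total cost of the assignment.
#' @export
#' @examples
#' solveAssignment(matrix(c(1, 2, 2, 4), 2, byrow = TRUE))
solveAssignment <- function(cost) {
    cost <- as.matrix(cost)
    if (!length(cost))
        return(list(assignment = integer(0), cost = 0))
    if (anyNA(cost) || any(!is.finite(cost)))
        stop("cost matrix must be finite")
    nr <- nrow(cost); nc <- ncol(cost)
    flip <- nr > nc
    a <- if (flip) t(cost) else cost
    n <- nrow(a); m <- ncol(a)

    ## potentials u (rows), v (cols); p[j] = row matched to column j
    ## (0 = free); indices offset by 1 for the virtual column 0
    u <- numeric(n + 1L)
    v <- numeric(m + 1L)
    p <- integer(m + 1L)
    way <- integer(m + 1L)
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(Inf, m)
        used <- logical(m + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            delta <- Inf; j1 <- 0L
            for (j in seq_len(m)) {
                if (!used[j + 1L]) {
                    cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
                    if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
                    if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
                }
            }
            for (j in 0:m) {
                if (used[j + 1L]) {
                    u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
                    v[j + 1L] <- v[j + 1L] - delta
                } else {
                    minv[j] <- minv[j] - delta
                }
            }
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0 + 1L]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    rowOf <- p[-1L]                      # rowOf[j] = row assigned to col j
    assign <- rep(NA_integer_, n)
    assign[rowOf[rowOf > 0L]] <- which(rowOf > 0L)
    total <- sum(a[cbind(which(!is.na(assign)), assign[!is.na(assign)])])
    if (flip) {
        colAssign <- rep(NA_integer_, nr)
        colAssign[assign[!is.na(assign)]] <- which(!is.na(assign))
        list(assignment = colAssign, cost = total)
    } else {
        list(assignment = assign, cost = total)
    }
}
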