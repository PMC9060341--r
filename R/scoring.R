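#' Estimate the carrier cell fraction from the call count
#'
#' A variant carried by a fraction f of N cells produces a call whenever
#' a carrier is compared against a non-carrier, so across all N^2 ordered
#' comparisons the expected call count is
#' \deqn{n = f (1 - f) N^2.}
#' Solving for f gives two roots; the smaller one,
#' \deqn{f_m = 0.5 - \sqrt{0.25 - n / N^2},}
#' is the mosaic-interpretation fraction (the larger root is its mirror
#' 1 - f, the fraction under the germline interpretation, i.e. f is also
#' the fraction of cells that \emph{lost} a germline variant). When
#' \code{n / N^2 > 0.25} -- more calls than any single-variant pattern
#' explains -- the discriminant is negative and f is clamped to its
#' maximum 0.5.
#'
#' @param n number of calls for the variant across all comparisons
#'   (vectorised).
#' @param N number of (active) cells; must be >= 2.
#' @return Estimated fraction in [0, 0.5]; monotone non-decreasing in n.
#' @examples
#' estimateCellFraction(6, 5)   # 0.4
#' estimateCellFraction(4, 5)   # 0.2
#' @export
estimateCellFraction <- function(n, N) {
    if (any(N < 2))
        stop("cell fraction is undefined for fewer than 2 cells")
    if (any(n < 0))
        stop("'n' must be non-negative")
    disc <- 0.25 - n / N^2
    ifelse(disc < 0, 0.5, 0.5 - sqrt(pmax(disc, 0)))
}

#' Estimated number of carrier cells
#'
#' Rounds \code{f * N} to the nearest integer (ties away from zero, so
#' 0.5 rounds up). A result of 0 -- a single sporadic call in a large
#' design -- means the pattern is too weak to support any carrier and the
#' variant scores (0, 0), i.e. noise.
#'
#' @param f estimated cell fraction in [0, 0.5]
#'   (\code{\link{estimateCellFraction}}).
#' @param N number of (active) cells.
#' @return Integer carrier count N' with 0 <= N' <= N.
#' @export
carrierCount <- function(f, N) {
    if (any(f < 0 | f > 0.5))
        stop("'f' must lie in [0, 0.5]")
    as.integer(floor(f * N + 0.5))
}

#' Compute mosaic and germline scores for one call matrix
#'
#' With N' estimated carriers, a true mosaic mutation places its n calls
#' in the N' carrier rows, and a true germline variant places them in the
#' N' loss columns. The best estimate of the in-pattern call count is the
#' maximum over all size-N' subsets of cells of the summed row
#' (respectively column) call counts, and
#' \deqn{MosaicScore = max(n_m) / n, \quad GermlineScore = max(n_g) / n.}
#' Because the summed counts are separable over disjoint rows/columns,
#' the subset maximum equals the sum of the N' largest row (column) sums,
#' which is what this function computes (verified against
#' \code{\link{bruteForceScores}}).
#'
#' Carrier cells are the cells of the maximizing row subset (mosaic
#' interpretation); ties among equal row sums resolve to the lowest cell
#' index for deterministic output.
#'
#' @param cm a \code{\link{CallMatrix}}.
#' @return One-row data.frame with columns \code{key, chrom, pos, ref,
#'   alt, n, N_active, f, N_prime, mosaic_score, germline_score,
#'   carrier_cells} (comma-separated cell ids), or \code{NULL} when no
#'   active call remains (the variant is dropped, e.g. after dropout
#'   exclusion).
#' @examples
#' m <- matrix(0L, 5, 5)
#' m[2, c(1, 3, 4)] <- 1L; m[5, c(1, 3, 4)] <- 1L  # mosaic in cells 2 and 5
#' cm <- CallMatrix("v", paste0("c", 1:5), m)
#' computeScores(cm)[, c("n", "f", "N_prime", "mosaic_score", "germline_score")]
#' @export
computeScores <- function(cm) {
    stopifnot(is(cm, "CallMatrix"))
    n_act <- sum(cm@active)
    n <- callCount(cm)
    if (n == 0L || n_act < 2L) return(NULL)
    rs <- rowCallSums(cm)
    cs <- colCallSums(cm)
    f <- estimateCellFraction(n, n_act)
    np <- carrierCount(f, n_act)
    if (np == 0L) {
        ms <- 0
        gs <- 0
        carriers <- character(0)
    } else {
        ord_r <- order(-rs, seq_len(n_act))
        ord_c <- order(-cs, seq_len(n_act))
        ms <- sum(rs[ord_r[seq_len(np)]]) / n
        gs <- sum(cs[ord_c[seq_len(np)]]) / n
        carriers <- names(rs)[sort(ord_r[seq_len(np)])]
    }
    data.frame(key = cm@key, chrom = cm@chrom, pos = cm@pos, ref = cm@ref,
               alt = cm@alt, n = n, N_active = n_act, f = f, N_prime = np,
               mosaic_score = ms, germline_score = gs,
               carrier_cells = paste(carriers, collapse = ","),
               stringsAsFactors = FALSE)
}

#' Score a list of call matrices
#'
#' Applies \code{\link{computeScores}} to every matrix; matrices with no
#' remaining active call (possible after allele-dropout exclusion) are
#' dropped.
#'
#' @param matrices named list of \code{\link{CallMatrix}} objects.
#' @return data.frame with one row per surviving variant.
#' @export
scoreCallMatrices <- function(matrices) {
    rows <- lapply(matrices, computeScores)
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(key = character(0), chrom = character(0),
                          pos = numeric(0), ref = character(0),
                          alt = character(0), n = numeric(0),
                          N_active = numeric(0), f = numeric(0),
                          N_prime = numeric(0), mosaic_score = numeric(0),
                          germline_score = numeric(0),
                          carrier_cells = character(0),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Exhaustive-subset score oracle
#'
#' Literal implementation of the score definition: enumerate every
#' size-N' subset of the active cells and maximize the summed row
#' (column) call counts over subsets. Exponential in N, so guarded to
#' N <= 12 active cells; exists to validate the greedy top-N' shortcut in
#' \code{\link{computeScores}}, which it must equal on every input.
#'
#' @param cm a \code{\link{CallMatrix}} with at most 12 active cells.
#' @return Named numeric vector \code{c(mosaic_score, germline_score)}.
#' @export
bruteForceScores <- function(cm) {
    stopifnot(is(cm, "CallMatrix"))
    n_act <- sum(cm@active)
    if (n_act > 12L)
        stop("brute-force enumeration is guarded to <= 12 active cells")
    n <- callCount(cm)
    if (n == 0L)
        return(c(mosaic_score = 0, germline_score = 0))
    rs <- rowCallSums(cm)
    cs <- colCallSums(cm)
    np <- carrierCount(estimateCellFraction(n, n_act), n_act)
    if (np == 0L)
        return(c(mosaic_score = 0, germline_score = 0))
    subsets <- utils::combn(n_act, np)
    best_r <- max(apply(subsets, 2, function(s) sum(rs[s])))
    best_c <- max(apply(subsets, 2, function(s) sum(cs[s])))
    c(mosaic_score = best_r / n, germline_score = best_c / n)
}
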