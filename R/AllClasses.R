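#' @import methods
#' @importFrom stats dbinom rbinom rpois runif rbeta
#' @importFrom utils read.delim write.table combn head
NULL

#' CallMatrix: per-variant N x N binary matrix of ordered pairwise calls
#'
#' For a cohort of N cells compared all-to-all, a variant's evidence is an
#' N x N binary matrix with entry \code{[i, j] = 1} when the variant was
#' called with cell i as case and cell j as control. Mosaic mutations show
#' up as rows (carriers called against every non-carrier), germline
#' variants as columns (every cell called against the cell that lost the
#' variant), and false positives as sporadic entries.
#'
#' The \code{active} slot records which cells currently contribute to
#' score computation; allele-dropout exclusion
#' (\code{\link{applyAdaExclusion}}) shrinks it. Entries of inactive cells
#' never contribute to any row/column sum.
#'
#' @slot key character(1), normalized variant identifier
#'   (\code{chrom:pos:ref:alt} for SNVs/indels, cluster representative for
#'   SVs).
#' @slot chrom,pos chromosome and 1-based position used for interval
#'   queries (dropout/capture lookup).
#' @slot ref,alt allele strings (for SVs, \code{ref = "N"} and
#'   \code{alt = "<TYPE>"}).
#' @slot cells ordered character vector of the N cell identifiers; fixes
#'   row/column order.
#' @slot calls integer N x N matrix in \{0, 1\} with zero diagonal.
#' @slot active logical N vector; cells currently included in scoring.
#' @slot vaf numeric N vector; per-cell variant allele fraction taken from
#'   the case side (maximum over that cell's calls), NA when absent.
#'
#' @seealso \code{\link{buildCallMatrices}}, \code{\link{computeScores}},
#'   \code{\link{applyAdaExclusion}}
#' @export
setClass("CallMatrix", representation(
    key = "character",
    chrom = "character",
    pos = "numeric",
    ref = "character",
    alt = "character",
    cells = "character",
    calls = "matrix",
    active = "logical",
    vaf = "numeric"
))

setValidity("CallMatrix", function(object) {
    n_cells <- length(object@cells)
    msg <- character(0)
    if (n_cells < 2L)
        msg <- c(msg, "a CallMatrix needs at least 2 cells")
    if (!identical(dim(object@calls), c(n_cells, n_cells)))
        msg <- c(msg, "'calls' must be an N x N matrix matching 'cells'")
    else {
        if (!all(object@calls %in% c(0L, 1L)))
            msg <- c(msg, "'calls' entries must be 0 or 1")
        if (any(diag(object@calls) != 0L))
            msg <- c(msg, "diagonal entries (self-comparisons) must be 0")
        if (!identical(rownames(object@calls), object@cells) ||
            !identical(colnames(object@calls), object@cells))
            msg <- c(msg, "'calls' dimnames must equal 'cells'")
    }
    if (length(object@active) != n_cells)
        msg <- c(msg, "'active' must have one flag per cell")
    if (length(object@vaf) != n_cells)
        msg <- c(msg, "'vaf' must have one value per cell")
    if (anyDuplicated(object@cells))
        msg <- c(msg, "cell identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a CallMatrix
#'
#' Low-level constructor; most users get CallMatrix objects from
#' \code{\link{buildCallMatrices}}.
#'
#' @param key variant identifier string.
#' @param cells ordered cell identifiers.
#' @param calls N x N binary matrix (integer or numeric 0/1).
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @param vaf per-cell case-side VAF (defaults to all NA).
#' @param active per-cell inclusion flags (defaults to all TRUE).
#' @return A \code{\link{CallMatrix}} object.
#' @examples
#' m <- matrix(0L, 3, 3)
#' m[1, 2] <- m[1, 3] <- 1L
#' cm <- CallMatrix("chr1:100:A:T", c("A", "B", "C"), m,
#'                  chrom = "chr1", pos = 100, ref = "A", alt = "T")
#' callCount(cm)
#' @export
CallMatrix <- function(key, cells, calls, chrom = NA_character_,
                       pos = NA_real_, ref = NA_character_,
                       alt = NA_character_, vaf = NULL, active = NULL) {
    storage.mode(calls) <- "integer"
    dimnames(calls) <- list(cells, cells)
    if (is.null(vaf)) vaf <- rep(NA_real_, length(cells))
    if (is.null(active)) active <- rep(TRUE, length(cells))
    new("CallMatrix", key = as.character(key), chrom = as.character(chrom),
        pos = as.numeric(pos), ref = as.character(ref),
        alt = as.character(alt), cells = as.character(cells),
        calls = calls, active = active, vaf = as.numeric(vaf))
}

#' @describeIn CallMatrix-accessors variant identifier string.
#' @export
setGeneric("variantKey", function(x) standardGeneric("variantKey"))

#' @describeIn CallMatrix-accessors ordered cell identifiers.
#' @export
setGeneric("cellNames", function(x) standardGeneric("cellNames"))

#' @describeIn CallMatrix-accessors identifiers of cells still included in
#'   scoring.
#' @export
setGeneric("activeCells", function(x) standardGeneric("activeCells"))

#' @describeIn CallMatrix-accessors total number of calls n over active
#'   rows/columns.
#' @export
setGeneric("callCount", function(x) standardGeneric("callCount"))

#' @describeIn CallMatrix-accessors per-cell row call counts (active cells
#'   only).
#' @export
setGeneric("rowCallSums", function(x) standardGeneric("rowCallSums"))

#' @describeIn CallMatrix-accessors per-cell column call counts (active
#'   cells only).
#' @export
setGeneric("colCallSums", function(x) standardGeneric("colCallSums"))

#' @describeIn CallMatrix-accessors per-cell case-side VAF, NA when the
#'   cell made no call.
#' @export
setGeneric("perCellVaf", function(x) standardGeneric("perCellVaf"))

#' Accessors for CallMatrix objects
#'
#' Row and column sums are restricted to the active cell set, so
#' \code{sum(rowCallSums(x)) == sum(colCallSums(x)) == callCount(x)} holds
#' before and after any exclusion.
#'
#' @param x a \code{\link{CallMatrix}}.
#' @name CallMatrix-accessors
#' @aliases variantKey cellNames activeCells callCount rowCallSums
#'   colCallSums perCellVaf
NULL

#' @rdname CallMatrix-accessors
#' @export
setMethod("variantKey", "CallMatrix", function(x) x@key)

#' @rdname CallMatrix-accessors
#' @export
setMethod("cellNames", "CallMatrix", function(x) x@cells)

#' @rdname CallMatrix-accessors
#' @export
setMethod("activeCells", "CallMatrix", function(x) x@cells[x@active])

#' @rdname CallMatrix-accessors
#' @export
setMethod("callCount", "CallMatrix", function(x) {
    sum(x@calls[x@active, x@active, drop = FALSE])
})

#' @rdname CallMatrix-accessors
#' @export
setMethod("rowCallSums", "CallMatrix", function(x) {
    rowSums(x@calls[x@active, x@active, drop = FALSE])
})

#' @rdname CallMatrix-accessors
#' @export
setMethod("colCallSums", "CallMatrix", function(x) {
    colSums(x@calls[x@active, x@active, drop = FALSE])
})

#' @rdname CallMatrix-accessors
#' @export
setMethod("perCellVaf", "CallMatrix", function(x) {
    stats::setNames(x@vaf, x@cells)
})

setMethod("show", "CallMatrix", function(object) {
    n_act <- sum(object@active)
    cat("CallMatrix ", object@key, "\n",
        "  cells: ", length(object@cells), " (", n_act, " active)\n",
        "  calls: n = ", callCount(object), "\n", sep = "")
    if (length(object@cells) <= 12L) {
        m <- object@calls
        dimnames(m) <- list(
            paste0(ifelse(object@active, "  ", "x "), object@cells),
            object@cells)
        print(m)
    }
})
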