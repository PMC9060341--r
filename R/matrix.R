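#' Build one CallMatrix per non-redundant variant
#'
#' Aggregates pairwise calls (one row per ordered comparison in which a
#' variant was called) into an N x N binary matrix per distinct variant
#' key. Matrix entry \code{[case, control]} is set to 1 for every
#' comparison carrying a call; everything else stays 0. Per-cell VAF is
#' taken from the case side (the maximum over that cell's calls when the
#' same variant was called against several controls).
#'
#' Variants only ever enter this table through at least one call, so
#' every stored matrix has \code{n >= 1}.
#'
#' @param calls data.frame of pairwise calls
#'   (\code{\link{loadCohortCalls}}); needs columns \code{key, chrom,
#'   pos, ref, alt, case, control} and optionally \code{vaf}.
#' @param cells ordered cell identifiers (from
#'   \code{\link{readManifest}}); every case/control id in \code{calls}
#'   must appear here.
#' @return Named list of \code{\link{CallMatrix}} objects, keyed and
#'   ordered by first appearance of each variant in \code{calls}.
#' @examples
#' calls <- data.frame(key = "chr1:1:A:T", chrom = "chr1", pos = 1,
#'                     ref = "A", alt = "T",
#'                     case = c("A", "A"), control = c("B", "C"),
#'                     vaf = c(0.5, 0.45))
#' cm <- buildCallMatrices(calls, c("A", "B", "C"))[[1]]
#' rowCallSums(cm)
#' @export
buildCallMatrices <- function(calls, cells) {
    stopifnot(is.data.frame(calls))
    unknown <- setdiff(unique(c(calls$case, calls$control)), cells)
    if (length(unknown))
        stop("call(s) reference cell id(s) absent from the cell list: ",
             paste(unknown, collapse = ", "))
    if (nrow(calls) == 0L)
        return(structure(list(), names = character(0)))
    if (is.null(calls$vaf)) calls$vaf <- NA_real_
    n_cells <- length(cells)
    case_idx <- match(calls$case, cells)
    ctrl_idx <- match(calls$control, cells)
    if (any(case_idx == ctrl_idx))
        stop("self-comparison call(s) encountered")
    key_f <- factor(calls$key, levels = unique(calls$key))
    groups <- split(seq_len(nrow(calls)), key_f)
    out <- lapply(groups, function(idx) {
        m <- matrix(0L, n_cells, n_cells)
        m[cbind(case_idx[idx], ctrl_idx[idx])] <- 1L
        vaf <- rep(NA_real_, n_cells)
        has_vaf <- idx[!is.na(calls$vaf[idx])]
        if (length(has_vaf)) {
            by_cell <- tapply(calls$vaf[has_vaf], case_idx[has_vaf], max)
            vaf[as.integer(names(by_cell))] <- as.numeric(by_cell)
        }
        i1 <- idx[1L]
        CallMatrix(key = calls$key[i1], cells = cells, calls = m,
                   chrom = calls$chrom[i1], pos = calls$pos[i1],
                   ref = calls$ref[i1], alt = calls$alt[i1], vaf = vaf)
    })
    names(out) <- levels(key_f)
    out
}

#' Dump call matrices to a long-format TSV
#'
#' One row per non-zero entry (\code{key, case, control}), so the exact
#' matrices can be reconstructed and inspected outside R; used by the
#' command-line \code{matrix} command next to its plot.
#'
#' @param matrices named list of \code{\link{CallMatrix}} objects.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMatrixDump <- function(matrices, path) {
    rows <- lapply(matrices, function(cm) {
        hit <- which(cm@calls == 1L, arr.ind = TRUE)
        if (nrow(hit) == 0L) return(NULL)
        data.frame(key = cm@key, case = cm@cells[hit[, 1]],
                   control = cm@cells[hit[, 2]],
                   case_active = cm@active[hit[, 1]],
                   control_active = cm@active[hit[, 2]],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(key = character(0), case = character(0),
                          control = character(0), case_active = logical(0),
                          control_active = logical(0))
    rownames(out) <- NULL
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
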