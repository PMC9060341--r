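#' Maximum-likelihood folded VAF of a bin of heterozygous SNPs
#'
#' Heterozygous SNPs in a well-amplified region have allele fractions
#' around 0.5; allele dropout pulls them towards 0 or 1. Because the
#' dropped haplotype is unknown (and SNPs are unphased), the likelihood
#' is a symmetric two-component binomial mixture and the allele fraction
#' is folded to [0, 0.5]:
#' \deqn{\ell(f) = \sum_i \log[0.5\,B(a_i; d_i, f) + 0.5\,B(a_i; d_i, 1-f)]}
#' maximised over the grid f in \{0, 0.01, ..., 0.50\}. When read depths
#' are unavailable the mean folded VAF \code{mean(min(v, 1-v))} is
#' returned instead.
#'
#' @param alt_reads,depth integer vectors of per-SNP alternate read
#'   counts and depths.
#' @param vaf optional per-SNP VAF, used only for the no-depth fallback.
#' @return The maximising folded allele fraction in [0, 0.5] (ties
#'   resolve to the smallest grid value), or NA for an empty bin.
#' @examples
#' maxLikelihoodVaf(15, 30)          # 0.5: a clean heterozygous site
#' maxLikelihoodVaf(30, 30)          # 0.0: complete dropout of one allele
#' maxLikelihoodVaf(c(6, 24), c(30, 30))  # 0.2: consistent imbalance
#' @export
maxLikelihoodVaf <- function(alt_reads, depth, vaf = NULL) {
    if (!is.null(depth) && any(!is.na(depth) & depth < 0))
        stop("negative read depths are invalid")
    usable <- !is.na(alt_reads) & !is.na(depth) & depth > 0
    if (!any(usable)) {
        if (!is.null(vaf) && any(!is.na(vaf)))
            return(mean(pmin(vaf, 1 - vaf), na.rm = TRUE))
        return(NA_real_)
    }
    a <- alt_reads[usable]
    d <- depth[usable]
    grid <- seq(0, 0.5, by = 0.01)
    ll <- vapply(grid, function(f) {
        sum(log(0.5 * stats::dbinom(a, d, f) +
                0.5 * stats::dbinom(a, d, 1 - f)))
    }, numeric(1))
    grid[which.max(ll)]
}

#' Detect allele-dropout bins from a cell's heterozygous-SNP VAFs
#'
#' The genome is divided into fixed-size bins (default 5000 bp). A bin
#' is marked as allele dropout when both of the following hold: (i) at
#' least one heterozygous SNP in the bin has VAF below 0.01 or above
#' 0.99, and (ii) the maximum-likelihood VAF of the bin
#' (\code{\link{maxLikelihoodVaf}}) deviates from 0.5 by more than 0.1.
#' The immediately neighbouring bin on each side (same chromosome) is
#' then also marked, and marked bins are merged into intervals.
#'
#' @param snps per-cell SNP table (\code{\link{readSnpTable}}): columns
#'   \code{chrom, pos, alt_reads, depth} (and/or \code{vaf}).
#' @param binSize bin width in bases.
#' @param neighbors number of flanking bins to co-mark on each side.
#' @return \code{GRanges} of merged dropout intervals (1-based,
#'   inclusive ends).
#' @export
detectDropoutBins <- function(snps, binSize = 5000, neighbors = 1L) {
    stopifnot(binSize >= 1)
    if (!is.null(snps$depth) && any(!is.na(snps$depth) & snps$depth < 0))
        stop("negative read depths are invalid")
    if (is.null(snps$vaf)) {
        snps$vaf <- ifelse(snps$depth > 0, snps$alt_reads / snps$depth,
                           NA_real_)
    }
    if (nrow(snps) == 0L) return(GenomicRanges::GRanges())
    bin <- (snps$pos - 1) %/% binSize
    grp <- paste(snps$chrom, bin, sep = "\r")
    # condition (i) first: it is cheap and most bins fail it
    extreme <- !is.na(snps$vaf) & (snps$vaf < 0.01 | snps$vaf > 0.99)
    cand <- unique(grp[extreme])
    flagged <- vapply(cand, function(g) {
        idx <- which(grp == g)
        mlv <- maxLikelihoodVaf(snps$alt_reads[idx], snps$depth[idx],
                                vaf = snps$vaf[idx])
        !is.na(mlv) && abs(0.5 - mlv) > 0.1
    }, logical(1))
    hit <- cand[flagged]
    if (!length(hit)) return(GenomicRanges::GRanges())
    parts <- strsplit(hit, "\r", fixed = TRUE)
    chrom <- vapply(parts, `[`, character(1), 1L)
    b <- as.numeric(vapply(parts, `[`, character(1), 2L))
    if (neighbors > 0L) {
        off <- setdiff(seq(-neighbors, neighbors), 0L)
        chrom <- c(chrom, rep(chrom, each = length(off)))
        b <- c(b, as.vector(vapply(b, function(x) x + off,
                                   numeric(length(off)))))
        keep <- b >= 0
        chrom <- chrom[keep]
        b <- b[keep]
    }
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(start = b * binSize + 1,
                                end = (b + 1) * binSize))
    GenomicRanges::reduce(sort(gr))
}

#' Exclude dropout-affected cells from a call matrix
#'
#' For each active cell, the cell is removed from the active set iff it
#' has no confident call for this variant (no call at all, or only calls
#' with case VAF below 0.5, or calls lacking a VAF) AND the variant's
#' locus is excluded for that cell: inside the cell's dropout intervals
#' (\code{type = "dropout"}), or outside its capture regions
#' (\code{type = "capture"}, for exome designs). Cells with a confident
#' call are never removed -- the call itself proves the allele was
#' amplified.
#'
#' n, N, f, N' and the scores are then recomputed on the reduced matrix
#' by the downstream accessors/scorers; when no call remains the variant
#' is dropped as a dropout artifact (e.g. a germline variant falsely
#' called as homozygous reference in the dropout cell).
#'
#' @param cm a \code{\link{CallMatrix}}.
#' @param regions named list (cell id -> \code{GRanges}) of per-cell
#'   dropout intervals or capture regions; cells absent from the list
#'   are never excluded in dropout mode and always excluded (for
#'   non-calling cells) in capture mode only if listed -- i.e. absent
#'   cells are left untouched in both modes.
#' @param type \code{"dropout"} (exclude inside regions) or
#'   \code{"capture"} (exclude outside regions).
#' @return The \code{CallMatrix} with an updated active set.
#' @export
applyAdaExclusion <- function(cm, regions,
                              type = c("dropout", "capture")) {
    type <- match.arg(type)
    stopifnot(is(cm, "CallMatrix"))
    if (!length(regions)) return(cm)
    act <- which(cm@active)
    if (length(act) < 2L) return(cm)
    sub <- cm@calls[act, act, drop = FALSE]
    rs <- rowSums(sub)
    locus <- GenomicRanges::GRanges(cm@chrom,
                                    IRanges::IRanges(cm@pos, cm@pos))
    drop_cell <- logical(length(act))
    for (k in seq_along(act)) {
        cell <- cm@cells[act[k]]
        gr <- regions[[cell]]
        if (is.null(gr)) next
        inside <- GenomicRanges::countOverlaps(locus, gr,
                                               ignore.strand = TRUE) > 0L
        excluded_locus <- if (type == "dropout") inside else !inside
        if (!excluded_locus) next
        vaf <- cm@vaf[act[k]]
        confident <- rs[k] > 0 && !is.na(vaf) && vaf >= 0.5
        if (!confident) drop_cell[k] <- TRUE
    }
    if (any(drop_cell)) cm@active[act[drop_cell]] <- FALSE
    cm
}

#' Apply dropout exclusion across all matrices
#'
#' @param matrices named list of \code{\link{CallMatrix}} objects.
#' @param regions,type see \code{\link{applyAdaExclusion}}.
#' @return Named list of matrices with updated active sets (matrices may
#'   end up with zero active calls; \code{\link{scoreCallMatrices}}
#'   drops those).
#' @export
applyAdaExclusionAll <- function(matrices, regions,
                                 type = c("dropout", "capture")) {
    type <- match.arg(type)
    lapply(matrices, applyAdaExclusion, regions = regions, type = type)
}

#' Load per-cell dropout/capture BEDs referenced from a manifest
#'
#' @param manifest result of \code{\link{readManifest}}.
#' @param column manifest column holding the per-cell BED path
#'   (\code{"dropout_bed"} or \code{"capture_bed"}).
#' @param dir directory against which relative paths resolve.
#' @return Named list (cell id -> \code{GRanges}) for the cells that
#'   have a BED attached.
#' @export
loadCellRegions <- function(manifest, column = "dropout_bed", dir = ".") {
    entries <- manifest$entries
    if (is.null(entries[[column]])) return(list())
    out <- list()
    for (i in seq_len(nrow(entries))) {
        p <- entries[[column]][i]
        if (is.na(p) || !nzchar(p)) next
        cell <- entries$case[i]
        if (!is.null(out[[cell]])) next
        if (!file.exists(p)) p <- file.path(dir, entries[[column]][i])
        out[[cell]] <- readBedRegions(p)
    }
    out
}

#' Detect dropout maps for every cell from SNP tables
#'
#' @param snpPaths named character vector (cell id -> SNP table path).
#' @param binSize,neighbors see \code{\link{detectDropoutBins}}.
#' @return Named list (cell id -> \code{GRanges}).
#' @export
detectCohortDropout <- function(snpPaths, binSize = 5000, neighbors = 1L) {
    out <- lapply(snpPaths, function(p)
        detectDropoutBins(readSnpTable(p), binSize = binSize,
                          neighbors = neighbors))
    names(out) <- names(snpPaths)
    out
}

#' Write a dropout map as BED
#'
#' @param gr \code{GRanges} of dropout intervals.
#' @param path output BED path (0-based half-open, as usual for BED).
#' @return \code{path}, invisibly.
#' @export
writeDropoutBed <- function(gr, path) {
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
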