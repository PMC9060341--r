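#' SVKey: identity of a structural-variant call
#'
#' Span coordinates follow the 0-based half-open convention
#' (\code{[start, end)}), so a deletion of bases 101..200 (1-based) is
#' \code{start = 100, end = 200} and has length \code{end - start}.
#' Insertions are point-like: they are stored with a 1-bp span at the
#' insertion point and matched by position rather than overlap.
#'
#' @slot chrom chromosome name.
#' @slot start,end 0-based half-open span; \code{start < end}.
#' @slot svtype one of DEL, DUP, INV, INS or a BND-like label.
#' @export
setClass("SVKey", representation(
    chrom = "character", start = "numeric", end = "numeric",
    svtype = "character"))

setValidity("SVKey", function(object) {
    if (!nzchar(object@svtype)) return("'svtype' must be non-empty")
    if (object@start >= object@end)
        return("zero- or negative-length span: start must be < end")
    TRUE
})

#' Construct an SVKey
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open span.
#' @param svtype SV type string (DEL, DUP, INV, INS, BND, ...).
#' @return An \code{\link{SVKey}} object.
#' @examples
#' reciprocalOverlap(SVKey("chr1", 0, 100, "DEL"),
#'                   SVKey("chr1", 50, 150, "DEL"))
#' @export
SVKey <- function(chrom, start, end, svtype) {
    new("SVKey", chrom = as.character(chrom), start = as.numeric(start),
        end = as.numeric(end), svtype = toupper(as.character(svtype)))
}

setMethod("show", "SVKey", function(object) {
    cat(sprintf("SVKey %s:%g-%g %s\n", object@chrom, object@start,
                object@end, object@svtype))
})

svKeyString <- function(chrom, start, end, svtype) {
    sprintf("%s:%g-%g:%s", chrom, start, end, svtype)
}

#' Reciprocal overlap of two SV spans
#'
#' Length of the span intersection divided by each span's own length;
#' \code{c(0, 0)} for different chromosomes or disjoint spans. Symmetric
#' up to swapping the two components.
#'
#' @param a,b \code{\link{SVKey}} objects.
#' @return Numeric vector \code{c(overlap/len(a), overlap/len(b))}.
#' @export
reciprocalOverlap <- function(a, b) {
    stopifnot(is(a, "SVKey"), is(b, "SVKey"))
    validObject(a); validObject(b)
    if (a@chrom != b@chrom) return(c(0, 0))
    ov <- max(0, min(a@end, b@end) - max(a@start, b@start))
    c(ov / (a@end - a@start), ov / (b@end - b@start))
}

#' Same-SV predicate
#'
#' Two SV calls are considered the same call iff they lie on the same
#' chromosome, have the same SV type, and overlap reciprocally by at
#' least \code{minOverlap} (default 50\%, boundary inclusive). Point-like
#' insertions are instead matched when their positions differ by at most
#' \code{insWindow} bases.
#'
#' @param a,b \code{\link{SVKey}} objects.
#' @param minOverlap reciprocal-overlap threshold in (0, 1].
#' @param insWindow position tolerance (bp) for insertions.
#' @return logical(1); symmetric in its arguments.
#' @export
sameSv <- function(a, b, minOverlap = 0.5, insWindow = 50) {
    stopifnot(is(a, "SVKey"), is(b, "SVKey"))
    if (a@chrom != b@chrom || a@svtype != b@svtype) return(FALSE)
    if (a@svtype == "INS")
        return(abs(a@start - b@start) <= insWindow)
    ro <- reciprocalOverlap(a, b)
    all(ro >= minOverlap)
}

#' Load SV calls from one pairwise VCF
#'
#' Parses SVTYPE and END from the INFO column (MANTA-style annotations).
#' Records without an SVTYPE are skipped; records without END get a 1-bp
#' span at POS (insertions, breakends).
#'
#' @param vcfPath,caseId,controlId,keepFiltered as in
#'   \code{\link{loadPairwiseCalls}}.
#' @return data.frame with columns \code{chrom, start, end, svtype,
#'   case, control, vaf, filter} (span 0-based half-open).
#' @export
loadPairwiseSvCalls <- function(vcfPath, caseId, controlId,
                                keepFiltered = FALSE) {
    if (!file.exists(vcfPath))
        stop("cannot read VCF: ", vcfPath)
    v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
    fix <- v@fix
    rownames(fix) <- NULL
    empty <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), svtype = character(0),
                        case = character(0), control = character(0),
                        vaf = numeric(0), filter = character(0),
                        stringsAsFactors = FALSE)
    if (is.null(fix) || nrow(fix) == 0L) return(empty)
    filt <- fix[, "FILTER"]
    filt[is.na(filt)] <- "."
    keep <- keepFiltered | filt %in% c("PASS", ".")
    svtype <- vcfR::extract.info(v, "SVTYPE")
    endpos <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
    keep <- keep & !is.na(svtype) & nzchar(svtype)
    if (!any(keep)) return(empty)
    pos <- as.numeric(fix[, "POS"])
    start0 <- pos - 1
    end0 <- ifelse(is.na(endpos), pos, endpos)
    af <- rep(NA_real_, nrow(fix))
    if (ncol(v@gt) >= 2L) {
        raw <- vcf_field(v@gt[, 2], v@gt[, 1], "AF")
        af <- suppressWarnings(as.numeric(vapply(
            strsplit(ifelse(is.na(raw), "", raw), ","),
            function(x) if (length(x)) x[1] else NA_character_,
            character(1))))
    }
    data.frame(chrom = fix[keep, "CHROM"], start = start0[keep],
               end = end0[keep], svtype = toupper(svtype[keep]),
               case = caseId, control = controlId, vaf = af[keep],
               filter = filt[keep], stringsAsFactors = FALSE)
}

#' Load all pairwise SV calls listed in a manifest
#'
#' @param manifest result of \code{\link{readManifest}}.
#' @param dir directory for relative VCF paths.
#' @param keepFiltered keep non-PASS records.
#' @return data.frame as \code{\link{loadPairwiseSvCalls}}.
#' @export
loadCohortSvCalls <- function(manifest, dir = ".", keepFiltered = FALSE) {
    entries <- manifest$entries
    parts <- lapply(seq_len(nrow(entries)), function(i) {
        p <- entries$vcf[i]
        if (!file.exists(p)) p <- file.path(dir, entries$vcf[i])
        loadPairwiseSvCalls(p, entries$case[i], entries$control[i],
                            keepFiltered = keepFiltered)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
}

#' Cluster SV calls into non-redundant variants
#'
#' Single-linkage clustering under the same-SV predicate
#' (\code{\link{sameSv}}): any chain of pairwise matches merges into one
#' cluster, so e.g. spans [0,100), [40,140), [80,180) form a single
#' cluster although the extremes overlap by less than 50\%. Each cluster
#' is labelled by its first-seen member (input order), which becomes the
#' representative span in downstream tables.
#'
#' @param svCalls data.frame from \code{\link{loadCohortSvCalls}}.
#' @param minOverlap,insWindow see \code{\link{sameSv}}.
#' @return \code{svCalls} with added columns \code{key} (representative
#'   label \code{chrom:start-end:TYPE}) plus \code{ref}/\code{alt}/
#'   \code{pos} fields so the result feeds straight into
#'   \code{\link{buildCallMatrices}}.
#' @export
clusterSvCalls <- function(svCalls, minOverlap = 0.5, insWindow = 50) {
    n <- nrow(svCalls)
    if (n == 0L) {
        svCalls$key <- character(0)
        svCalls$pos <- numeric(0)
        svCalls$ref <- character(0)
        svCalls$alt <- character(0)
        return(svCalls)
    }
    keys <- lapply(seq_len(n), function(i)
        SVKey(svCalls$chrom[i], svCalls$start[i], svCalls$end[i],
              svCalls$svtype[i]))
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) i <- parent[i]
        i
    }
    grp <- paste(svCalls$chrom, svCalls$svtype, sep = "\r")
    for (g in unique(grp)) {
        idx <- which(grp == g)
        if (length(idx) < 2L) next
        for (ai in seq_along(idx)[-1L]) {
            for (bi in seq_len(ai - 1L)) {
                i <- idx[ai]; j <- idx[bi]
                if (sameSv(keys[[i]], keys[[j]], minOverlap = minOverlap,
                           insWindow = insWindow)) {
                    ri <- find(i); rj <- find(j)
                    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
                }
            }
        }
    }
    root <- vapply(seq_len(n), find, integer(1))
    rep_idx <- root  # roots are always the smallest (first-seen) index
    svCalls$key <- svKeyString(svCalls$chrom[rep_idx],
                               svCalls$start[rep_idx],
                               svCalls$end[rep_idx],
                               svCalls$svtype[rep_idx])
    svCalls$pos <- svCalls$start[rep_idx] + 1  # 1-based locus for queries
    svCalls$ref <- "N"
    svCalls$alt <- paste0("<", svCalls$svtype[rep_idx], ">")
    svCalls
}
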