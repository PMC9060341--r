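#' Default score cut-offs and post-filters
#'
#' The (mosaic, germline) score plane is partitioned into four regions by
#' two cut-offs. The defaults of 0.75 for both keep perfect patterns
#' in-region under up to 25\% smearing by missed or spurious calls; they
#' are package defaults, not canonical values, and every analysis
#' function and CLI flag accepts overrides.
#'
#' The remaining values are the conventional per-call confidence filters
#' for clone-derived data: minimum allele fraction 0.35 (removes
#' culture-acquired artifacts), indels shorter than 10 bp only, depth
#' above 10 reads, and at least 2 alternate-supporting reads. They are
#' applied by \code{\link{postFilterCalls}}, optionally, and not in SV
#' mode.
#'
#' @param mosaic_cut,germline_cut score thresholds in [0, 1]; a score
#'   equal to the cut-off is inside the high region.
#' @param vaf_min minimum variant allele fraction.
#' @param indel_max_len indels with length (in bases) >= this are
#'   dropped.
#' @param depth_min calls need depth strictly greater than this.
#' @param alt_min minimum alternate-supporting reads.
#' @return Named list of cut-off values.
#' @export
defaultCutoffs <- function(mosaic_cut = 0.75, germline_cut = 0.75,
                           vaf_min = 0.35, indel_max_len = 10,
                           depth_min = 10, alt_min = 2) {
    stopifnot(mosaic_cut >= 0, mosaic_cut <= 1,
              germline_cut >= 0, germline_cut <= 1,
              vaf_min >= 0, vaf_min <= 1)
    list(mosaic_cut = mosaic_cut, germline_cut = germline_cut,
         vaf_min = vaf_min, indel_max_len = indel_max_len,
         depth_min = depth_min, alt_min = alt_min)
}

#' Read cut-offs from a key = value config file
#'
#' Plain-text file with one \code{key = value} pair per line (\code{#}
#' comments allowed); unknown keys are an error. Values override the
#' defaults of \code{\link{defaultCutoffs}}.
#'
#' @param path path to the config file.
#' @return Named list as from \code{\link{defaultCutoffs}}.
#' @export
readCutoffsConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    cuts <- defaultCutoffs()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L)
            stop("malformed config line: ", ln)
        key <- trimws(kv[1])
        if (!key %in% names(cuts))
            stop("unknown cut-off '", key, "' in config file")
        cuts[[key]] <- as.numeric(trimws(kv[2]))
    }
    do.call(defaultCutoffs, cuts)
}

#' Four-way classification of scored variants
#'
#' The unit score square is partitioned into: \emph{mosaic} (high mosaic
#' score, low germline score -- calls arranged in rows),
#' \emph{germline} (high germline, low mosaic -- calls arranged in
#' columns), \emph{high_frequency_mosaic} (both high -- mutations present
#' in a large fraction of cells, e.g. from early embryonic divisions) and
#' \emph{noise} (both low -- sporadic false positives). "High" means
#' score >= cut-off, so the regions are mutually exclusive and exhaustive
#' and a perfect score of 1 always classifies.
#'
#' @param mosaic,germline numeric score vectors in [0, 1].
#' @param cutoffs list from \code{\link{defaultCutoffs}}.
#' @return Character vector over \code{c("mosaic", "germline",
#'   "high_frequency_mosaic", "noise")}.
#' @examples
#' scoreCategory(c(1, 0.25, 0.9, 0.1), c(0.25, 1, 0.9, 0.1))
#' @export
scoreCategory <- function(mosaic, germline, cutoffs = defaultCutoffs()) {
    stopifnot(all(mosaic >= 0 & mosaic <= 1),
              all(germline >= 0 & germline <= 1))
    hi_m <- mosaic >= cutoffs$mosaic_cut
    hi_g <- germline >= cutoffs$germline_cut
    ifelse(hi_m & hi_g, "high_frequency_mosaic",
           ifelse(hi_m, "mosaic",
                  ifelse(hi_g, "germline", "noise")))
}

#' Annotate a score table with categories
#'
#' @param scores data.frame from \code{\link{scoreCallMatrices}}.
#' @param cutoffs list from \code{\link{defaultCutoffs}}.
#' @return \code{scores} with an added \code{category} column.
#' @export
classifyScores <- function(scores, cutoffs = defaultCutoffs()) {
    scores$category <- scoreCategory(scores$mosaic_score,
                                     scores$germline_score, cutoffs)
    scores
}

#' Expand scored variants to per-carrier-cell annotated calls
#'
#' One row per (variant, carrier cell), carrying the variant's scores
#' and category plus the carrier's case-side VAF from the call matrix.
#' For germline variants the "carriers" are the cells estimated to have
#' lost the variant (the column cells), matching the mosaic-side
#' interpretation of f.
#'
#' @param scores classified score table (\code{\link{classifyScores}}).
#' @param matrices the call matrices the scores came from.
#' @return data.frame with columns of \code{scores} plus \code{cell} and
#'   \code{cell_vaf}.
#' @export
annotateCarriers <- function(scores, matrices) {
    rows <- lapply(seq_len(nrow(scores)), function(i) {
        carriers <- strsplit(scores$carrier_cells[i], ",", fixed = TRUE)[[1]]
        if (!length(carriers)) return(NULL)
        cm <- matrices[[scores$key[i]]]
        vafs <- if (!is.null(cm)) perCellVaf(cm)[carriers] else NA_real_
        cbind(scores[rep(i, length(carriers)), , drop = FALSE],
              data.frame(cell = carriers, cell_vaf = as.numeric(vafs),
                         stringsAsFactors = FALSE))
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
        out <- cbind(scores[0, , drop = FALSE],
                     data.frame(cell = character(0), cell_vaf = numeric(0)))
    }
    rownames(out) <- NULL
    out
}

#' Per-call confidence post-filters
#'
#' Applies the optional confidence filters to annotated calls: VAF below
#' \code{vaf_min}, indel length >= \code{indel_max_len}, depth <=
#' \code{depth_min}, or fewer than \code{alt_min} alternate reads. A
#' missing field never triggers its filter (set \code{dropMissing} to
#' invert that and drop calls lacking the field). Indel length is the
#' difference between ref and alt allele lengths; SNVs have length 0 and
#' are never indel-filtered.
#'
#' @param calls data.frame with (any of) columns \code{vaf} (or
#'   \code{cell_vaf}), \code{ref}, \code{alt}, \code{depth},
#'   \code{alt_reads}.
#' @param cutoffs list from \code{\link{defaultCutoffs}}.
#' @param dropMissing drop calls whose filterable fields are missing.
#' @return \code{calls} with added logical \code{keep} and character
#'   \code{filter_reason} (empty string when kept).
#' @export
postFilterCalls <- function(calls, cutoffs = defaultCutoffs(),
                            dropMissing = FALSE) {
    n <- nrow(calls)
    vaf <- if (!is.null(calls$vaf)) calls$vaf else calls$cell_vaf
    if (is.null(vaf)) vaf <- rep(NA_real_, n)
    indel_len <- if (!is.null(calls$ref) && !is.null(calls$alt))
        abs(nchar(calls$alt) - nchar(calls$ref)) else rep(NA_real_, n)
    depth <- if (!is.null(calls$depth)) calls$depth else rep(NA_real_, n)
    alt_reads <- if (!is.null(calls$alt_reads)) calls$alt_reads
                 else rep(NA_real_, n)

    miss_fails <- dropMissing
    fail_vaf <- ifelse(is.na(vaf), miss_fails, vaf < cutoffs$vaf_min)
    fail_indel <- ifelse(is.na(indel_len), miss_fails,
                         indel_len > 0 & indel_len >= cutoffs$indel_max_len)
    fail_depth <- ifelse(is.na(depth), miss_fails,
                         depth <= cutoffs$depth_min)
    fail_alt <- ifelse(is.na(alt_reads), miss_fails,
                       alt_reads < cutoffs$alt_min)

    reason <- rep("", n)
    reason[fail_alt] <- "alt_reads"
    reason[fail_depth] <- "depth"
    reason[fail_indel] <- "indel_len"
    reason[fail_vaf] <- "vaf"
    calls$keep <- reason == ""
    calls$filter_reason <- reason
    calls
}
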