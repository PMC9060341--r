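#' Read a pairwise-comparison manifest
#'
#' The manifest is a tab-separated file with a header naming at least the
#' columns \code{case}, \code{control} and \code{vcf}: one row per ordered
#' comparison, where the VCF holds the somatic calls made with
#' \code{case} as tumor-like and \code{control} as normal-like sample.
#' Optional columns \code{dropout_bed} and \code{capture_bed} attach
#' per-cell region files (keyed by the case cell) for allele-dropout
#' analysis mode.
#'
#' The cell list returned defines the row/column order of every
#' \code{\link{CallMatrix}} built from this manifest: cells appear in
#' first-occurrence order scanning case then control within each row.
#'
#' @param path path to the manifest TSV.
#' @return A list with elements \code{entries} (data.frame of the
#'   manifest rows) and \code{cells} (ordered character vector of the N
#'   distinct cell identifiers).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("case\tcontrol\tvcf", "A\tB\ta_b.vcf", "B\tA\tb_a.vcf"), tf)
#' readManifest(tf)$cells
#' @export
readManifest <- function(path) {
    if (!file.exists(path))
        stop("manifest file not found: ", path)
    entries <- utils::read.delim(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
    required <- c("case", "control", "vcf")
    missing_cols <- setdiff(required, names(entries))
    if (length(missing_cols))
        stop("manifest is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    if (nrow(entries) == 0L)
        stop("manifest has no comparison rows")
    if (any(entries$case == entries$control))
        stop("manifest contains self-comparison(s): ",
             paste(unique(entries$case[entries$case == entries$control]),
                   collapse = ", "))
    pair_id <- paste(entries$case, entries$control, sep = "\r")
    if (anyDuplicated(pair_id))
        stop("duplicate ordered pair(s) in manifest: ",
             paste(unique(sub("\r", " vs ", pair_id[duplicated(pair_id)])),
                   collapse = ", "))
    cells <- unique(as.vector(t(as.matrix(entries[, c("case", "control")]))))
    if (length(cells) < 2L)
        stop("manifest must involve at least 2 distinct cells")
    list(entries = entries, cells = cells)
}

#' Check all-to-all completeness of a manifest
#'
#' Scoring assumes every ordered pair (i, j), i != j, was compared once.
#' Incomplete designs are allowed (absent comparisons count as no-call)
#' but weaken the scores, so completeness is reported rather than
#' enforced.
#'
#' @param manifest result of \code{\link{readManifest}}.
#' @return A list with \code{complete} (logical), \code{n_expected},
#'   \code{n_present} and \code{missing_pairs} (data.frame).
#' @export
manifestCompleteness <- function(manifest) {
    cells <- manifest$cells
    exp_pairs <- expand.grid(control = cells, case = cells,
                             stringsAsFactors = FALSE)[, c("case", "control")]
    exp_pairs <- exp_pairs[exp_pairs$case != exp_pairs$control, ]
    have <- paste(manifest$entries$case, manifest$entries$control, sep = "\r")
    want <- paste(exp_pairs$case, exp_pairs$control, sep = "\r")
    miss <- exp_pairs[!(want %in% have), , drop = FALSE]
    list(complete = nrow(miss) == 0L,
         n_expected = nrow(exp_pairs),
         n_present = length(have),
         missing_pairs = miss)
}

#' Read genomic regions from a BED file
#'
#' Thin wrapper over \code{rtracklayer::import} returning a
#' \code{GRanges}; BED's 0-based half-open coordinates are converted to
#' the 1-based inclusive convention used internally.
#'
#' @param path path to a BED file.
#' @return A \code{GRanges} of the (reduced) regions.
#' @export
readBedRegions <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    GenomicRanges::reduce(rtracklayer::import(path, format = "BED"))
}

vcf_field <- function(gt_strings, format, field) {
    # extract one FORMAT field from raw genotype strings; NA when absent
    keys <- strsplit(format, ":", fixed = TRUE)
    vals <- strsplit(gt_strings, ":", fixed = TRUE)
    vapply(seq_along(vals), function(i) {
        k <- match(field, keys[[i]])
        if (is.na(k) || k > length(vals[[i]])) NA_character_
        else vals[[i]][k]
    }, character(1))
}

#' Load calls from one pairwise VCF
#'
#' Reads the VCF of a single ordered (case, control) comparison and
#' returns one row per record x alternate allele; multi-allelic records
#' are split so each call carries a single-allele
#' \code{chrom:pos:ref:alt} key. Left-alignment of indels is assumed done
#' upstream by the caller.
#'
#' The case-side VAF is taken from the first sample column with
#' precedence: per-allele \code{AF} FORMAT field, else alt/total from the
#' \code{AD} allelic depths, else missing. Records failing their caller's
#' FILTER are dropped unless \code{keepFiltered = TRUE}; \code{PASS} and
#' \code{.} both count as passing. When \code{inclusion} regions are
#' given, records whose position lies outside them are dropped.
#'
#' @param vcfPath path to the VCF (uncompressed or bgzipped).
#' @param caseId,controlId cell identifiers of the ordered comparison.
#' @param inclusion optional \code{GRanges} of regions to keep
#'   (e.g. from \code{\link{readBedRegions}}).
#' @param keepFiltered keep records with a non-PASS FILTER value.
#' @return data.frame with columns \code{key, chrom, pos, ref, alt, case,
#'   control, vaf, depth, alt_reads, filter}.
#' @export
loadPairwiseCalls <- function(vcfPath, caseId, controlId, inclusion = NULL,
                              keepFiltered = FALSE) {
    if (!file.exists(vcfPath))
        stop("cannot read VCF: ", vcfPath)
    v <- tryCatch(vcfR::read.vcfR(vcfPath, verbose = FALSE),
                  error = function(e)
                      stop("failed to parse VCF '", vcfPath, "': ",
                           conditionMessage(e)))
    fix <- v@fix
    rownames(fix) <- NULL
    empty <- data.frame(key = character(0), chrom = character(0),
                        pos = numeric(0), ref = character(0),
                        alt = character(0), case = character(0),
                        control = character(0), vaf = numeric(0),
                        depth = numeric(0), alt_reads = numeric(0),
                        filter = character(0), stringsAsFactors = FALSE)
    if (is.null(fix) || nrow(fix) == 0L)
        return(empty)
    filt <- unname(fix[, "FILTER"])
    filt[is.na(filt)] <- "."
    keep <- keepFiltered | filt %in% c("PASS", ".")
    if (!any(keep)) return(empty)

    has_gt <- ncol(v@gt) >= 2L
    format <- if (has_gt) unname(v@gt[, 1]) else rep(NA_character_, nrow(fix))
    gt <- if (has_gt) unname(v@gt[, 2]) else rep(NA_character_, nrow(fix))
    af_raw <- if (has_gt) vcf_field(gt, format, "AF") else rep(NA_character_, nrow(fix))
    ad_raw <- if (has_gt) vcf_field(gt, format, "AD") else rep(NA_character_, nrow(fix))
    dp_raw <- if (has_gt) vcf_field(gt, format, "DP") else rep(NA_character_, nrow(fix))

    rows <- lapply(which(keep), function(i) {
        chrom_i <- unname(fix[i, "CHROM"])
        ref_i <- unname(fix[i, "REF"])
        alts <- strsplit(unname(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
        alts <- alts[!is.na(alts) & nzchar(alts) & alts != "."]
        if (!length(alts)) return(NULL)
        n_alt <- length(alts)
        afs <- suppressWarnings(as.numeric(
            strsplit(ifelse(is.na(af_raw[i]), "", af_raw[i]), ",")[[1]]))
        ads <- suppressWarnings(as.numeric(
            strsplit(ifelse(is.na(ad_raw[i]), "", ad_raw[i]), ",")[[1]]))
        dp <- suppressWarnings(as.numeric(dp_raw[i]))
        ad_total <- if (length(ads)) sum(ads, na.rm = TRUE) else NA_real_
        vaf <- rep(NA_real_, n_alt)
        alt_reads <- rep(NA_real_, n_alt)
        for (k in seq_len(n_alt)) {
            if (length(ads) >= k + 1L && !is.na(ads[k + 1L]))
                alt_reads[k] <- ads[k + 1L]
            if (length(afs) >= k && !is.na(afs[k]))
                vaf[k] <- afs[k]
            else if (!is.na(alt_reads[k]) && !is.na(ad_total) && ad_total > 0)
                vaf[k] <- alt_reads[k] / ad_total
        }
        depth <- if (!is.na(dp)) dp else ad_total
        pos <- as.numeric(fix[i, "POS"])
        data.frame(key = sprintf("%s:%d:%s:%s", chrom_i, pos, ref_i, alts),
                   chrom = chrom_i, pos = pos, ref = ref_i,
                   alt = alts, case = caseId, control = controlId,
                   vaf = vaf, depth = rep(depth, n_alt),
                   alt_reads = alt_reads, filter = filt[i],
                   stringsAsFactors = FALSE)
    })
    calls <- do.call(rbind, rows)
    if (is.null(calls)) return(empty)
    rownames(calls) <- NULL
    if (!is.null(inclusion) && length(inclusion) > 0L) {
        pts <- GenomicRanges::GRanges(calls$chrom,
                                      IRanges::IRanges(calls$pos, calls$pos))
        hit <- GenomicRanges::countOverlaps(pts, inclusion,
                                            ignore.strand = TRUE) > 0L
        calls <- calls[hit, , drop = FALSE]
    }
    calls
}

#' Load all pairwise calls listed in a manifest
#'
#' @param manifest result of \code{\link{readManifest}}.
#' @param dir directory that relative VCF paths in the manifest are
#'   resolved against (defaults to the manifest's own directory when the
#'   manifest was read from file; pass "." for as-is paths).
#' @param inclusion,keepFiltered passed to
#'   \code{\link{loadPairwiseCalls}}.
#' @return data.frame concatenating the calls of every comparison.
#' @export
loadCohortCalls <- function(manifest, dir = ".", inclusion = NULL,
                            keepFiltered = FALSE) {
    entries <- manifest$entries
    parts <- lapply(seq_len(nrow(entries)), function(i) {
        p <- entries$vcf[i]
        if (!file.exists(p)) p <- file.path(dir, entries$vcf[i])
        loadPairwiseCalls(p, entries$case[i], entries$control[i],
                          inclusion = inclusion, keepFiltered = keepFiltered)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
}

#' Read a per-cell heterozygous-SNP table
#'
#' TSV with columns \code{chrom, pos, alt_reads, depth} giving, for known
#' heterozygous SNP positions of the individual, the read support
#' observed in one cell. Used by \code{\link{detectDropoutBins}}.
#'
#' @param path path to the TSV.
#' @return data.frame with an added \code{vaf = alt_reads/depth} column.
#' @export
readSnpTable <- function(path) {
    snps <- utils::read.delim(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    required <- c("chrom", "pos", "alt_reads", "depth")
    missing_cols <- setdiff(required, names(snps))
    if (length(missing_cols))
        stop("SNP table is missing column(s): ",
             paste(missing_cols, collapse = ", "))
    snps$vaf <- ifelse(snps$depth > 0, snps$alt_reads / snps$depth, NA_real_)
    snps
}

score_columns <- c("key", "chrom", "pos", "ref", "alt", "n", "N_active",
                   "f", "N_prime", "mosaic_score", "germline_score",
                   "carrier_cells")

#' Write / read per-variant score tables
#'
#' Scores are stored as TSV with one row per variant and full numeric
#' precision (17 significant digits), so that
#' \code{readScores(writeScores(x))} reproduces every value exactly.
#'
#' @param scores data.frame from \code{\link{scoreCallMatrices}}
#'   (optionally with a \code{category} column from
#'   \code{\link{classifyScores}}).
#' @param path output (input) TSV path.
#' @return \code{writeScores} returns \code{path} invisibly;
#'   \code{readScores} returns the data.frame.
#' @export
writeScores <- function(scores, path) {
    df <- as.data.frame(scores)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    ok <- tryCatch({
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write scores to: ", path)
    invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
    if (!file.exists(path))
        stop("scores file not found: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    num_cols <- intersect(c("pos", "n", "N_active", "f", "N_prime",
                            "mosaic_score", "germline_score",
                            "start", "end"), names(df))
    df[num_cols] <- lapply(df[num_cols], as.numeric)
    df
}

#' Write per-cell annotated calls
#'
#' One row per (variant, carrier cell) pair: the cells estimated to carry
#' a mosaic mutation (or, for germline variants, the cells that lost it),
#' together with the variant's scores, category and that cell's VAF.
#'
#' @param annotated data.frame from \code{\link{annotateCarriers}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotatedCalls <- function(annotated, path) {
    writeScores(annotated, path)
}
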