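#' @importFrom rlang .data
#' @importFrom tools file_path_sans_ext
NULL

log_msg <- function(level, threshold, ...) {
    levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
    if (levels[[level]] >= levels[[threshold]])
        message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

write_provenance <- function(outDir, command, params) {
    lines <- c(sprintf("command\t%s", command),
               sprintf("package_version\t%s",
                       as.character(utils::packageVersion("pairwiseMosaic"))),
               vapply(names(params), function(k)
                   sprintf("%s\t%s", k,
                           paste(format(params[[k]]), collapse = ",")),
                   character(1)))
    writeLines(lines, file.path(outDir, paste0(command, "_provenance.tsv")))
}

#' Score all variants of a pairwise-comparison cohort
#'
#' The 'score' stage: reads the manifest, loads every pairwise VCF,
#' builds one call matrix per non-redundant variant, optionally applies
#' allele-dropout (or capture-region) exclusion, scores each matrix and
#' writes \code{scores.tsv} plus the score-plane density plot to
#' \code{outDir}. Incomplete all-to-all designs are scored with a
#' warning, since the fraction estimate assumes N^2 comparisons.
#'
#' @param manifestPath path to the manifest TSV
#'   (\code{\link{readManifest}}).
#' @param outDir output directory, created if needed.
#' @param inclusionBed optional BED restricting the analysed regions.
#' @param ada \code{"off"} (default), \code{"dropout"} or
#'   \code{"capture"}: apply per-cell region exclusion using the
#'   manifest's \code{dropout_bed}/\code{capture_bed} columns (or
#'   \code{adaRegions}).
#' @param adaRegions optional named list (cell -> \code{GRanges})
#'   overriding the manifest's per-cell BEDs.
#' @param keepFiltered keep VCF records with non-PASS FILTER.
#' @param sv treat input VCFs as structural-variant calls and cluster
#'   them by reciprocal overlap instead of exact keys.
#' @param plot write the density plot (TSV side-file included).
#' @param logLevel one of \code{"debug", "info", "warn", "quiet"}.
#' @return A list with \code{scores} (data.frame), \code{matrices}
#'   (named list of \code{\link{CallMatrix}}), \code{cells} and
#'   \code{scoresPath}.
#' @export
scoreCohort <- function(manifestPath, outDir, inclusionBed = NULL,
                        ada = c("off", "dropout", "capture"),
                        adaRegions = NULL, keepFiltered = FALSE,
                        sv = FALSE, plot = TRUE, logLevel = "info") {
    ada <- match.arg(ada)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    manifest <- readManifest(manifestPath)
    dir <- dirname(manifestPath)
    comp <- manifestCompleteness(manifest)
    if (!comp$complete)
        warning(sprintf(
            "manifest is not all-to-all: %d of %d ordered pairs present",
            comp$n_present, comp$n_expected))
    inclusion <- if (!is.null(inclusionBed)) readBedRegions(inclusionBed)
    log_msg("info", logLevel, "loading calls for ",
            length(manifest$cells), " cells (", nrow(manifest$entries),
            " comparisons)")
    if (sv) {
        calls <- loadCohortSvCalls(manifest, dir = dir,
                                   keepFiltered = keepFiltered)
        calls <- clusterSvCalls(calls)
        calls$chrom <- as.character(calls$chrom)
    } else {
        calls <- loadCohortCalls(manifest, dir = dir,
                                 inclusion = inclusion,
                                 keepFiltered = keepFiltered)
    }
    log_msg("info", logLevel, nrow(calls), " pairwise calls loaded")
    matrices <- buildCallMatrices(calls, manifest$cells)
    if (ada != "off") {
        regions <- if (!is.null(adaRegions)) adaRegions
            else loadCellRegions(manifest,
                                 column = paste0(ada, "_bed"), dir = dir)
        if (!length(regions))
            warning("ADA mode requested but no per-cell regions found")
        matrices <- applyAdaExclusionAll(matrices, regions, type = ada)
    }
    scores <- scoreCallMatrices(matrices)
    scoresPath <- file.path(outDir, if (sv) "scores_sv.tsv" else "scores.tsv")
    writeScores(scores, scoresPath)
    if (plot)
        plotScoreDensity(scores, defaultCutoffs(),
                         file.path(outDir, if (sv) "score_density_sv.png"
                                   else "score_density.png"))
    write_provenance(outDir, if (sv) "score_sv" else "score",
                     list(manifest = manifestPath,
                          cells = length(manifest$cells),
                          inclusion = inclusionBed %||% "none", ada = ada,
                          keep_filtered = keepFiltered,
                          variants = nrow(scores)))
    log_msg("info", logLevel, nrow(scores), " variants scored")
    invisible(list(scores = scores, matrices = matrices,
                   cells = manifest$cells, scoresPath = scoresPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify scored variants and write annotated outputs
#'
#' The 'call' stage: consumes the score table written by
#' \code{\link{scoreCohort}} (two-stage by design, so cut-offs can be
#' re-tuned without re-reading VCFs), assigns the four-way category,
#' writes the annotated per-variant and per-carrier-cell tables, the
#' region-annotated density plot and the summary report plots.
#'
#' @param scores score table or path to \code{scores.tsv}.
#' @param outDir output directory.
#' @param cutoffs list from \code{\link{defaultCutoffs}}.
#' @param matrices optional list of \code{\link{CallMatrix}} (for
#'   per-cell VAF annotation; without it VAFs are NA).
#' @param applyFilters apply the per-call confidence post-filters
#'   (\code{\link{postFilterCalls}}) to the annotated calls.
#' @param plot write plots.
#' @param logLevel verbosity.
#' @return A list with \code{classified}, \code{annotated} (data.frames)
#'   and their file paths.
#' @export
callCohort <- function(scores, outDir, cutoffs = defaultCutoffs(),
                       matrices = NULL, applyFilters = FALSE, plot = TRUE,
                       logLevel = "info") {
    if (is.character(scores)) {
        if (!file.exists(scores))
            stop("score table not found (run the score stage first): ",
                 scores)
        scores <- readScores(scores)
    }
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    classified <- classifyScores(scores, cutoffs)
    annotated <- annotateCarriers(classified, matrices %||% list())
    if (applyFilters) {
        annotated <- postFilterCalls(annotated, cutoffs)
        annotated <- annotated[annotated$keep, , drop = FALSE]
    }
    classifiedPath <- file.path(outDir, "calls_classified.tsv")
    annotatedPath <- file.path(outDir, "calls_per_cell.tsv")
    writeScores(classified, classifiedPath)
    writeAnnotatedCalls(annotated, annotatedPath)
    if (plot) {
        plotScoreDensity(classified, cutoffs,
                         file.path(outDir, "score_density_classified.png"))
        plotReports(annotated, file.path(outDir, "report"))
    }
    write_provenance(outDir, "call",
                     list(mosaic_cut = cutoffs$mosaic_cut,
                          germline_cut = cutoffs$germline_cut,
                          filters = applyFilters,
                          variants = nrow(classified)))
    log_msg("info", logLevel, nrow(classified), " variants classified")
    invisible(list(classified = classified, annotated = annotated,
                   classifiedPath = classifiedPath,
                   annotatedPath = annotatedPath))
}
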