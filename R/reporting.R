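#' @importFrom ggplot2 ggplot aes geom_point geom_bar geom_histogram
#'   geom_tile geom_text annotate scale_size_area labs theme_bw
#'   coord_cartesian facet_wrap ggsave scale_fill_manual element_text
#'   theme geom_col
NULL

region_fills <- c(mosaic = "#c8e6c0", germline = "#c5dcf0",
                  high_frequency_mosaic = "#d9d9d9", noise = "#f4c7c3")

save_plot <- function(p, path, width = 6, height = 5) {
    ok <- tryCatch({
        ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
        TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write plot to: ", path)
    invisible(path)
}

side_tsv <- function(path) paste0(tools::file_path_sans_ext(path), ".tsv")

#' Density scatter plot of the score plane
#'
#' Every scored variant is a point at (mosaic score, germline score);
#' coincident points collapse to one dot whose size and colour encode
#' multiplicity. The four classification regions are shaded: mosaic
#' (green), germline (blue), high-frequency mosaic (grey), noise (red).
#' The plotted table is also written to a TSV side-file next to the
#' image so every number is machine-checkable.
#'
#' @param scores score table (\code{\link{scoreCallMatrices}}).
#' @param cutoffs list from \code{\link{defaultCutoffs}}.
#' @param path output image path (.png or .pdf).
#' @return \code{path}, invisibly.
#' @export
plotScoreDensity <- function(scores, cutoffs = defaultCutoffs(), path) {
    mc <- cutoffs$mosaic_cut
    gc <- cutoffs$germline_cut
    if (nrow(scores)) {
        pts <- as.data.frame(table(
            mosaic_score = round(scores$mosaic_score, 3),
            germline_score = round(scores$germline_score, 3)),
            stringsAsFactors = FALSE)
        names(pts)[3] <- "count"
        pts <- pts[pts$count > 0, , drop = FALSE]
        pts$mosaic_score <- as.numeric(pts$mosaic_score)
        pts$germline_score <- as.numeric(pts$germline_score)
    } else {
        pts <- data.frame(mosaic_score = numeric(0),
                          germline_score = numeric(0),
                          count = integer(0))
    }
    pts <- pts[order(pts$mosaic_score, pts$germline_score), , drop = FALSE]
    utils::write.table(pts, side_tsv(path), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p <- ggplot() +
        annotate("rect", xmin = mc, xmax = 1.02, ymin = -0.02, ymax = gc,
                 fill = region_fills[["mosaic"]]) +
        annotate("rect", xmin = -0.02, xmax = mc, ymin = gc, ymax = 1.02,
                 fill = region_fills[["germline"]]) +
        annotate("rect", xmin = mc, xmax = 1.02, ymin = gc, ymax = 1.02,
                 fill = region_fills[["high_frequency_mosaic"]]) +
        annotate("rect", xmin = -0.02, xmax = mc, ymin = -0.02, ymax = gc,
                 fill = region_fills[["noise"]]) +
        coord_cartesian(xlim = c(-0.02, 1.02), ylim = c(-0.02, 1.02),
                        expand = FALSE) +
        labs(x = "mosaic score", y = "germline score",
             size = "calls", colour = "calls") +
        theme_bw()
    if (nrow(pts))
        p <- p + geom_point(data = pts,
                            aes(x = .data$mosaic_score,
                                y = .data$germline_score,
                                size = .data$count,
                                colour = .data$count)) +
            scale_size_area(max_size = 8)
    save_plot(p, path)
}

#' Six-class mutation spectrum of SNV calls
#'
#' Counts single-nucleotide substitutions into the six pyrimidine-strand
#' classes C>A, C>G, C>T, T>A, T>C, T>G; purine-strand calls (ref G or
#' A) are reverse-complemented first, so e.g. G>A counts as C>T. Indels
#' and non-ACGT alleles are excluded; class counts always sum to the
#' number of spectrum-eligible SNVs.
#'
#' @param variants data.frame with \code{ref} and \code{alt} columns.
#' @return Named integer vector over the six classes.
#' @examples
#' mutationSpectrum(data.frame(ref = c("G", "C"), alt = c("A", "T")))
#' @export
mutationSpectrum <- function(variants) {
    classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    ref <- toupper(variants$ref)
    alt <- toupper(variants$alt)
    snv <- nchar(ref) == 1 & nchar(alt) == 1 &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
        ref != alt
    ref <- ref[snv]
    alt <- alt[snv]
    flip <- ref %in% c("G", "A")
    ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    table(factor(paste(ref, alt, sep = ">"), levels = classes))
}

#' Summary report plots for classified calls
#'
#' Writes four plot/TSV pairs under \code{prefix}: per-category variant
#' counts, per-cell carrier call counts (a shared mutation counts once
#' per carrier cell), the VAF histogram of carrier calls, and the
#' six-class mutation spectrum.
#'
#' @param annotated per-carrier annotated calls
#'   (\code{\link{annotateCarriers}}).
#' @param prefix output path prefix, e.g. \code{"out/report"}.
#' @return Character vector of the image paths, invisibly.
#' @export
plotReports <- function(annotated, prefix) {
    paths <- character(0)

    variants <- annotated[!duplicated(annotated$key), , drop = FALSE]
    cat_counts <- as.data.frame(table(category = variants$category),
                                stringsAsFactors = FALSE)
    names(cat_counts)[2] <- "n_variants"
    p1 <- file.path(paste0(prefix, "_category_counts.png"))
    utils::write.table(cat_counts, side_tsv(p1), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_plot(ggplot(cat_counts,
                     aes(x = .data$category, y = .data$n_variants)) +
              geom_col(fill = "steelblue") +
              labs(x = NULL, y = "variants") + theme_bw() +
              theme(axis.text.x = element_text(angle = 30, hjust = 1)), p1)
    paths <- c(paths, p1)

    cell_counts <- as.data.frame(table(cell = annotated$cell,
                                       category = annotated$category),
                                 stringsAsFactors = FALSE)
    names(cell_counts)[3] <- "n_calls"
    p2 <- file.path(paste0(prefix, "_cell_counts.png"))
    utils::write.table(cell_counts, side_tsv(p2), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    save_plot(ggplot(cell_counts,
                     aes(x = .data$cell, y = .data$n_calls,
                         fill = .data$category)) +
              geom_col() + labs(x = NULL, y = "calls") + theme_bw() +
              theme(axis.text.x = element_text(angle = 90, vjust = 0.5)),
              p2, width = 8)
    paths <- c(paths, p2)

    vafs <- annotated[!is.na(annotated$cell_vaf), , drop = FALSE]
    p3 <- file.path(paste0(prefix, "_vaf.png"))
    utils::write.table(vafs[, c("key", "cell", "cell_vaf", "category")],
                       side_tsv(p3), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pv <- ggplot(vafs, aes(x = .data$cell_vaf)) +
        geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey40") +
        labs(x = "variant allele fraction", y = "calls") + theme_bw()
    save_plot(pv, p3)
    paths <- c(paths, p3)

    spec <- mutationSpectrum(variants)
    spec_df <- data.frame(class = names(spec), n = as.integer(spec))
    p4 <- file.path(paste0(prefix, "_spectrum.png"))
    utils::write.table(spec_df, side_tsv(p4), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_plot(ggplot(spec_df, aes(x = .data$class, y = .data$n,
                                  fill = .data$class)) +
              geom_col(show.legend = FALSE) +
              labs(x = NULL, y = "SNVs") + theme_bw(), p4)
    paths <- c(paths, p4)

    invisible(paths)
}

#' Render pairwise call matrices for selected variants
#'
#' Draws the N x N binary matrix of each requested variant as a tile
#' grid (case cells as rows, control cells as columns), annotated with
#' the variant's mosaic/germline scores and each cell's VAF; excluded
#' (inactive) cells are marked. Multiple variants become facets of one
#' image.
#'
#' @param keys variant key(s) to render.
#' @param matrices named list of \code{\link{CallMatrix}} objects.
#' @param scores score table covering \code{keys} (optional but
#'   recommended; used for the panel headers).
#' @param path output image path.
#' @return \code{path}, invisibly.
#' @export
renderMatrixPlot <- function(keys, matrices, scores = NULL, path) {
    missing_keys <- setdiff(keys, names(matrices))
    if (length(missing_keys)) {
        near <- unlist(lapply(missing_keys, function(k)
            utils::head(agrep(k, names(matrices), value = TRUE,
                              max.distance = 0.2), 3)))
        stop("variant(s) not found: ", paste(missing_keys, collapse = ", "),
             if (length(near)) paste0("; did you mean: ",
                                      paste(unique(near), collapse = ", "))
             else "")
    }
    long <- do.call(rbind, lapply(keys, function(k) {
        cm <- matrices[[k]]
        df <- expand.grid(case = cm@cells, control = cm@cells,
                          stringsAsFactors = FALSE)
        df$call <- as.vector(cm@calls[cbind(match(df$case, cm@cells),
                                            match(df$control, cm@cells))])
        df$active <- cm@active[match(df$case, cm@cells)] &
            cm@active[match(df$control, cm@cells)]
        header <- k
        if (!is.null(scores)) {
            s <- scores[scores$key == k, , drop = FALSE]
            if (nrow(s))
                header <- sprintf("%s\nmosaic %.2f / germline %.2f", k,
                                  s$mosaic_score[1], s$germline_score[1])
        }
        vaf <- perCellVaf(cm)[df$case]
        df$label <- ifelse(df$call == 1L & !is.na(vaf),
                           sprintf("%.2f", vaf), "")
        df$panel <- header
        df$case <- factor(df$case, levels = rev(cm@cells))
        df$control <- factor(df$control, levels = cm@cells)
        df
    }))
    long$state <- ifelse(!long$active, "excluded",
                         ifelse(long$call == 1L, "call", "no call"))
    p <- ggplot(long, aes(x = .data$control, y = .data$case,
                          fill = .data$state)) +
        geom_tile(colour = "grey70") +
        geom_text(aes(label = .data$label), size = 2.5) +
        scale_fill_manual(values = c(call = "#2c7fb8",
                                     `no call` = "white",
                                     excluded = "grey80")) +
        facet_wrap(~panel) +
        labs(x = "control cell", y = "case cell") + theme_bw() +
        theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
    save_plot(p, path, width = 5.5 * min(length(keys), 2),
              height = 5 * ceiling(length(keys) / 2))
}
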