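test_that("mutation spectrum folds purine-strand calls and conserves counts", {
    spec <- mutationSpectrum(data.frame(ref = "G", alt = "A"))
    expect_equal(unname(spec[["C>T"]]), 1L)
    variants <- data.frame(
        ref = c("C", "C", "G", "T", "A", "A", "T", "AT", "C", "G"),
        alt = c("A", "T", "T", "G", "C", "T", "TTT", "A", "G", "C"),
        stringsAsFactors = FALSE)
    spec2 <- mutationSpectrum(variants)
    # 8 SNVs, 2 indels: class totals count only the SNVs
    expect_equal(sum(spec2), 8L)
    expect_named(spec2, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
    # A>C folds to T>G, G>T folds to C>A, A>T folds to T>A
    expect_equal(unname(spec2[["T>G"]]), 2L)
    expect_equal(unname(spec2[["C>A"]]), 2L)
    expect_equal(unname(spec2[["T>A"]]), 1L)
})

test_that("score density plot writes an image plus a checkable TSV", {
    scores <- rbind(
        computeScores(row_pattern_matrix(5, c(2, 5), key = "v1")),
        computeScores(row_pattern_matrix(5, c(2, 5), key = "v2")),
        computeScores(row_pattern_matrix(5, c(2, 5), key = "v3")),
        computeScores(col_pattern_matrix(5, 3, key = "v4")))
    img <- file.path(tempfile("plots"), "density.png")
    dir.create(dirname(img))
    plotScoreDensity(scores, defaultCutoffs(), img)
    expect_true(file.size(img) > 0)
    side <- read.delim(sub("png$", "tsv", img))
    # three variants share one score pair -> multiplicity 3
    expect_equal(sort(side$count), c(1, 3))
    expect_equal(sum(side$count), nrow(scores))
    # empty input still draws the plane
    img0 <- file.path(dirname(img), "empty.png")
    plotScoreDensity(scores[0, ], defaultCutoffs(), img0)
    expect_true(file.size(img0) > 0)
})

test_that("report plots emit per-category, per-cell, VAF and spectrum tables", {
    scores <- classifyScores(rbind(
        computeScores(row_pattern_matrix(5, c(2, 5), key = "chr1:1:C:A")),
        computeScores(col_pattern_matrix(5, 3, key = "chr1:2:G:A"))))
    scores$ref <- c("C", "G")
    scores$alt <- c("A", "A")
    matrices <- list(
        "chr1:1:C:A" = row_pattern_matrix(5, c(2, 5)),
        "chr1:2:G:A" = col_pattern_matrix(5, 3))
    ann <- annotateCarriers(scores, matrices)
    prefix <- file.path(tempfile("rep"), "report")
    dir.create(dirname(prefix))
    paths <- plotReports(ann, prefix)
    expect_length(paths, 4L)
    expect_true(all(file.size(paths) > 0))
    cat_tab <- read.delim(paste0(prefix, "_category_counts.tsv"))
    expect_equal(sum(cat_tab$n_variants), 2L)
    spec_tab <- read.delim(paste0(prefix, "_spectrum.tsv"))
    expect_equal(sum(spec_tab$n), 2L)  # C>A plus folded G>A
    cell_tab <- read.delim(paste0(prefix, "_cell_counts.tsv"))
    # shared mutations count once per carrier cell
    expect_gte(sum(cell_tab$n_calls), 2L)
})

test_that("matrix rendering reports scores and rejects unknown variants", {
    matrices <- list("chr1:1:A:T" = row_pattern_matrix(5, c(2, 5),
                                                       key = "chr1:1:A:T"))
    scores <- computeScores(matrices[[1]])
    img <- file.path(tempfile("mat"), "m.png")
    dir.create(dirname(img))
    renderMatrixPlot("chr1:1:A:T", matrices, scores, img)
    expect_true(file.size(img) > 0)
    expect_error(renderMatrixPlot("chr1:9:A:T", matrices, scores, img),
                 "not found")
})
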