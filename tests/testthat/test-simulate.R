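test_that("perfect calling emits exactly the pattern-implied calls", {
    # one mosaic carried by 2 of 5 cells: |C| * (N - |C|) = 6 calls
    cfg <- cohortConfig(nCells = 5, nGermline = 0, nMosaic = 1,
                        nNoise = 0, sensitivity = 1,
                        mosaicFractions = 0.4, seed = 21)
    sim <- simulateCohort(cfg, tempfile("simA"))
    expect_equal(sim$truth$n_calls, 6L)
    calls <- loadCohortCalls(readManifest(sim$manifest), dir = sim$dir)
    expect_equal(nrow(calls), 6L)
    carriers <- strsplit(sim$truth$carrier_cells, ",")[[1]]
    expect_setequal(unique(calls$case), carriers)

    # one germline lost in one cell: N - 1 calls, all into one column
    cfg2 <- cohortConfig(nCells = 5, nGermline = 1, nMosaic = 0,
                         nNoise = 0, sensitivity = 1,
                         germlineLossRate = 1e-9, seed = 22)
    sim2 <- simulateCohort(cfg2, tempfile("simB"))
    calls2 <- loadCohortCalls(readManifest(sim2$manifest), dir = sim2$dir)
    expect_equal(nrow(calls2), 4L)
    expect_length(unique(calls2$control), 1L)
})

test_that("the same seed reproduces byte-identical cohorts", {
    cfg <- cohortConfig(nCells = 4, nGermline = 5, nMosaic = 5,
                        nNoise = 5, dropoutPerCell = 1,
                        nMaskedGermline = 2, seed = 77)
    d1 <- simulateCohort(cfg, tempfile("det1"))$dir
    d2 <- simulateCohort(cfg, tempfile("det2"))$dir
    f1 <- sort(list.files(d1))
    expect_identical(f1, sort(list.files(d2)))
    for (f in f1) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = paste("md5 of", f))
    }
})

test_that("full pipeline recovers every category under perfect calling", {
    cfg <- cohortConfig(nCells = 8, nGermline = 15, nMosaic = 15,
                        nNoise = 10, sensitivity = 1,
                        mosaicFractions = c(0.125, 0.25, 0.375),
                        seed = 31)
    sim <- simulateCohort(cfg, tempfile("simC"))
    res <- scoreCohort(sim$manifest, tempfile("outC"), plot = FALSE,
                       logLevel = "quiet")
    cls <- classifyScores(res$scores)
    merged <- merge(cls, sim$truth, by = "key",
                    suffixes = c("", ".truth"))
    expect_equal(nrow(merged), nrow(sim$truth))
    expect_true(all(merged$category == merged$category.truth))
    # carrier sets recovered exactly for mosaics
    mos <- merged[merged$category.truth == "mosaic", ]
    expect_identical(mos$carrier_cells, mos$carrier_cells.truth)
    # estimated fraction equals the true carrier fraction exactly
    expect_equal(mos$f, mos$true_fraction, tolerance = 1e-9)
})

test_that("fraction estimates stay accurate under imperfect sensitivity", {
    cfg <- cohortConfig(nCells = 10, nGermline = 0, nMosaic = 100,
                        nNoise = 0, sensitivity = 0.9, seed = 13)
    sim <- simulateCohort(cfg, tempfile("simD"))
    res <- scoreCohort(sim$manifest, tempfile("outD"), plot = FALSE,
                       logLevel = "quiet")
    merged <- merge(res$scores, sim$truth, by = "key")
    mae <- mean(abs(merged$f - merged$true_fraction))
    expect_lt(mae, 0.1)
})

test_that("infeasible configurations are rejected", {
    expect_error(cohortConfig(mosaicFractions = 0.6), "0.5")
    expect_error(cohortConfig(nMaskedGermline = 5, dropoutPerCell = 0),
                 "dropout")
    expect_error(cohortConfig(nCells = 1), "nCells")
})

test_that("dropout-masked germline variants appear as column patterns", {
    cfg <- cohortConfig(nCells = 5, nGermline = 0, nMosaic = 0,
                        nNoise = 0, sensitivity = 1, nMaskedGermline = 3,
                        dropoutPerCell = 2, seed = 41)
    sim <- simulateCohort(cfg, tempfile("simE"))
    calls <- loadCohortCalls(readManifest(sim$manifest), dir = sim$dir)
    matrices <- buildCallMatrices(calls, sim$cells)
    expect_length(matrices, 3L)
    for (key in names(matrices)) {
        cm <- matrices[[key]]
        expect_equal(callCount(cm), 4)  # N - 1 calls into one column
        expect_equal(max(colCallSums(cm)), 4)
        # the column is the dropout cell, whose SNP table shows
        # homozygous-looking VAFs at the locus
        dcell <- names(which.max(colCallSums(cm)))
        truth_row <- sim$truth[sim$truth$key == key, ]
        expect_true(truth_row$dropout_affected)
        gr <- sim$dropoutRegions[[dcell]]
        expect_equal(GenomicRanges::countOverlaps(
            GenomicRanges::GRanges(truth_row$chrom,
                IRanges::IRanges(truth_row$pos, truth_row$pos)), gr), 1L)
    }
})
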