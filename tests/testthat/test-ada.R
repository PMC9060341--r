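test_that("maximum-likelihood folded VAF matches the grid oracle", {
    # independent oracle: direct evaluation of the folded binomial
    # mixture log-likelihood over the same grid
    grid_oracle <- function(a, d) {
        grid <- seq(0, 0.5, 0.01)
        ll <- sapply(grid, function(f)
            sum(log(0.5 * dbinom(a, d, f) + 0.5 * dbinom(a, d, 1 - f))))
        grid[which.max(ll)]
    }
    expect_equal(maxLikelihoodVaf(15, 30), 0.5)
    expect_equal(maxLikelihoodVaf(30, 30), 0.0)
    expect_equal(maxLikelihoodVaf(c(6, 24), c(30, 30)), 0.2)
    set.seed(3)
    for (i in 1:20) {
        d <- sample(10:60, 4)
        a <- rbinom(4, d, runif(1))
        expect_equal(maxLikelihoodVaf(a, d), grid_oracle(a, d))
    }
    # no depths: falls back to mean folded VAF
    expect_equal(maxLikelihoodVaf(NA, NA, vaf = c(0.8, 0.9)),
                 mean(c(0.2, 0.1)))
    expect_error(maxLikelihoodVaf(5, -1), "negative")
})

test_that("dropout bins require both conditions, then spread to neighbors", {
    mk <- function(pos, a, d) data.frame(chrom = "chr1", pos = pos,
                                         alt_reads = a, depth = d)
    # balanced het SNPs: neither condition -> clean
    expect_length(detectDropoutBins(mk(c(100, 2000, 4000),
                                       c(15, 14, 16), 30)), 0L)
    # extreme VAFs and skewed ML VAF: both conditions -> dropout,
    # flagged bin is 5001..10000 plus one neighbor on each side
    gr <- detectDropoutBins(mk(c(5100, 7000, 9000), c(30, 29, 30), 30))
    expect_equal(GenomicRanges::start(gr), 1)
    expect_equal(GenomicRanges::end(gr), 15000)
    # imbalance without an extreme SNP: condition (i) fails -> clean
    expect_length(detectDropoutBins(mk(c(100, 300), c(19, 18), 30)), 0L)
    # extreme SNP but bin ML VAF still near 0.5: condition (ii) fails
    snps <- mk(c(100, 200, 300, 400, 450), c(10, 15, 15, 14, 16),
               c(10, 30, 30, 30, 30))
    expect_length(detectDropoutBins(snps), 0L)
    expect_error(detectDropoutBins(mk(1, 5, -2)), "negative")
})

test_that("dropout exclusion removes only unsupported cells at covered loci", {
    dropout3 <- list(c03 = GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(900, 1100)))
    # germline-minus-cell-3 pattern, dropout covering the locus in cell 3:
    # the variant was likely called hom-ref in c03 by dropout -> artifact
    cm <- col_pattern_matrix(5, 3)
    red <- applyAdaExclusion(cm, dropout3)
    expect_equal(activeCells(red), paste0("c0", c(1, 2, 4, 5)))
    expect_equal(callCount(red), 0)
    expect_null(computeScores(red))

    # same pattern but the dropout cell carries a confident call
    cm2 <- col_pattern_matrix(5, 3)
    cm2@vaf[2] <- 0.5
    red2 <- applyAdaExclusion(cm2, list(c02 = dropout3$c03))
    expect_equal(activeCells(red2), cellNames(cm2))
    expect_equal(computeScores(red2), computeScores(cm2))

    # low-VAF call counts as "no call" for the exclusion clause
    cm3 <- col_pattern_matrix(5, 3)
    cm3@vaf[2] <- 0.3
    red3 <- applyAdaExclusion(cm3, list(c02 = dropout3$c03))
    expect_false("c02" %in% activeCells(red3))

    # empty maps are the identity
    expect_equal(applyAdaExclusion(cm, list()), cm)

    # locus outside the dropout interval: untouched
    far <- list(c03 = GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(5e5, 6e5)))
    expect_equal(activeCells(applyAdaExclusion(cm, far)), cellNames(cm))
})

test_that("exclusion never increases n and preserves clean mosaic patterns", {
    set.seed(9)
    for (i in 1:20) {
        cm <- random_call_matrix(6)
        maps <- list(c03 = GenomicRanges::GRanges(
            "chr1", IRanges::IRanges(1, 2000)))
        red <- applyAdaExclusion(cm, maps)
        expect_lte(callCount(red), callCount(cm))
    }
    # perfect mosaic, dropout over a non-carrier that made no call:
    # carrier rows stay intact, mosaic score stays 1
    cm <- row_pattern_matrix(6, c(1, 2))
    red <- applyAdaExclusion(cm, list(c05 = GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1, 2000))))
    expect_equal(computeScores(red)$mosaic_score, 1.0)
})

test_that("capture mode excludes non-calling cells outside their capture", {
    capture <- list(c03 = GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(5e5, 6e5)))  # locus 1000 is off-capture
    cm <- col_pattern_matrix(5, 3)
    red <- applyAdaExclusion(cm, capture, type = "capture")
    expect_false("c03" %in% activeCells(red))
    # inside capture: kept
    capture_in <- list(c03 = GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1, 2000)))
    red2 <- applyAdaExclusion(cm, capture_in, type = "capture")
    expect_equal(activeCells(red2), cellNames(cm))
})

test_that("per-cell dropout BEDs round-trip and attach via the manifest", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 6000))
    bed <- tempfile(fileext = ".bed")
    writeDropoutBed(gr, bed)
    expect_equal(GenomicRanges::start(readBedRegions(bed)), 1001)
    tf <- tempfile(fileext = ".tsv")
    write_test_manifest(tf, c("A", "B"), c("B", "A"), c("x.vcf", "y.vcf"),
                        dropout_bed = c(bed, ""))
    maps <- loadCellRegions(readManifest(tf), "dropout_bed")
    expect_named(maps, "A")
    expect_equal(GenomicRanges::end(maps$A), 6000)
})
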