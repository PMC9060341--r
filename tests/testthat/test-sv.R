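test_that("reciprocal overlap follows half-open interval arithmetic", {
    ro <- reciprocalOverlap(SVKey("chr1", 100, 200, "DEL"),
                            SVKey("chr1", 100, 200, "DEL"))
    expect_equal(ro, c(1, 1))
    # the 50% boundary case is accepted ("at least 50%")
    a <- SVKey("chr1", 0, 100, "DEL")
    b <- SVKey("chr1", 50, 150, "DEL")
    expect_equal(reciprocalOverlap(a, b), c(0.5, 0.5))
    expect_true(sameSv(a, b))
    expect_true(sameSv(b, a))
    # any strictly smaller overlap is rejected
    expect_false(sameSv(a, SVKey("chr1", 51, 151, "DEL")))
    c <- SVKey("chr1", 90, 300, "DEL")
    expect_equal(reciprocalOverlap(a, c), c(0.1, 10 / 210))
    expect_false(sameSv(a, c))
    expect_equal(reciprocalOverlap(a, SVKey("chr2", 0, 100, "DEL")),
                 c(0, 0))
    expect_error(SVKey("chr1", 100, 100, "DEL"), "length")
})

test_that("same-SV predicate needs matching type; insertions match by position", {
    a <- SVKey("chr1", 0, 100, "DEL")
    expect_false(sameSv(a, SVKey("chr1", 0, 100, "DUP")))
    i1 <- SVKey("chr1", 500, 501, "INS")
    expect_true(sameSv(i1, SVKey("chr1", 550, 551, "INS")))
    expect_false(sameSv(i1, SVKey("chr1", 551, 552, "INS")))
})

test_that("single-linkage clustering chains overlapping SVs", {
    sv <- data.frame(
        chrom = "chr1",
        start = c(0, 40, 80), end = c(100, 140, 180),
        svtype = "DEL",
        case = c("A", "B", "C"), control = c("B", "C", "A"),
        vaf = NA_real_, stringsAsFactors = FALSE)
    out <- clusterSvCalls(sv)
    # adjacent pairs overlap 60%, the extremes only 20%: one chain
    expect_length(unique(out$key), 1L)
    expect_equal(unique(out$key), "chr1:0-100:DEL")

    # identical DELs from two comparisons -> one cluster, row A gets both
    sv2 <- data.frame(chrom = "chr1", start = 0, end = 100, svtype = "DEL",
                      case = "A", control = c("B", "C"), vaf = NA_real_,
                      stringsAsFactors = FALSE)
    out2 <- clusterSvCalls(sv2)
    cm <- buildCallMatrices(out2, c("A", "B", "C"))[[1]]
    expect_equal(unname(rowCallSums(cm)), c(2, 0, 0))

    # type mismatch keeps clusters apart
    sv3 <- sv2
    sv3$svtype <- c("DEL", "DUP")
    expect_length(unique(clusterSvCalls(sv3)$key), 2L)

    # clustering is input-order independent up to the representative label
    out_rev <- clusterSvCalls(sv[3:1, ])
    expect_length(unique(out_rev$key), 1L)
})

test_that("SV matrices score exactly like the same SNV pattern", {
    # mosaic DEL carried by cells 2 and 5 of 5, called in all 6 pairs
    cells <- sprintf("c%02d", 1:5)
    pairs <- expand.grid(case = c(2, 5), control = c(1, 3, 4))
    sv <- data.frame(chrom = "chr1", start = 1000, end = 6000,
                     svtype = "DEL", case = cells[pairs$case],
                     control = cells[pairs$control], vaf = NA_real_,
                     stringsAsFactors = FALSE)
    cm <- buildCallMatrices(clusterSvCalls(sv), cells)[[1]]
    s <- computeScores(cm)
    snv <- computeScores(row_pattern_matrix(5, c(2, 5)))
    expect_equal(s$mosaic_score, snv$mosaic_score)
    expect_equal(s$germline_score, snv$germline_score)
    expect_equal(s$n, snv$n)
})

test_that("SV VCFs parse SVTYPE and END into half-open spans", {
    tf <- tempfile(fileext = ".vcf")
    write_test_sv_vcf(tf, data.frame(pos = c(1001, 5001), chrom = "chr1",
                                     end = c(2000, 5600),
                                     svtype = c("DEL", "DUP")))
    sv <- loadPairwiseSvCalls(tf, "A", "B")
    expect_equal(nrow(sv), 2L)
    expect_equal(sv$start, c(1000, 5000))
    expect_equal(sv$end, c(2000, 5600))
    expect_equal(sv$svtype, c("DEL", "DUP"))
})
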