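test_that("cell-fraction estimate inverts n = f(1-f)N^2 with clamping", {
    expect_equal(estimateCellFraction(0, 5), 0)
    expect_equal(estimateCellFraction(6, 5), 0.4)  # 0.4 * 0.6 * 25 = 6
    expect_equal(estimateCellFraction(4, 5), 0.2)  # 0.2 * 0.8 * 25 = 4
    expect_equal(estimateCellFraction(7, 5), 0.5)  # discriminant < 0
    expect_error(estimateCellFraction(1, 1), "fewer than 2")
    expect_error(estimateCellFraction(-1, 5), "non-negative")

    # exact inverse on the grid f = k/N, and monotone in n
    for (N in c(4, 7, 12)) {
        ks <- 0:floor(N / 2)
        f <- estimateCellFraction(ks * (N - ks), N)
        expect_equal(f, ks / N, tolerance = 1e-9)
        expect_true(all(diff(estimateCellFraction(0:floor(N^2 / 4), N)) >=
                        0))
    }
})

test_that("carrier count rounds f*N to nearest, ties up, floor zero", {
    expect_equal(carrierCount(0.4, 5), 2L)
    expect_equal(carrierCount(0.2, 5), 1L)
    expect_equal(carrierCount(0.0417, 5), 0L)  # sporadic call -> no carrier
    expect_equal(carrierCount(0.5, 5), 3L)     # 2.5 rounds up
    expect_equal(carrierCount(0.5, 10), 5L)
    expect_error(carrierCount(0.7, 5), "0, 0.5")
})

test_that("archetype matrices score as in the worked examples", {
    s <- computeScores(row_pattern_matrix(5, c(2, 5)))
    expect_equal(s$n, 6)
    expect_equal(s$f, 0.4)
    expect_equal(s$N_prime, 2)
    expect_equal(s$mosaic_score, 1.0)
    expect_equal(s$germline_score, 2 / 3, tolerance = 1e-12)
    expect_equal(s$carrier_cells, "c02,c05")

    s2 <- computeScores(col_pattern_matrix(5, 3))
    expect_equal(s2$n, 4)
    expect_equal(s2$N_prime, 1)
    expect_equal(s2$mosaic_score, 0.25)
    expect_equal(s2$germline_score, 1.0)

    # a single sporadic call in a 5-cell design collapses to noise
    m <- matrix(0L, 5, 5)
    m[2, 4] <- 1L
    s3 <- computeScores(CallMatrix("sp", cells5, m))
    expect_equal(s3$N_prime, 0)
    expect_equal(s3$mosaic_score, 0)
    expect_equal(s3$germline_score, 0)
    expect_equal(s3$carrier_cells, "")
})

test_that("greedy top-N' selection equals exhaustive subset maximization", {
    set.seed(11)
    for (i in 1:200) {
        cm <- random_call_matrix(sample(3:7, 1), p = runif(1, 0.1, 0.6))
        expected <- bruteForceScores(cm)
        got <- computeScores(cm)
        expect_equal(got$mosaic_score, unname(expected["mosaic_score"]))
        expect_equal(got$germline_score,
                     unname(expected["germline_score"]))
    }
    big <- random_call_matrix(13)
    expect_error(bruteForceScores(big), "12")
})

test_that("perfect patterns score exactly 1 for every carrier-set size", {
    for (N in c(4, 7, 12)) {
        for (k in seq_len(floor(N / 2))) {
            expect_equal(computeScores(
                row_pattern_matrix(N, seq_len(k)))$mosaic_score, 1.0)
            expect_equal(computeScores(
                col_pattern_matrix(N, seq_len(k)))$germline_score, 1.0)
        }
    }
})

test_that("excluded cells contribute nothing to scores", {
    cm <- row_pattern_matrix(6, c(1, 2))
    cm@active[6] <- FALSE  # a non-carrier: pattern survives reduced
    s <- computeScores(cm)
    expect_equal(s$N_active, 5)
    expect_equal(s$n, 6)  # 2 carriers x 3 remaining non-carrier columns
    expect_equal(s$mosaic_score, 1.0)

    cm2 <- col_pattern_matrix(5, 3)
    cm2@active[3] <- FALSE  # the lost cell: whole pattern disappears
    expect_null(computeScores(cm2))
    expect_equal(nrow(scoreCallMatrices(list(cm2))), 0L)
})
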