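test_that("two-sided Fisher exact test matches enumeration on known tables", {
    # all six tables with margins (5,5)/(5,5) tie at or below the observed
    expect_equal(fisherExactTwoSided(2, 3, 3, 2), 1)
    # degenerate column margin: a single compatible table
    expect_equal(fisherExactTwoSided(0, 10, 0, 10), 1)
    expect_equal(fisherExactTwoSided(8, 614, 37, 10828),
                 fisherOracle(8, 614, 37, 10828), tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(fisherExactTwoSided(8, 614, 37, 10828),
                 stats::fisher.test(matrix(c(8, 614, 37, 10828), 2,
                                           byrow = TRUE))$p.value,
                 tolerance = 1e-9)
})

test_that("Fisher exact test agrees with brute-force oracle on random tables", {
    set.seed(42)
    for (i in 1:60) {
        m <- sample(0:100, 4, replace = TRUE)
        if ((m[1] + m[2]) == 0 || (m[3] + m[4]) == 0) next
        p1 <- fisherExactTwoSided(m[1], m[2], m[3], m[4])
        expect_equal(p1, fisherOracle(m[1], m[2], m[3], m[4]),
                     tolerance = 1e-10)
        # invariant under simultaneous row and column swaps
        expect_equal(p1, fisherExactTwoSided(m[4], m[3], m[2], m[1]),
                     tolerance = 1e-10)
    }
})

test_that("Pearson chi-square companion reproduces normal-approximation p", {
    expect_equal(chisqTwoSided(8, 614, 37, 10828), 0.000241,
                 tolerance = 5e-4)
    expect_equal(chisqTwoSided(8, 614, 37, 10828),
                 suppressWarnings(stats::prop.test(
                     c(8, 37), c(622, 10865), correct = FALSE)$p.value),
                 tolerance = 1e-12)
    expect_equal(chisqTwoSided(0, 10, 0, 10), 1)
})

test_that("Woolf odds ratios and CIs reproduce reference rows", {
    r <- oddsRatioWoolf(8, 614, 37, 10828)
    expect_equal(roundHalfAway(r$or, 2), 3.81)
    expect_equal(roundHalfAway(r$ciLow, 2), 1.77)
    expect_equal(roundHalfAway(r$ciHigh, 2), 8.22)
    expect_false(r$zeroCellCorrected)
    expect_equal(roundHalfAway(oddsRatioWoolf(7, 615, 71, 10794)$or, 2),
                 1.73)
    expect_equal(oddsRatioWoolf(1, 1, 1, 1)$or, 1)
})

test_that("Woolf CI contains the point estimate and handles zero cells", {
    set.seed(7)
    for (i in 1:40) {
        m <- sample(0:50, 4, replace = TRUE)
        if ((m[1] + m[2]) == 0 || (m[3] + m[4]) == 0) next
        r <- oddsRatioWoolf(m[1], m[2], m[3], m[4])
        expect_lte(r$ciLow, r$or + 1e-12)
        expect_gte(r$ciHigh, r$or - 1e-12)
        expect_gt(r$or, 0)
        expect_identical(r$zeroCellCorrected, any(m == 0))
    }
    # CI widens monotonically as a cell shrinks toward 1
    widths <- vapply(c(20, 10, 5, 2, 1), function(a) {
        r <- oddsRatioWoolf(a, 50, 50, 50)
        log(r$ciHigh) - log(r$ciLow)
    }, numeric(1))
    expect_true(all(diff(widths) > 0))
})

test_that("Bonferroni thresholds follow alpha / k", {
    expect_equal(bonferroniThreshold(0.05, 7), 0.05 / 7)
    expect_equal(bonferroniThreshold(0.05, 4), 0.0125)
    expect_equal(bonferroniThreshold(0.05, 1), 0.05)
    expect_error(bonferroniThreshold(0.05, 0), "positive integer")
    expect_error(bonferroniThreshold(1.2, 3), "alpha")
})

test_that("genotype-count reconstruction inverts printed percentages", {
    expect_identical(reconstructGenotypeCounts(83, c(0, 32.5, 67.5))$counts,
                     c(0L, 27L, 56L))
    expect_identical(
        reconstructGenotypeCounts(539, c(6.3, 39.5, 54.2))$counts,
        c(34L, 213L, 292L))
    expect_identical(reconstructGenotypeCounts(10, c(0, 0, 100))$counts,
                     c(0L, 0L, 10L))
})

test_that("reconstruction is exact-inverse on random triples", {
    set.seed(11)
    for (i in 1:80) {
        n <- sample(30:800, 1)
        cnt <- as.vector(stats::rmultinom(1, n, c(0.05, 0.35, 0.6)))
        pct <- roundHalfAway(100 * cnt / n, 1)
        rec <- reconstructGenotypeCounts(n, pct)
        if (!rec$multiple)
            expect_identical(rec$counts, as.integer(cnt))
        else  # genuine multiplicity: recovered triple must print the same
            expect_equal(roundHalfAway(100 * rec$counts / n, 1), pct)
    }
})

test_that("infeasible printed percentages error unless nearest is accepted", {
    # 4.7 / 38 / 57.3 of 469 admits no integer triple
    expect_error(reconstructGenotypeCounts(469, c(4.7, 38, 57.3)),
                 "no exact genotype triple")
    rec <- reconstructGenotypeCounts(469, c(4.7, 38, 57.3), nearest = TRUE)
    expect_false(rec$exact)
    expect_identical(sum(rec$counts), 469L)
})

test_that("allele tables from genotype triples conserve allele counts", {
    t1 <- alleleTableFromGenotypes(c(0, 27, 56), c(34, 213, 292))
    expect_identical(as.vector(t1), c(27L, 281L, 139L, 797L))
    expect_identical(as.vector(alleleTableFromGenotypes(c(0, 0, 10),
                                                        c(10, 0, 0))),
                     c(0L, 20L, 20L, 0L))
    set.seed(3)
    for (i in 1:20) {
        g1 <- sample(0:40, 3); g2 <- sample(0:40, 3)
        tt <- alleleTableFromGenotypes(g1, g2)
        expect_identical(as.integer(rowSums(tt)),
                         c(2L * sum(g1), 2L * sum(g2)))
    }
})
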