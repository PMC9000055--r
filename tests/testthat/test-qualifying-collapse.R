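test_that("sample QC retains samples at or above the coverage fraction", {
    co <- toyCohort()
    SummarizedExperiment::colData(co)$ccdsCovered <-
        c(0.95, 0.89, 0.90, 1, 0.5)
    kept <- applySampleQC(co)
    expect_identical(colnames(kept), c("s1", "s3", "s4"))
    expect_identical(S4Vectors::metadata(kept)$sampleQCExcluded,
                     c("s2", "s5"))
    expect_identical(ncol(applySampleQC(toyCohort())), 5L)
})

test_that("site QC drops sites with differential case/control coverage", {
    co <- toyCohort()
    cov <- matrix(TRUE, 4, 5, dimnames = dimnames(dosages(co)))
    cov[1, 4:5] <- FALSE          # 100% cases vs 0% controls -> drop
    cov[2, 4] <- FALSE            # 100% vs 50% -> drop
    SummarizedExperiment::assay(co, "coverageOK") <- cov
    kept <- applySiteQC(co)
    expect_identical(nrow(kept), 2L)
    # boundary: a difference of exactly the threshold is dropped
    co2 <- toyCohort()
    expect_identical(nrow(applySiteQC(co2)), 4L)
    expect_identical(nrow(applySiteQC(co2, maxDiff = 0)), 0L)
})

test_that("qualifying filter applies strict MAF and CADD bounds", {
    co <- orientSites(toyCohort())
    q <- qualifyingSites(co, mafMax = 0.005, caddMin = 25)
    # site 1: maf 0.001, cadd 30 -> yes; site 2: maf 0.21 -> no;
    # site 3: cadd 10 -> no; site 4: absent in panel, cadd 26 -> yes
    expect_identical(unname(q), c(TRUE, FALSE, FALSE, TRUE))
    # sentinel selects only absent-in-panel sites
    qnd <- qualifyingSites(co, mafMax = "nd")
    expect_identical(unname(qnd), c(FALSE, FALSE, FALSE, TRUE))
    # boundary: minor AF exactly at the threshold is excluded
    vi <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                     gene = "X", cadd = c(30, 25),
                     global_af = c(0.005, 0.004))
    co2 <- orientSites(GenotypeCohort(
        matrix(0L, 2, 1, dimnames = list(NULL, "s1")), vi,
        data.frame(role = "case", row.names = "s1")))
    q2 <- qualifyingSites(co2, mafMax = 0.005, caddMin = 25)
    expect_identical(unname(q2), c(FALSE, FALSE))  # =maf and =cadd excluded
})

test_that("sites without CADD are excluded with a message, not an error", {
    vi <- data.frame(chrom = "1", pos = 1, ref = "A", alt = "G",
                     gene = "X", cadd = NA_real_, global_af = 0.001)
    co <- orientSites(GenotypeCohort(
        matrix(1L, 1, 1, dimnames = list(NULL, "s1")), vi,
        data.frame(role = "case", row.names = "s1")))
    expect_message(q <- qualifyingSites(co), "without CADD")
    expect_false(any(q))
})

test_that("collapsing dichotomizes carriers per gene with missing kept in denominator", {
    vi <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                     gene = "G1", cadd = 30, global_af = 0.001)
    dm <- rbind(c(0L, 1L, 2L, 0L, NA),
                c(0L, 1L, 0L, 0L, NA))
    co <- orientSites(GenotypeCohort(
        dm, vi, data.frame(role = rep("case", 5),
                           row.names = paste0("s", 1:5))))
    carrier <- collapseCarriers(co, qualifyingSites(co))
    # two qualifying hets in one gene still count once; missing dosage
    # leaves the sample as a non-carrier, denominator unchanged
    expect_identical(unname(carrier[, "G1"]),
                     c(FALSE, TRUE, TRUE, FALSE, FALSE))
    expect_identical(nrow(carrier), 5L)
    expect_identical(carrier[, "G1"], carrier[, "geneSet"])
})

test_that("collapsing is invariant to site and sample ordering", {
    sim <- generateCohort(smallConfig(seed = 21))
    co <- sim$cohort
    q <- qualifyingSites(co)
    c1 <- collapseCarriers(co, q)
    perm <- sample(nrow(co)); permS <- sample(ncol(co))
    co2 <- co[perm, permS]
    c2 <- collapseCarriers(co2, q[perm])
    expect_identical(c2[rownames(c1), colnames(c1)], c1)
})

test_that("enrichment rows reproduce the reference collapsing statistics", {
    r <- enrichmentTable(c(ROM1 = 8), 622, c(ROM1 = 37), 10865, kTests = 7)
    expect_equal(r$p, 0.000241, tolerance = 5e-4)
    expect_equal(roundHalfAway(r$or, 2), 3.81)
    expect_true(r$significant)
    expect_equal(r$bonferroniThreshold, 0.05 / 7)
    r2 <- enrichmentTable(24, 622, 306, 10865, kTests = 5)
    expect_equal(r2$p, 0.1302, tolerance = 1e-3)
    # symmetric toy table: no enrichment
    r3 <- enrichmentTable(5, 100, 5, 100, kTests = 1, method = "fisher")
    expect_equal(r3$or, 1)
    expect_equal(r3$p, 1)
})

test_that("carrier sets are nested down the MAF ladder on synthetic cohorts", {
    for (seed in c(2, 13)) {
        sim <- generateCohort(smallConfig(seed = seed))
        co <- orientSites(sim$cohort)
        lad <- mafLadder(co)
        totals <- lad$caseCarriers + lad$controlCarriers
        expect_true(all(diff(totals[1:4]) <= 0))
        expect_lte(totals[5], totals[4])    # sentinel inside every row
    }
})

test_that("observed carrier fractions match the generating probabilities", {
    cfg <- smallConfig(seed = 31, nCases = 500, nControls = 2000,
                       subgroupSizes = c(HYPOMORPH_CAUSAL = 80,
                                         G1961E = 120, OTHER = 300),
                       genes = data.frame(
                           gene = "ROM1", chrom = "11",
                           baseWindow = 62380000,
                           caseP = 0.10, controlP = 0.03))
    sim <- generateCohort(cfg)
    co <- sim$cohort
    carrier <- collapseCarriers(co, qualifyingSites(co))[, "ROM1"]
    cs <- isCase(co)
    for (grp in list(list(cs, 0.10), list(!cs, 0.03))) {
        n <- sum(grp[[1]]); pi <- grp[[2]]
        x <- sum(carrier[grp[[1]]])
        band <- qnorm(0.995) * sqrt(pi * (1 - pi) * n)
        expect_lt(abs(x - n * pi), band + 1)
    }
})
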