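test_that("EM recovers the closed-form MLE on the two-haplotype fixture", {
    # 8 samples homozygous for the all-major haplotype, 2 double-het at
    # sites 1 and 3: likelihood f1^16 (2(f1 f2 + f3 f4))^2 is maximised at
    # f(0-0-0) = 0.9, f(1-0-1) = 0.1
    G <- rbind(matrix(0L, 8, 3), matrix(c(1L, 0L, 1L), 2, 3, byrow = TRUE))
    sp <- emHaplotypes(G)
    f <- hapFreq(sp)
    expect_equal(unname(f["0-0-0"]), 0.9, tolerance = 1e-6)
    expect_equal(unname(f["1-0-1"]), 0.1, tolerance = 1e-6)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_equal(sum(f[setdiff(names(f), c("0-0-0", "1-0-1"))]), 0,
                 tolerance = 1e-6)
})

test_that("EM equals direct allele counting when phase is unambiguous", {
    # all samples homozygous at every site
    G <- rbind(c(0L, 0L, 0L), c(2L, 2L, 2L), c(2L, 0L, 0L), c(0L, 0L, 0L))
    f <- hapFreq(emHaplotypes(G))
    expect_equal(unname(f[c("0-0-0", "1-1-1", "1-0-0")]),
                 c(4, 2, 2) / 8, tolerance = 1e-9)
    # at most one het site per sample: direct phasing oracle
    set.seed(19)
    for (rep in 1:5) {
        n <- 40
        hap <- matrix(rbinom(n * 2 * 3, 1, c(0.3, 0.1, 0.25)), ncol = 3,
                      byrow = TRUE)
        # force phase-unambiguous samples: second haplotype copies the
        # first except possibly at one site
        h1 <- hap[seq_len(n), , drop = FALSE]
        h2 <- h1
        flip <- sample(1:3, n, replace = TRUE)
        doFlip <- rbinom(n, 1, 0.5) == 1
        h2[cbind(which(doFlip), flip[doFlip])] <-
            1L - h2[cbind(which(doFlip), flip[doFlip])]
        G <- h1 + h2
        sp <- emHaplotypes(G)
        direct <- table(factor(
            c(apply(h1, 1, paste, collapse = "-"),
              apply(h2, 1, paste, collapse = "-")),
            levels = hapLabels(sp))) / (2 * n)
        expect_equal(unname(hapFreq(sp)), as.vector(direct),
                     tolerance = 1e-6)
    }
})

test_that("EM excludes incomplete samples and errors when none remain", {
    G <- rbind(c(0L, NA, 0L), c(1L, 0L, 0L))
    sp <- emHaplotypes(G)
    expect_identical(sp@nExcluded, 1L)
    expect_identical(sp@nAlleles, 2L)
    expect_error(emHaplotypes(rbind(c(NA, 0L, 0L))), "no samples")
})

test_that("haplotype tables format expected counts and 1-dp percentages", {
    sp <- new("HaplotypeSpectrum", siteLabels = c("a", "b", "c"),
              hapAlleles = transmodR:::.hapUniverse(3),
              hapLabels = sprintf("h%d", 1:8),
              freq = c(937 / 1244, 0, 0, 0, 0, 0, 0, 307 / 1244),
              nAlleles = 1244L, group = "all", logLik = 0,
              iterations = 1L, diplotypes = matrix(1L, 1, 2),
              nExcluded = 0L)
    tab <- haplotypeTable(sp)
    expect_identical(tab$formatted[1], "937 (75.3)")
    expect_identical(tab$formatted[2], "0")
    expect_lte(abs(sum(tab$pct) - 100), 0.3)
})

test_that("tag-SNP summaries compute minor allele frequencies from counts", {
    s <- tagSnpSummary(c(34, 240, 348))
    expect_equal(roundHalfAway(s$minorAF, 2), 0.25)
    expect_identical(s$minorAlleles + s$majorAlleles, 2L * 622L)
    expect_equal(s$minorAF, (2 * 34 + 240) / (2 * 622))
    expect_equal(tagSnpSummary(c(10, 0, 0))$minorAF, 1)
})

test_that("allele contrasts reproduce the reference subgroup rows", {
    r <- alleleContrast(tagSnpSummary(c(0, 27, 56), "hyp"),
                        tagSnpSummary(c(34, 213, 292), "rest"))
    expect_equal(roundHalfAway(r$or, 2), 0.55)
    r2 <- alleleContrast(tagSnpSummary(c(0, 29, 68), "hyp_ext"),
                         tagSnpSummary(c(34, 211, 280), "rest"))
    expect_equal(r2$p, 0.00057, tolerance = 2e-2)
    expect_equal(roundHalfAway(r2$or, 2), 0.49)
    # identical groups: no signal
    same <- tagSnpSummary(c(5, 20, 30))
    r3 <- alleleContrast(same, same, method = "fisher")
    expect_equal(r3$or, 1); expect_equal(r3$p, 1)
})

test_that("homozygote contrasts use exact enumeration and respond to scale", {
    r <- homozygoteContrast(tagSnpSummary(c(0, 27, 56), "hyp"),
                            tagSnpSummary(c(12, 62, 79), "g1961e"))
    expect_equal(r$p, fisherOracle(0, 83, 12, 141), tolerance = 1e-10)
    expect_equal(homozygoteContrast(tagSnpSummary(c(0, 5, 5)),
                                    tagSnpSummary(c(0, 3, 7)))$p, 1)
    # doubling all counts on a fixed-ratio family strengthens the signal
    p1 <- homozygoteContrast(tagSnpSummary(c(0, 27, 56)),
                             tagSnpSummary(c(12, 62, 79)))$p
    p2 <- homozygoteContrast(tagSnpSummary(2 * c(0, 27, 56)),
                             tagSnpSummary(2 * c(12, 62, 79)))$p
    expect_lt(p2, p1)
})

test_that("LD statistics behave at the construction limits", {
    # complete LD by construction: haplotypes 0-0 and 1-1 only
    vi <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                     gene = "X", cadd = 1, global_af = 0.3)
    h <- c(rep(0L, 30), rep(1L, 20))
    G <- cbind(h + rev(h), h + rev(h))   # same haplotype pair at both sites
    co <- orientSites(GenotypeCohort(
        t(G), vi, data.frame(role = rep("case", 50),
                             row.names = sprintf("s%02d", 1:50))))
    ld <- ldStats(co, 1, 2)
    expect_equal(ld$r2, 1, tolerance = 1e-9)
    expect_equal(abs(ld$Dprime), 1, tolerance = 1e-9)
    # independent sites at AF 0.5: r2 near 0 at large n
    set.seed(23)
    G2 <- cbind(rbinom(4000, 2, 0.5), rbinom(4000, 2, 0.5))
    co2 <- orientSites(GenotypeCohort(
        t(G2), vi, data.frame(role = rep("case", 4000),
                              row.names = sprintf("s%04d", 1:4000))))
    ld2 <- ldStats(co2, 1, 2)
    expect_lt(ld2$r2, 0.01)
    expect_lte(abs(ld2$Dprime), 1)
    # monomorphic site: flagged missing
    G3 <- cbind(rep(0L, 10), rbinom(10, 2, 0.5))
    co3 <- orientSites(GenotypeCohort(
        t(G3), vi, data.frame(role = rep("case", 10),
                              row.names = sprintf("s%02d", 1:10))))
    expect_true(ldStats(co3, 1, 2)$monomorphic)
})

test_that("EM recovers generating spectra within sampling error at scale", {
    # single-replicate recovery on the discovery-sized all-patients
    # spectrum; the acceptance suite repeats this over 100 replicates
    freqs <- c("G-A-G" = 937, "C-G-A" = 136, "C-A-A" = 151, "G-A-A" = 19,
               "C-A-G" = 1) / 1244
    cfg <- simConfig(nCases = 622, nControls = 50,
                     subgroupSizes = c(HYPOMORPH_CAUSAL = 0, G1961E = 0,
                                       OTHER = 622),
                     nExtendedHypomorph = 0, nCisHypomorph = 0,
                     hapFreqs = list(HYPOMORPH_CAUSAL = freqs,
                                     G1961E = freqs, OTHER = freqs),
                     seed = 27)
    sim <- generateCohort(cfg)
    co <- sim$cohort
    G <- t(minorDosage(co, sites = sim$truth$hapSiteKeys,
                       samples = which(isCase(co))))
    est <- hapFreq(emHaplotypes(G))
    bits <- transmodR:::.hapBits
    for (h in names(freqs)) {
        lab <- paste(bits[h, ], collapse = "-")
        se <- sqrt(freqs[h] * (1 - freqs[h]) / 1244)
        expect_lt(abs(est[lab] - freqs[h]), 3 * se + 1e-3)
    }
})
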