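# Small simulation configs and hand-built fixtures shared across tests.

smallConfig <- function(seed = 1, ...) {
    args <- list(nCases = 60, nControls = 240,
                 subgroupSizes = c(HYPOMORPH_CAUSAL = 10, G1961E = 14,
                                   OTHER = 36),
                 nExtendedHypomorph = 3, nCisHypomorph = 4,
                 sitesPerGene = 4, qualifyingPerGene = 2, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}

# deterministic toy cohort built by hand (no RNG): 5 samples x 4 sites
toyCohort <- function() {
    vi <- data.frame(
        chrom = c("1", "1", "2", "2"), pos = c(100, 200, 50, 60),
        ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
        gene = c("ROM1", "ROM1", "PRPH2", "PRPH2"),
        cadd = c(30, 28, 10, 26),
        global_af = c(0.001, 0.79, 0.004, NA))
    si <- data.frame(
        role = c("case", "case", "case", "control", "control"),
        ccdsCovered = c(1, 1, 1, 1, 1),
        row.names = paste0("s", 1:5))
    dm <- rbind(c(0L, 1L, 2L, 0L, NA),      # qualifying ROM1
                c(2L, 2L, 1L, 2L, 2L),      # flipped site (alt is major)
                c(0L, 0L, 0L, 1L, 0L),      # low CADD, never qualifies
                c(1L, 0L, 0L, 0L, 0L))      # absent-in-panel, CADD 26
    GenotypeCohort(dm, vi, si)
}

# independent brute-force two-sided Fisher oracle: enumerate every table
# with the observed margins, point probabilities from choose()
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    tot <- r1 + r2
    xs <- max(0, c1 - r2):min(c1, r1)
    prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(tot, c1)
    p0 <- prob(a)
    ps <- vapply(xs, prob, numeric(1))
    min(1, sum(ps[ps <= p0 * (1 + 1e-7)]))
}
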