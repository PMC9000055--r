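# Seeded synthetic case/control cohorts with the statistical structure the
# analysis assumes: per-gene qualifying-carrier rates, a 3-SNP haplotype
# region with subgroup-specific spectra, ethnicity mixture and coverage QC
# flags.

.hapOrder <- c("G-A-G", "C-G-A", "C-A-A", "G-A-A",
               "G-G-A", "C-A-G", "G-G-G", "C-G-G")
# minor-allele indicator per site (910, 929, 1013); minor alleles C, G, A
.hapBits <- rbind(
    "G-A-G" = c(0, 0, 0), "C-G-A" = c(1, 1, 1), "C-A-A" = c(1, 0, 1),
    "G-A-A" = c(0, 0, 1), "G-G-A" = c(0, 1, 1), "C-A-G" = c(1, 0, 0),
    "G-G-G" = c(0, 1, 0), "C-G-G" = c(1, 1, 0))

.defaultEthnicityMix <- c(European = 0.79, African = 0.05, Latino = 0.06,
                          EastAsian = 0.03, SouthAsian = 0.02,
                          MiddleEastern = 0.02, Admixed = 0.03)

.defaultGenes <- data.frame(
    gene = c("CDHR1", "CHM", "CRX", "ELOVL4", "PROM1", "PRPH2", "ROM1"),
    chrom = c("10", "X", "19", "6", "4", "6", "11"),
    baseWindow = c(85950000, 85100000, 48325000, 80600000, 15970000,
                   42660000, 62380000),
    caseP = c(3, 3, 1, 1, 7, 1, 8) / 622,
    controlP = c(119, 37, 7, 6, 71, 31, 37) / 10865,
    stringsAsFactors = FALSE)

# per-ethnicity minor-allele frequencies at the three linked PRPH2 sites
.defaultPanelMinorAF <- rbind(
    European = c(0.20, 0.10, 0.21), African = c(0.15, 0.08, 0.16),
    Latino = c(0.18, 0.09, 0.19), EastAsian = c(0.12, 0.06, 0.13),
    SouthAsian = c(0.17, 0.09, 0.18), MiddleEastern = c(0.19, 0.10, 0.20),
    Admixed = c(0.18, 0.09, 0.19))

.defaultHapFreqs <- list(
    HYPOMORPH_CAUSAL = c("G-A-G" = 139, "C-G-A" = 14, "C-A-A" = 13) / 166,
    G1961E = c("G-A-G" = 220, "C-G-A" = 52, "C-A-A" = 34) / 306,
    OTHER = c("G-A-G" = 578, "C-G-A" = 70, "C-A-A" = 104,
              "G-A-A" = 19, "C-A-G" = 1) / 772)

.fullHapVec <- function(x) {
    v <- setNames(numeric(length(.hapOrder)), .hapOrder)
    v[names(x)] <- x
    if (abs(sum(v) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
    v
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the discovery-study design: 622 cases / 10,865
#' controls, 79\% European ethnicity mixture, per-gene qualifying-carrier
#' probabilities at the observed per-gene rates, genetic subgroups of sizes
#' 83 / 153 / 386 (with 14 extended-hypomorph cases inside the third
#' group), and subgroup-specific 3-SNP haplotype spectra with
#' Hardy-Weinberg pairing.
#'
#' @param nCases,nControls cohort sizes.
#' @param ethnicityMix named proportions summing to 1.
#' @param subgroupSizes named integer vector over HYPOMORPH_CAUSAL, G1961E,
#'   OTHER summing to \code{nCases}.
#' @param nExtendedHypomorph cases inside OTHER whose causal allele is a
#'   pure c.4253+43G>A hypomorph (joins the extended hypomorph group).
#' @param nCisHypomorph cases inside OTHER carrying p.Asn1868Ile in cis
#'   with a pathogenic variant (must stay OTHER).
#' @param genes data.frame with columns gene, chrom, baseWindow, caseP,
#'   controlP.
#' @param sitesPerGene rare sites simulated per gene.
#' @param qualifyingPerGene of these, how many pass both filters.
#' @param hapFreqs per-subgroup named haplotype frequency vectors (subsets
#'   of the 8-haplotype universe).
#' @param panelMinorAF ethnicity x 3 matrix of panel minor-allele
#'   frequencies at the haplotype sites.
#' @param coverageDropout per-genotype probability of a failing coverage
#'   flag.
#' @param null when TRUE, cases are generated from the control model
#'   (carrier rates and haplotype-region genotypes), for type-I-error
#'   harnesses.
#' @param seed integer seed; the generator derives one sub-stream per
#'   purpose (ethnicity, sites, carriers, haplotypes, coverage) so adding a
#'   feature does not shift existing draws.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nCases = 622, nControls = 10865,
                      ethnicityMix = .defaultEthnicityMix,
                      subgroupSizes = c(HYPOMORPH_CAUSAL = 83,
                                        G1961E = 153, OTHER = 386),
                      nExtendedHypomorph = 14, nCisHypomorph = 20,
                      genes = .defaultGenes, sitesPerGene = 6,
                      qualifyingPerGene = 3,
                      hapFreqs = .defaultHapFreqs,
                      panelMinorAF = .defaultPanelMinorAF,
                      coverageDropout = 0.02, null = FALSE, seed = 1) {
    if (abs(sum(ethnicityMix) - 1) > 1e-9)
        stop("ethnicityMix must sum to 1")
    if (sum(subgroupSizes) != nCases)
        stop("subgroup sizes must sum to nCases")
    if (nExtendedHypomorph + nCisHypomorph > subgroupSizes["OTHER"])
        stop("extended + cis hypomorph cases exceed the OTHER group")
    if (qualifyingPerGene < 1 && any(genes$caseP > 0 | genes$controlP > 0))
        stop("positive carrier rate with zero qualifying sites")
    if (qualifyingPerGene > sitesPerGene)
        stop("qualifyingPerGene exceeds sitesPerGene")
    hapFreqs <- lapply(hapFreqs, .fullHapVec)
    miss <- setdiff(rownames(panelMinorAF), names(ethnicityMix))
    if (length(setdiff(names(ethnicityMix), rownames(panelMinorAF))))
        stop("panelMinorAF lacks ethnicity rows")
    structure(list(nCases = nCases, nControls = nControls,
                   ethnicityMix = ethnicityMix,
                   subgroupSizes = subgroupSizes,
                   nExtendedHypomorph = nExtendedHypomorph,
                   nCisHypomorph = nCisHypomorph,
                   genes = genes, sitesPerGene = sitesPerGene,
                   qualifyingPerGene = qualifyingPerGene,
                   hapFreqs = hapFreqs, panelMinorAF = panelMinorAF,
                   coverageDropout = coverageDropout, null = null,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

.subSeed <- function(seed, k) as.integer((seed * 11L + k * 7919L) %% .Machine$integer.max)

#' Generate a synthetic case/control cohort
#'
#' Deterministic given the config seed. Rare sites are drawn per gene with
#' panel frequencies and CADD scores straddling the qualifying filters;
#' carrier status is Bernoulli per gene and assigned to one random
#' qualifying site as a heterozygote; 3-SNP haplotype pairs are drawn per
#' subgroup under Hardy-Weinberg pairing; control haplotype-region
#' genotypes are drawn per site from the control's own population
#' frequency; coverage flags drop out at the configured rate.
#'
#' @param config a [simConfig()].
#' @return list with \code{cohort} (a \linkS4class{GenotypeCohort}, rowData
#'   annotated, realized alt AFs in \code{metadata}), \code{popAF}
#'   (population AF table for the haplotype-region sites), \code{truth}
#'   (generating parameters: subgroup labels, carrier matrix) and
#'   \code{config}.
#' @export
generateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    nCa <- config$nCases; nCo <- config$nControls
    n <- nCa + nCo
    ids <- c(sprintf("case_%04d", seq_len(nCa)),
             sprintf("ctrl_%05d", seq_len(nCo)))
    role <- rep(c("case", "control"), c(nCa, nCo))

    # -- ethnicity ---------------------------------------------------------
    set.seed(.subSeed(config$seed, 1L))
    eths <- names(config$ethnicityMix)
    eth <- sample(eths, n, replace = TRUE, prob = config$ethnicityMix)

    # -- rare variant sites ------------------------------------------------
    set.seed(.subSeed(config$seed, 2L))
    g <- config$genes
    siteRows <- list()
    for (i in seq_len(nrow(g))) {
        nS <- config$sitesPerGene
        nQ <- config$qualifyingPerGene
        pos <- sort(sample.int(20000L, nS)) + g$baseWindow[i]
        refalt <- cbind(sample(c("A", "C", "G", "T"), nS, TRUE), "")
        refalt[, 2] <- vapply(refalt[, 1], function(r)
            sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
        qual <- rep(FALSE, nS); qual[seq_len(nQ)] <- TRUE
        af <- 10^runif(nS, -5.2, -2.6)          # all below 0.005
        cadd <- runif(nS, 26, 45)               # all above 25
        # non-qualifying sites fail exactly one filter
        fail <- which(!qual)
        half <- fail[seq_len(floor(length(fail) / 2))]
        af[half] <- runif(length(half), 0.006, 0.02)       # too common
        cadd[setdiff(fail, half)] <- runif(length(setdiff(fail, half)),
                                           5, 24)          # low CADD
        # one qualifying site per gene is absent from the panel ("nd")
        af[1] <- NA
        siteRows[[i]] <- data.frame(
            chrom = g$chrom[i], pos = pos, ref = refalt[, 1],
            alt = refalt[, 2], gene = g$gene[i], cdna = NA_character_,
            cadd = round(cadd, 1), global_af = signif(af, 4),
            qualTruth = qual, stringsAsFactors = FALSE)
    }
    rare <- do.call(rbind, siteRows)

    # haplotype-region sites: ALT is the major allele (reference genome
    # carries the minor nucleotide), exercising minor-allele orientation
    wEth <- config$ethnicityMix / sum(config$ethnicityMix)
    mixedMinor <- as.numeric(wEth %*%
        config$panelMinorAF[names(wEth), , drop = FALSE])
    hapSites <- data.frame(
        chrom = "6", pos = c(42672325, 42672306, 42672222),
        ref = c("C", "G", "A"), alt = c("G", "A", "G"), gene = "PRPH2",
        cdna = c("c.910C>G", "c.929G>A", "c.1013A>G"),
        cadd = c(0.5, 1.2, 7.4),
        global_af = round(1 - mixedMinor, 4),
        qualTruth = FALSE, stringsAsFactors = FALSE)

    ann <- rbind(rare, hapSites)
    ord <- order(ann$chrom, ann$pos)
    ann <- ann[ord, , drop = FALSE]
    key <- siteKey(ann)
    hapKeys <- siteKey(hapSites)
    nSites <- nrow(ann)

    # per-ethnicity AF columns: rare sites share the global AF; haplotype
    # sites get the population-specific ALT (major) frequency
    for (e in eths) ann[[paste0("af_", e)]] <- ann$global_af
    for (j in 1:3) {
        r <- match(hapKeys[j], key)
        for (e in eths)
            ann[[paste0("af_", e)]][r] <-
                round(1 - config$panelMinorAF[e, j], 4)
    }

    # -- carriers at rare sites -------------------------------------------
    set.seed(.subSeed(config$seed, 3L))
    dosage <- matrix(0L, nSites, n, dimnames = list(key, ids))
    carrierTruth <- matrix(FALSE, n, nrow(g),
                           dimnames = list(ids, g$gene))
    for (i in seq_len(nrow(g))) {
        gk <- key[ann$gene == g$gene[i] & ann$qualTruth]
        pCase <- if (config$null) g$controlP[i] else g$caseP[i]
        carrier <- rbinom(n, 1, ifelse(role == "case", pCase,
                                       g$controlP[i])) == 1
        carrierTruth[, i] <- carrier
        if (any(carrier)) {
            at <- sample(gk, sum(carrier), replace = TRUE)
            dosage[cbind(match(at, key), which(carrier))] <- 1L
        }
        # background: non-qualifying common-ish sites under HWE
        bg <- key[ann$gene == g$gene[i] & !ann$qualTruth &
                  !key %in% hapKeys]
        for (s in bg) {
            af <- ann$global_af[match(s, key)]
            if (!is.na(af) && af > 0)
                dosage[s, ] <- rbinom(n, 2, af)
        }
    }

    # -- subgroups and ABCA4 diplotypes -----------------------------------
    sg <- config$subgroupSizes
    stratum <- rep(c("HYPOMORPH_CAUSAL", "G1961E", "OTHER"),
                   c(sg["HYPOMORPH_CAUSAL"], sg["G1961E"], sg["OTHER"]))
    isExt <- rep(FALSE, nCa)
    oth <- which(stratum == "OTHER")
    isExt[oth[seq_len(config$nExtendedHypomorph)]] <- TRUE
    isCis <- rep(FALSE, nCa)
    isCis[oth[config$nExtendedHypomorph +
              seq_len(config$nCisHypomorph)]] <- TRUE
    al1 <- character(nCa); al2 <- character(nCa)
    al1[stratum == "HYPOMORPH_CAUSAL"] <- "p.Asn1868Ile"
    al1[stratum == "G1961E"] <- "p.Gly1961Glu"
    al1[stratum == "OTHER"] <- "pathogenic_A"
    al1[isExt] <- "c.4253+43G>A"
    al1[isCis] <- "pathogenic_A,p.Asn1868Ile"
    al2[] <- "pathogenic_B"

    # -- haplotype-region genotypes ---------------------------------------
    set.seed(.subSeed(config$seed, 4L))
    hapRowIdx <- match(hapKeys, key)
    minorD <- matrix(0L, 3, n)
    # cases: HWE pairing of subgroup-specific haplotypes; the extended
    # hypomorph stratum shares the hypomorph spectrum
    drawGroup <- function(freqs, k) {
        h1 <- sample(.hapOrder, k, replace = TRUE, prob = freqs)
        h2 <- sample(.hapOrder, k, replace = TRUE, prob = freqs)
        t(.hapBits[h1, , drop = FALSE] + .hapBits[h2, , drop = FALSE])
    }
    if (config$null) {
        pm <- config$panelMinorAF
        for (j in 1:3)
            minorD[j, seq_len(nCa)] <-
                rbinom(nCa, 2, pm[cbind(match(eth[seq_len(nCa)],
                                              rownames(pm)), j)])
    } else {
        strat <- stratum
        strat[isExt] <- "HYPOMORPH_CAUSAL"
        for (lab in unique(strat)) {
            w <- which(strat == lab)
            minorD[, w] <- drawGroup(config$hapFreqs[[lab]], length(w))
        }
    }
    # controls: independent per-site draws from own-population frequency
    ctrlIdx <- nCa + seq_len(nCo)
    pm <- config$panelMinorAF
    for (j in 1:3)
        minorD[j, ctrlIdx] <-
            rbinom(nCo, 2, pm[cbind(match(eth[ctrlIdx], rownames(pm)), j)])
    dosage[hapRowIdx, ] <- 2L - minorD    # ALT is the major allele

    # -- coverage ----------------------------------------------------------
    set.seed(.subSeed(config$seed, 5L))
    covOK <- matrix(rbinom(nSites * n, 1, 1 - config$coverageDropout) == 1,
                    nSites, n, dimnames = dimnames(dosage))
    ccds <- round(runif(n, 0.95, 1), 4)

    si <- DataFrame(role = role, ethnicity = eth,
                    row.names = ids)
    W <- matrix(0, n, length(eths), dimnames = list(NULL, eths))
    W[cbind(seq_len(n), match(eth, eths))] <- 1
    si$ethWeights <- W
    si$abca4Allele1 <- c(al1, rep(NA_character_, nCo))
    si$abca4Allele2 <- c(al2, rep(NA_character_, nCo))
    si$ccdsCovered <- ccds

    annOut <- ann[, setdiff(names(ann), "qualTruth"), drop = FALSE]
    cohort <- GenotypeCohort(dosage, annOut, si, covOK)
    metadata(cohort)$realizedAltAF <- rowMeans(dosage, na.rm = TRUE) / 2
    cohort <- orientSites(cohort)

    popAF <- hapSites[, c("chrom", "pos", "ref", "alt")]
    for (e in eths)
        popAF[[paste0("af_", e)]] <- round(1 - config$panelMinorAF[e, ], 4)
    rownames(popAF) <- hapKeys

    list(cohort = cohort, popAF = popAF,
         truth = list(stratum = stratum, extendedHypomorph = isExt,
                      cisHypomorph = isCis, carriers = carrierTruth,
                      hapSiteKeys = hapKeys, tagSiteKey = hapKeys[3],
                      qualifyingKeys = key[ann$qualTruth]),
         config = config)
}

#' Null cohort: cases generated from the control model
#'
#' Same outputs as [generateCohort()] with identical generative parameters
#' in cases and controls (carrier probabilities and haplotype-region
#' frequencies), for type-I-error harnesses.
#'
#' @param config a [simConfig()]; its \code{null} flag is forced on.
#' @return as [generateCohort()].
#' @export
nullCohort <- function(config) {
    config$null <- TRUE
    generateCohort(config)
}

#' Write the synthetic file set
#'
#' Writes the four standard inputs (VCF, annotation TSV, sample sheet,
#' population AF table) plus the coverage-flag TSV.
#'
#' @param sim result of [generateCohort()].
#' @param dir output directory.
#' @return invisibly, named vector of paths.
#' @export
writeSyntheticCohort <- function(sim, dir) {
    paths <- writeCohort(sim$cohort, dir)
    popPath <- file.path(dir, "pop_af.tsv")
    write.table(sim$popAF, popPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(paths, pop_af = popPath))
}
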