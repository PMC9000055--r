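# Haplotype spectrum estimation from unphased genotypes (EM), haplotype
# tabulation, tag-SNP summaries and association contrasts.

.hapUniverse <- function(m) {
    H <- as.matrix(expand.grid(rep(list(0:1), m)))[, seq_len(m),
                                                   drop = FALSE]
    colnames(H) <- NULL
    storage.mode(H) <- "integer"
    H
}

.hapLabelsFrom <- function(H, alleleLabels) {
    apply(H, 1, function(h)
        paste(ifelse(h == 1, alleleLabels["minor", ],
                     alleleLabels["major", ]), collapse = "-"))
}

#' EM haplotype frequency estimation from unphased multilocus genotypes
#'
#' Maximum-likelihood frequencies for all \eqn{2^m} haplotypes over m
#' biallelic sites, from unphased per-sample minor-allele dosages, via the
#' classical EM algorithm: the E-step distributes each sample over its
#' phase-compatible ordered haplotype pairs in proportion to the current
#' frequency products, the M-step re-estimates frequencies from expected
#' allele counts. Initialisation is uniform over all haplotypes, so the run
#' is fully deterministic. Convergence: max absolute frequency change
#' below \code{tol} (default 1e-8) or \code{maxit} iterations. The
#' observed-data log-likelihood is asserted non-decreasing every iteration.
#' Samples with any missing site are excluded (and counted); samples with
#' at most one heterozygous site have unambiguous phase and EM reduces to
#' direct counting for them.
#'
#' @param G integer matrix (samples x m sites) of minor-allele dosages in
#'   \{0,1,2\}, NA allowed (row excluded).
#' @param siteLabels character length m (default from column names).
#' @param alleleLabels optional 2 x m character matrix with rownames
#'   "major" and "minor" giving the allele letter per site; default labels
#'   haplotypes by 0/1 strings.
#' @param group group label carried into the result.
#' @param tol convergence tolerance on max frequency change.
#' @param maxit iteration cap.
#' @return A \linkS4class{HaplotypeSpectrum}.
#' @examples
#' G <- rbind(matrix(0L, 8, 3), matrix(c(1L, 0L, 1L), 2, 3, byrow = TRUE))
#' hapFreq(emHaplotypes(G))   # 0.9 for 0-0-0, 0.1 for 1-0-1
#' @export
emHaplotypes <- function(G, siteLabels = colnames(G), alleleLabels = NULL,
                         group = "all", tol = 1e-8, maxit = 1000) {
    G <- as.matrix(G)
    m <- ncol(G)
    if (is.null(siteLabels)) siteLabels <- paste0("site", seq_len(m))
    complete <- stats::complete.cases(G)
    nExcluded <- sum(!complete)
    G <- G[complete, , drop = FALSE]
    if (nrow(G) == 0) stop("no samples with complete genotypes")
    if (!all(G %in% 0:2)) stop("dosages must be 0, 1 or 2")
    H <- .hapUniverse(m)
    nh <- nrow(H)
    # group samples by genotype pattern; enumerate compatible ordered pairs
    pat <- apply(G, 1, paste, collapse = ",")
    upat <- unique(pat)
    patCount <- as.numeric(table(pat)[upat])
    pairList <- lapply(upat, function(p) {
        g <- as.integer(strsplit(p, ",")[[1]])
        prs <- expand.grid(h1 = seq_len(nh), h2 = seq_len(nh))
        keep <- vapply(seq_len(nrow(prs)), function(r)
            all(H[prs$h1[r], ] + H[prs$h2[r], ] == g), logical(1))
        as.matrix(prs[keep, , drop = FALSE])
    })
    n <- nrow(G)
    f <- rep(1 / nh, nh)
    llOld <- -Inf
    it <- 0L
    repeat {
        it <- it + 1L
        num <- rep(0, nh)
        ll <- 0
        for (k in seq_along(pairList)) {
            pr <- pairList[[k]]
            w <- f[pr[, 1]] * f[pr[, 2]]
            s <- sum(w)
            if (s <= 0) stop("zero-likelihood genotype pattern: ", upat[k])
            ll <- ll + patCount[k] * log(s)
            w <- patCount[k] * w / s
            num <- num + vapply(seq_len(nh), function(h)
                sum(w[pr[, 1] == h]) + sum(w[pr[, 2] == h]), numeric(1))
        }
        stopifnot(ll >= llOld - 1e-9)   # EM monotonicity invariant
        llOld <- ll
        fNew <- num / (2 * n)
        delta <- max(abs(fNew - f))
        f <- fNew
        if (delta < tol || it >= maxit) break
    }
    # maximum-posterior diplotype per sample
    dip <- matrix(NA_integer_, n, 2)
    for (k in seq_along(pairList)) {
        pr <- pairList[[k]]
        w <- f[pr[, 1]] * f[pr[, 2]]
        bst <- pr[which.max(w), ]
        dip[pat == upat[k], 1] <- min(bst)
        dip[pat == upat[k], 2] <- max(bst)
    }
    labs <- if (!is.null(alleleLabels)) .hapLabelsFrom(H, alleleLabels)
            else apply(H, 1, paste, collapse = "-")
    new("HaplotypeSpectrum", siteLabels = as.character(siteLabels),
        hapAlleles = H, hapLabels = labs, freq = f,
        nAlleles = 2L * n, group = as.character(group),
        logLik = llOld, iterations = it, diplotypes = dip,
        nExcluded = as.integer(nExcluded))
}

#' Tabulate haplotype spectra as expected counts and percentages
#'
#' One row per haplotype per group: expected allele count
#' (frequency x 2n, rounded half away from zero) and percentage of
#' alleles to 1 dp.
#'
#' @param spectra a \linkS4class{HaplotypeSpectrum} or list of them (must
#'   share site labels).
#' @return data.frame with group, haplotype, count, pct and a
#'   \code{formatted} "count (pct)" column.
#' @export
haplotypeTable <- function(spectra) {
    if (is(spectra, "HaplotypeSpectrum")) spectra <- list(spectra)
    sl <- spectra[[1]]@siteLabels
    for (s in spectra)
        if (!identical(s@siteLabels, sl))
            stop("spectra have different site labels")
    do.call(rbind, lapply(spectra, function(s) {
        cnt <- roundHalfAway(s@freq * s@nAlleles)
        pct <- roundHalfAway(100 * s@freq, 1)
        data.frame(group = s@group, haplotype = s@hapLabels,
                   count = cnt, pct = pct,
                   formatted = ifelse(cnt == 0, "0",
                                      sprintf("%d (%.1f)", cnt, pct)),
                   stringsAsFactors = FALSE)
    }))
}

#' Tag-SNP genotype and allele summary
#'
#' Genotype counts in minor-allele orientation with the implied allele
#' counts and frequencies.
#'
#' @param counts integer length-3: (minor-hom, het, major-hom) counts.
#' @param group optional label.
#' @return list with \code{n}, \code{genotypes}, \code{minorAlleles},
#'   \code{majorAlleles}, \code{minorAF}, \code{majorAF}, \code{group}.
#' @examples
#' tagSnpSummary(c(34, 240, 348))$minorAF   # 0.2476
#' @export
tagSnpSummary <- function(counts, group = "") {
    stopifnot(length(counts) == 3, all(counts >= 0))
    n <- sum(counts)
    minor <- 2 * counts[1] + counts[2]
    major <- 2 * counts[3] + counts[2]
    list(n = n,
         genotypes = setNames(as.integer(counts),
                              c("minorHom", "het", "majorHom")),
         minorAlleles = as.integer(minor),
         majorAlleles = as.integer(major),
         minorAF = minor / (2 * n), majorAF = major / (2 * n),
         group = group)
}

#' Tag-SNP summary for a sample group in a cohort
#'
#' @param cohort an oriented \linkS4class{GenotypeCohort}.
#' @param site site key or index of the tag SNP.
#' @param samples sample names/indices (default all); missing genotypes are
#'   excluded from the counts.
#' @param group optional label.
#' @return as [tagSnpSummary()].
#' @export
cohortTagSnp <- function(cohort, site, samples = NULL, group = "") {
    md <- minorDosage(cohort, sites = site, samples = samples)[1, ]
    md <- md[!is.na(md)]
    tagSnpSummary(c(sum(md == 2), sum(md == 1), sum(md == 0)),
                  group = group)
}

#' Allele-frequency contrast between two groups at a tag SNP
#'
#' 2x2 test on the (minor, major) allele-count table, group1 vs group2,
#' with Woolf odds ratio (odds of the minor allele in group1).
#'
#' @param group1,group2 summaries from [tagSnpSummary()] /
#'   [cohortTagSnp()].
#' @param method \code{"chisq"} (default, matches study-style reporting) or
#'   \code{"fisher"}.
#' @return data.frame row with allele counts, AFs, p, OR and CI.
#' @examples
#' alleleContrast(tagSnpSummary(c(0, 27, 56)),
#'                tagSnpSummary(c(34, 213, 292)))   # OR 0.55
#' @export
alleleContrast <- function(group1, group2,
                           method = c("chisq", "fisher")) {
    method <- match.arg(method)
    a <- group1$minorAlleles; b <- group1$majorAlleles
    c0 <- group2$minorAlleles; d <- group2$majorAlleles
    p <- .assocTest(a, b, c0, d, method)
    orr <- oddsRatioWoolf(a, b, c0, d)
    data.frame(group1 = group1$group, group2 = group2$group,
               n1 = group1$n, n2 = group2$n,
               minor1 = a, major1 = b, minor2 = c0, major2 = d,
               af1 = group1$minorAF, af2 = group2$minorAF,
               p = p, or = orr$or, ciLow = orr$ciLow,
               ciHigh = orr$ciHigh,
               zeroCellCorrected = orr$zeroCellCorrected,
               stringsAsFactors = FALSE)
}

#' Minor-allele homozygote contrast between two groups
#'
#' Fisher exact test on (minor-hom, rest) x group: used to test the
#' absence of minor-allele homozygotes in a subgroup.
#'
#' @inheritParams alleleContrast
#' @return data.frame row with homozygote counts, group sizes and p.
#' @export
homozygoteContrast <- function(group1, group2) {
    a <- group1$genotypes["minorHom"]
    c0 <- group2$genotypes["minorHom"]
    p <- fisherExactTwoSided(a, group1$n - a, c0, group2$n - c0)
    data.frame(group1 = group1$group, group2 = group2$group,
               hom1 = as.integer(a), n1 = group1$n,
               hom2 = as.integer(c0), n2 = group2$n, p = p,
               stringsAsFactors = FALSE)
}

#' Pairwise linkage disequilibrium from EM haplotype frequencies
#'
#' Estimates the two-site haplotype frequencies by [emHaplotypes()] and
#' returns \eqn{D = p_{AB} - p_A p_B}, \eqn{D' = D / D_{max}} and
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)}, where A/B are the minor alleles.
#' Monomorphic sites yield flagged missing values.
#'
#' @param cohort an oriented \linkS4class{GenotypeCohort}.
#' @param siteA,siteB site keys or indices.
#' @param samples sample subset (default all).
#' @return list with \code{D}, \code{Dprime}, \code{r2}, \code{pA},
#'   \code{pB}, \code{monomorphic}.
#' @export
ldStats <- function(cohort, siteA, siteB, samples = NULL) {
    G <- t(minorDosage(cohort, sites = c(siteA, siteB),
                       samples = samples))
    sp <- emHaplotypes(G, siteLabels = c("A", "B"))
    # haplotype order for m=2: (0,0), (1,0), (0,1), (1,1)
    pAB <- sp@freq[4]
    pA <- sp@freq[2] + sp@freq[4]
    pB <- sp@freq[3] + sp@freq[4]
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        return(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                    pA = pA, pB = pB, monomorphic = TRUE))
    D <- pAB - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    list(D = D,
         Dprime = if (dmax > 0) D / dmax else 0,
         r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
         pA = pA, pB = pB, monomorphic = FALSE)
}
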