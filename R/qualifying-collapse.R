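# Qualifying-variant filtering, coverage QC and gene-level collapsing.

#' Per-sample coverage QC
#'
#' Retains samples covered at >= 10x in at least \code{minFraction} of the
#' consensus coding sequence (CCDS) regions; the per-sample covered
#' fraction arrives with the sample sheet (\code{ccdsCovered}).
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param minFraction retention threshold on the covered fraction
#'   (default 0.90, inclusive).
#' @return the cohort restricted to retained samples; excluded sample ids
#'   are recorded in \code{metadata(.)$sampleQCExcluded}.
#' @export
applySampleQC <- function(cohort, minFraction = 0.90) {
    si <- sampleInfo(cohort)
    frac <- if (!is.null(si$ccdsCovered)) si$ccdsCovered
            else rep(1, ncol(cohort))
    if (any(frac < 0 | frac > 1, na.rm = TRUE))
        stop("ccdsCovered fractions must be in [0,1]")
    keep <- !is.na(frac) & frac >= minFraction
    out <- cohort[, keep]
    metadata(out)$sampleQCExcluded <- colnames(cohort)[!keep]
    out
}

#' Per-site differential-coverage QC
#'
#' Drops sites whose fraction of coverage-passing genotypes differs between
#' all cases and all controls by \code{maxDiff} or more (default 0.11,
#' inclusive): sites with unequal capture between cohorts would bias
#' carrier counts.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param maxDiff drop threshold on the absolute case/control difference in
#'   coverage-passing fraction.
#' @return the cohort restricted to retained sites; dropped site keys are
#'   recorded in \code{metadata(.)$siteQCDropped}.
#' @export
applySiteQC <- function(cohort, maxDiff = 0.11) {
    cs <- isCase(cohort)
    if (!any(cs) || !any(!cs)) return(cohort)
    cov <- coverageOK(cohort)
    diff <- abs(rowMeans(cov[, cs, drop = FALSE]) -
                rowMeans(cov[, !cs, drop = FALSE]))
    keep <- diff < maxDiff - 1e-12
    out <- cohort[keep, ]
    metadata(out)$siteQCDropped <- rownames(cohort)[!keep]
    out
}

#' Qualifying-variant filter
#'
#' A site qualifies when its minor allele frequency in the reference panel
#' is strictly below \code{mafMax} and its CADD score is strictly above
#' \code{caddMin}. Sites absent from the panel (missing global frequency)
#' are rarer than any threshold and therefore qualify under every numeric
#' \code{mafMax}; the sentinel \code{mafMax = "nd"} selects exactly those
#' absent-in-panel sites, so the ladder of thresholds yields nested
#' qualifying sets with the sentinel a subset of every numeric row. Sites
#' without a CADD score are excluded and reported via message, never
#' silently.
#'
#' @param cohort an oriented \linkS4class{GenotypeCohort} (see
#'   [orientSites()]; called automatically if needed).
#' @param mafMax frequency threshold in (0, 1], or \code{"nd"} for the
#'   absent-in-panel sentinel.
#' @param caddMin CADD threshold (strict >), default 25.
#' @return logical vector over sites (TRUE = qualifying), named by site key.
#' @export
qualifyingSites <- function(cohort, mafMax = 0.005, caddMin = 25) {
    rd <- variantInfo(cohort)
    if (is.null(rd$minorAF)) {
        cohort <- orientSites(cohort)
        rd <- variantInfo(cohort)
    }
    cadd <- rd$cadd
    noCadd <- is.na(cadd)
    if (any(noCadd))
        message(sum(noCadd), " site(s) without CADD score excluded: ",
                paste(head(rownames(cohort)[noCadd], 5), collapse = ", "))
    if (identical(mafMax, "nd")) {
        q <- is.na(rd$global_af)
    } else {
        if (!is.numeric(mafMax) || mafMax <= 0 || mafMax > 1)
            stop("mafMax must be in (0,1] or \"nd\"")
        q <- is.na(rd$global_af) |
            (!is.na(rd$minorAF) & rd$minorAF < mafMax)
    }
    q <- q & !noCadd & cadd > caddMin
    setNames(q, rownames(cohort))
}

#' Collapse qualifying variants to per-gene carrier status
#'
#' A sample carries a gene when it has minor-allele dosage >= 1 at one or
#' more qualifying sites in that gene; a sample carries the gene set when
#' it carries any member gene. Each sample counts at most once per
#' gene/set. Missing dosages at a sample's qualifying sites leave the
#' sample in the denominator as a non-carrier.
#'
#' @param cohort an oriented \linkS4class{GenotypeCohort}.
#' @param qualifying logical vector over sites (from [qualifyingSites()]).
#' @param genes character vector of genes defining the set (default: all
#'   genes present).
#' @return logical matrix (samples x (genes + "geneSet")) of carrier status.
#' @export
collapseCarriers <- function(cohort, qualifying, genes = NULL) {
    rd <- variantInfo(cohort)
    if (is.null(genes)) genes <- sort(unique(rd$gene))
    md <- minorDosage(cohort)
    carrier <- matrix(FALSE, ncol(cohort), length(genes) + 1L,
                      dimnames = list(colnames(cohort),
                                      c(genes, "geneSet")))
    for (g in genes) {
        idx <- which(qualifying & rd$gene == g)
        if (length(idx))
            carrier[, g] <- colSums(md[idx, , drop = FALSE] >= 1,
                                    na.rm = TRUE) > 0
    }
    carrier[, "geneSet"] <- rowSums(
        carrier[, genes, drop = FALSE]) > 0
    carrier
}

#' Case/control enrichment of carrier counts
#'
#' Builds the (carrier, non-carrier) x (case, control) table per gene,
#' tests it and computes the Woolf odds ratio, the case/control percentage
#' ratio and the Bonferroni significance flag at \code{0.05 / kTests}.
#'
#' @param caseCarriers,controlCarriers named integer vectors of carrier
#'   counts per gene (or single counts).
#' @param caseN,controlN cohort sizes (post-QC denominators).
#' @param kTests number of tests for the Bonferroni flag.
#' @param method association test: \code{"chisq"} (uncorrected Pearson,
#'   the default used for study-style reporting) or \code{"fisher"}.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with one row per gene: carrier counts, percentages,
#'   ratio, p, OR and CI, zero-cell flag, Bonferroni threshold and flag.
#' @examples
#' enrichmentTable(c(ROM1 = 8), 622, c(ROM1 = 37), 10865, kTests = 7)
#' @export
enrichmentTable <- function(caseCarriers, caseN, controlCarriers, controlN,
                            kTests, method = c("chisq", "fisher"),
                            alpha = 0.05) {
    method <- match.arg(method)
    stopifnot(length(caseCarriers) == length(controlCarriers),
              all(caseCarriers <= caseN),
              all(controlCarriers <= controlN))
    thr <- bonferroniThreshold(alpha, kTests)
    rows <- lapply(seq_along(caseCarriers), function(i) {
        a <- caseCarriers[i]; c0 <- controlCarriers[i]
        p <- .assocTest(a, caseN - a, c0, controlN - c0, method)
        orr <- oddsRatioWoolf(a, caseN - a, c0, controlN - c0)
        casePct <- 100 * a / caseN
        ctrlPct <- 100 * c0 / controlN
        data.frame(
            gene = if (!is.null(names(caseCarriers)))
                names(caseCarriers)[i] else as.character(i),
            caseCarriers = a, caseN = caseN,
            controlCarriers = c0, controlN = controlN,
            casePct = casePct, controlPct = ctrlPct,
            ratio = if (ctrlPct > 0) casePct / ctrlPct else NA_real_,
            p = p, or = orr$or, ciLow = orr$ciLow, ciHigh = orr$ciHigh,
            zeroCellCorrected = orr$zeroCellCorrected,
            bonferroniThreshold = thr,
            significant = p < thr,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Gene-set collapsing down a MAF ladder
#'
#' Runs the qualifying filter and gene-set collapsing at each threshold of
#' a strictly decreasing MAF ladder, ending with the absent-in-panel
#' sentinel \code{"nd"}. Carrier sets are nested down the ladder (asserted;
#' a violation indicates corrupt annotations).
#'
#' @param cohort an oriented \linkS4class{GenotypeCohort} (post QC).
#' @param thresholds list/vector of thresholds, numeric values strictly
#'   decreasing with optional final \code{"nd"}.
#' @param caddMin CADD threshold, default 25.
#' @param kTests Bonferroni k (default: number of ladder rows).
#' @param method association test, as in [enrichmentTable()].
#' @return data.frame with one gene-set enrichment row per threshold.
#' @export
mafLadder <- function(cohort, thresholds = list(0.005, 0.001, 1e-4, 1e-5,
                                                "nd"),
                      caddMin = 25, kTests = length(thresholds),
                      method = c("chisq", "fisher")) {
    method <- match.arg(method)
    num <- vapply(thresholds, function(t) is.numeric(t), logical(1))
    tn <- unlist(thresholds[num])
    if (is.unsorted(rev(tn), strictly = TRUE) && length(tn) > 1)
        stop("numeric thresholds must be strictly decreasing")
    cohort <- orientSites(cohort)
    cs <- isCase(cohort)
    prev <- NULL
    out <- NULL
    for (t in thresholds) {
        q <- qualifyingSites(cohort, mafMax = t, caddMin = caddMin)
        carrier <- collapseCarriers(cohort, q)[, "geneSet"]
        if (!is.null(prev) && !all(!carrier | prev))
            stop("carrier-set nesting violated down the MAF ladder")
        if (!identical(t, "nd")) prev <- carrier
        row <- enrichmentTable(sum(carrier & cs), sum(cs),
                               sum(carrier & !cs), sum(!cs),
                               kTests = kTests, method = method)
        row$gene <- NULL
        row <- cbind(mafMax = if (identical(t, "nd")) "nd"
                     else format(t, scientific = FALSE), row)
        out <- rbind(out, row)
    }
    rownames(out) <- NULL
    out
}
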