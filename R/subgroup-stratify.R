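# Genetic subgroup classification of bi-allelic ABCA4 cases with
# cis-modifier control.

#' Classify one bi-allelic case into a genetic subgroup
#'
#' Cases fall into three disjoint groups. HYPOMORPH_CAUSAL: one ABCA4
#' allele carries a hypomorphic variant (p.Asn1868Ile, optionally
#' c.4253+43G>A) with no pathogenic variant in cis on that same allele
#' ("pure" hypomorph), and the other allele carries at least one pathogenic
#' variant. G1961E: otherwise, either allele carries p.Gly1961Glu. OTHER:
#' all remaining bi-allelic cases, including those where the hypomorph sits
#' in cis with a pathogenic variant (cis-modifier control). A case that
#' satisfies both definitions (pure hypomorph on one allele, p.Gly1961Glu
#' as the pathogenic partner) is labelled by \code{precedence}.
#'
#' @param allele1,allele2 character vectors of variant labels on each
#'   ABCA4 allele (per-allele sets encode phase); may be empty for an
#'   allele carrying only an unlisted pathogenic variant, but not both.
#' @param hypomorphLabels labels counting as hypomorphic; default
#'   p.Asn1868Ile and c.4253+43G>A.
#' @param g1961eLabel the p.Gly1961Glu label.
#' @param pathogenicLabels labels counting as pathogenic; \code{NULL}
#'   (default) treats every non-hypomorph label as pathogenic.
#' @param precedence which group wins when both definitions hold.
#' @return one of "HYPOMORPH_CAUSAL", "G1961E", "OTHER".
#' @examples
#' classifyCase("p.Asn1868Ile", "p.X1234fs")          # HYPOMORPH_CAUSAL
#' classifyCase(c("p.X1234fs", "p.Asn1868Ile"),       # in cis -> OTHER
#'              "p.Y999del")
#' classifyCase("p.Gly1961Glu", "p.X1234fs")          # G1961E
#' @export
classifyCase <- function(allele1, allele2,
                         hypomorphLabels = c("p.Asn1868Ile",
                                             "c.4253+43G>A"),
                         g1961eLabel = "p.Gly1961Glu",
                         pathogenicLabels = NULL,
                         precedence = c("HYPOMORPH_CAUSAL", "G1961E")) {
    precedence <- match.arg(precedence)
    a1 <- allele1[nzchar(allele1) & !is.na(allele1)]
    a2 <- allele2[nzchar(allele2) & !is.na(allele2)]
    if (length(a1) == 0 && length(a2) == 0)
        stop("empty diplotype: case is not bi-allelic")
    isPath <- function(v) {
        if (is.null(pathogenicLabels)) !(v %in% hypomorphLabels)
        else v %in% pathogenicLabels
    }
    pureHyp <- function(al) length(al) > 0 &&
        any(al %in% hypomorphLabels) && !any(isPath(al))
    hasPath <- function(al) any(isPath(al))
    hyp <- (pureHyp(a1) && hasPath(a2)) || (pureHyp(a2) && hasPath(a1))
    g19 <- g1961eLabel %in% c(a1, a2)
    if (hyp && g19) return(precedence)
    if (hyp) return("HYPOMORPH_CAUSAL")
    if (g19) return("G1961E")
    "OTHER"
}

#' Partition the case cohort into genetic subgroups
#'
#' Applies [classifyCase()] to every case and returns the partition plus
#' the complement ("minus") groups used in stratified contrasts.
#'
#' @param cohort a \linkS4class{GenotypeCohort}, or a sample
#'   \code{DataFrame} with \code{role}, \code{abca4Allele1},
#'   \code{abca4Allele2} (comma-separated labels per allele).
#' @inheritParams classifyCase
#' @return list with \code{label} (named character over cases),
#'   \code{groups} (list of case-id vectors per label) and
#'   \code{complements} (case ids outside each label).
#' @export
subgroupPartition <- function(cohort,
                              hypomorphLabels = c("p.Asn1868Ile",
                                                  "c.4253+43G>A"),
                              g1961eLabel = "p.Gly1961Glu",
                              pathogenicLabels = NULL,
                              precedence = c("HYPOMORPH_CAUSAL",
                                             "G1961E")) {
    si <- if (is(cohort, "GenotypeCohort")) sampleInfo(cohort) else cohort
    cs <- which(si$role == "case")
    if (!length(cs)) stop("no case samples")
    ids <- rownames(si)[cs]
    splitLabels <- function(x)
        if (is.na(x) || !nzchar(x)) character(0)
        else trimws(strsplit(x, ",")[[1]])
    lab <- vapply(cs, function(i)
        classifyCase(splitLabels(si$abca4Allele1[i]),
                     splitLabels(si$abca4Allele2[i]),
                     hypomorphLabels = hypomorphLabels,
                     g1961eLabel = g1961eLabel,
                     pathogenicLabels = pathogenicLabels,
                     precedence = precedence),
        character(1))
    names(lab) <- ids
    lv <- c("HYPOMORPH_CAUSAL", "G1961E", "OTHER")
    groups <- lapply(setNames(lv, lv), function(l) ids[lab == l])
    complements <- lapply(setNames(lv, lv),
                          function(l) ids[lab != l])
    list(label = lab, groups = groups, complements = complements)
}
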