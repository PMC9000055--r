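# Ethnicity-matched external control synthesis from population-stratified
# reference allele frequencies.

#' Average ethnicity weights over the case cohort
#'
#' The ethnicity composition used to mix population reference frequencies:
#' the arithmetic mean of per-case admixture weight vectors (hard labels
#' count as weight 1).
#'
#' @param cohort a \linkS4class{GenotypeCohort}, or a sample
#'   \code{DataFrame} with \code{role} and \code{ethWeights}.
#' @return named numeric vector of proportions summing to 1.
#' @export
caseEthnicityWeights <- function(cohort) {
    si <- if (is(cohort, "GenotypeCohort")) sampleInfo(cohort) else cohort
    cs <- si$role == "case"
    if (!any(cs)) stop("no case samples")
    W <- si$ethWeights
    if (is.null(W)) stop("no ethnicity weights in sample metadata")
    w <- colMeans(W[cs, , drop = FALSE])
    w / sum(w)
}

#' Read a population reference allele-frequency table
#'
#' TSV with site key columns (chrom, pos, ref, alt) plus one
#' \code{af_<ethnicity>} column per population and optional
#' \code{an_<ethnicity>} allele numbers.
#'
#' @param path TSV path.
#' @return data.frame keyed by [siteKey()].
#' @export
readPopulationAF <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    df$chrom <- as.character(df$chrom)
    rownames(df) <- siteKey(df)
    afc <- grep("^af_", names(df), value = TRUE)
    for (cc in afc)
        if (any(df[[cc]] < 0 | df[[cc]] > 1, na.rm = TRUE))
            stop("population AF outside [0,1] in column ", cc)
    df
}

#' Ethnicity-weighted matched control allele frequency
#'
#' Combines per-population reference frequencies at a site in the same
#' proportions of ethnicities as the case cohort:
#' \eqn{\sum_e w_e \, af_e}.
#'
#' @param popTable data.frame from [readPopulationAF()] (or any
#'   data.frame with \code{af_<ethnicity>} columns).
#' @param weights named proportions summing to 1 (see
#'   [caseEthnicityWeights()]).
#' @param site site key (rowname of \code{popTable}) or row index.
#' @return the mixed allele frequency.
#' @export
matchedAF <- function(popTable, weights, site) {
    if (abs(sum(weights) - 1) > 1e-6)
        stop("ethnicity weights must sum to 1")
    row <- popTable[site, , drop = FALSE]
    if (nrow(row) != 1 || all(is.na(row)))
        stop("site not found in population table: ", site)
    cols <- paste0("af_", names(weights))
    missing <- !(cols %in% names(popTable))
    if (any(missing))
        stop("ethnicity absent from population table: ",
             paste(names(weights)[missing], collapse = ", "))
    af <- as.numeric(row[1, cols])
    if (anyNA(af))
        stop("missing population AF for: ",
             paste(names(weights)[is.na(af)], collapse = ", "))
    sum(weights * af)
}

#' Largest-remainder apportionment
#'
#' Integer counts proportional to \code{p} summing exactly to \code{n}.
#' @param n total.
#' @param p non-negative weights.
#' @return integer vector summing to n.
#' @keywords internal
largestRemainder <- function(n, p) {
    tgt <- n * p / sum(p)
    fl <- floor(tgt)
    rem <- n - sum(fl)
    if (rem > 0) {
        ord <- order(tgt - fl, decreasing = TRUE)
        fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
    }
    as.integer(fl)
}

#' Materialise a matched control cohort at one site
#'
#' Converts a mixed minor-allele frequency into an integer allele count
#' (\code{round(2 n af)}) and Hardy-Weinberg genotype counts
#' (\eqn{n q^2, 2npq, n p^2}, largest-remainder rounded to sum to n).
#' Genotype counts are model-derived (HWE assumed), flagged as such.
#'
#' @param af minor-allele frequency in \[0, 1\].
#' @param n number of control individuals (>= 1).
#' @return list with \code{n}, \code{af}, \code{minorAlleles},
#'   \code{totalAlleles}, \code{genotypes} (minorHom, het, majorHom),
#'   \code{genotypePct} and \code{hweAssumed = TRUE}.
#' @examples
#' materializeControls(0.21, 43029)
#' @export
materializeControls <- function(af, n) {
    stopifnot(n >= 1, n == floor(n), af >= 0, af <= 1)
    q <- af; p <- 1 - af
    geno <- largestRemainder(n, c(q^2, 2 * p * q, p^2))
    names(geno) <- c("minorHom", "het", "majorHom")
    list(n = as.integer(n), af = af,
         minorAlleles = as.integer(round(2 * n * af)),
         totalAlleles = as.integer(2 * n),
         genotypes = geno,
         genotypePct = 100 * geno / n,
         hweAssumed = TRUE)
}
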