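#' @importFrom stats dhyper chisq.test setNames qnorm median rbinom runif complete.cases
#' @importFrom utils head
NULL

.checkTable <- function(a, b, c, d) {
    x <- c(a, b, c, d)
    if (any(is.na(x)) || any(x < 0) || any(x != floor(x)))
        stop("2x2 table cells must be non-negative integers")
    if ((a + b) == 0 || (c + d) == 0)
        stop("empty row margin in 2x2 table")
    invisible(TRUE)
}

#' Two-sided Fisher exact test (minimum-likelihood convention)
#'
#' Exact p-value for independence in a 2x2 table: the sum of point
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (with a 1e-7 relative
#' guard against floating ties). This is the convention used by
#' \code{stats::fisher.test}.
#'
#' @param a,b,c,d cell counts; rows are groups, columns event/non-event.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(2, 3, 3, 2)   # 1: all 6 margin-compatible tables tie
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
    .checkTable(a, b, c, d)
    m <- a + b; n <- c + d; k <- a + c
    if (k == 0 || k == m + n) return(1)     # degenerate column margin
    supp <- max(0L, k - n):min(k, m)
    pr <- dhyper(supp, m, n, k)
    p0 <- dhyper(a, m, n, k)
    min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

#' Two-sided Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no continuity correction) Pearson chi-square, equivalent to
#' the two-proportion z test. This is the asymptotic companion of
#' [fisherExactTwoSided()] and the test that reproduces the bundled study
#' tables' printed p-values.
#'
#' @inheritParams fisherExactTwoSided
#' @return p-value in (0, 1].
#' @export
chisqTwoSided <- function(a, b, c, d) {
    .checkTable(a, b, c, d)
    if ((a + c) == 0 || (b + d) == 0) return(1)
    suppressWarnings(
        chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                   correct = FALSE)$p.value)
}

.assocTest <- function(a, b, c, d, method = c("chisq", "fisher")) {
    method <- match.arg(method)
    if (method == "chisq") chisqTwoSided(a, b, c, d)
    else fisherExactTwoSided(a, b, c, d)
}

#' Odds ratio with Woolf (logit) 95\% confidence interval
#'
#' Point estimate \eqn{ad/bc}; interval
#' \eqn{\exp(\log OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})}. If any cell is zero,
#' the Haldane-Anscombe 0.5 correction is added to all cells first and the
#' result is flagged.
#'
#' @inheritParams fisherExactTwoSided
#' @return list with \code{or}, \code{ciLow}, \code{ciHigh},
#'   \code{zeroCellCorrected}.
#' @examples
#' oddsRatioWoolf(8, 614, 37, 10828)  # OR 3.81, CI [1.77, 8.22]
#' @export
oddsRatioWoolf <- function(a, b, c, d) {
    .checkTable(a, b, c, d)
    corrected <- any(c(a, b, c, d) == 0)
    if (corrected) {
        a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(or = or,
         ciLow = exp(log(or) - 1.96 * se),
         ciHigh = exp(log(or) + 1.96 * se),
         zeroCellCorrected = corrected)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1].
#' @param k number of tests, a positive integer.
#' @return \code{alpha / k}.
#' @export
bonferroniThreshold <- function(alpha, k) {
    if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
        stop("alpha must be in (0, 1]")
    if (!is.numeric(k) || k < 1 || k != floor(k))
        stop("k must be a positive integer")
    alpha / k
}

#' Round half away from zero
#'
#' The rounding convention used by the bundled study tables (1-dp
#' percentages, 2-dp odds ratios), unlike base R's round-half-even.
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfAway <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reconstruct integer genotype counts from printed percentages
#'
#' Inverts 1-dp genotype percentages back to the integer counts
#' (nAA, nAG, nGG) summing to \code{n} whose percentages, rounded half away
#' from zero to 1 dp, equal the printed values. Among feasible triples the
#' one minimising \eqn{\max_i |count_i - n p_i/100|} is returned
#' (lexicographic tie-break), with genuine multiplicity flagged.
#'
#' @param n group size (number of individuals).
#' @param pcts numeric length-3, printed percentages (1 dp) for the
#'   minor-hom / het / major-hom genotypes, in \[0, 100\].
#' @param nearest if \code{TRUE}, when no exact triple exists return the
#'   best near-miss (percentage off by one rounding step in one class)
#'   instead of erroring; the result is flagged.
#' @return list with \code{counts} (integer length-3), \code{multiple}
#'   (logical), \code{exact} (logical).
#' @examples
#' reconstructGenotypeCounts(83, c(0, 32.5, 67.5))$counts    # 0 27 56
#' reconstructGenotypeCounts(539, c(6.3, 39.5, 54.2))$counts # 34 213 292
#' @export
reconstructGenotypeCounts <- function(n, pcts, nearest = FALSE) {
    if (n < 1 || n != floor(n)) stop("n must be a positive integer")
    if (length(pcts) != 3 || any(pcts < 0 | pcts > 100))
        stop("pcts must be three percentages in [0,100]")
    cand <- function(p) {
        ctr <- round(n * p / 100)
        lo <- max(0L, ctr - max(3L, ceiling(n / 1000) + 2L))
        hi <- min(n, ctr + max(3L, ceiling(n / 1000) + 2L))
        v <- lo:hi
        v[roundHalfAway(100 * v / n, 1) == p]
    }
    c1 <- cand(pcts[1]); c2 <- cand(pcts[2])
    tgt <- n * pcts / 100
    best <- NULL; bestScore <- Inf; multiple <- FALSE
    for (i in c1) for (j in c2) {
        k <- n - i - j
        if (k < 0 || roundHalfAway(100 * k / n, 1) != pcts[3]) next
        sc <- max(abs(c(i, j, k) - tgt))
        if (sc < bestScore - 1e-12) {
            best <- c(i, j, k); bestScore <- sc; multiple <- FALSE
        } else if (abs(sc - bestScore) <= 1e-12) {
            multiple <- TRUE
            if (i < best[1] || (i == best[1] && j < best[2]))
                best <- c(i, j, k)
        }
    }
    if (!is.null(best))
        return(list(counts = as.integer(best), multiple = multiple,
                    exact = TRUE))
    # no feasible triple: nearest mode relaxes one class by one rounding step
    near <- function(p) {
        ctr <- round(n * p / 100)
        lo <- max(0L, ctr - max(3L, ceiling(n / 1000) + 2L))
        hi <- min(n, ctr + max(3L, ceiling(n / 1000) + 2L))
        v <- lo:hi
        v[abs(roundHalfAway(100 * v / n, 1) - p) <= 0.1 + 1e-9]
    }
    n1 <- near(pcts[1]); n2 <- near(pcts[2])
    for (i in n1) for (j in n2) {
        k <- n - i - j
        if (k < 0 ||
            abs(roundHalfAway(100 * k / n, 1) - pcts[3]) > 0.1 + 1e-9) next
        sc <- max(abs(c(i, j, k) - tgt))
        if (sc < bestScore - 1e-12) { best <- c(i, j, k); bestScore <- sc }
    }
    if (is.null(best))
        stop("no feasible genotype triple for n=", n, " and percentages ",
             paste(pcts, collapse = "/"))
    if (!nearest)
        stop("no exact genotype triple for n=", n, " and percentages ",
             paste(pcts, collapse = "/"), "; nearest candidate: ",
             paste(best, collapse = ","),
             " (use nearest=TRUE to accept)")
    list(counts = as.integer(best), multiple = FALSE, exact = FALSE)
}

#' Allele-count 2x2 table from two genotype-count triples
#'
#' Rows are groups, columns (minor-allele count, major-allele count) with
#' minor = 2 nAA + nAG and major = 2 nGG + nAG when triples are ordered
#' (minor-hom, het, major-hom).
#'
#' @param counts1,counts2 integer length-3 genotype counts.
#' @return 2x2 integer matrix.
#' @examples
#' alleleTableFromGenotypes(c(0, 27, 56), c(34, 213, 292))
#' @export
alleleTableFromGenotypes <- function(counts1, counts2) {
    stopifnot(length(counts1) == 3, length(counts2) == 3,
              all(counts1 >= 0), all(counts2 >= 0))
    al <- function(g) as.integer(c(2 * g[1] + g[2], 2 * g[3] + g[2]))
    m <- rbind(al(counts1), al(counts2))
    dimnames(m) <- list(c("group1", "group2"), c("minor", "major"))
    m
}
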