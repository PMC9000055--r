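#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData rowData<- colData colData<-
NULL

#' Case/control genotype cohort
#'
#' A \linkS4class{SummarizedExperiment} holding a diploid genotype cohort:
#' rows are biallelic variant sites, columns are samples. Two assays are
#' required: \code{dosage} (integer count of ALT alleles per genotype, in
#' \{0,1,2\} with \code{NA} for missing) and \code{coverageOK} (logical
#' per-genotype coverage QC flag). \code{rowData} carries the site
#' annotations (chrom, pos, ref, alt, gene, cadd, global_af and per-population
#' \code{af_<ethnicity>} columns); \code{colData} carries the sample sheet
#' (role, ethnicity label, admixture weight matrix, ABCA4 diplotype
#' annotation, CCDS coverage fraction).
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [GenotypeCohort()] for the constructor, [readCohort()] to build
#'   one from files.
#' @export
setClass("GenotypeCohort", contains = "SummarizedExperiment")

.validGenotypeCohort <- function(object) {
    msg <- character()
    an <- names(assays(object))
    if (!all(c("dosage", "coverageOK") %in% an))
        msg <- c(msg, "assays must include 'dosage' and 'coverageOK'")
    if ("dosage" %in% an) {
        d <- assay(object, "dosage")
        bad <- !(d %in% c(0L, 1L, 2L) | is.na(d))
        if (any(bad))
            msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
    }
    rd <- rowData(object)
    need <- c("chrom", "pos", "ref", "alt", "gene", "cadd", "global_af")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("pos" %in% colnames(rd) && any(rd$pos < 1))
        msg <- c(msg, "positions must be >= 1 (1-based)")
    if (all(c("ref", "alt") %in% colnames(rd)) &&
        any(rd$ref == rd$alt))
        msg <- c(msg, "ref and alt alleles must differ")
    cd <- colData(object)
    if (!"role" %in% colnames(cd)) {
        msg <- c(msg, "colData lacks 'role'")
    } else if (!all(cd$role %in% c("case", "control"))) {
        msg <- c(msg, "role must be 'case' or 'control'")
    }
    afc <- grep("^af_", colnames(rd), value = TRUE)
    for (cc in c("global_af", afc)) {
        if (cc %in% colnames(rd)) {
            v <- rd[[cc]]
            if (any(v < 0 | v > 1, na.rm = TRUE))
                msg <- c(msg, paste0(cc, " outside [0,1]"))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeCohort", .validGenotypeCohort)

#' Construct a GenotypeCohort
#'
#' @param dosage integer matrix (sites x samples) of ALT-allele dosages in
#'   \{0,1,2,NA\}.
#' @param variantInfo \code{data.frame}/\code{DataFrame} of site annotations,
#'   one row per site; must contain chrom, pos, ref, alt, gene, cadd,
#'   global_af (and optionally cdna and af_<ethnicity> columns).
#' @param sampleInfo \code{data.frame}/\code{DataFrame} of sample metadata,
#'   one row per sample; must contain \code{role} ("case"/"control").
#' @param coverageOK logical matrix of per-genotype coverage flags; defaults
#'   to all \code{TRUE}.
#' @return A \linkS4class{GenotypeCohort}.
#' @examples
#' vi <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
#'                  gene = "ROM1", cadd = 30, global_af = c(0.001, 0.9))
#' si <- data.frame(role = c("case", "control"),
#'                  row.names = c("s1", "s2"))
#' gc <- GenotypeCohort(matrix(c(0L, 1L, 2L, NA), 2,
#'                             dimnames = list(NULL, c("s1", "s2"))), vi, si)
#' dosages(gc)
#' @export
GenotypeCohort <- function(dosage, variantInfo, sampleInfo,
                           coverageOK = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(coverageOK))
        coverageOK <- matrix(TRUE, nrow(dosage), ncol(dosage))
    dimnames(coverageOK) <- dimnames(dosage)
    rd <- DataFrame(variantInfo)
    rownames(rd) <- siteKey(variantInfo)
    rownames(dosage) <- rownames(coverageOK) <- rownames(rd)
    se <- SummarizedExperiment(
        assays = SimpleList(dosage = dosage, coverageOK = coverageOK),
        rowData = rd, colData = DataFrame(sampleInfo))
    new("GenotypeCohort", se)
}

#' Canonical site key
#'
#' \code{chrom:pos_ref/alt}, the key joining VCF records to annotation rows.
#' @param x data.frame-like with chrom, pos, ref, alt columns.
#' @return character vector of keys.
#' @export
siteKey <- function(x) {
    paste0(x$chrom, ":", x$pos, "_", x$ref, "/", x$alt)
}

#' Estimated haplotype spectrum over a small set of linked SNPs
#'
#' Holds the maximum-likelihood haplotype frequency estimates for all
#' \eqn{2^m} haplotypes over \eqn{m} biallelic sites, as produced by
#' [emHaplotypes()], together with the EM diagnostics and per-sample
#' maximum-posterior diplotypes.
#'
#' @slot siteLabels character, the m site labels in order.
#' @slot hapAlleles integer matrix (2^m x m) of minor-allele indicators
#'   defining each haplotype (0 = major allele, 1 = minor allele).
#' @slot hapLabels character, display label per haplotype (e.g. "G-A-G").
#' @slot freq numeric, estimated frequency per haplotype (sums to 1).
#' @slot nAlleles integer, 2 x number of samples used.
#' @slot group character, group label.
#' @slot logLik numeric, final observed-data log-likelihood.
#' @slot iterations integer, EM iterations run.
#' @slot diplotypes integer matrix (n x 2) of haplotype indices of the
#'   maximum-posterior diplotype per retained sample.
#' @slot nExcluded integer, samples dropped for missing genotypes.
#' @export
setClass("HaplotypeSpectrum",
    representation(siteLabels = "character", hapAlleles = "matrix",
                   hapLabels = "character", freq = "numeric",
                   nAlleles = "integer", group = "character",
                   logLik = "numeric", iterations = "integer",
                   diplotypes = "matrix", nExcluded = "integer"))

setValidity("HaplotypeSpectrum", function(object) {
    msg <- character()
    if (abs(sum(object@freq) - 1) > 1e-9)
        msg <- c(msg, "haplotype frequencies must sum to 1")
    if (length(object@freq) != nrow(object@hapAlleles))
        msg <- c(msg, "freq length must match haplotype count")
    if (any(object@freq < -1e-12))
        msg <- c(msg, "negative haplotype frequency")
    if (length(msg)) msg else TRUE
})

#' @describeIn HaplotypeSpectrum-class compact display
#' @param object a \code{HaplotypeSpectrum}
#' @export
setMethod("show", "HaplotypeSpectrum", function(object) {
    cat("HaplotypeSpectrum over", length(object@siteLabels),
        "sites (", paste(object@siteLabels, collapse = ", "), ")\n")
    cat("group:", object@group, "  n alleles:", object@nAlleles,
        "  EM iterations:", object@iterations,
        "  logLik:", format(object@logLik, digits = 6), "\n")
    df <- data.frame(haplotype = object@hapLabels,
                     frequency = round(object@freq, 4),
                     expected_count = round(object@freq * object@nAlleles, 1))
    print(df[order(-df$frequency), ], row.names = FALSE)
    invisible(NULL)
})

setMethod("show", "GenotypeCohort", function(object) {
    callNextMethod()
    cd <- colData(object)
    cat("cases:", sum(cd$role == "case"),
        " controls:", sum(cd$role == "control"), "\n")
})
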