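#' @importFrom utils read.delim write.table packageVersion
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges DataFrameList
#' @importFrom Biostrings DNAStringSet DNAStringSetList
#' @importFrom VariantAnnotation readVcf writeVcf VCF VCFHeader geno ref alt
NULL

# ---- ethnicity parsing -----------------------------------------------------

#' Parse ethnicity annotations into an admixture weight matrix
#'
#' Accepts either plain labels ("European") or semicolon-separated
#' weight pairs ("European:0.6;African:0.4"). Weights must sum to 1 within
#' 1e-9 (plain labels get weight 1). Samples whose maximum weight is below
#' the admixture cutoff are labelled "Admixed"; the full weight vector is
#' retained either way for matched-control mixing.
#'
#' @param ethnicity character vector of labels or weight strings.
#' @param admixtureCutoff minimum probability for a single-population label
#'   (default 0.95).
#' @return list with \code{weights} (samples x ethnicities matrix, rows sum
#'   to 1) and \code{label} (character).
#' @export
parseEthnicity <- function(ethnicity, admixtureCutoff = 0.95) {
    parsed <- lapply(ethnicity, function(s) {
        if (!grepl(":", s)) return(setNames(1, s))
        parts <- strsplit(strsplit(s, ";")[[1]], ":")
        w <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
        names(w) <- vapply(parts, `[`, character(1), 1)
        w
    })
    for (w in parsed)
        if (abs(sum(w) - 1) > 1e-9)
            stop("ethnicity weights must sum to 1: ",
                 paste(names(w), w, sep = ":", collapse = ";"))
    eths <- sort(unique(unlist(lapply(parsed, names))))
    W <- matrix(0, length(parsed), length(eths),
                dimnames = list(NULL, eths))
    for (i in seq_along(parsed)) W[i, names(parsed[[i]])] <- parsed[[i]]
    lab <- apply(W, 1, function(r)
        if (max(r) >= admixtureCutoff) colnames(W)[which.max(r)]
        else "Admixed")
    list(weights = W, label = lab)
}

.formatEthnicity <- function(W) {
    apply(W, 1, function(r) {
        nz <- r[r > 0]
        if (length(nz) == 1 && abs(nz - 1) < 1e-12) return(names(nz))
        paste(names(nz), format(nz, trim = TRUE, digits = 10),
              sep = ":", collapse = ";")
    })
}

# ---- reading ---------------------------------------------------------------

.gtToDosage <- function(gt) {
    gt <- sub("\\|", "/", gt)
    ok <- gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (!all(ok))
        stop("malformed GT value(s): ",
             paste(unique(gt[!ok]), collapse = ", "))
    d <- rep(NA_integer_, length(gt))
    d[gt == "0/0"] <- 0L
    d[gt %in% c("0/1", "1/0")] <- 1L
    d[gt == "1/1"] <- 2L
    d
}

#' Read a genotype cohort from VCF plus annotation and sample sheets
#'
#' The VCF must be sorted and contain biallelic records only (pre-split
#' multiallelics); only the GT field is used. Every record must have a
#' matching annotation row keyed by chrom/pos/ref/alt, otherwise a hard
#' error names the offending site. Missing genotypes (./.) become missing
#' dosages.
#'
#' @param vcfPath path to a VCF v4.2 file.
#' @param annotationPath TSV with header columns
#'   chrom, pos, ref, alt, gene, cadd, global_af and optionally cdna and
#'   af_<ethnicity> columns.
#' @param samplePath optional sample-sheet TSV with columns sample_id, role,
#'   ethnicity, abca4_allele1, abca4_allele2 and optionally ccds_covered;
#'   when absent, all samples are controls.
#' @param coveragePath optional TSV (site key column \code{site} then one
#'   0/1 column per sample) of coverage-QC flags; default all covered.
#' @param admixtureCutoff see [parseEthnicity()].
#' @return A \linkS4class{GenotypeCohort}.
#' @export
readCohort <- function(vcfPath, annotationPath, samplePath = NULL,
                       coveragePath = NULL, admixtureCutoff = 0.95) {
    vcf <- readVcf(vcfPath, genome = "unknown")
    nAlt <- lengths(alt(vcf))
    if (any(nAlt != 1))
        stop("multiallelic records present; pre-split them: ",
             paste(head(rownames(vcf)[nAlt != 1]), collapse = ", "))
    rr <- SummarizedExperiment::rowRanges(vcf)
    vcfKey <- paste0(as.character(GenomicRanges::seqnames(rr)), ":",
                     GenomicRanges::start(rr), "_",
                     as.character(ref(vcf)), "/",
                     as.character(unlist(alt(vcf))))
    ann <- read.delim(annotationPath, stringsAsFactors = FALSE,
                      check.names = FALSE)
    ann$chrom <- as.character(ann$chrom)
    annKey <- siteKey(ann)
    hit <- match(vcfKey, annKey)
    if (anyNA(hit))
        stop("VCF record(s) without annotation: ",
             paste(vcfKey[is.na(hit)], collapse = ", "))
    ann <- ann[hit, , drop = FALSE]
    gt <- geno(vcf)$GT
    dosage <- matrix(.gtToDosage(gt), nrow(gt), ncol(gt),
                     dimnames = list(vcfKey, colnames(gt)))
    samples <- colnames(gt)
    if (!is.null(samplePath)) {
        sh <- read.delim(samplePath, stringsAsFactors = FALSE)
        if (!all(samples %in% sh$sample_id))
            stop("sample sheet lacks sample(s): ",
                 paste(setdiff(samples, sh$sample_id), collapse = ", "))
        sh <- sh[match(samples, sh$sample_id), , drop = FALSE]
        eth <- parseEthnicity(sh$ethnicity, admixtureCutoff)
        si <- DataFrame(role = sh$role, ethnicity = eth$label,
                        row.names = sh$sample_id)
        si$ethWeights <- eth$weights
        si$abca4Allele1 <- if ("abca4_allele1" %in% names(sh))
            sh$abca4_allele1 else NA_character_
        si$abca4Allele2 <- if ("abca4_allele2" %in% names(sh))
            sh$abca4_allele2 else NA_character_
        si$ccdsCovered <- if ("ccds_covered" %in% names(sh))
            sh$ccds_covered else 1
        isCtrl <- si$role == "control"
        if (any(!is.na(si$abca4Allele1[isCtrl]) &
                nzchar(si$abca4Allele1[isCtrl])))
            stop("ABCA4 diplotype annotation present for control sample(s)")
    } else {
        si <- DataFrame(role = rep("control", length(samples)),
                        row.names = samples)
    }
    covOK <- matrix(TRUE, nrow(dosage), ncol(dosage),
                    dimnames = dimnames(dosage))
    if (!is.null(coveragePath)) {
        cv <- read.delim(coveragePath, stringsAsFactors = FALSE,
                         check.names = FALSE)
        rn <- cv$site
        cv <- as.matrix(cv[, samples, drop = FALSE])
        covOK[rn, ] <- cv[, ] == 1
    }
    GenotypeCohort(dosage, ann, si, covOK)
}

# ---- writing ---------------------------------------------------------------

#' Write a cohort to the standard file set
#'
#' Emits \code{cohort.vcf} (GT only), \code{annotations.tsv},
#' \code{samples.tsv} and \code{coverage.tsv} into \code{dir}; these
#' round-trip through [readCohort()].
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rd <- variantInfo(cohort)
    d <- dosages(cohort)
    gtChr <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
    gtChr[!is.na(d) & d == 0L] <- "0/0"
    gtChr[!is.na(d) & d == 1L] <- "0/1"
    gtChr[!is.na(d) & d == 2L] <- "1/1"
    gr <- GRanges(as.character(rd$chrom), IRanges(rd$pos, width = 1))
    hdr <- VCFHeader(
        samples = colnames(d),
        header = DataFrameList(
            fileformat = DataFrame(Value = "VCFv4.2",
                                   row.names = "fileformat"),
            FORMAT = DataFrame(Number = "1", Type = "String",
                               Description = "Genotype",
                               row.names = "GT")))
    vcf <- VCF(rowRanges = gr,
               colData = DataFrame(Samples = seq_len(ncol(d)),
                                   row.names = colnames(d)),
               exptData = list(header = hdr),
               fixed = DataFrame(REF = DNAStringSet(as.character(rd$ref)),
                                 ALT = DNAStringSetList(
                                     as.list(as.character(rd$alt))),
                                 QUAL = rep(NA_real_, nrow(d)),
                                 FILTER = rep(".", nrow(d))),
               geno = SimpleList(GT = gtChr), collapsed = TRUE)
    vcfPath <- file.path(dir, "cohort.vcf")
    writeVcf(vcf, vcfPath)
    annCols <- setdiff(colnames(rd),
                       c("minorIsAlt", "minorAF", "ambiguous"))
    annPath <- file.path(dir, "annotations.tsv")
    write.table(as.data.frame(rd[, annCols, drop = FALSE]), annPath,
                sep = "\t", quote = FALSE, row.names = FALSE)
    si <- sampleInfo(cohort)
    sh <- data.frame(sample_id = rownames(si), role = si$role,
                     stringsAsFactors = FALSE)
    sh$ethnicity <- if (!is.null(si$ethWeights))
        .formatEthnicity(si$ethWeights) else si$ethnicity
    sh$abca4_allele1 <- if (!is.null(si$abca4Allele1))
        si$abca4Allele1 else NA
    sh$abca4_allele2 <- if (!is.null(si$abca4Allele2))
        si$abca4Allele2 else NA
    sh$ccds_covered <- if (!is.null(si$ccdsCovered)) si$ccdsCovered else 1
    smpPath <- file.path(dir, "samples.tsv")
    write.table(sh, smpPath, sep = "\t", quote = FALSE, row.names = FALSE)
    cv <- data.frame(site = rownames(d),
                     ifelse(coverageOK(cohort), 1L, 0L),
                     check.names = FALSE)
    colnames(cv)[-1] <- colnames(d)
    covPath <- file.path(dir, "coverage.tsv")
    write.table(cv, covPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(vcf = vcfPath, annotations = annPath, samples = smpPath,
                coverage = covPath))
}

# ---- minor-allele orientation ----------------------------------------------

#' Orient sites so frequencies refer to the true minor allele
#'
#' Public frequency databases report ALT-allele frequencies relative to the
#' reference genome; at some sites the reference carries the minor allele,
#' so the ALT frequency exceeds 0.5 and the "variant" is in fact the major
#' allele. \code{orientMinor} flags such sites: \code{minorIsAlt} is FALSE
#' when the global ALT frequency exceeds 0.5, \code{minorAF = min(af, 1-af)},
#' and sites with frequency exactly 0.5 or missing are marked ambiguous
#' (kept as ALT-minor, no flip).
#'
#' @param globalAF numeric vector of global ALT-allele frequencies (NA
#'   allowed).
#' @return data.frame with logical \code{minorIsAlt}, numeric \code{minorAF}
#'   and logical \code{ambiguous}, one row per input.
#' @examples
#' orientMinor(c(0.79, 0.10, 0.5, NA))
#' @export
orientMinor <- function(globalAF) {
    ambiguous <- is.na(globalAF) | globalAF == 0.5
    minorIsAlt <- is.na(globalAF) | globalAF <= 0.5
    minorAF <- ifelse(is.na(globalAF), NA_real_,
                      pmin(globalAF, 1 - globalAF))
    data.frame(minorIsAlt = minorIsAlt, minorAF = minorAF,
               ambiguous = ambiguous)
}

#' Attach minor-allele orientation to a cohort
#'
#' Runs [orientMinor()] on the global ALT frequencies and stores the result
#' in \code{rowData}. Idempotent.
#'
#' @param cohort a \linkS4class{GenotypeCohort}.
#' @return the cohort with rowData columns \code{minorIsAlt},
#'   \code{minorAF}, \code{ambiguous}.
#' @export
orientSites <- function(cohort) {
    o <- orientMinor(variantInfo(cohort)$global_af)
    rowData(cohort)$minorIsAlt <- o$minorIsAlt
    rowData(cohort)$minorAF <- o$minorAF
    rowData(cohort)$ambiguous <- o$ambiguous
    cohort
}

#' Minor-allele dosage matrix
#'
#' ALT dosage where the ALT allele is the minor allele, \code{2 - dosage}
#' where the site is flipped; missing propagates. Requires
#' [orientSites()] to have been applied.
#'
#' @param cohort an oriented \linkS4class{GenotypeCohort}.
#' @param sites site keys or indices (default all).
#' @param samples sample names or indices (default all).
#' @return integer matrix (sites x samples) of minor-allele dosages.
#' @export
minorDosage <- function(cohort, sites = NULL, samples = NULL) {
    rd <- variantInfo(cohort)
    if (is.null(rd$minorIsAlt))
        stop("cohort is not oriented; call orientSites() first")
    if (is.null(sites)) sites <- seq_len(nrow(cohort))
    if (is.character(sites)) {
        idx <- match(sites, rownames(cohort))
        if (anyNA(idx)) stop("unknown site(s): ",
                             paste(sites[is.na(idx)], collapse = ", "))
        sites <- idx
    } else if (any(sites < 1 | sites > nrow(cohort))) {
        stop("site index out of range")
    }
    if (is.null(samples)) samples <- seq_len(ncol(cohort))
    if (is.character(samples)) {
        idx <- match(samples, colnames(cohort))
        if (anyNA(idx)) stop("unknown sample(s): ",
                             paste(samples[is.na(idx)], collapse = ", "))
        samples <- idx
    }
    d <- dosages(cohort)[sites, samples, drop = FALSE]
    flip <- !rd$minorIsAlt[sites]
    d[flip, ] <- 2L - d[flip, , drop = FALSE]
    d
}
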