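# Replay mode: recompute study-style statistics from the bundled summary
# tables (the raw cohorts are not public; the printed counts and
# percentages are the verification surface), plus the full-pipeline
# orchestrator. Replay and full mode share the same statistics code path.

.extdata <- function(f) {
    p <- system.file("extdata", f, package = "transmodR")
    if (!nzchar(p)) stop("bundled table not found: ", f)
    p
}

#' Bundled study summary tables
#'
#' Reference contingency inputs distributed with the package: per-gene
#' qualifying-carrier counts (discovery cohort, MAF<0.005 and CADD>25),
#' the gene-set carrier MAF ladder, tag-SNP genotype percentages per
#' cohort/subgroup, and the 3-SNP haplotype allele counts.
#'
#' @return data.frame of the requested table.
#' @name studyTables
NULL

#' @rdname studyTables
#' @export
studyCollapseByGene <- function() {
    read.delim(.extdata("study_collapse_by_gene.tsv"))
}

#' @rdname studyTables
#' @export
studyCollapseLadder <- function() {
    read.delim(.extdata("study_collapse_ladder.tsv"),
               colClasses = c(maf_max = "character"))
}

#' @rdname studyTables
#' @export
studyTagGenotypes <- function() {
    read.delim(.extdata("study_tag_genotypes.tsv"))
}

#' @rdname studyTables
#' @export
studyHaplotypes <- function() {
    read.delim(.extdata("study_haplotypes.tsv"))
}

#' Replay the per-gene collapsing analysis from carrier counts
#'
#' @param counts data.frame shaped like [studyCollapseByGene()] (the
#'   default): gene, case_carriers, case_n, control_carriers, control_n.
#' @param kTests Bonferroni k (default 7, one per gene).
#' @param method association test, see [enrichmentTable()].
#' @return the [enrichmentTable()] data.frame.
#' @export
replayCollapse <- function(counts = studyCollapseByGene(), kTests = 7,
                           method = c("chisq", "fisher")) {
    n1 <- unique(counts$case_n); n2 <- unique(counts$control_n)
    stopifnot(length(n1) == 1, length(n2) == 1)
    enrichmentTable(setNames(counts$case_carriers, counts$gene), n1,
                    setNames(counts$control_carriers, counts$gene), n2,
                    kTests = kTests, method = match.arg(method))
}

#' Replay the gene-set MAF ladder from carrier counts
#'
#' @param counts data.frame shaped like [studyCollapseLadder()].
#' @param kTests Bonferroni k (default 5, one per ladder row).
#' @inheritParams replayCollapse
#' @return data.frame with one enrichment row per threshold.
#' @export
replayLadder <- function(counts = studyCollapseLadder(), kTests = 5,
                         method = c("chisq", "fisher")) {
    out <- replayCollapse(counts = data.frame(
        gene = counts$maf_max, case_carriers = counts$case_carriers,
        case_n = counts$case_n, control_carriers = counts$control_carriers,
        control_n = counts$control_n), kTests = kTests,
        method = match.arg(method))
    names(out)[names(out) == "gene"] <- "mafMax"
    out
}

.tagGroup <- function(tg, cohortName, groupName) {
    row <- tg[tg$cohort == cohortName & tg$group == groupName, ]
    if (nrow(row) != 1)
        stop("no tag-genotype row for ", cohortName, "/", groupName)
    rec <- reconstructGenotypeCounts(
        row$n, c(row$pct_minor_hom, row$pct_het, row$pct_major_hom),
        nearest = TRUE)
    s <- tagSnpSummary(rec$counts, group = paste(cohortName, groupName))
    s$reconstructionExact <- rec$exact
    s
}

#' Replay the tag-SNP association contrasts from genotype percentages
#'
#' Reconstructs integer genotype counts from the printed 1-dp percentages
#' for every group in the tag-genotype table, then runs the allele
#' contrast of each cohort's patient groups against their comparator
#' (matched external controls for all-patients rows, the complement
#' patient group for subgroup rows).
#'
#' @param tg data.frame shaped like [studyTagGenotypes()].
#' @param method association test, see [alleleContrast()].
#' @return data.frame with one row per contrast: reconstructed counts,
#'   allele frequencies, p, OR, CI.
#' @export
replayTagContrasts <- function(tg = studyTagGenotypes(),
                               method = c("chisq", "fisher")) {
    method <- match.arg(method)
    contrasts <- list(
        c("discovery", "all_patients", "gnomad_matched_controls"),
        c("discovery", "hypomorph", "minus_hypomorph"),
        c("discovery", "g1961e", "minus_g1961e"),
        c("discovery", "hypomorph_ext", "minus_hypomorph_ext"),
        c("replication", "all_patients", "gnomad_matched_controls"),
        c("replication", "hypomorph", "minus_hypomorph"),
        c("replication", "g1961e", "minus_g1961e"),
        c("combined", "all_patients", "gnomad_matched_controls"),
        c("combined", "hypomorph", "minus_hypomorph"),
        c("combined", "g1961e", "minus_g1961e"))
    avail <- paste(tg$cohort, tg$group)
    out <- NULL
    for (ct in contrasts) {
        if (!paste(ct[1], ct[2]) %in% avail ||
            !paste(ct[1], ct[3]) %in% avail) next
        s1 <- .tagGroup(tg, ct[1], ct[2])
        s2 <- .tagGroup(tg, ct[1], ct[3])
        row <- alleleContrast(s1, s2, method = method)
        row <- cbind(cohort = ct[1], contrast = ct[2], row)
        out <- rbind(out, row)
    }
    rownames(out) <- NULL
    out
}

#' Run the full pipeline on a genotype cohort
#'
#' Stage order: sample QC, site QC, qualifying filter, per-gene collapsing
#' and MAF ladder, matched external controls, subgroup stratification,
#' haplotype spectra, tag-SNP contrasts. Every reported p-value row
#' carries its Bonferroni threshold and k. Results are returned as a list
#' of data.frames and optionally written as TSVs with a run manifest.
#'
#' @param cohort a \linkS4class{GenotypeCohort} (e.g. from
#'   [generateCohort()] or [readCohort()]).
#' @param popAF population AF table for the haplotype-region sites (see
#'   [readPopulationAF()]); NULL skips matched-control synthesis.
#' @param hapSiteKeys site keys of the 3 linked haplotype sites (in cDNA
#'   order); NULL skips the haplotype stage.
#' @param tagSiteKey site key of the haplotype-tagging SNP.
#' @param matchedControlN size of the synthesised matched control cohort.
#' @param mafMax,caddMin qualifying filter, see [qualifyingSites()].
#' @param ladder MAF ladder thresholds, see [mafLadder()].
#' @param kGenes,kLadder,kContrasts Bonferroni k for the per-gene
#'   collapsing, ladder and tag contrasts.
#' @param method association test for reported tables.
#' @param outDir when non-NULL, TSV outputs plus \code{manifest.tsv} are
#'   written here.
#' @return list with \code{collapse}, \code{ladder}, \code{matched},
#'   \code{subgroups}, \code{spectra}, \code{haplotypeTable},
#'   \code{contrasts}, \code{manifest}.
#' @export
runAll <- function(cohort, popAF = NULL, hapSiteKeys = NULL,
                   tagSiteKey = NULL, matchedControlN = 43029,
                   mafMax = 0.005, caddMin = 25,
                   ladder = list(0.005, 0.001, 1e-4, 1e-5, "nd"),
                   kGenes = 7, kLadder = 5, kContrasts = 4,
                   method = c("chisq", "fisher"), outDir = NULL) {
    method <- match.arg(method)
    stage <- "sample QC"
    res <- tryCatch({
        cohort <- applySampleQC(cohort)
        stage <- "site QC"
        cohort <- applySiteQC(cohort)
        stage <- "qualifying filter"
        cohort <- orientSites(cohort)
        q <- qualifyingSites(cohort, mafMax = mafMax, caddMin = caddMin)
        stage <- "collapsing"
        cs <- isCase(cohort)
        carrier <- collapseCarriers(cohort, q)
        genes <- setdiff(colnames(carrier), "geneSet")
        collapse <- enrichmentTable(
            colSums(carrier[cs, genes, drop = FALSE]), sum(cs),
            colSums(carrier[!cs, genes, drop = FALSE]), sum(!cs),
            kTests = kGenes, method = method)
        ladderTab <- mafLadder(cohort, thresholds = ladder,
                               caddMin = caddMin, kTests = kLadder,
                               method = method)
        stage <- "matched controls"
        matched <- NULL
        if (!is.null(popAF) && !is.null(tagSiteKey)) {
            w <- caseEthnicityWeights(cohort)
            altAF <- matchedAF(popAF, w, tagSiteKey)
            o <- orientMinor(variantInfo(cohort)[tagSiteKey, "global_af"])
            minorAF <- if (o$minorIsAlt) altAF else 1 - altAF
            matched <- materializeControls(minorAF, matchedControlN)
        }
        stage <- "stratification"
        part <- subgroupPartition(cohort)
        stage <- "haplotypes"
        spectra <- NULL; hapTab <- NULL; contrasts <- NULL
        if (!is.null(hapSiteKeys)) {
            alleleLabels <- .hapAlleleLabels(cohort, hapSiteKeys)
            caseIds <- colnames(cohort)[cs]
            mkSpec <- function(idSet, lab) {
                G <- t(minorDosage(cohort, sites = hapSiteKeys,
                                   samples = idSet))
                emHaplotypes(G, siteLabels = hapSiteKeys,
                             alleleLabels = alleleLabels, group = lab)
            }
            spectra <- list(
                all = mkSpec(caseIds, "all_patients"),
                hypomorph = mkSpec(part$groups$HYPOMORPH_CAUSAL,
                                   "hypomorph"),
                g1961e = mkSpec(part$groups$G1961E, "g1961e"))
            hapTab <- haplotypeTable(spectra)
            stage <- "contrasts"
            if (!is.null(tagSiteKey)) {
                thr <- bonferroniThreshold(0.05, kContrasts)
                mkTag <- function(idSet, lab)
                    cohortTagSnp(cohort, tagSiteKey, idSet, group = lab)
                pairs <- list(
                    list(mkTag(part$groups$HYPOMORPH_CAUSAL, "hypomorph"),
                         mkTag(part$complements$HYPOMORPH_CAUSAL,
                               "minus_hypomorph")),
                    list(mkTag(part$groups$G1961E, "g1961e"),
                         mkTag(part$complements$G1961E, "minus_g1961e")))
                contrasts <- do.call(rbind, lapply(pairs, function(p)
                    alleleContrast(p[[1]], p[[2]], method = method)))
                if (!is.null(matched)) {
                    mt <- tagSnpSummary(matched$genotypes,
                                        group = "matched_controls")
                    contrasts <- rbind(
                        alleleContrast(mkTag(caseIds, "all_patients"), mt,
                                       method = method),
                        contrasts)
                }
                contrasts$bonferroniThreshold <- thr
                contrasts$k <- kContrasts
                contrasts$significant <- contrasts$p < thr
            }
        }
        list(collapse = collapse, ladder = ladderTab, matched = matched,
             subgroups = part, spectra = spectra,
             haplotypeTable = hapTab, contrasts = contrasts)
    }, error = function(e)
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE))
    res$manifest <- data.frame(
        key = c("package_version", "n_samples_post_qc", "n_sites_post_qc",
                "maf_max", "cadd_min", "method", "k_genes", "k_ladder",
                "k_contrasts"),
        value = c(as.character(packageVersion("transmodR")),
                  ncol(cohort), nrow(cohort), as.character(mafMax),
                  caddMin, method, kGenes, kLadder, kContrasts),
        stringsAsFactors = FALSE)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        wr <- function(df, f) if (!is.null(df))
            write.table(df, file.path(outDir, f), sep = "\t",
                        quote = FALSE, row.names = FALSE)
        wr(res$collapse, "collapse_by_gene.tsv")
        wr(res$ladder, "collapse_ladder.tsv")
        wr(res$haplotypeTable, "haplotype_table.tsv")
        wr(res$contrasts, "tag_contrasts.tsv")
        wr(res$manifest, "manifest.tsv")
    }
    res
}

.hapAlleleLabels <- function(cohort, hapSiteKeys) {
    rd <- variantInfo(cohort)[hapSiteKeys, , drop = FALSE]
    o <- orientMinor(rd$global_af)
    minor <- ifelse(o$minorIsAlt, rd$alt, rd$ref)
    major <- ifelse(o$minorIsAlt, rd$ref, rd$alt)
    rbind(major = as.character(major), minor = as.character(minor))
}
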