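#' @rdname GenotypeCohort-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeCohort-accessors
#' @export
setGeneric("coverageOK", function(x) standardGeneric("coverageOK"))

#' @rdname GenotypeCohort-accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname GenotypeCohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeCohort-accessors
#' @export
setGeneric("isCase", function(x) standardGeneric("isCase"))

#' @rdname hapAccessors
#' @export
setGeneric("hapFreq", function(x) standardGeneric("hapFreq"))

#' @rdname hapAccessors
#' @export
setGeneric("hapLabels", function(x) standardGeneric("hapLabels"))

#' Accessors for GenotypeCohort
#'
#' \code{dosages} returns the sites x samples integer ALT-dosage matrix;
#' \code{coverageOK} the logical coverage-QC matrix; \code{variantInfo} the
#' per-site annotation \code{DataFrame}; \code{sampleInfo} the sample
#' metadata; \code{isCase} a logical vector over samples.
#'
#' @param x a \linkS4class{GenotypeCohort}.
#' @return see description.
#' @name GenotypeCohort-accessors
NULL

#' @rdname GenotypeCohort-accessors
#' @export
setMethod("dosages", "GenotypeCohort", function(x) assay(x, "dosage"))

#' @rdname GenotypeCohort-accessors
#' @export
setMethod("coverageOK", "GenotypeCohort", function(x) assay(x, "coverageOK"))

#' @rdname GenotypeCohort-accessors
#' @export
setMethod("variantInfo", "GenotypeCohort", function(x) rowData(x))

#' @rdname GenotypeCohort-accessors
#' @export
setMethod("sampleInfo", "GenotypeCohort", function(x) colData(x))

#' @rdname GenotypeCohort-accessors
#' @export
setMethod("isCase", "GenotypeCohort",
          function(x) colData(x)$role == "case")

#' Accessors for HaplotypeSpectrum
#'
#' \code{hapFreq} returns the named frequency vector; \code{hapLabels} the
#' haplotype display labels.
#' @param x a \linkS4class{HaplotypeSpectrum}.
#' @return see description.
#' @name hapAccessors
NULL

#' @rdname hapAccessors
#' @export
setMethod("hapFreq", "HaplotypeSpectrum", function(x) {
    stats::setNames(x@freq, x@hapLabels)
})

#' @rdname hapAccessors
#' @export
setMethod("hapLabels", "HaplotypeSpectrum", function(x) x@hapLabels)
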