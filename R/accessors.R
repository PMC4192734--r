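#' @include AllClasses.R
NULL

#' Accessors for simulation and call objects
#'
#' `chromLengths()`, `genes()`, `rateProfiles()`, `maskedRegions()` access a
#' [GenomeModel-class]; `panelSamples()` the sample sheet of a
#' [PanelConfig-class] or [SimulatedTruth-class]; `trueGenotypes()`,
#' `variantInfo()`, `poolFreqs()`, `flankingGenotypes()`, `otvCarriers()` a
#' [SimulatedTruth-class]; `genoCalls()` and `callConfidence()` a
#' [GenotypeCallSet-class].
#'
#' @param x The object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GenomeModel", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("rateProfiles", function(x) standardGeneric("rateProfiles"))
#' @rdname accessors
#' @export
setMethod("rateProfiles", "GenomeModel", function(x) x@rateProfiles)

#' @rdname accessors
#' @export
setGeneric("maskedRegions", function(x) standardGeneric("maskedRegions"))
#' @rdname accessors
#' @export
setMethod("maskedRegions", "GenomeModel", function(x) x@masked)

#' @rdname accessors
#' @export
setGeneric("panelSamples", function(x) standardGeneric("panelSamples"))
#' @rdname accessors
#' @export
setMethod("panelSamples", "PanelConfig", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("panelSamples", "SimulatedTruth", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("trueGenotypes", function(x) standardGeneric("trueGenotypes"))
#' @rdname accessors
#' @export
setMethod("trueGenotypes", "SimulatedTruth", function(x) x@genotypes)

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setMethod("variantInfo", "SimulatedTruth", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("variantInfo", "SeqVariantSet",
          function(x) SummarizedExperiment::rowRanges(x))

#' @rdname accessors
#' @export
setGeneric("poolFreqs", function(x) standardGeneric("poolFreqs"))
#' @rdname accessors
#' @export
setMethod("poolFreqs", "SimulatedTruth", function(x) x@poolFreqs)

#' @rdname accessors
#' @export
setGeneric("flankingGenotypes", function(x) standardGeneric("flankingGenotypes"))
#' @rdname accessors
#' @export
setMethod("flankingGenotypes", "SimulatedTruth", function(x) x@flankingGenotypes)

#' @rdname accessors
#' @export
setGeneric("otvCarriers", function(x) standardGeneric("otvCarriers"))
#' @rdname accessors
#' @export
setMethod("otvCarriers", "SimulatedTruth", function(x) {
  fg <- x@flankingGenotypes
  lapply(seq_len(nrow(fg)), function(i) {
    colnames(fg)[which(fg[i, ] >= 1L)]
  }) |> stats::setNames(rownames(fg))
})

#' @rdname accessors
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))
#' @rdname accessors
#' @export
setMethod("genoCalls", "GenotypeCallSet",
          function(x) SummarizedExperiment::assay(x, "call"))

#' @rdname accessors
#' @export
setGeneric("callConfidence", function(x) standardGeneric("callConfidence"))
#' @rdname accessors
#' @export
setMethod("callConfidence", "GenotypeCallSet",
          function(x) SummarizedExperiment::assay(x, "confidence"))

#' Sequencing genotype and depth matrices
#'
#' @param x A [SeqVariantSet-class].
#' @return Integer/numeric matrix (variants x samples).
#' @export
seqGenotypes <- function(x) SummarizedExperiment::assay(x, "geno")

#' @rdname seqGenotypes
#' @export
seqDepths <- function(x) SummarizedExperiment::assay(x, "depth")

#' Convert AA/AB/BB/OO calls to alt-allele dosage
#'
#' `AA` is the homozygous alternative (allele A) genotype, `BB` the
#' homozygous reference one; `OO` and no-calls become NA.
#'
#' @param calls Character matrix of calls.
#' @return Integer matrix of dosages (0/1/2/NA).
#' @export
callsToDosage <- function(calls) {
  d <- matrix(NA_integer_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  d[calls == "BB"] <- 0L
  d[calls == "AB"] <- 1L
  d[calls == "AA"] <- 2L
  d
}

#' Convert alt-allele dosage to AA/AB/BB calls
#'
#' @param dosage Integer matrix (0/1/2/NA).
#' @return Character matrix of calls.
#' @export
dosageToCalls <- function(dosage) {
  cl <- matrix(NA_character_, nrow(dosage), ncol(dosage),
               dimnames = dimnames(dosage))
  cl[dosage == 0L] <- "BB"
  cl[dosage == 1L] <- "AB"
  cl[dosage == 2L] <- "AA"
  cl
}
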