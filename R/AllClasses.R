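#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom stats setNames
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importClassesFrom vcfR vcfR
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' GenomeModel: a toy genome for simulation
#'
#' Holds chromosome lengths, gene intervals, a relative polymorphism-rate
#' profile along each chromosome (piecewise constant at `rateResolution` bp)
#' and optional masked intervals in which no variants are emitted (emulating
#' variant deserts such as the nucleolus organizer region on maize 6S).
#'
#' @slot chromLengths Named integer vector of chromosome lengths (bp).
#' @slot genes `GRanges` of gene intervals (1-based, inclusive) with strand.
#' @slot rateProfiles List (one numeric vector per chromosome) of relative
#'   polymorphism rates per `rateResolution` window; all values >= 0.
#' @slot rateResolution Width in bp of one rate window.
#' @slot masked `GRanges` of masked intervals (zero variant rate) or NULL.
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(
    chromLengths = "integer",
    genes = "GRanges",
    rateProfiles = "list",
    rateResolution = "integer",
    masked = "GRangesOrNULL"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  if (length(object@chromLengths) < 1L || is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be a named vector of length >= 1")
  if (any(object@chromLengths <= 0L))
    msg <- c(msg, "chromosome lengths must be > 0")
  if (!all(names(object@rateProfiles) == names(object@chromLengths)))
    msg <- c(msg, "rateProfiles must be named like chromLengths")
  if (any(vapply(object@rateProfiles, function(r) any(r < 0), logical(1))))
    msg <- c(msg, "polymorphism rates must be >= 0")
  if (length(object@genes) > 0) {
    chr <- as.character(seqnames(object@genes))
    if (!all(chr %in% names(object@chromLengths)))
      msg <- c(msg, "gene chromosomes not in chromLengths")
    else if (any(start(object@genes) < 1L) ||
             any(end(object@genes) > object@chromLengths[chr]))
      msg <- c(msg, "gene intervals must lie within chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(object@chromLengths), "chromosome(s),",
      sum(as.double(object@chromLengths)), "bp total\n")
  cat("  genes:", length(object@genes),
      " masked intervals:", length(object@masked %||% GRanges()), "\n")
  cat("  rate resolution:", object@rateResolution, "bp\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PanelConfig: composition of a simulated maize panel
#'
#' Describes the samples of a simulated panel (germplasm pool, inbreeding
#' coefficient, inbred penalty for genotype calling, replicate and trio
#' structure) together with the per-pool Beta parameters for non-reference
#' allele frequencies and the divergence between the Dent and Flint pools.
#'
#' @slot samples data.frame with columns id, pool (Dent/Flint/admixed/
#'   hybrid/outgroup), subgroup, f (inbreeding coefficient in [0,1]),
#'   penalty (inbred penalty in [0,16]), replicate_of, parent1, parent2,
#'   admix_w (Dent weight for admixed samples).
#' @slot poolBeta Named list of c(shape1, shape2) Beta parameters per pool.
#' @slot divergence Logit-scale shift between Dent and Flint pool
#'   allele-frequency means.
#' @exportClass PanelConfig
setClass("PanelConfig",
  representation(
    samples = "data.frame",
    poolBeta = "list",
    divergence = "numeric"
  )
)

setValidity("PanelConfig", function(object) {
  s <- object@samples
  msg <- character()
  need <- c("id", "pool", "subgroup", "f", "penalty",
            "replicate_of", "parent1", "parent2")
  if (!all(need %in% names(s)))
    return(paste("samples must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(s$id)) msg <- c(msg, "sample ids must be unique")
  if (!all(s$pool %in% c("Dent", "Flint", "admixed", "hybrid", "outgroup")))
    msg <- c(msg, "unknown pool label")
  if (any(s$f < 0 | s$f > 1)) msg <- c(msg, "f must be in [0,1]")
  if (any(s$penalty < 0 | s$penalty > 16))
    msg <- c(msg, "inbred penalty must be in [0,16]")
  hyb <- s$pool == "hybrid"
  if (any(hyb)) {
    if (!all(s$parent1[hyb] %in% s$id) || !all(s$parent2[hyb] %in% s$id))
      msg <- c(msg, "hybrid parents must reference existing sample ids")
    if (any(s$f[hyb] != 0))
      msg <- c(msg, "inbreeding coefficient of hybrids must be 0")
  }
  rep_of <- s$replicate_of[!is.na(s$replicate_of)]
  if (!all(rep_of %in% s$id))
    msg <- c(msg, "replicate_of must reference an existing sample")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PanelConfig", function(object) {
  cat("PanelConfig with", nrow(object@samples), "samples\n")
  print(table(object@samples$pool))
  cat("  divergence:", object@divergence, "\n")
})

#' SimulatedTruth: planted ground truth for a simulated panel
#'
#' @slot genotypes Integer matrix (variants x samples), coded 0 = hom-ref,
#'   1 = het, 2 = hom-alt, NA = missing.
#' @slot variants `GRanges` of variant positions with metadata columns
#'   id, ref, alt, type, coding, monomorphic, paralog, otv, flankingFreq.
#' @slot flankingGenotypes Integer matrix (OTV variants x samples) of
#'   flanking-variant dosages (0/1/2); carriers are samples with dosage >= 1.
#' @slot poolFreqs Matrix (variants x pools) of true non-reference allele
#'   frequencies per pool.
#' @slot samples data.frame copied from the `PanelConfig`.
#' @exportClass SimulatedTruth
setClass("SimulatedTruth",
  representation(
    genotypes = "matrix",
    variants = "GRanges",
    flankingGenotypes = "matrix",
    poolFreqs = "matrix",
    samples = "data.frame"
  )
)

setValidity("SimulatedTruth", function(object) {
  msg <- character()
  if (nrow(object@genotypes) != length(object@variants))
    msg <- c(msg, "genotype rows must match variants")
  if (ncol(object@genotypes) != nrow(object@samples))
    msg <- c(msg, "genotype columns must match samples")
  g <- object@genotypes
  if (!all(g[!is.na(g)] %in% 0:2))
    msg <- c(msg, "genotypes must be 0/1/2/NA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulatedTruth", function(object) {
  cat("SimulatedTruth:", length(object@variants), "variants x",
      nrow(object@samples), "samples\n")
  cat("  paralog-confounded:", sum(mcols(object@variants)$paralog),
      " OTV:", sum(mcols(object@variants)$otv),
      " monomorphic:", sum(mcols(object@variants)$monomorphic), "\n")
})

#' SeqVariantSet: caller-style sequencing variant records
#'
#' A `RangedSummarizedExperiment` with assays `geno` (0/1/2/NA) and `depth`,
#' and row metadata id, ref, alt, type (SNP/indel), qual (site quality),
#' DP (total depth), CN (genomic copy number from k-mer counts), MQ0F
#' (fraction of mapping-quality-zero reads), samCall and gatkCall
#' (caller-support flags).
#'
#' @exportClass SeqVariantSet
setClass("SeqVariantSet",
  contains = "RangedSummarizedExperiment")

setValidity("SeqVariantSet", function(object) {
  rd <- mcols(SummarizedExperiment::rowRanges(object))
  need <- c("id", "ref", "alt", "type", "qual", "DP", "CN", "MQ0F",
            "samCall", "gatkCall")
  if (!all(need %in% names(rd)))
    return(paste("rowData must have columns:", paste(need, collapse = ", ")))
  if (any(rd$MQ0F < 0 | rd$MQ0F > 1, na.rm = TRUE))
    return("MQ0F must be in [0,1]")
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("assay 'geno' is required")
  TRUE
})

#' IntensitySet: two-channel probe intensities
#'
#' A `SummarizedExperiment` with assays `signalA` and `signalB`
#' (variants x samples, raw scale) and row metadata including the planted
#' cluster category when simulated.
#'
#' @exportClass IntensitySet
setClass("IntensitySet", contains = "SummarizedExperiment")

setValidity("IntensitySet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("signalA", "signalB") %in% an))
    return("assays 'signalA' and 'signalB' are required")
  TRUE
})

#' GenotypeCallSet: called genotypes with confidences
#'
#' A `SummarizedExperiment` with assays `call` (character, one of AA/AB/BB/OO
#' or NA for no-call) and `confidence` (posterior of the emitted call).
#'
#' @exportClass GenotypeCallSet
setClass("GenotypeCallSet", contains = "SummarizedExperiment")

setValidity("GenotypeCallSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("call", "confidence") %in% an))
    return("assays 'call' and 'confidence' are required")
  cl <- SummarizedExperiment::assay(object, "call")
  if (!all(cl[!is.na(cl)] %in% c("AA", "AB", "BB", "OO")))
    return("calls must be AA/AB/BB/OO or NA")
  cf <- SummarizedExperiment::assay(object, "confidence")
  if (any(cf[!is.na(cf)] < 0 | cf[!is.na(cf)] > 1))
    return("confidences must be in [0,1]")
  TRUE
})

#' ClusterModel: fitted genotype-cluster mixture for one variant
#'
#' @slot centers 4 x 2 matrix of cluster centers (contrast x, size y) with
#'   rows AA, AB, BB, OO.
#' @slot sds 4 x 2 matrix of cluster standard deviations.
#' @slot weights Mixing weights of the four components (present ones sum
#'   to 1).
#' @slot present Logical flags for cluster presence.
#' @slot n Effective number of samples per cluster.
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(
    centers = "matrix",
    sds = "matrix",
    weights = "numeric",
    present = "logical",
    n = "numeric"
  )
)

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (!identical(rownames(object@centers), c("AA", "AB", "BB", "OO")))
    msg <- c(msg, "centers must have rows AA, AB, BB, OO")
  w <- object@weights[object@present]
  if (length(w) && abs(sum(w) - 1) > 1e-6)
    msg <- c(msg, "weights of present clusters must sum to 1")
  if (object@present["AA"] && object@present["BB"] &&
      object@centers["AA", 1] <= object@centers["BB", 1])
    msg <- c(msg, "AA center contrast must exceed BB center contrast")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: clusters",
      paste(rownames(object@centers)[object@present], collapse = "/"), "\n")
  print(round(object@centers[object@present, , drop = FALSE], 3))
})
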