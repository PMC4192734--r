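#' Simulate a complete array-design study
#'
#' Convenience orchestrator: builds a toy genome (telomere-enriched
#' polymorphism, optional NOR-like masked gap), simulates a structured
#' panel with planted truth, emits caller-style sequencing records for
#' the discovery subset and two-channel intensities for the whole panel.
#' All stages draw from named substreams of the single seed.
#'
#' @param seed Top-level integer seed.
#' @param nVariants Number of simulated variants.
#' @param chromLengths Named chromosome lengths (bp).
#' @param panel A [PanelConfig-class] (default [validationPanelConfig()]).
#' @param maskNOR Logical; mask a NOR-like interval on the last
#'   chromosome (7 to 28 percent of its length).
#' @param paralogFraction,otvFraction,monoFraction Planted-flag
#'   fractions, passed to [simulatePanel()].
#' @param geometry Intensity cluster geometry ([clusterGeometry()]).
#' @param nGenes Number of gene intervals on the toy genome.
#' @return A list with `genome`, `panel`, `truth`, `seqCalls`,
#'   `intensities`, `seed` and `settings`.
#' @export
simulateStudy <- function(seed = 1L, nVariants = 1000,
                          chromLengths = c(chr1 = 1e7, chr2 = 1e7),
                          panel = validationPanelConfig(),
                          maskNOR = TRUE,
                          paralogFraction = 0.1,
                          otvFraction = 0.075,
                          monoFraction = 0.02,
                          geometry = clusterGeometry(),
                          nGenes = 200L) {
  lastChr <- names(chromLengths)[length(chromLengths)]
  masked <- if (maskNOR) {
    L <- chromLengths[[lastChr]]
    GRanges(lastChr, IRanges(round(0.07 * L), round(0.28 * L)))
  } else NULL
  genome <- simulateGenome(chromLengths, nGenes = nGenes,
                           masked = masked, seed = seed)
  truth <- simulatePanel(genome, panel, nVariants,
                         paralogFraction = paralogFraction,
                         otvFraction = otvFraction,
                         monoFraction = monoFraction, seed = seed)
  seqCalls <- simulateSequencingCalls(truth, seed = seed)
  intensities <- simulateIntensities(truth, geometry, seed = seed)
  list(genome = genome, panel = panel, truth = truth,
       seqCalls = seqCalls, intensities = intensities, seed = seed,
       settings = list(nVariants = nVariants,
                       chromLengths = as.list(chromLengths),
                       paralogFraction = paralogFraction,
                       otvFraction = otvFraction,
                       monoFraction = monoFraction))
}

#' Run the dual (with / without inbred correction) clustering analyses
#'
#' Calls the intensity set twice — once with all penalties zero and once
#' with the sample-sheet penalties — classifies both analyses, and
#' returns the category comparison that feeds the voting system.
#'
#' @param intensities An [IntensitySet-class].
#' @param panel A [PanelConfig-class] supplying the inbred penalties.
#' @param ... Passed to [callIntensitySet()].
#' @return A list with `without`, `with` (results of
#'   [callIntensitySet()]) and `comparison` (data.frame from
#'   [compareCorrection()] with an `id` column).
#' @export
runDualClustering <- function(intensities, panel, ...) {
  pen <- stats::setNames(panelSamples(panel)$penalty,
                         panelSamples(panel)$id)
  without <- callIntensitySet(intensities, penalties = pen,
                              inbredCorrection = FALSE, ...)
  with_ <- callIntensitySet(intensities, penalties = pen,
                            inbredCorrection = TRUE, ...)
  comp <- compareCorrection(without$metrics$category,
                            with_$metrics$category)
  comp$id <- rownames(without$metrics)
  list(without = without, with = with_, comparison = comp)
}
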