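#' Construct a SeqVariantSet
#'
#' @param ranges `GRanges` of variant positions with metadata columns id,
#'   ref, alt, type, qual, DP, CN, MQ0F, samCall, gatkCall.
#' @param geno Integer matrix (variants x samples) of genotypes 0/1/2/NA.
#' @param depth Numeric matrix of per-sample depths (optional).
#' @return A [SeqVariantSet-class].
#' @export
SeqVariantSet <- function(ranges, geno, depth = NULL) {
  if (is.null(depth))
    depth <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno, depth = depth),
    rowRanges = ranges)
  new("SeqVariantSet", se)
}

#' Simulate caller-style sequencing records from planted truth
#'
#' Emits per-line depths around each sample's mean coverage (deep vs
#' shallow lines), genotype calls equal to truth apart from a configurable
#' error rate, and site-level annotations. Paralog-confounded variants —
#' collapsed repeats and homeologous regions typical of the ancient
#' polyploid maize genome — emit spuriously heterozygous calls at rate
#' `hetInflation`, carry genomic copy number >= 50 and an elevated MQ0
#' fraction. Caller-support flags for the two callers are set jointly with
#' a configurable disagreement rate.
#'
#' @param truth A [SimulatedTruth-class].
#' @param meanDepths Per-sample mean coverage; a single value is recycled.
#'   Defaults to 50x for the first two samples of each pool and 12x
#'   otherwise when NULL (deep vs shallow discovery lines).
#' @param paralogFraction If not NULL, redraw the paralog flags with this
#'   fraction instead of using the flags planted in `truth`.
#' @param errorRate Per-call genotype error rate on clean variants.
#' @param hetInflation Probability that a call on a paralog-confounded
#'   variant is rendered heterozygous.
#' @param disagreeRate Probability that only one caller supports a record.
#' @param seed Integer seed.
#' @return A [SeqVariantSet-class]; metadata column `paralogTruth` on the
#'   row ranges records the flags actually used.
#' @export
simulateSequencingCalls <- function(truth,
                                    meanDepths = NULL,
                                    paralogFraction = NULL,
                                    errorRate = 0.002,
                                    hetInflation = 0.8,
                                    disagreeRate = 0.05,
                                    seed = 1L) {
  stopifnot(is(truth, "SimulatedTruth"))
  .assertScalarNumber(errorRate, "errorRate", 0, 1)
  if (!is.null(paralogFraction))
    .assertScalarNumber(paralogFraction, "paralogFraction", 0, 1)

  G <- trueGenotypes(truth)
  nv <- nrow(G); ns <- ncol(G)
  samples <- panelSamples(truth)

  if (is.null(meanDepths)) {
    deep <- unlist(lapply(unique(samples$pool), function(p) {
      idx <- which(samples$pool == p)
      idx[seq_len(min(2L, length(idx)))]
    }))
    meanDepths <- rep(12, ns)
    meanDepths[deep] <- 50
  }
  if (length(meanDepths) == 1L) meanDepths <- rep(meanDepths, ns)
  stopifnot(length(meanDepths) == ns)

  withSeed(substreamSeed(seed, "sequencing"), {
    paralog <- if (is.null(paralogFraction)) {
      mcols(variantInfo(truth))$paralog
    } else {
      stats::runif(nv) < paralogFraction
    }

    depth <- matrix(stats::rpois(nv * ns, rep(meanDepths, each = nv)),
                    nv, ns, dimnames = dimnames(G))
    geno <- G
    geno[depth == 0L] <- NA_integer_

    if (errorRate > 0) {
      flip <- which(stats::runif(nv * ns) < errorRate & !is.na(geno))
      if (length(flip))
        geno[flip] <- (geno[flip] + sample(1:2, length(flip),
                                           replace = TRUE)) %% 3L
    }
    if (hetInflation > 0 && any(paralog)) {
      pm <- matrix(stats::runif(nv * ns) < hetInflation, nv, ns) &
        paralog & !is.na(geno)
      geno[pm] <- 1L
    }

    info <- variantInfo(truth)
    vmc <- mcols(info)
    DP <- as.integer(round(rowSums(depth)))
    qual <- pmax(1, round(stats::rnorm(nv, mean = pmin(3 * DP, 900),
                                       sd = 40)))
    CN <- ifelse(paralog,
                 50L + stats::rpois(nv, 30),
                 1L + stats::rpois(nv, 1))
    MQ0F <- ifelse(paralog,
                   stats::runif(nv, 0.06, 0.5),
                   stats::rbeta(nv, 0.5, 30))
    MQ0F <- pmin(pmax(MQ0F, 0), 1)
    oneOnly <- stats::runif(nv) < disagreeRate
    whichOne <- stats::runif(nv) < 0.5
    samCall <- !(oneOnly & whichOne)
    gatkCall <- !(oneOnly & !whichOne)

    gr <- GRanges(seqnames(info), IRanges(start(info), width = 1))
    mcols(gr) <- DataFrame(
      id = vmc$id, ref = vmc$ref, alt = vmc$alt, type = vmc$type,
      qual = as.numeric(qual), DP = DP, CN = as.integer(CN),
      MQ0F = as.numeric(MQ0F), samCall = samCall, gatkCall = gatkCall,
      paralogTruth = paralog)
    names(gr) <- vmc$id
    SeqVariantSet(gr, geno, depth)
  })
}
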