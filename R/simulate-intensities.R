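#' Default cluster-geometry settings for intensity simulation
#'
#' Geometry is specified in transformed coordinates (contrast
#' `x = log2(A/B)`, size `y = (log2 A + log2 B)/2`); signals are emitted on
#' the raw two-channel scale, so the log-transform happens downstream in
#' the caller, as with real array data. The defaults produce well-separated
#' clusters (center separation more than 10 within-cluster SDs).
#'
#' @param delta Contrast of the homozygous clusters (+delta for AA,
#'   -delta for BB).
#' @param hetLift Size lift of the heterozygous cluster above the
#'   homozygous ones.
#' @param y0 Baseline size (log2 scale).
#' @param sdX,sdY Within-cluster standard deviations.
#' @param otvShift Downward size shift of the off-target (OO) cluster.
#' @param centerJitter Per-variant SD of random cluster-center displacement.
#' @param lowCallFraction Fraction of eligible variants planted as
#'   CallRateBelowThreshold.
#' @param otherFraction Fraction of eligible variants planted as failed
#'   ("Other": widened heterozygous cluster sitting slightly below the
#'   homozygote line, so FLD and HetSO fail while calls remain confident).
#' @param lowCallScatter Fraction of samples of a planted low-call-rate
#'   variant whose hybridization fails: their signals scatter broadly
#'   around the cluster region instead of concentrating in a genotype
#'   cluster, so the caller's outlier rule renders them no-calls.
#' @param otherAbSdFactor Contrast-SD inflation of the AB cluster for
#'   planted "Other" variants.
#' @param otherHetDrop Downward size shift of the AB cluster for planted
#'   "Other" variants (within the HetSO band between the plain cut and the
#'   OTV cut).
#' @return A named list of settings.
#' @export
clusterGeometry <- function(delta = 1.5, hetLift = 0.3, y0 = 10,
                            sdX = 0.12, sdY = 0.12, otvShift = 2.5,
                            centerJitter = 0.04,
                            lowCallFraction = 0.05, otherFraction = 0.07,
                            lowCallScatter = 0.25,
                            otherAbSdFactor = 6, otherHetDrop = 0.2) {
  as.list(environment())
}

#' Simulate two-channel probe intensities with planted cluster categories
#'
#' Each variant is planted with one of the six cluster-quality categories,
#' consistent with its true genotype composition: monomorphic variants
#' yield a single cluster; variants lacking a minor-allele homozygote give
#' NoMinorHom geometry; variants flagged with a flanking off-target variant
#' (and at least two carriers) emit carrier samples from an additional
#' low-size cluster, emulating the reduced hybridization efficiency of
#' OTVs; configurable fractions of sufficiently polymorphic variants are
#' planted as low-call-rate (a share of samples placed midway between
#' clusters, yielding ambiguous posteriors) or as failed "Other" variants
#' (widened, slightly lowered heterozygous cluster). The planted category
#' is stored in the row metadata for recovery tests.
#'
#' @param truth A [SimulatedTruth-class].
#' @param geometry Settings from [clusterGeometry()].
#' @param seed Integer seed.
#' @return An [IntensitySet-class] with assays `signalA`, `signalB` and row
#'   metadata `plantedCategory` and `otvCarrierCount`.
#' @export
simulateIntensities <- function(truth, geometry = clusterGeometry(),
                                seed = 1L) {
  stopifnot(is(truth, "SimulatedTruth"))
  g <- geometry
  G <- trueGenotypes(truth)
  nv <- nrow(G); ns <- ncol(G)
  flank <- flankingGenotypes(truth)
  vmc <- mcols(variantInfo(truth))

  withSeed(substreamSeed(seed, "intensities"), {
    planted <- character(nv)
    carrierCount <- integer(nv)
    failMode <- stats::runif(nv)

    X <- matrix(0, nv, ns, dimnames = dimnames(G))
    Y <- matrix(0, nv, ns, dimnames = dimnames(G))

    for (i in seq_len(nv)) {
      gt <- G[i, ]
      tab <- tabulate(gt + 1L, nbins = 3L)          # counts of 0/1/2
      nAlleleA <- 2L * tab[3] + tab[2]
      nAlleleB <- 2L * tab[1] + tab[2]
      minorCount <- min(nAlleleA, nAlleleB)
      minorHomPresent <- if (nAlleleA <= nAlleleB) tab[3] > 0 else tab[1] > 0
      nClasses <- sum(tab > 0)

      composition <- if (nClasses <= 1L) {
        "MonoHighResolution"
      } else if (!minorHomPresent || minorCount < 2L) {
        "NoMinorHom"
      } else {
        "PolyHighResolution"
      }

      isOtv <- vmc$otv[i] && nrow(flank) > 0 &&
        vmc$id[i] %in% rownames(flank) &&
        sum(flank[vmc$id[i], ] >= 1L) >= 2L

      cat_i <- if (isOtv) {
        "OTV"
      } else if (composition == "PolyHighResolution" && tab[2] >= 3L &&
                 failMode[i] < g$otherFraction) {
        "Other"
      } else if (composition != "MonoHighResolution" &&
                 failMode[i] >= g$otherFraction &&
                 failMode[i] < g$otherFraction + g$lowCallFraction) {
        "CallRateBelowThreshold"
      } else {
        composition
      }
      planted[i] <- cat_i

      jx <- stats::rnorm(3, 0, g$centerJitter)
      jy <- stats::rnorm(3, 0, g$centerJitter)
      cx <- c(-g$delta, 0, g$delta) + jx            # BB, AB, AA
      cy <- c(g$y0, g$y0 + g$hetLift, g$y0) + jy
      sdx <- rep(g$sdX, 3)
      sdy <- rep(g$sdY, 3)
      if (cat_i == "Other") {
        sdx[2] <- g$sdX * g$otherAbSdFactor
        cy[2] <- g$y0 - g$otherHetDrop              # HetSO in the Other band
      }

      gt0 <- gt
      gt0[is.na(gt0)] <- sample(0:2, sum(is.na(gt0)), replace = TRUE)
      x <- stats::rnorm(ns, cx[gt0 + 1L], sdx[gt0 + 1L])
      y <- stats::rnorm(ns, cy[gt0 + 1L], sdy[gt0 + 1L])

      if (cat_i == "OTV") {
        carriers <- which(flank[vmc$id[i], ] >= 1L)
        carrierCount[i] <- length(carriers)
        x[carriers] <- stats::rnorm(length(carriers), 0, g$sdX * 1.5)
        y[carriers] <- stats::rnorm(length(carriers),
                                    g$y0 - g$otvShift, g$sdY * 1.5)
      } else if (cat_i == "CallRateBelowThreshold") {
        failed <- which(stats::runif(ns) < g$lowCallScatter)
        x[failed] <- stats::runif(length(failed), -g$delta - 1, g$delta + 1)
        y[failed] <- g$y0 + stats::runif(length(failed), -1.5, 1.5)
      }
      X[i, ] <- x
      Y[i, ] <- y
    }

    # back-transform to raw two-channel signals
    A <- 2^(Y + X / 2)
    B <- 2^(Y - X / 2)
    rownames(A) <- rownames(B) <- vmc$id
    rd <- DataFrame(id = vmc$id,
                    chrom = as.character(seqnames(variantInfo(truth))),
                    pos = start(variantInfo(truth)),
                    plantedCategory = planted,
                    otv = vmc$otv,
                    otvCarrierCount = carrierCount)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(signalA = A, signalB = B), rowData = rd)
    new("IntensitySet", se)
  })
}
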