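#' Simulate a toy genome model
#'
#' Generates chromosome lengths, gene intervals and a relative
#' polymorphism-rate profile for each chromosome. With
#' `telomereGradient = TRUE` the rate rises towards the chromosome ends,
#' emulating the telomere-enriched, centromere-depleted variant density of
#' temperate maize; masked intervals (such as a NOR-like gap) carry zero
#' rate and therefore receive no variants.
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param nGenes Total number of gene intervals to place (proportional to
#'   chromosome length).
#' @param geneMeanLength Mean gene length in bp (exponential with a 500 bp
#'   floor).
#' @param telomereGradient Logical; if TRUE the rate profile follows
#'   `1 + gradientStrength * (2|pos - L/2| / L)^2`, otherwise it is uniform.
#' @param gradientStrength Strength of the telomere gradient.
#' @param masked Optional `GRanges` of intervals with zero variant rate.
#' @param rateResolution Width (bp) of one piecewise-constant rate window.
#' @param seed Integer seed (substream "genome" of the top-level seed).
#' @return A [GenomeModel-class].
#' @export
#' @examples
#' gm <- simulateGenome(c(chr1 = 2066000), nGenes = 40, seed = 1)
#' chromLengths(gm)
simulateGenome <- function(chromLengths,
                           nGenes = 100L,
                           geneMeanLength = 3000,
                           telomereGradient = TRUE,
                           gradientStrength = 3,
                           masked = NULL,
                           rateResolution = 1000L,
                           seed = 1L) {
  if (length(chromLengths) < 1L)
    stop("at least one chromosome is required")
  if (any(!is.finite(chromLengths)) || any(chromLengths <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- paste0("chr", seq_along(chromLengths))
  chromLengths <- vapply(chromLengths, as.integer, integer(1))

  withSeed(substreamSeed(seed, "genome"), {
    profiles <- lapply(chromLengths, function(L) {
      nwin <- ceiling(L / rateResolution)
      mid <- (seq_len(nwin) - 0.5) * rateResolution
      mid <- pmin(mid, L)
      if (telomereGradient) {
        1 + gradientStrength * (2 * abs(mid - L / 2) / L)^2
      } else {
        rep(1, nwin)
      }
    })

    # zero out masked windows
    if (!is.null(masked) && length(masked) > 0) {
      for (i in seq_along(masked)) {
        chr <- as.character(seqnames(masked))[i]
        if (!chr %in% names(chromLengths)) next
        w1 <- max(1L, ceiling(start(masked)[i] / rateResolution))
        w2 <- min(length(profiles[[chr]]),
                  ceiling(end(masked)[i] / rateResolution))
        if (w1 <= w2) profiles[[chr]][w1:w2] <- 0
      }
    }

    # genes: count per chromosome proportional to length, positions uniform
    nPerChrom <- stats::rmultinom(
      1, nGenes, prob = chromLengths / sum(as.double(chromLengths)))[, 1]
    geneList <- lapply(names(chromLengths), function(chr) {
      n <- nPerChrom[chr]
      if (n == 0L) return(GRanges())
      len <- pmax(500, round(stats::rexp(n, 1 / geneMeanLength)))
      len <- pmin(len, chromLengths[chr])
      st <- floor(stats::runif(n, 1, chromLengths[chr] - len + 1))
      GRanges(chr, IRanges(st, width = len),
              strand = sample(c("+", "-"), n, replace = TRUE))
    })
    gr <- sort(suppressWarnings(do.call(c, geneList)))
    if (length(gr) > 0) mcols(gr)$gene_id <- paste0("gene", seq_along(gr))

    new("GenomeModel",
        chromLengths = chromLengths,
        genes = gr,
        rateProfiles = profiles,
        rateResolution = as.integer(rateResolution),
        masked = masked)
  })
}

#' Draw variant positions along a genome model
#'
#' Positions are drawn per chromosome proportionally to the rate profile;
#' masked windows have zero probability. Positions are unique and sorted.
#'
#' @param genome A [GenomeModel-class].
#' @param nVariants Number of positions to draw.
#' @param seed Integer seed.
#' @return A sorted `GRanges` of width-1 positions.
#' @export
drawVariantPositions <- function(genome, nVariants, seed = 1L) {
  stopifnot(nVariants >= 1)
  withSeed(substreamSeed(seed, "positions"), {
    cl <- chromLengths(genome)
    weights <- vapply(names(cl), function(chr)
      sum(rateProfiles(genome)[[chr]]), numeric(1))
    if (sum(weights) <= 0) stop("genome has zero total polymorphism rate")
    nPer <- stats::rmultinom(1, nVariants, prob = weights)[, 1]
    res <- genome@rateResolution
    grl <- lapply(names(cl), function(chr) {
      n <- nPer[chr]
      if (n == 0L) return(GRanges())
      prof <- rateProfiles(genome)[[chr]]
      win <- sample.int(length(prof), n, replace = TRUE, prob = prof)
      lo <- (win - 1L) * res + 1L
      hi <- pmin(win * res, cl[chr])
      pos <- unique(floor(stats::runif(n, lo, hi + 1)))
      # top up in case of duplicate draws
      while (length(pos) < n) {
        extra <- sample.int(length(prof), n - length(pos),
                            replace = TRUE, prob = prof)
        lo2 <- (extra - 1L) * res + 1L
        hi2 <- pmin(extra * res, cl[chr])
        pos <- unique(c(pos, floor(stats::runif(length(extra), lo2, hi2 + 1))))
      }
      GRanges(chr, IRanges(sort(pos[seq_len(n)]), width = 1))
    })
    sort(suppressWarnings(do.call(c, grl)))
  })
}
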