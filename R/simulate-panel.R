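#' Construct a PanelConfig
#'
#' @param samples data.frame with columns id, pool, subgroup, f, penalty,
#'   replicate_of, parent1, parent2 and optionally admix_w (Dent mixing
#'   weight of admixed samples, defaulting to 0.5).
#' @param poolBeta Named list of Beta(shape1, shape2) parameters per pool;
#'   pools without an entry fall back to `c(0.8, 0.8)`.
#' @param divergence Logit-scale shift applied between the Dent and Flint
#'   allele-frequency means (0 = identical pools).
#' @return A [PanelConfig-class].
#' @export
PanelConfig <- function(samples,
                        poolBeta = list(Dent = c(0.8, 0.8),
                                        Flint = c(0.8, 0.8),
                                        outgroup = c(0.4, 1.2)),
                        divergence = 1.5) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"admix_w" %in% names(samples))
    samples$admix_w <- ifelse(samples$pool == "admixed", 0.5, NA_real_)
  for (col in c("replicate_of", "parent1", "parent2"))
    if (!col %in% names(samples)) samples[[col]] <- NA_character_
  if (nrow(samples) == 0L) stop("panel must contain at least one sample")
  new("PanelConfig", samples = samples, poolBeta = poolBeta,
      divergence = divergence)
}

.sampleRow <- function(id, pool, subgroup = pool, f = 0, penalty = 0,
                       replicate_of = NA_character_,
                       parent1 = NA_character_, parent2 = NA_character_) {
  data.frame(id = id, pool = pool, subgroup = subgroup, f = f,
             penalty = penalty, replicate_of = replicate_of,
             parent1 = parent1, parent2 = parent2,
             stringsAsFactors = FALSE)
}

#' Default discovery-panel configuration
#'
#' Thirty inbred lines — 13 Dent and 17 Flint — as in the variant-discovery
#' panel, with four deep-sequenced lines (the first two of each pool) and
#' 26 shallow lines. Inbreeding coefficient 0.99 reflects the small
#' residual heterozygosity of elite inbreds.
#'
#' @param divergence Pool divergence (logit-scale shift).
#' @return A [PanelConfig-class] of 30 inbred samples.
#' @export
discoveryPanelConfig <- function(divergence = 1.5) {
  rows <- rbind(
    do.call(rbind, lapply(seq_len(13), function(i)
      .sampleRow(sprintf("D%02d", i), "Dent", "Dent-discovery",
                 f = 0.99, penalty = 14))),
    do.call(rbind, lapply(seq_len(17), function(i)
      .sampleRow(sprintf("F%02d", i), "Flint", "Flint-discovery",
                 f = 0.99, penalty = 14)))
  )
  PanelConfig(rows, divergence = divergence)
}

#' Default validation-panel configuration
#'
#' Emulates the structure of the experimental validation panel: public Dent
#' and Flint inbreds (penalty 14), a few lines with unclear homozygosity
#' (penalty 12), doubled-haploid lines (f = 1, penalty 14), F1 hybrids from
#' trios with both parents present (f = 0, penalty 0), admixed
#' (sub)tropical lines, outgroup accessions, and technical plus biological
#' replicates.
#'
#' @param nDent,nFlint Numbers of public Dent and Flint inbred lines.
#' @param nTrios Number of Dent x Flint trios; each contributes one F1
#'   hybrid whose parents are existing panel lines.
#' @param nAdmixed Number of admixed (sub)tropical lines.
#' @param nOutgroup Number of outgroup accessions.
#' @param nProprietary Number of additional proprietary-style inbred
#'   lines (penalty 12, alternating pools); with the other defaults the
#'   panel totals 285 samples.
#' @param nTechReps Technical replicates of the first Dent line.
#' @param nBioReps Biological replicate pairs (one per replicated line).
#' @param divergence Pool divergence.
#' @return A [PanelConfig-class].
#' @export
validationPanelConfig <- function(nDent = 73, nFlint = 79, nTrios = 23,
                                  nAdmixed = 13, nOutgroup = 2,
                                  nProprietary = 89,
                                  nTechReps = 3, nBioReps = 3,
                                  divergence = 1.5) {
  dent <- do.call(rbind, lapply(seq_len(nDent), function(i)
    .sampleRow(sprintf("DL%03d", i), "Dent",
               c("BSSS", "Iodent", "LSC", "nonBSSS")[1 + (i %% 4)],
               f = 0.99, penalty = if (i %% 10 == 0) 12 else 14)))
  flint <- do.call(rbind, lapply(seq_len(nFlint), function(i)
    .sampleRow(sprintf("FL%03d", i), "Flint",
               c("NorthernFlint", "nonNorthernFlint")[1 + (i %% 2)],
               f = if (i <= 10) 1 else 0.99,     # first ten are DH lines
               penalty = if (i %% 10 == 0) 12 else 14)))
  hyb <- do.call(rbind, lapply(seq_len(nTrios), function(i)
    .sampleRow(sprintf("HY%03d", i), "hybrid", "F1",
               f = 0, penalty = 0,
               parent1 = dent$id[1 + (i - 1) %% nDent],
               parent2 = flint$id[1 + (i - 1) %% nFlint])))
  adm <- if (nAdmixed > 0)
    do.call(rbind, lapply(seq_len(nAdmixed), function(i)
      .sampleRow(sprintf("TR%03d", i), "admixed", "subtropical",
                 f = 0.99, penalty = 12))) else NULL
  prop <- if (nProprietary > 0)
    do.call(rbind, lapply(seq_len(nProprietary), function(i)
      .sampleRow(sprintf("PR%03d", i), c("Dent", "Flint")[1 + (i %% 2)],
                 "proprietary", f = 0.99, penalty = 12))) else NULL
  outg <- if (nOutgroup > 0)
    do.call(rbind, lapply(seq_len(nOutgroup), function(i)
      .sampleRow(sprintf("TE%03d", i), "outgroup", "teosinte",
                 f = 0.9, penalty = 12))) else NULL
  tech <- if (nTechReps > 0)
    do.call(rbind, lapply(seq_len(nTechReps), function(i)
      .sampleRow(sprintf("%s_tech%d", dent$id[1], i), "Dent",
                 dent$subgroup[1], f = 0.99, penalty = 14,
                 replicate_of = dent$id[1]))) else NULL
  bio <- if (nBioReps > 0)
    do.call(rbind, lapply(seq_len(nBioReps), function(i)
      .sampleRow(sprintf("%s_bio", flint$id[i + 10]), "Flint",
                 flint$subgroup[i + 10], f = 0.99, penalty = 14,
                 replicate_of = flint$id[i + 10]))) else NULL
  PanelConfig(rbind(dent, flint, hyb, adm, prop, outg, tech, bio),
              divergence = divergence)
}

#' Simulate planted genotypes for a panel
#'
#' Per-variant pool allele frequencies are drawn from the pool Beta
#' distribution; the Dent and Flint means are shifted apart on the logit
#' scale by the divergence parameter (random sign per variant). A sample
#' with inbreeding coefficient `f` and non-reference frequency `p` is
#' heterozygous with probability `2 p (1-p) (1-f)`. Hybrids receive one
#' gamete from each simulated parent; replicates copy their source sample's
#' genotypes exactly. A fraction of variants is flagged paralog-confounded
#' (sequencing emulation inflates their het calls) and a fraction carries
#' an off-target flanking variant whose frequency is drawn from a
#' rare-allele-heavy Beta, emulating unascertained variation.
#'
#' @param genome A [GenomeModel-class].
#' @param panel A [PanelConfig-class].
#' @param nVariants Number of variants to simulate.
#' @param paralogFraction Fraction of variants flagged paralog-confounded.
#' @param otvFraction Fraction of variants carrying a flanking off-target
#'   variant.
#' @param monoFraction Fraction of variants forced monomorphic (frequency
#'   0 in all pools).
#' @param flankingBeta Beta parameters of the flanking-variant frequency
#'   (default heavily skewed to rare alleles).
#' @param seed Integer seed.
#' @return A [SimulatedTruth-class].
#' @export
simulatePanel <- function(genome, panel, nVariants,
                          paralogFraction = 0.1,
                          otvFraction = 0.075,
                          monoFraction = 0.02,
                          flankingBeta = c(0.25, 1.25),
                          seed = 1L) {
  stopifnot(is(genome, "GenomeModel"), is(panel, "PanelConfig"),
            nVariants >= 1)
  samples <- panelSamples(panel)
  hyb <- samples$pool == "hybrid"
  if (any(hyb) && (!all(samples$parent1[hyb] %in% samples$id) ||
                   !all(samples$parent2[hyb] %in% samples$id)))
    stop("trio parent missing from panel")

  pos <- drawVariantPositions(genome, nVariants, seed = seed)
  vid <- sprintf("var%06d", seq_len(nVariants))

  withSeed(substreamSeed(seed, "panel"), {
    betaD <- panel@poolBeta[["Dent"]] %||% c(0.8, 0.8)
    betaO <- panel@poolBeta[["outgroup"]] %||% c(0.4, 1.2)
    d <- panel@divergence

    base <- stats::rbeta(nVariants, betaD[1], betaD[2])
    base <- pmin(pmax(base, 1e-4), 1 - 1e-4)
    sgn <- sample(c(-1, 1), nVariants, replace = TRUE)
    pD <- stats::plogis(stats::qlogis(base) + sgn * d / 2)
    pF <- stats::plogis(stats::qlogis(base) - sgn * d / 2)
    pO <- stats::rbeta(nVariants, betaO[1], betaO[2])

    mono <- stats::runif(nVariants) < monoFraction
    pD[mono] <- 0; pF[mono] <- 0; pO[mono] <- 0

    paralog <- stats::runif(nVariants) < paralogFraction
    otv <- stats::runif(nVariants) < otvFraction

    freq <- cbind(Dent = pD, Flint = pF, outgroup = pO)
    rownames(freq) <- vid

    # non-hybrid, non-replicate genotypes
    G <- matrix(NA_integer_, nVariants, nrow(samples),
                dimnames = list(vid, samples$id))
    for (j in seq_len(nrow(samples))) {
      s <- samples[j, ]
      if (s$pool == "hybrid" || !is.na(s$replicate_of)) next
      p <- switch(s$pool,
                  Dent = pD, Flint = pF, outgroup = pO,
                  admixed = s$admix_w * pD + (1 - s$admix_w) * pF)
      f <- s$f
      pHet <- 2 * p * (1 - p) * (1 - f)
      pAlt <- p^2 + f * p * (1 - p)
      u <- stats::runif(nVariants)
      G[, j] <- ifelse(u < pAlt, 2L, ifelse(u < pAlt + pHet, 1L, 0L))
    }
    # hybrids: one gamete per parent
    gamete <- function(g) ifelse(g == 2L, 1L,
                          ifelse(g == 0L, 0L,
                                 as.integer(stats::runif(length(g)) < 0.5)))
    for (j in which(hyb)) {
      g1 <- G[, samples$parent1[j]]
      g2 <- G[, samples$parent2[j]]
      G[, j] <- gamete(g1) + gamete(g2)
    }
    # replicates copy truth
    for (j in which(!is.na(samples$replicate_of)))
      G[, j] <- G[, samples$replicate_of[j]]

    # flanking off-target variants: rare-heavy frequency, inbred dosages
    otvIdx <- which(otv)
    flank <- matrix(0L, length(otvIdx), nrow(samples),
                    dimnames = list(vid[otvIdx], samples$id))
    if (length(otvIdx) > 0) {
      q <- stats::rbeta(length(otvIdx), flankingBeta[1], flankingBeta[2])
      q <- pmin(pmax(q, 0.02), 0.98)   # at least a chance of carriers
      for (k in seq_along(otvIdx)) {
        fS <- ifelse(samples$pool == "hybrid", 0, samples$f)
        pHet <- 2 * q[k] * (1 - q[k]) * (1 - fS)
        pAlt <- q[k]^2 + fS * q[k] * (1 - q[k])
        u <- stats::runif(nrow(samples))
        flank[k, ] <- ifelse(u < pAlt, 2L, ifelse(u < pAlt + pHet, 1L, 0L))
      }
      # replicates share flanking truth too
      for (j in which(!is.na(samples$replicate_of)))
        flank[, j] <- flank[, samples$replicate_of[j]]
    }

    gr <- pos
    isCoding <- IRanges::overlapsAny(gr, genes(genome))
    mcols(gr) <- DataFrame(
      id = vid,
      ref = sample(c("A", "C", "G", "T"), nVariants, replace = TRUE),
      type = ifelse(stats::runif(nVariants) < 0.011, "indel", "SNP"),
      coding = isCoding,
      monomorphic = mono,
      paralog = paralog,
      otv = otv,
      flankingFreq = ifelse(otv, NA_real_, NA_real_))
    alt <- vapply(seq_len(nVariants), function(i) {
      if (mcols(gr)$type[i] == "indel") return("AT")
      sample(setdiff(c("A", "C", "G", "T"), mcols(gr)$ref[i]), 1)
    }, character(1))
    mcols(gr)$alt <- alt
    if (length(otvIdx) > 0) mcols(gr)$flankingFreq[otvIdx] <-
      rowMeans(flank) / 2

    new("SimulatedTruth",
        genotypes = G, variants = gr, flankingGenotypes = flank,
        poolFreqs = freq, samples = samples)
  })
}
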