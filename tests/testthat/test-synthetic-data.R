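test_that("simulateGenome honours its configuration and is deterministic", {
  gm <- simulateGenome(c(chrA = 2066000), nGenes = 20, seed = 3,
                       telomereGradient = FALSE)
  expect_s4_class(gm, "GenomeModel")
  expect_identical(unname(chromLengths(gm)), 2066000L)
  expect_length(chromLengths(gm), 1L)

  gm2 <- simulateGenome(c(chrA = 2066000), nGenes = 20, seed = 3,
                        telomereGradient = FALSE)
  expect_identical(gm, gm2)

  expect_error(simulateGenome(c(chrA = -5)), "positive")
})

test_that("telomere gradient raises outer-decile rates above inner ones", {
  gm <- simulateGenome(c(chr1 = 5e6), telomereGradient = TRUE, seed = 1)
  r <- rateProfiles(gm)$chr1
  n <- length(r)
  dec <- floor(n / 10)
  outer <- c(r[seq_len(dec)], r[seq(n - dec + 1, n)])
  inner <- r[seq(floor(n * 0.45), ceiling(n * 0.55))]
  expect_gt(mean(outer), mean(inner))
})

test_that("masked intervals produce zero variants inside them", {
  msk <- GRanges("chr1", IRanges(1e6, 2e6))
  gm <- simulateGenome(c(chr1 = 5e6), masked = msk, seed = 2)
  pos <- drawVariantPositions(gm, 2000, seed = 2)
  expect_false(any(start(pos) >= 1e6 & start(pos) <= 2e6))
})

test_that("inbreeding and divergence control simulated genotypes", {
  gm <- simulateGenome(c(chr1 = 1e6), seed = 1)
  # fully inbred sample has zero heterozygosity
  s <- data.frame(id = c("a", "b"), pool = "Dent", subgroup = "x",
                  f = c(1, 0), penalty = 14,
                  replicate_of = NA, parent1 = NA, parent2 = NA)
  truth <- simulatePanel(gm, PanelConfig(s), 800, monoFraction = 0,
                         seed = 5)
  expect_identical(sum(trueGenotypes(truth)[, "a"] == 1L), 0L)

  # zero divergence: identical pool frequencies
  panel0 <- PanelConfig(s, divergence = 0)
  t0 <- simulatePanel(gm, panel0, 500, seed = 2)
  pf <- poolFreqs(t0)
  expect_lt(mean(abs(pf[, "Dent"] - pf[, "Flint"])), 1e-12)

  # het fraction about 2p(1-p) for f = 0 at p drawn tightly around 0.5
  s2 <- data.frame(id = "h", pool = "Dent", subgroup = "x", f = 0,
                   penalty = 0, replicate_of = NA, parent1 = NA,
                   parent2 = NA)
  pc <- PanelConfig(s2, poolBeta = list(Dent = c(500, 500)),
                    divergence = 0)
  t2 <- simulatePanel(gm, pc, 1000, monoFraction = 0, otvFraction = 0,
                      seed = 7)
  hetFrac <- mean(trueGenotypes(t2)[, "h"] == 1L)
  expect_lt(abs(hetFrac - 0.5), 4 * sqrt(0.25 / 1000))
})

test_that("hybrids are Mendelian and replicates copy truth exactly", {
  gm <- simulateGenome(c(chr1 = 1e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 400, seed = 3)
  s <- panelSamples(truth)
  G <- trueGenotypes(truth)
  for (j in which(s$pool == "hybrid")) {
    g1 <- G[, s$parent1[j]]; g2 <- G[, s$parent2[j]]; off <- G[, j]
    gam <- function(g) switch(as.character(g), `0` = 0L, `2` = 1L,
                              `1` = c(0L, 1L))
    ok <- vapply(seq_along(off), function(i)
      off[i] %in% outer(gam(g1[i]), gam(g2[i]), `+`), logical(1))
    expect_true(all(ok))
  }
  for (j in which(!is.na(s$replicate_of)))
    expect_identical(unname(G[, j]), unname(G[, s$replicate_of[j]]))
  expect_error(
    simulatePanel(gm, PanelConfig(data.frame(
      id = "x", pool = "hybrid", subgroup = "f1", f = 0, penalty = 0,
      replicate_of = NA, parent1 = "ghost", parent2 = "ghost2")), 10),
    "parent")
})

test_that("sequencing emulation reproduces truth in the no-noise limit", {
  gm <- simulateGenome(c(chr1 = 1e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 300, paralogFraction = 0,
                         seed = 4)
  sv <- simulateSequencingCalls(truth, meanDepths = 60,
                                paralogFraction = 0, errorRate = 0,
                                disagreeRate = 0, seed = 4)
  expect_identical(seqGenotypes(sv), trueGenotypes(truth))
  expect_true(all(mcols(variantInfo(sv))$samCall))
  expect_true(all(mcols(variantInfo(sv))$gatkCall))
})

test_that("paralog flags follow the requested fraction and carry CN >= 50", {
  gm <- simulateGenome(c(chr1 = 5e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 4000, seed = 5)
  sv <- simulateSequencingCalls(truth, paralogFraction = 0.1, seed = 5)
  rd <- mcols(variantInfo(sv))
  frac <- mean(rd$paralogTruth)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / 4000))
  expect_true(all(rd$CN[rd$paralogTruth] >= 50L))
  expect_true(all(rd$MQ0F >= 0 & rd$MQ0F <= 1))
})

test_that("intensity simulation plants recoverable geometry", {
  gm <- simulateGenome(c(chr1 = 2e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 250, seed = 6)
  it <- simulateIntensities(truth, seed = 6)
  rd <- SummarizedExperiment::rowData(it)
  tr <- intensityTransform(SummarizedExperiment::assay(it, "signalA"),
                           SummarizedExperiment::assay(it, "signalB"))

  # monomorphic variants: one tight cluster in contrast
  monoIdx <- which(rd$plantedCategory == "MonoHighResolution")
  expect_gt(length(monoIdx), 0)
  expect_true(all(apply(tr$x[monoIdx, , drop = FALSE], 1, sd) < 0.5))

  # OTV carriers sit lower in size than non-carriers
  carriers <- otvCarriers(truth)
  otvIdx <- which(rd$plantedCategory == "OTV")
  for (i in otvIdx) {
    cs <- carriers[[rd$id[i]]]
    expect_gt(mean(tr$y[i, setdiff(colnames(tr$y), cs)]) -
                mean(tr$y[i, cs]), 1)
  }

  # determinism
  it2 <- simulateIntensities(truth, seed = 6)
  expect_identical(SummarizedExperiment::assay(it, "signalA"),
                   SummarizedExperiment::assay(it2, "signalA"))
})

test_that("fixture sets round-trip through the module readers", {
  dir <- withr::local_tempdir()
  st <- simulateStudy(seed = 11, nVariants = 60, panel = smallPanel(),
                      chromLengths = c(chr1 = 5e5))
  paths <- writeFixtureSet(st, dir)

  sv <- readSeqVcf(paths$vcf)
  expect_identical(unname(seqGenotypes(sv)), unname(seqGenotypes(st$seqCalls)))
  rdIn <- mcols(variantInfo(st$seqCalls))
  rdOut <- mcols(variantInfo(sv))
  expect_identical(rdOut$CN, rdIn$CN)
  expect_identical(rdOut$samCall, rdIn$samCall)
  expect_equal(rdOut$MQ0F, rdIn$MQ0F, tolerance = 1e-4)

  it <- readIntensityTable(paths$intensities)
  expect_equal(
    SummarizedExperiment::assay(it, "signalA")[rownames(st$intensities), ],
    SummarizedExperiment::assay(st$intensities, "signalA"),
    tolerance = 1e-6)

  pc <- readSampleSheet(paths$samples)
  expect_identical(panelSamples(pc)$id, panelSamples(st$panel)$id)
  expect_identical(panelSamples(pc)$penalty, panelSamples(st$panel)$penalty)

  genesBack <- readGenesBed(paths$genes)
  expect_identical(start(genesBack), start(genes(st$genome)))
  expect_identical(end(genesBack), end(genes(st$genome)))

  manifest <- jsonlite::fromJSON(paths$manifest)
  expect_identical(manifest$seed, 11L)

  st$truth@samples <- st$truth@samples[0, ]
  expect_error(writeFixtureSet(st, dir), "empty panel")
})

test_that("identical seeds give identical studies end to end", {
  a <- simulateStudy(seed = 21, nVariants = 50, panel = smallPanel(),
                     chromLengths = c(chr1 = 5e5))
  b <- simulateStudy(seed = 21, nVariants = 50, panel = smallPanel(),
                     chromLengths = c(chr1 = 5e5))
  expect_identical(trueGenotypes(a$truth), trueGenotypes(b$truth))
  expect_identical(seqGenotypes(a$seqCalls), seqGenotypes(b$seqCalls))
  expect_identical(SummarizedExperiment::assay(a$intensities, "signalB"),
                   SummarizedExperiment::assay(b$intensities, "signalB"))
})
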