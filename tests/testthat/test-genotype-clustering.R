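mkModel <- function(centers, sds = NULL, present = NULL) {
  full <- matrix(NA_real_, 4, 2, dimnames = list(c("AA", "AB", "BB", "OO"),
                                                 NULL))
  full[rownames(centers), ] <- centers
  sdFull <- matrix(0.1, 4, 2, dimnames = dimnames(full))
  if (!is.null(sds)) sdFull[rownames(sds), ] <- sds
  pres <- setNames(rownames(full) %in% rownames(centers),
                   rownames(full))
  if (!is.null(present)) pres[] <- present
  w <- ifelse(pres, 1 / sum(pres), 0)
  new("ClusterModel", centers = full, sds = sdFull, weights = w,
      present = pres, n = ifelse(pres, 10, 0))
}

test_that("contrast/size transform follows the log identities", {
  tr <- intensityTransform(1024, 1024)
  expect_equal(tr$x, 0)
  expect_equal(tr$y, 10)
  expect_equal(intensityTransform(4 * 256, 256)$x, 2)
  expect_equal(intensityTransform(0, 1, floor = 1)$x, 0)
  expect_error(intensityTransform(-1, 5), "non-negative")
})

test_that("perfectly separated clusters are called without error", {
  set.seed(1)
  gt <- rep(c(0L, 1L, 2L), each = 20)
  x <- c(-1.5, 0, 1.5)[gt + 1L] + rnorm(60, 0, 0.05)
  y <- c(10, 10.3, 10)[gt + 1L] + rnorm(60, 0, 0.05)
  fit <- callGenotypes(x, y, penalties = 0)
  expect_identical(unname(fit$call), c("BB", "AB", "AA")[gt + 1L])
  met <- clusterMetrics(fit)
  expect_equal(met$callRate, 100)
  expect_identical(met$nClusters, 3L)
})

test_that("the inbred penalty suppresses ambiguous het calls", {
  set.seed(2)
  x <- c(rnorm(25, 1.5, 0.25), rnorm(25, 0, 0.25), 0.75)
  y <- c(rnorm(50, 10, 0.15), 10.15)
  fitHi <- callGenotypes(x, y, penalties = c(rep(0, 50), 16))
  expect_identical(unname(fitHi$call[51]), "AA")

  # monotone contract: higher penalty never yields more het calls
  gm <- simulateGenome(c(chr1 = 1e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 120, seed = 8)
  it <- simulateIntensities(truth, seed = 8)
  pen <- setNames(panelSamples(truth)$penalty, panelSamples(truth)$id)
  n0 <- sum(genoCalls(callIntensitySet(it, inbredCorrection = FALSE)$calls)
            == "AB", na.rm = TRUE)
  n14 <- sum(genoCalls(callIntensitySet(it, penalties = pen)$calls)
             == "AB", na.rm = TRUE)
  expect_lte(n14, n0)
})

test_that("FLD and homFLD follow the separation formula", {
  m <- mkModel(rbind(AA = c(1, 10), AB = c(-1, 10.3), BB = c(-3, 10)),
               sds = rbind(AA = c(0.5, 0.1), AB = c(0.5, 0.1),
                           BB = c(0.5, 0.1)))
  expect_equal(fld(m), 2 / 0.5)       # centers 2 apart, pooled s = 0.5
  expect_equal(homFld(m), 4 / 0.5)

  coincident <- mkModel(rbind(AA = c(0, 10), AB = c(0, 10.3),
                              BB = c(-1, 10)))
  expect_equal(fld(coincident), 0)

  wide <- mkModel(rbind(AA = c(1, 10), AB = c(-1, 10.3), BB = c(-3, 10)),
                  sds = rbind(AA = c(1, 0.1), AB = c(1, 0.1),
                              BB = c(1, 0.1)))
  expect_lt(fld(wide), fld(m))        # wider variance, same centers

  noAB <- mkModel(rbind(AA = c(1.5, 10), BB = c(-1.5, 10)))
  expect_true(is.na(fld(noAB)))
  expect_false(is.na(homFld(noAB)))
})

test_that("FLD is translation invariant and scale equivariant", {
  base <- rbind(AA = c(1.5, 10), AB = c(0, 10.3), BB = c(-1.5, 10))
  sds <- rbind(AA = c(0.2, 0.1), AB = c(0.2, 0.1), BB = c(0.2, 0.1))
  m1 <- mkModel(base, sds)
  shifted <- base; shifted[, 1] <- shifted[, 1] + 7
  m2 <- mkModel(shifted, sds)
  expect_equal(fld(m1), fld(m2))
  scaled <- base; scaled[, 1] <- scaled[, 1] * 3
  m3 <- mkModel(scaled, sds * c(3, 1)[col(sds)])
  expect_equal(fld(m3), fld(m1))
})

test_that("HetSO measures the offset from the homozygote line", {
  onLine <- mkModel(rbind(AA = c(1.5, 10), AB = c(0, 10), BB = c(-1.5, 10)))
  expect_equal(hetSO(onLine), 0)

  above <- mkModel(rbind(AA = c(1.5, 10), AB = c(0, 10.4), BB = c(-1.5, 10)))
  expect_equal(hetSO(above), 0.4)

  slanted <- mkModel(rbind(AA = c(1, 10), AB = c(0, 10.4), BB = c(-2, 9.4)))
  expect_equal(hetSO(slanted),
               10.4 - (10 + (9.4 - 10) * (0 - 1) / (-2 - 1)))

  otvLike <- mkModel(rbind(AA = c(1.5, 10), AB = c(0, 8), BB = c(-1.5, 10)))
  expect_lt(hetSO(otvLike), 0)

  oneHom <- mkModel(rbind(AA = c(1.5, 10), AB = c(0, 10.3)))
  expect_equal(hetSO(oneHom), 0.3)
  expect_true(is.na(hetSO(mkModel(rbind(AA = c(1.5, 10))))))
})

test_that("HomRO is the worst-case signed homozygote contrast", {
  both <- mkModel(rbind(AA = c(1.2, 10), AB = c(0, 10.3), BB = c(-0.9, 10)))
  expect_equal(homRO(both), 0.9)
  misplaced <- mkModel(rbind(AA = c(-0.1, 10), AB = c(0, 10.3)))
  expect_lt(homRO(misplaced), 0)
  single <- mkModel(rbind(AA = c(0.5, 10)))
  expect_equal(homRO(single), 0.5)
  expect_true(is.na(homRO(mkModel(rbind(AB = c(0, 10.3))))))
})

test_that("classification implements the six-way decision tree", {
  mkMet <- function(callRate = 95, FLD = 5, homFLD = 10, HetSO = 0.2,
                    HomRO = 1, nMinorAllele = 10L, nClusters = 3L,
                    minorHomPresent = TRUE, singleClusterIsHet = FALSE,
                    otvTriggered = FALSE) {
    data.frame(callRate = callRate, FLD = FLD, homFLD = homFLD,
               HetSO = HetSO, HomRO = HomRO,
               nMinorAllele = nMinorAllele, nClusters = nClusters,
               minorHomPresent = minorHomPresent,
               singleClusterIsHet = singleClusterIsHet,
               otvTriggered = otvTriggered)
  }
  expect_identical(classifyVariants(mkMet()), "PolyHighResolution")
  expect_identical(classifyVariants(mkMet(callRate = 80)),
                   "CallRateBelowThreshold")
  expect_identical(classifyVariants(mkMet(nClusters = 1L,
                                          minorHomPresent = FALSE)),
                   "MonoHighResolution")
  expect_identical(classifyVariants(mkMet(nClusters = 1L, HomRO = 0.1)),
                   "Other")
  expect_identical(classifyVariants(mkMet(FLD = 3.5)), "Other")
  expect_identical(classifyVariants(mkMet(HetSO = -0.2)), "Other")
  expect_identical(classifyVariants(mkMet(HetSO = -0.4)), "OTV")
  expect_identical(classifyVariants(mkMet(otvTriggered = TRUE)), "OTV")
  expect_identical(classifyVariants(mkMet(minorHomPresent = FALSE)),
                   "NoMinorHom")
  expect_identical(classifyVariants(mkMet(nMinorAllele = 1L)),
                   "NoMinorHom")
  # two-cluster HomRO cut (0.3) vs three-cluster cut (-0.9)
  expect_identical(classifyVariants(mkMet(HomRO = 0.2, nClusters = 2L,
                                          minorHomPresent = FALSE)),
                   "Other")
  expect_identical(classifyVariants(mkMet(HomRO = 0.2, nClusters = 3L)),
                   "PolyHighResolution")
  # pure function: same input, same output
  expect_identical(classifyVariants(mkMet()), classifyVariants(mkMet()))
})

test_that("category comparison labels stability and promotions", {
  cmp <- compareCorrection(
    c("PolyHighResolution", "NoMinorHom", "Other"),
    c("PolyHighResolution", "PolyHighResolution", "Other"))
  expect_identical(cmp$stable, c(TRUE, FALSE, TRUE))
  expect_identical(cmp$transition,
                   c("stable", "promotion", "stable"))
})

test_that("planted OTV carrier sets are recovered exactly at zero noise", {
  gm <- simulateGenome(c(chr1 = 1e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 150, otvFraction = 0.3,
                         seed = 12)
  geomZero <- clusterGeometry(sdX = 0.01, sdY = 0.01, centerJitter = 0,
                              lowCallFraction = 0, otherFraction = 0)
  it <- simulateIntensities(truth, geomZero, seed = 12)
  res <- callIntensitySet(it, inbredCorrection = FALSE)
  rd <- SummarizedExperiment::rowData(it)
  carriers <- otvCarriers(truth)
  otvIdx <- which(rd$plantedCategory == "OTV")
  expect_gt(length(otvIdx), 3)
  for (i in otvIdx) {
    oo <- colnames(genoCalls(res$calls))[genoCalls(res$calls)[i, ] == "OO"]
    oo <- oo[!is.na(oo)]
    expect_setequal(oo, carriers[[rd$id[i]]])
  }
  # clean PHR variants emit no OO calls
  phrIdx <- which(rd$plantedCategory == "PolyHighResolution")
  expect_false(any(genoCalls(res$calls)[phrIdx, ] == "OO", na.rm = TRUE))
})
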