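mkGeno <- function(m) {
  if (is.null(dimnames(m)))
    dimnames(m) <- list(sprintf("v%03d", seq_len(nrow(m))),
                        sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("replicate concordance counts identical comparable calls", {
  set.seed(1)
  g <- mkGeno(matrix(sample(0:2, 2000, TRUE), 1000, 2))
  g[, 2] <- g[, 1]
  g[sample.int(1000, 5), 2] <- (g[sample.int(1000, 5), 2] + 1L) %% 3L
  res <- replicateConcordance(g, data.frame(a = "s01", b = "s02"))
  expect_gte(res$concordance, 99.5 - 0.2)
  expect_lte(res$concordance, 100)

  ident <- mkGeno(matrix(1L, 10, 2))
  expect_equal(replicateConcordance(
    ident, data.frame(a = "s01", b = "s02"))$concordance, 100)

  disj <- mkGeno(matrix(c(1L, NA, NA, 1L), 2, 2))
  res2 <- replicateConcordance(disj, data.frame(a = "s01", b = "s02"))
  expect_true(res2$undefined)
})

test_that("trio consistency follows Mendelian transmission", {
  g <- mkGeno(matrix(c(2L, 0L, 1L,    # AA x BB -> AB: consistent
                       2L, 2L, 1L,    # AA x AA -> AB: inconsistent
                       1L, 1L, 0L,    # het x het -> anything
                       NA, 0L, 0L),   # missing parent: skipped
                     4, 3, byrow = TRUE))
  trios <- data.frame(parent1 = "s01", parent2 = "s02", offspring = "s03")
  res <- trioMendelian(g, trios)
  expect_identical(res$perTrio$n_evaluated, 3L)
  expect_identical(res$perTrio$n_consistent, 2L)
  expect_error(trioMendelian(g, data.frame(parent1 = "x", parent2 = "y",
                                           offspring = "z")),
               "malformed")

  # noise-free simulated trios are 100% consistent
  gm <- simulateGenome(c(chr1 = 1e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 300, seed = 3)
  s <- panelSamples(truth)
  hyb <- s[s$pool == "hybrid", ]
  res2 <- trioMendelian(trueGenotypes(truth),
                        data.frame(parent1 = hyb$parent1,
                                   parent2 = hyb$parent2,
                                   offspring = hyb$id))
  expect_equal(res2$overall, 100)
})

test_that("polymorphism partition matches brute-force set algebra", {
  set.seed(2)
  g <- mkGeno(matrix(sample(c(0:2, NA), 600, TRUE), 100, 6))
  groups <- list(A = c("s01", "s02"), B = c("s03", "s04", "s05"),
                 C = "s06")
  res <- polymorphismPartition(g, groups)
  for (nm in names(groups)) {
    want <- rownames(g)[apply(g[, groups[[nm]], drop = FALSE], 1,
                              function(r) length(unique(r[!is.na(r)])) >= 2)]
    expect_setequal(res$sets[[nm]], want)
  }
  # single-sample group: nothing polymorphic
  expect_length(res$sets$C, 0)
  # monomorphic column everywhere
  gMono <- mkGeno(matrix(1L, 5, 6))
  resM <- polymorphismPartition(gMono, groups)
  expect_identical(resM$perGroup$n_polymorphic, c(0L, 0L, 0L))
})

test_that("MAF spectrum and ascertainment direction behave as expected", {
  allAlt <- mkGeno(matrix(2L, 3, 10))
  expect_equal(unname(mafSpectrum(allAlt)$maf), rep(0, 3))
  half <- mkGeno(matrix(rep(c(0L, 2L), each = 5), 1, 10))
  expect_equal(unname(mafSpectrum(half)$maf), 0.5)

  # intermediate-frequency ascertainment depletes rare alleles
  set.seed(3)
  p <- rbeta(800, 0.25, 0.9)
  g <- mkGeno(t(vapply(p, function(pp)
    rbinom(60, 2, pp), integer(60))))
  full <- mafSpectrum(g)
  keep <- full$maf >= 0.15 & full$maf <= 0.5
  asc <- mafSpectrum(g[keep, , drop = FALSE])
  expect_lt(asc$fractionRare, full$fractionRare)
})

test_that("Rogers distance has its closed-form values and metric shape", {
  g <- mkGeno(matrix(c(2L, 2L, 0L,
                       0L, 2L, 1L), 2, 3, byrow = TRUE))
  D <- rogersDistance(g)
  expect_equal(unname(D["s01", "s03"]), mean(c(1, 0.5)))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_true(isSymmetric(D))

  ident <- mkGeno(matrix(c(1L, 1L), 1, 2))
  expect_equal(unname(rogersDistance(ident)["s01", "s02"]), 0)
  opp <- mkGeno(matrix(rep(c(0L, 2L), 5), 5, 2, byrow = TRUE))
  expect_equal(unname(rogersDistance(opp)["s01", "s02"]), 1)
  one <- mkGeno(matrix(c(2L, 1L), 1, 2))
  expect_equal(unname(rogersDistance(one)["s01", "s02"]), 0.5)

  # triangle inequality on random matrices
  set.seed(4)
  gr <- mkGeno(matrix(sample(c(0:2, NA), 50 * 8, TRUE,
                             prob = c(.3, .2, .3, .2)), 50, 8))
  Dr <- rogersDistance(gr)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    if (!anyNA(c(Dr[i, j], Dr[i, k], Dr[k, j])))
      expect_lte(Dr[i, j], Dr[i, k] + Dr[k, j] + 1e-12)
})

test_that("classical scaling recovers Euclidean configurations", {
  pts <- c(0, 1, 3, 7, 12)
  D <- as.matrix(dist(pts))
  fit <- pcoa(D, nAxes = 2)
  ax1 <- fit$coords[, 1]
  expect_equal(as.matrix(dist(ax1)), as.matrix(dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)

  zero <- suppressWarnings(pcoa(matrix(0, 3, 3)))
  expect_equal(unname(zero$coords), matrix(0, 3, 2),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("two diverged pools separate on the first PCoA axis", {
  gm <- simulateGenome(c(chr1 = 2e6), seed = 1)
  truth <- simulatePanel(gm, smallPanel(), 400, seed = 5)
  s <- panelSamples(truth)
  keep <- s$pool %in% c("Dent", "Flint") & is.na(s$replicate_of)
  g <- trueGenotypes(truth)[, s$id[keep]]
  fit <- pcoa(rogersDistance(g), nAxes = 2)
  ax1 <- fit$coords[, 1]
  lab <- s$pool[keep]
  # silhouette along axis 1 must be positive on average
  sil <- vapply(seq_along(ax1), function(i) {
    same <- setdiff(which(lab == lab[i]), i)
    own <- mean(abs(ax1[i] - ax1[same]))
    oth <- mean(abs(ax1[i] - ax1[lab != lab[i]]))
    (oth - own) / max(own, oth)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("pairwise r2 matches expectations on planted structure", {
  set.seed(6)
  base <- sample(0:2, 100, TRUE)
  g <- matrix(c(base, base, sample(0:2, 100, TRUE)), 3, 100,
              byrow = TRUE,
              dimnames = list(c("v001", "v002", "v003"), NULL))
  posn <- data.frame(chrom = "chr1", pos = c(100, 200, 50000),
                     row.names = rownames(g))
  res <- ldR2(g, posn)
  dup <- res[res$dist == 100, ]
  expect_equal(dup$r2, 1, tolerance = 1e-12)

  # independent loci: mean r2 about 1/n
  set.seed(7)
  n <- 200
  gi <- mkGeno(matrix(rbinom(80 * n, 2, 0.5), 80, n))
  posi <- data.frame(chrom = "chr1", pos = seq_len(80) * 1000,
                     row.names = rownames(gi))
  resi <- ldR2(gi, posi)
  expect_lt(abs(mean(resi$r2) - 1 / n), 3 / n)

  # monomorphic columns are excluded
  gm2 <- mkGeno(rbind(rep(1L, 20), sample(0:2, 20, TRUE)))
  posm <- data.frame(chrom = "chr1", pos = c(1, 2),
                     row.names = rownames(gm2))
  expect_identical(nrow(ldR2(gm2, posm)), 0L)
})

test_that("LD decay estimation inverts a planted exponential curve", {
  set.seed(8)
  d <- 10^runif(4000, 2, 6.3)
  r2 <- pmin(1, pmax(0, 0.4 * exp(-d / 1e5) + rnorm(4000, 0, 0.01)))
  est <- ldDecayDistance(data.frame(dist = d, r2 = r2))
  expect_identical(est$flag, "ok")
  expect_lt(abs(est$decay_kb - 100 * log(2)) / (100 * log(2)), 0.15)

  below <- data.frame(dist = d, r2 = rep(0.05, length(d)))
  expect_identical(ldDecayDistance(below)$flag, "below_at_start")
  expect_equal(ldDecayDistance(below)$decay_kb, 0)
  above <- data.frame(dist = d, r2 = rep(0.9, length(d)))
  expect_identical(ldDecayDistance(above)$flag, "never_crosses")
  expect_identical(ldDecayDistance(above[1:5, ])$flag, "too_few_pairs")
})

test_that("greedy LD pruning matches the brute-force oracle", {
  set.seed(9)
  nb <- 12
  blocks <- lapply(seq_len(nb), function(b) {
    base <- sample(0:2, 60, TRUE)
    n <- sample(1:4, 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
      g <- base
      flip <- sample.int(60, rbinom(1, 8, 0.5))
      g[flip] <- sample(0:2, length(flip), TRUE)
      g
    }))
  })
  g <- mkGeno(do.call(rbind, blocks))
  posn <- data.frame(chrom = "chr1", pos = seq_len(nrow(g)) * 500,
                     row.names = rownames(g))
  expect_identical(ldPrune(g, posn), oracleLdPrune(g, posn))

  dup <- matrix(rep(g[1, ], 2), 2, ncol(g), byrow = TRUE,
                dimnames = list(c("d1", "d2"), NULL))
  posd <- data.frame(chrom = "chr1", pos = c(1, 2),
                     row.names = rownames(dup))
  expect_length(ldPrune(dup, posd), 1)
})

test_that("mode imputation drops high-missingness variants first", {
  g <- mkGeno(matrix(0L, 3, 25))
  g[1, 1:3] <- NA          # 12% missing -> dropped
  g[2, 1] <- NA            # 4% -> imputed
  g[2, 2:20] <- 0L
  g[3, ] <- 2L             # complete -> identity
  out <- imputeMissing(g, maxMissingFraction = 0.10)
  expect_identical(rownames(out), c("v002", "v003"))
  expect_identical(unname(out["v002", 1]), 0L)
  expect_identical(out["v003", ], g["v003", ])
  expect_false(anyNA(out))
})
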