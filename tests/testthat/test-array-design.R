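test_that("stable PolyHighResolution variants are forwarded", {
  cats <- data.frame(id = c("a", "b", "c"),
                     without = c("PolyHighResolution", "PolyHighResolution",
                                 "NoMinorHom"),
                     with = c("PolyHighResolution", "NoMinorHom",
                              "PolyHighResolution"))
  expect_identical(forwardPhrStable(cats), "a")
  expect_identical(forwardPhrStable(cats[0, ]), character())
})

test_that("OTV-stable selection applies the custom thresholds", {
  cats <- data.frame(id = c("o1", "o2", "o3", "o4", "o5"),
                     without = c("OTV", "OTV", "OTV", "Other", "OTV"),
                     with = c("OTV", "OTV", "OTV", "OTV", "OTV"))
  metrics <- data.frame(
    row.names = cats$id,
    FLD = c(4.0, 3.4, NA, 4.0, 4.0),
    homFLD = c(8, 8, 6, 8, 8),
    HetSO = c(-1.0, -1.0, NA, -1.0, -1.0),
    HomRO = c(1.5, 1.5, 1.5, 1.5, 1.5))
  calls <- matrix("AA", 5, 20, dimnames = list(cats$id, paste0("s", 1:20)))
  calls[, 1:6] <- "BB"
  calls["o5", ] <- "AA"                      # monomorphic
  calls["o1", 1:2] <- NA                     # 10% missing, still passes
  sel <- selectOtvStable(cats, metrics, calls)
  expect_setequal(sel, c("o1", "o3"))        # o2 fails FLD, o4 unstable,
                                             # o5 monomorphic; o3 via homFLD
  calls["o1", 1:3] <- NA                     # 15% missing now
  expect_identical(selectOtvStable(cats, metrics, calls), "o3")
})

test_that("class weights follow the printed transition rules", {
  expect_identical(classWeight("OTV", "OTV"), 10)
  expect_identical(classWeight("NoMinorHom", "PolyHighResolution"), 10)
  expect_identical(classWeight("Other", "PolyHighResolution"), 5)
  expect_identical(classWeight("CallRateBelowThreshold",
                               "PolyHighResolution"), 5)
  expect_identical(classWeight("Other", "Other"), 0)
  expect_identical(classWeight("PolyHighResolution",
                               "PolyHighResolution"), 0)
  expect_error(classWeight("Bogus", "Other"), "unknown")
})

test_that("sequence concordance is matches over comparable pairs", {
  a <- matrix(0L, 2, 30, dimnames = list(c("v1", "v2"), paste0("L", 1:30)))
  s <- a
  s["v1", 1:3] <- NA                          # 27 comparable
  a["v1", 4:12] <- 2L                         # 9 mismatches -> 18 match
  res <- sequenceConcordance(a, s, paste0("L", 1:30))
  expect_equal(res["v1", "concordance"], 18 / 27)
  expect_equal(res["v2", "concordance"], 1)
  aAllNA <- a; aAllNA["v2", ] <- NA
  res2 <- sequenceConcordance(aAllNA, s, paste0("L", 1:30))
  expect_equal(res2["v2", "concordance"], 0)
  expect_true(res2["v2", "undefined"])
  expect_error(sequenceConcordance(a, s, "nope"), "overlapping")
})

test_that("bin representation score scales deviation into [-1, 1]", {
  expect_equal(binRepresentationScore(c(10, 10, 10))[2], 0)
  expect_equal(binRepresentationScore(c(10, 0, 10))[2], 1)
  counts <- c(10, 10, 10, 10, 10, 30, 10, 10, 10, 10, 10)
  expect_equal(binRepresentationScore(counts)[6], -0.5)
  expect_equal(binRepresentationScore(c(0, 0, 0))[1], 0)
  expect_error(binRepresentationScore(c(-1, 2)), "non-negative")
})

test_that("total rank is the documented weighted sum", {
  expect_equal(rankVariant(10, 1, 1), 450)
  expect_equal(rankVariant(0, 0, -1), -10)
  expect_equal(rankVariant(5, 0.5, 0), 220)
  expect_error(rankVariant(7, 0.5, 0), "class weight")
  expect_error(rankVariant(10, 1.5, 0), "concordance")
  expect_error(rankVariant(10, 0.5, 2), "bin score")
})

test_that("duplicate probes resolve by rank with seeded ties", {
  probes <- data.frame(id = c("v1", "v1", "v2", "v2", "v3"),
                       probe_id = c("p1a", "p1b", "p2a", "p2b", "p3"),
                       rank = c(440, 430, 100, 100, 50))
  res <- resolveDuplicateProbes(probes, seed = 1)
  expect_identical(res$probe_id[res$id == "v1"], "p1a")
  expect_identical(res$probe_id[res$id == "v3"], "p3")
  expect_identical(resolveDuplicateProbes(probes, seed = 1),
                   resolveDuplicateProbes(probes, seed = 1))
})

test_that("final assembly keeps forwarded sets and fills by rank", {
  ranked <- data.frame(id = sprintf("r%03d", 1:100),
                       rank = seq(100, 1, by = -1))
  fw <- c("f1", "f2")
  sel <- assembleFinal(fw, ranked, targetSize = 12, seed = 1)
  expect_identical(sel[1:2], fw)
  expect_setequal(sel[3:12], ranked$id[order(-ranked$rank)][1:10])

  # top-k equals the brute-force sort oracle on shuffled input
  shuffled <- ranked[sample.int(100), ]
  sel2 <- assembleFinal(character(), shuffled, targetSize = 25, seed = 1)
  expect_setequal(sel2, ranked$id[order(-ranked$rank)][1:25])

  expect_identical(assembleFinal(fw, ranked[0, ], targetSize = 2), fw)
  expect_warning(out <- assembleFinal(character(), ranked,
                                      targetSize = 1000),
                 "smaller")
  expect_length(out, 100)
  expect_error(assembleFinal(fw, ranked, targetSize = 1), "smaller")
  # exclusion list removes candidates before selection
  sel3 <- assembleFinal(character(), ranked, targetSize = 5,
                        exclude = ranked$id[1:3])
  expect_false(any(ranked$id[1:3] %in% sel3))
})

test_that("variant annotation labels regions and tags genes", {
  genes <- GRanges("chr1", IRanges(c(10000, 30000), width = 500),
                   strand = c("+", "-"))
  mcols(genes)$gene_id <- c("g1", "g2")
  v <- GRanges("chr1", IRanges(c(10200, 5001, 500000, 25001), width = 1))
  # v2 is 4999 bp upstream of g1 start; v4 lies in the downstream flank
  # of minus-strand g2 (lower coordinates)
  ann <- annotateVariants(v, genes, flank = 5000)
  expect_true("genic" %in% ann$labels[[1]])
  expect_true("upstream-5kb" %in% ann$labels[[2]])
  expect_identical(ann$labels[[3]], "intergenic")
  expect_true(any(grepl("5kb", ann$labels[[4]])))
  expect_true(ann$collapsed)

  # planted tagging fraction: 7 of 10 genes hit in their bodies
  genes10 <- GRanges("chr2", IRanges(seq(1e5, 1e6, length.out = 10),
                                     width = 1000))
  mcols(genes10)$gene_id <- paste0("G", 1:10)
  hits <- GRanges("chr2", IRanges(start(genes10)[1:7] + 5, width = 1))
  ann2 <- annotateVariants(hits, genes10, flank = 5000)
  expect_equal(
    ann2$summary$percent[ann2$summary$stringency == "gene_body"], 70)
  expect_gte(
    ann2$summary$percent[ann2$summary$stringency == "with_flanks"], 70)
})

test_that("density statistics summarize neighbor spacing", {
  v2 <- GRanges("chr1", IRanges(c(1000, 2000), width = 1))
  ds <- densityStats(v2, c(chr1 = 1e6))
  expect_equal(unname(ds$overall["mean_kb"]), 1)

  grid <- GRanges("chr1", IRanges(seq(1, 1e6, by = 1e4), width = 1))
  dg <- densityStats(grid, c(chr1 = 1e6))
  expect_equal(unname(dg$overall["mean_kb"]),
               unname(dg$overall["median_kb"]))

  map <- data.frame(chrom = "chr1", pos = c(1, 1e6), cM = c(0, 100))
  dm <- densityStats(grid, c(chr1 = 1e6), geneticMap = map)
  expect_equal(dm$meanCM, 1, tolerance = 1e-4)
  expect_error(densityStats(GRanges(), c(chr1 = 1)), "empty")
})
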