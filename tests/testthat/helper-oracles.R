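# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-record loops, no shared code with the package
# internals) so they can certify the vectorized implementations.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
})

# build a SeqVariantSet from a plain data.frame of site annotations and a
# genotype matrix
makeRecords <- function(df, geno, depth = NULL) {
  gr <- GRanges(df$chrom, IRanges(df$pos, width = 1))
  mcols(gr) <- DataFrame(
    id = df$id, ref = df$ref, alt = df$alt, type = df$type,
    qual = df$qual, DP = df$DP, CN = df$CN, MQ0F = df$MQ0F,
    samCall = df$samCall, gatkCall = df$gatkCall)
  names(gr) <- df$id
  rownames(geno) <- df$id
  SeqVariantSet(gr, geno, depth)
}

randomRecords <- function(n, nLines = 30, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(5e6, n),
    id = sprintf("v%05d", seq_len(n)),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = ifelse(runif(n) < 0.05, "C,G", "T"),
    type = "SNP",
    qual = round(runif(n, 10, 900)),
    DP = round(runif(n, 10, 4000)),
    CN = rpois(n, 10),
    MQ0F = round(runif(n, 0, 0.2), 4),
    samCall = runif(n) < 0.95,
    gatkCall = runif(n) < 0.95)
  df <- df[order(df$chrom, df$pos), ]
  df$id <- sprintf("v%05d", seq_len(n))     # ids in sorted order
  geno <- matrix(sample(c(0L, 1L, 2L, NA), n * nLines, replace = TRUE,
                        prob = c(0.4, 0.25, 0.3, 0.05)),
                 n, nLines,
                 dimnames = list(df$id, sprintf("L%02d", seq_len(nLines))))
  makeRecords(df, geno)
}

# single-pass brute-force evaluation of the whole discovery cascade on one
# record table; returns the ids that survive, in order
oracleCascade <- function(df, geno,
                          qualityMin = 50, depthLow = 50, depthHigh = 3000,
                          minHomNonrefLines = 2, cnMax = 50, mq0Max = 0.05,
                          coverageFoldMax = 6, qualityMin2 = 100,
                          minDistance = 20) {
  keep1 <- df$samCall & df$gatkCall
  df1 <- df[keep1, ]; g1 <- geno[keep1, , drop = FALSE]
  keep2 <- logical(nrow(df1))
  for (i in seq_len(nrow(df1))) {
    g <- g1[i, ]
    keep2[i] <- df1$qual[i] >= qualityMin &&
      df1$DP[i] >= depthLow && df1$DP[i] < depthHigh &&
      sum(g == 0L, na.rm = TRUE) >= 1 &&
      sum(g == 2L, na.rm = TRUE) >= minHomNonrefLines
  }
  df2 <- df1[keep2, ]
  meanCov <- mean(df2$DP)
  keep3 <- logical(nrow(df2))
  for (i in seq_len(nrow(df2))) {
    keep3[i] <- df2$CN[i] < cnMax && df2$MQ0F[i] <= mq0Max &&
      df2$DP[i] <= coverageFoldMax * meanCov && df2$qual[i] >= qualityMin2
  }
  df3 <- df2[keep3, ]
  keep4 <- logical(nrow(df3))
  for (i in seq_len(nrow(df3))) {
    same <- df3$chrom == df3$chrom[i]
    others <- df3$pos[same & df3$id != df3$id[i]]
    left <- others[others < df3$pos[i]]
    right <- others[others > df3$pos[i]]
    dl <- if (length(left)) df3$pos[i] - max(left) else Inf
    dr <- if (length(right)) min(right) - df3$pos[i] else Inf
    keep4[i] <- dl >= minDistance || dr >= minDistance
  }
  df4 <- df3[keep4, ]
  df4$id[!grepl(",", df4$alt)]
}

# brute-force largest-remainder apportionment with proportional shortfall
# redistribution
oracleApportion <- function(total, quotas, avail) {
  take <- setNames(rep(0, length(quotas)), names(quotas))
  active <- rep(TRUE, length(quotas))
  remaining <- total
  repeat {
    if (remaining <= 0 || !any(active)) break
    q <- ifelse(active, quotas, 0)
    raw <- remaining * q / sum(q)
    base <- floor(raw)
    left <- remaining - sum(base)
    if (left > 0) {
      o <- order(raw - base, decreasing = TRUE)
      base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
    }
    got <- pmin(base, avail - take)
    take <- take + got
    remaining <- remaining - sum(got)
    newActive <- active & (take < avail)
    if (identical(newActive, active) && sum(got) == 0) break
    active <- newActive
  }
  take
}

# brute-force greedy LD pruning
oracleLdPrune <- function(geno, positions, r2Max = 0.8, windowBp = 5e7) {
  ids <- rownames(positions)
  kept <- character()
  for (c0 in unique(positions$chrom)) {
    sel <- which(positions$chrom == c0)
    sel <- sel[order(positions$pos[sel])]
    keptHere <- integer()
    for (i in sel) {
      ok <- TRUE
      for (j in keptHere) {
        if (positions$pos[i] - positions$pos[j] > windowBp) next
        r <- suppressWarnings(cor(geno[ids[i], ], geno[ids[j], ],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2Max) { ok <- FALSE; break }
      }
      if (ok) keptHere <- c(keptHere, i)
    }
    kept <- c(kept, ids[keptHere])
  }
  kept
}

# small panel used across tests (fast; 57 samples)
smallPanel <- function(...) {
  validationPanelConfig(nDent = 20, nFlint = 20, nTrios = 6,
                        nAdmixed = 4, nOutgroup = 1, nProprietary = 0,
                        ...)
}
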