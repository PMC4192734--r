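#' Replicate concordance
#'
#' Percentage of identical non-missing call pairs over comparable loci
#' for each replicate pair.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param pairs data.frame with columns `a`, `b` (sample ids).
#' @return data.frame with per-pair concordance (%), comparable-locus
#'   counts and an `undefined` flag (no comparable loci).
#' @export
replicateConcordance <- function(geno, pairs) {
  stopifnot(all(c(pairs$a, pairs$b) %in% colnames(geno)))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    ga <- geno[, pairs$a[k]]; gb <- geno[, pairs$b[k]]
    comp <- !is.na(ga) & !is.na(gb)
    n <- sum(comp)
    data.frame(a = pairs$a[k], b = pairs$b[k], n_comparable = n,
               concordance = if (n > 0) 100 * sum(ga[comp] == gb[comp]) / n
                             else NA_real_,
               undefined = n == 0)
  }))
}

#' Trio Mendelian consistency
#'
#' A variant is consistent for a trio when the offspring genotype is
#' compatible with one allele from each parent; variants with a missing
#' call in any trio member are skipped for that trio. Returns the
#' percentage of evaluated (variant, trio) combinations that are
#' consistent, per trio and overall.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param trios data.frame with columns `parent1`, `parent2`, `offspring`.
#' @return list with `perTrio` data.frame and `overall` (%).
#' @export
trioMendelian <- function(geno, trios) {
  need <- c("parent1", "parent2", "offspring")
  if (!all(need %in% names(trios)) ||
      !all(unlist(trios[need]) %in% colnames(geno)))
    stop("malformed trio table")
  gam <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)   # possible gametes
  perTrio <- do.call(rbind, lapply(seq_len(nrow(trios)), function(k) {
    p1 <- geno[, trios$parent1[k]]
    p2 <- geno[, trios$parent2[k]]
    off <- geno[, trios$offspring[k]]
    ok <- !is.na(p1) & !is.na(p2) & !is.na(off)
    cons <- vapply(which(ok), function(i) {
      off[i] %in% outer(gam[[as.character(p1[i])]],
                        gam[[as.character(p2[i])]], `+`)
    }, logical(1))
    data.frame(trio = k, n_evaluated = sum(ok),
               n_consistent = sum(cons),
               percent = if (sum(ok) > 0) 100 * mean(cons) else NA_real_)
  }))
  list(perTrio = perTrio,
       overall = 100 * sum(perTrio$n_consistent) /
         max(1, sum(perTrio$n_evaluated)))
}

#' Polymorphism partition across sample groups
#'
#' A variant is polymorphic within a group when at least two distinct
#' non-missing genotypes occur among the group's samples. Returns the
#' polymorphic sets per group, per-group percentages and all Venn
#' intersection cells.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param groups Named list of character vectors of sample ids.
#' @return list with `perGroup` (data.frame), `sets` (list of variant
#'   ids) and `venn` (named counts of exclusive cells).
#' @export
polymorphismPartition <- function(geno, groups) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  sets <- lapply(groups, function(ids) {
    g <- geno[, ids, drop = FALSE]
    nDistinct <- apply(g, 1, function(r) length(unique(r[!is.na(r)])))
    rownames(geno)[nDistinct >= 2L]
  })
  perGroup <- data.frame(
    group = names(groups),
    n_samples = lengths(groups),
    n_polymorphic = lengths(sets),
    percent = 100 * lengths(sets) / nrow(geno))
  # exclusive Venn cells over all non-empty membership patterns
  memb <- sapply(sets, function(s) rownames(geno) %in% s)
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = nrow(geno))
  pat <- apply(memb, 1, function(r)
    paste(names(groups)[r], collapse = "&"))
  pat[pat == ""] <- "none"
  list(perGroup = perGroup, sets = sets, venn = table(pat))
}

#' Minor-allele-frequency spectrum
#'
#' Per-variant MAF from non-missing dosage calls (heterozygotes count
#' half); reports the histogram over the requested bins and the fraction
#' of variants with MAF below `rareCut`.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param breaks Histogram breaks on [0, 0.5].
#' @param rareCut Rare-allele threshold (default 0.05).
#' @return list with `maf` (per-variant), `histogram` and
#'   `fractionRare`.
#' @export
mafSpectrum <- function(geno, breaks = seq(0, 0.5, by = 0.025),
                        rareCut = 0.05) {
  n <- rowSums(!is.na(geno))
  p <- ifelse(n > 0, rowSums(geno, na.rm = TRUE) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  h <- graphics::hist(maf[!is.na(maf)], breaks = breaks, plot = FALSE)
  list(maf = maf, histogram = h,
       fractionRare = mean(maf < rareCut, na.rm = TRUE))
}

#' Rogers' genetic distance matrix
#'
#' For two samples, the per-locus distance between allele-frequency
#' vectors (homozygote = (1,0) or (0,1), heterozygote = (0.5, 0.5)) is
#' `sqrt(0.5 * sum((p - q)^2))`, which for bi-allelic loci equals the
#' absolute dosage difference divided by two; the Rogers distance is its
#' mean over loci non-missing in both samples.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @return Symmetric distance matrix in [0, 1] with zero diagonal; `NA`
#'   for pairs without shared loci.
#' @export
rogersDistance <- function(geno) {
  if (ncol(geno) < 2L) stop("at least two samples are required")
  P <- geno / 2
  ns <- ncol(P)
  D <- matrix(0, ns, ns, dimnames = list(colnames(geno), colnames(geno)))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      d <- abs(P[, i] - P[, j])
      m <- mean(d, na.rm = TRUE)
      D[i, j] <- D[j, i] <- if (is.nan(m)) NA_real_ else m
    }
  }
  D
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared distance matrix, eigendecomposes, and
#' returns coordinates scaled by the square roots of the positive
#' eigenvalues, ordered by eigenvalue.
#'
#' @param D Square symmetric non-negative distance matrix.
#' @param nAxes Number of axes to return.
#' @return list with `coords` (samples x axes) and `explained`
#'   (proportions of positive-eigenvalue variance).
#' @export
pcoa <- function(D, nAxes = 2) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  D <- as.matrix(D)
  fit <- stats::cmdscale(stats::as.dist(D), k = min(nAxes, nrow(D) - 1),
                         eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  expl <- if (length(pos)) fit$eig[seq_len(ncol(fit$points))] / sum(pos)
          else rep(0, ncol(fit$points))
  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0)
    coords <- matrix(0, nrow(D), nAxes,
                     dimnames = list(rownames(D), NULL))
  list(coords = coords, explained = pmax(expl, 0))
}

#' Pairwise LD (r-squared) within physical windows
#'
#' Squared Pearson correlation of genotype dosages (0/1/2,
#' pairwise-complete) for variant pairs on the same chromosome within
#' `windowBp`. Monomorphic variants are excluded.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param positions data.frame with columns `chrom`, `pos` (rownames or
#'   `id` matching the genotype rownames).
#' @param windowBp Maximal pair distance (default 50 Mb).
#' @return data.frame with columns `chrom`, `dist`, `r2`.
#' @export
ldR2 <- function(geno, positions, windowBp = 5e7) {
  ids <- if (!is.null(positions$id)) positions$id else rownames(positions)
  stopifnot(all(ids %in% rownames(geno)))
  out <- list()
  for (c0 in unique(positions$chrom)) {
    sel <- positions$chrom == c0
    p <- positions$pos[sel]
    o <- order(p); p <- p[o]
    g <- t(geno[ids[sel][o], , drop = FALSE])       # samples x variants
    keep <- apply(g, 2, function(x) length(unique(x[!is.na(x)])) >= 2L)
    g <- g[, keep, drop = FALSE]; p <- p[keep]
    nv <- ncol(g)
    if (nv < 2L) next
    cc <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
    idx <- which(upper.tri(cc), arr.ind = TRUE)
    d <- p[idx[, 2]] - p[idx[, 1]]
    inWin <- d <= windowBp
    r2 <- cc[idx][inWin]^2
    out[[c0]] <- data.frame(chrom = c0, dist = d[inWin], r2 = r2)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), dist = numeric(),
                      r2 = numeric())
  res[!is.na(res$r2), , drop = FALSE]
}

#' LD-decay distance at a threshold
#'
#' Pairs are binned by distance (log-spaced bins), bin-mean r-squared is
#' made monotone non-increasing by isotonic regression, and the smallest
#' distance where the fitted curve crosses the threshold (linear
#' interpolation between bin midpoints) is returned. Returns 0 (flagged)
#' when the curve starts below the threshold and `NA` (flagged) when it
#' never crosses or fewer than `minPairs` pairs are available.
#'
#' @param pairs data.frame with columns `dist` (bp) and `r2`.
#' @param threshold Crossing threshold (default 0.2).
#' @param binsPerDecade Log-spaced distance bins per decade.
#' @param minPairs Minimal number of pairs.
#' @return list with `decay_kb`, `flag` ("ok", "below_at_start",
#'   "never_crosses", "too_few_pairs") and the binned curve.
#' @export
ldDecayDistance <- function(pairs, threshold = 0.2, binsPerDecade = 50,
                            minPairs = 20) {
  if (nrow(pairs) < minPairs)
    return(list(decay_kb = NA_real_, flag = "too_few_pairs", curve = NULL))
  d <- pairs$dist[pairs$dist > 0]
  r2 <- pairs$r2[pairs$dist > 0]
  lo <- floor(log10(min(d)) * binsPerDecade)
  hi <- ceiling(log10(max(d)) * binsPerDecade)
  edges <- 10^(seq(lo, hi) / binsPerDecade)
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  mids <- sqrt(edges[-length(edges)] * edges[-1])
  binMean <- tapply(r2, bin, mean)
  bx <- mids[as.integer(names(binMean))]
  keep <- !is.na(bx) & !is.na(binMean)
  bx <- bx[keep]; by <- as.numeric(binMean[keep])
  o <- order(bx); bx <- bx[o]; by <- by[o]
  # monotone non-increasing fit
  fit <- -stats::isoreg(-by)$yf
  curve <- data.frame(dist = bx, r2 = fit)
  if (fit[1] < threshold)
    return(list(decay_kb = 0, flag = "below_at_start", curve = curve))
  if (all(fit >= threshold))
    return(list(decay_kb = NA_real_, flag = "never_crosses", curve = curve))
  k <- which(fit < threshold)[1]
  x1 <- bx[k - 1]; x2 <- bx[k]; y1 <- fit[k - 1]; y2 <- fit[k]
  xc <- if (y1 == y2) x2 else x1 + (y1 - threshold) * (x2 - x1) / (y1 - y2)
  list(decay_kb = xc / 1000, flag = "ok", curve = curve)
}

#' Greedy LD pruning
#'
#' Left-to-right scan per chromosome: a variant is dropped when its
#' r-squared with any retained variant within `windowBp` exceeds `r2Max`.
#' Deterministic.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param positions data.frame with `chrom`, `pos` and rownames/`id`.
#' @param r2Max Pruning threshold (default 0.8).
#' @param windowBp Window in bp.
#' @return Character vector of retained variant ids.
#' @export
ldPrune <- function(geno, positions, r2Max = 0.8, windowBp = 5e7) {
  ids <- if (!is.null(positions$id)) positions$id else rownames(positions)
  retained <- character()
  for (c0 in unique(positions$chrom)) {
    sel <- which(positions$chrom == c0)
    o <- sel[order(positions$pos[sel])]
    keptIdx <- integer()
    for (i in o) {
      inWin <- keptIdx[positions$pos[keptIdx] >=
                         positions$pos[i] - windowBp]
      drop <- FALSE
      for (j in inWin) {
        r <- suppressWarnings(stats::cor(geno[ids[i], ], geno[ids[j], ],
                                         use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 > r2Max) { drop <- TRUE; break }
      }
      if (!drop) keptIdx <- c(keptIdx, i)
    }
    retained <- c(retained, ids[keptIdx])
  }
  retained
}

#' Drop high-missingness variants and impute the rest by mode
#'
#' Variants with at least `maxMissingFraction` missing calls are dropped;
#' remaining missing calls are filled with the variant's most frequent
#' genotype (ties broken towards the lower dosage). Deterministic.
#'
#' @param geno Integer dosage matrix (variants x samples).
#' @param maxMissingFraction Exclusion threshold (default 0.10).
#' @return Completed dosage matrix (possibly fewer rows).
#' @export
imputeMissing <- function(geno, maxMissingFraction = 0.10) {
  missFrac <- rowMeans(is.na(geno))
  g <- geno[missFrac < maxMissingFraction, , drop = FALSE]
  for (i in which(rowSums(is.na(g)) > 0)) {
    tab <- tabulate(g[i, ] + 1L, nbins = 3L)
    mode <- which.max(tab) - 1L
    g[i, is.na(g[i, ])] <- mode
  }
  g
}
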