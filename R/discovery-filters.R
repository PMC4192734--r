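#' Discovery filters: reduce caller output to high-confidence candidates
#'
#' The filters below implement the two-round cascade used to reduce raw
#' dual-caller variant records to the high-confidence bi-allelic candidate
#' set: caller intersection; round 1 on site quality, total depth,
#' presence of the reference allele and homozygous non-reference support;
#' round 2 on genomic copy number, MQ0 fraction, relative coverage and a
#' stricter quality cut; a flanking-distance rule; and the bi-allelic
#' restriction. Each filter returns the retained [SeqVariantSet-class]
#' plus a [filterReport()] row.
#'
#' @name discovery-filters
NULL

.reportRow <- function(name, nIn, nPass) {
  data.frame(filter = name, input = nIn, pass = nPass, fail = nIn - nPass)
}

#' Build a filter report
#'
#' @param ... data.frames of report rows.
#' @return data.frame with columns filter, input, pass, fail
#'   (input = pass + fail for every row).
#' @export
filterReport <- function(...) {
  do.call(rbind, list(...))
}

#' @describeIn discovery-filters Retain records supported by both callers.
#' @param records A [SeqVariantSet-class].
#' @export
intersectCallers <- function(records) {
  rd <- mcols(variantInfo(records))
  if (is.null(rd$samCall) || is.null(rd$gatkCall) ||
      anyNA(rd$samCall) || anyNA(rd$gatkCall))
    stop("caller-support flags must be present on every record")
  keep <- rd$samCall & rd$gatkCall
  list(records = records[keep, ],
       report = .reportRow("caller_intersection", length(keep), sum(keep)))
}

#' @describeIn discovery-filters Round-1 filters: site quality >=
#'   `qualityMin`, `depthLow <= DP < depthHigh` (half-open), at least one
#'   line with a homozygous reference call, and at least
#'   `minHomNonrefLines` lines with homozygous non-reference calls.
#' @param qualityMin,depthLow,depthHigh,minHomNonrefLines Round-1
#'   thresholds.
#' @export
applyRound1Filters <- function(records, qualityMin = 50,
                               depthLow = 50, depthHigh = 3000,
                               minHomNonrefLines = 2) {
  stopifnot(depthLow < depthHigh, qualityMin > 0)
  rd <- mcols(variantInfo(records))
  G <- seqGenotypes(records)
  nHomRef <- rowSums(G == 0L, na.rm = TRUE)
  nHomAlt <- rowSums(G == 2L, na.rm = TRUE)
  passQ <- rd$qual >= qualityMin
  passDP <- rd$DP >= depthLow & rd$DP < depthHigh
  passRef <- nHomRef >= 1L
  passHomAlt <- nHomAlt >= minHomNonrefLines
  keep <- passQ & passDP & passRef & passHomAlt
  rep <- filterReport(
    .reportRow("r1_quality", length(keep), sum(passQ)),
    .reportRow("r1_depth", length(keep), sum(passDP)),
    .reportRow("r1_reference_allele", length(keep), sum(passRef)),
    .reportRow("r1_hom_nonref", length(keep), sum(passHomAlt)),
    .reportRow("round1_combined", length(keep), sum(keep)))
  list(records = records[keep, ], report = rep)
}

#' @describeIn discovery-filters Round-2 filters: copy number < `cnMax`,
#'   MQ0 fraction <= `mq0Max`, site coverage <= `coverageFoldMax` times
#'   the panel-wide mean site depth, and quality >= `qualityMin2`.
#' @param cnMax,mq0Max,coverageFoldMax,qualityMin2 Round-2 thresholds.
#' @param meanCoverage Panel-wide mean site depth; computed from the
#'   records when NULL.
#' @export
applyRound2Filters <- function(records, cnMax = 50, mq0Max = 0.05,
                               coverageFoldMax = 6, qualityMin2 = 100,
                               meanCoverage = NULL) {
  rd <- mcols(variantInfo(records))
  if (anyNA(rd$CN) || anyNA(rd$MQ0F))
    stop("CN and MQ0F annotations must be present on every record")
  if (is.null(meanCoverage)) meanCoverage <- mean(rd$DP)
  passCN <- rd$CN < cnMax
  passMQ0 <- rd$MQ0F <= mq0Max
  passCov <- rd$DP <= coverageFoldMax * meanCoverage
  passQ <- rd$qual >= qualityMin2
  keep <- passCN & passMQ0 & passCov & passQ
  rep <- filterReport(
    .reportRow("r2_copy_number", length(keep), sum(passCN)),
    .reportRow("r2_mq0_fraction", length(keep), sum(passMQ0)),
    .reportRow("r2_coverage_fold", length(keep), sum(passCov)),
    .reportRow("r2_quality", length(keep), sum(passQ)),
    .reportRow("round2_combined", length(keep), sum(keep)))
  list(records = records[keep, ], report = rep)
}

#' @describeIn discovery-filters Retain records whose nearest neighboring
#'   variant is at least `minDistance` bp away on at least one side;
#'   chromosome ends count as a clear side. Unsorted input is sorted
#'   internally.
#' @param minDistance Minimal flanking distance in bp.
#' @export
flankingDistanceFilter <- function(records, minDistance = 20) {
  info <- variantInfo(records)
  chr <- as.character(seqnames(info))
  pos <- start(info)
  o <- order(chr, pos)
  if (any(o != seq_along(o))) message("input not sorted; sorting internally")
  keep <- logical(length(pos))
  for (c0 in unique(chr)) {
    idx <- o[chr[o] == c0]
    p <- pos[idx]
    leftGap <- c(Inf, diff(p))
    rightGap <- c(diff(p), Inf)
    keep[idx] <- leftGap >= minDistance | rightGap >= minDistance
  }
  list(records = records[keep, ],
       report = .reportRow("flanking_distance", length(keep), sum(keep)))
}

#' @describeIn discovery-filters Remove records with more than one
#'   alternative allele.
#' @export
restrictBiallelic <- function(records) {
  alt <- mcols(variantInfo(records))$alt
  nAlt <- vapply(strsplit(as.character(alt), ","), length, integer(1))
  keep <- nAlt <= 1L
  list(records = records[keep, ],
       report = .reportRow("biallelic", length(keep), sum(keep)))
}

#' @describeIn discovery-filters Set every heterozygous genotype to
#'   missing; homozygous calls are untouched. Idempotent.
#' @export
maskHeterozygousCalls <- function(records) {
  G <- seqGenotypes(records)
  G[G == 1L] <- NA_integer_
  SummarizedExperiment::assay(records, "geno") <- G
  records
}

#' Run the complete discovery-filter cascade
#'
#' Caller intersection, round 1, round 2, flanking distance, bi-allelic
#' restriction, then heterozygote masking, in the documented order.
#'
#' @param records A [SeqVariantSet-class].
#' @param ... Threshold arguments forwarded to the individual filters.
#' @return A list with `records` (filtered, het-masked) and `report`.
#' @export
runDiscoveryCascade <- function(records, ...) {
  args <- list(...)
  s1 <- intersectCallers(records)
  s2 <- do.call(applyRound1Filters,
                c(list(s1$records), args[names(args) %in%
                  c("qualityMin", "depthLow", "depthHigh",
                    "minHomNonrefLines")]))
  s3 <- do.call(applyRound2Filters,
                c(list(s2$records), args[names(args) %in%
                  c("cnMax", "mq0Max", "coverageFoldMax", "qualityMin2",
                    "meanCoverage")]))
  s4 <- do.call(flankingDistanceFilter,
                c(list(s3$records), args[names(args) %in% "minDistance"]))
  s5 <- restrictBiallelic(s4$records)
  out <- maskHeterozygousCalls(s5$records)
  list(records = out,
       report = filterReport(s1$report, s2$report, s3$report,
                             s4$report, s5$report))
}

#' False discovery rate of heterozygous and homozygous calls
#'
#' A sequencing call of a class (het or hom) is a false discovery when it
#' disagrees with a non-missing truth call at the same sample and variant.
#' Returns `NA` with an `undefined` flag when a class has no comparable
#' calls.
#'
#' @param seqCalls,truthCalls Genotype matrices (0/1/2/NA) sharing
#'   dimnames (variants x samples).
#' @return list with `FDR_het`, `FDR_hom`, and counts.
#' @export
fdrByClass <- function(seqCalls, truthCalls) {
  common_v <- intersect(rownames(seqCalls), rownames(truthCalls))
  common_s <- intersect(colnames(seqCalls), colnames(truthCalls))
  if (!length(common_v) || !length(common_s))
    stop("call matrices share no variants or samples")
  s <- seqCalls[common_v, common_s, drop = FALSE]
  t <- truthCalls[common_v, common_s, drop = FALSE]
  comparable <- !is.na(s) & !is.na(t)
  isHet <- s == 1L & comparable
  isHom <- (s == 0L | s == 2L) & comparable
  mism <- s != t
  nHet <- sum(isHet); nHom <- sum(isHom)
  list(
    FDR_het = if (nHet > 0) sum(mism[isHet]) / nHet else NA_real_,
    FDR_hom = if (nHom > 0) sum(mism[isHom]) / nHom else NA_real_,
    n_het = nHet, n_hom = nHom,
    undefined_het = nHet == 0, undefined_hom = nHom == 0)
}

#' Per-variant non-reference allele frequency within a pool
#'
#' The ratio of homozygous non-reference calls to all non-missing calls
#' per variant within the given pool samples; intended for het-masked
#' records, where only homozygous calls remain.
#'
#' @param records A [SeqVariantSet-class] (het calls already masked).
#' @param poolSamples Character vector of sample ids.
#' @return Numeric vector (one per variant); `NA` when a variant has no
#'   non-missing calls in the pool.
#' @export
nonrefFrequency <- function(records, poolSamples) {
  if (!length(poolSamples)) stop("pool must contain at least one sample")
  G <- seqGenotypes(records)
  miss <- setdiff(poolSamples, colnames(G))
  if (length(miss)) stop("unknown pool samples: ", paste(miss, collapse = ", "))
  G <- G[, poolSamples, drop = FALSE]
  nCalled <- rowSums(!is.na(G))
  nAlt <- rowSums(G == 2L, na.rm = TRUE)
  ifelse(nCalled > 0, nAlt / nCalled, NA_real_)
}
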