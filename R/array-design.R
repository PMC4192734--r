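#' Forward variants classified PolyHighResolution in both analyses
#'
#' @param categories data.frame with columns `id`, `without`, `with`
#'   (categories without and with inbred correction).
#' @return Character vector of forwarded ids.
#' @export
forwardPhrStable <- function(categories) {
  stopifnot(all(c("id", "without", "with") %in% names(categories)))
  categories$id[categories$without == "PolyHighResolution" &
                categories$with == "PolyHighResolution"]
}

#' Select OTV-stable variants passing the custom cluster thresholds
#'
#' Variants classified OTV both with and without inbred correction are
#' kept when they are polymorphic, have at most `maxMissingFraction`
#' missing calls, and pass FLD > `fldMin`, HetSO > `hetsoMin` and
#' HomRO > `homroMin`; when FLD or HetSO is undefined (two-cluster case)
#' the homFLD > `homfldMin` rule applies instead.
#'
#' @param categories data.frame with `id`, `without`, `with`.
#' @param metrics data.frame with rownames = variant ids and columns
#'   `FLD`, `homFLD`, `HetSO`, `HomRO` (from the inbred-corrected
#'   analysis).
#' @param calls Character call matrix (variants x samples).
#' @param maxMissingFraction,fldMin,hetsoMin,homroMin,homfldMin
#'   Thresholds.
#' @return Character vector of selected ids.
#' @export
selectOtvStable <- function(categories, metrics, calls,
                            maxMissingFraction = 0.10,
                            fldMin = 3.5, hetsoMin = -3.5,
                            homroMin = 1, homfldMin = 5) {
  otvIds <- categories$id[categories$without == "OTV" &
                          categories$with == "OTV"]
  keep <- vapply(otvIds, function(v) {
    cl <- calls[v, ]
    nonmiss <- cl[!is.na(cl)]
    geno <- nonmiss[nonmiss != "OO"]
    if (length(unique(geno)) < 2L) return(FALSE)       # monomorphic
    if (mean(is.na(cl)) > maxMissingFraction) return(FALSE)
    m <- metrics[v, ]
    if (is.na(m$FLD) || is.na(m$HetSO)) {
      !is.na(m$homFLD) && m$homFLD > homfldMin &&
        (!is.na(m$HomRO) && m$HomRO > homroMin)
    } else {
      m$FLD > fldMin && m$HetSO > hetsoMin &&
        (!is.na(m$HomRO) && m$HomRO > homroMin)
    }
  }, logical(1))
  otvIds[keep]
}

#' Class weight of a category transition
#'
#' OTV-stable variants and NoMinorHom-to-PolyHighResolution promotions
#' weigh 10; any other promotion to PolyHighResolution upon inbred
#' correction weighs 5; everything else weighs 0.
#'
#' @param without,with Character vectors of categories.
#' @return Numeric vector in {10, 5, 0}.
#' @export
classWeight <- function(without, with) {
  valid <- c("PolyHighResolution", "NoMinorHom", "MonoHighResolution",
             "OTV", "CallRateBelowThreshold", "Other")
  if (!all(c(without, with) %in% valid))
    stop("unknown category label")
  ifelse(without == "OTV" & with == "OTV", 10,
  ifelse(without == "NoMinorHom" & with == "PolyHighResolution", 10,
  ifelse(with == "PolyHighResolution" & without != "PolyHighResolution", 5,
         0)))
}

#' Concordance of array calls with sequencing calls
#'
#' Per variant, the number of matching calls across the discovery samples
#' divided by the number of pairs where both calls are non-missing.
#' Variants without comparable pairs get 0 with a flag.
#'
#' @param arrayCalls Integer dosage matrix (variants x samples) of array
#'   calls.
#' @param seqCalls Integer dosage matrix of sequencing calls.
#' @param discoverySamples Character vector of the sequenced sample ids.
#' @return data.frame with `concordance` in [0,1] and `undefined` flag.
#' @export
sequenceConcordance <- function(arrayCalls, seqCalls, discoverySamples) {
  common <- intersect(intersect(colnames(arrayCalls), colnames(seqCalls)),
                      discoverySamples)
  if (!length(common)) stop("no overlapping discovery samples")
  vids <- intersect(rownames(arrayCalls), rownames(seqCalls))
  a <- arrayCalls[vids, common, drop = FALSE]
  s <- seqCalls[vids, common, drop = FALSE]
  comp <- !is.na(a) & !is.na(s)
  nComp <- rowSums(comp)
  nMatch <- rowSums(comp & (a == s), na.rm = TRUE)
  data.frame(row.names = vids,
             concordance = ifelse(nComp > 0, nMatch / nComp, 0),
             undefined = nComp == 0)
}

#' Bin-representation score
#'
#' For each bin, the deviation of its variant count `n` from the mean `m`
#' of up to `window` bins on each side (truncated at chromosome ends),
#' scaled to [-1, 1] as `(m - n) / (m + n)` (0 when both are 0). Positive
#' scores mark under-represented bins.
#'
#' @param binCounts Numeric vector of per-bin variant counts along one
#'   chromosome.
#' @param window Number of bins on each side.
#' @return Numeric vector of scores, one per bin.
#' @export
binRepresentationScore <- function(binCounts, window = 5) {
  if (any(binCounts < 0)) stop("bin counts must be non-negative")
  n <- length(binCounts)
  vapply(seq_len(n), function(i) {
    nb <- c(seq(max(1, i - window), i - 1),
            seq(i + 1, min(n, i + window)))
    nb <- nb[nb >= 1 & nb <= n & nb != i]
    m <- if (length(nb)) mean(binCounts[nb]) else 0
    own <- binCounts[i]
    if (m + own > 0) (m - own) / (m + own) else 0
  }, numeric(1))
}

#' Total rank of a variant in the voting system
#'
#' `rank = 35 w + 90 c + 10 s` with class weight `w` in {10, 5, 0},
#' sequence concordance `c` in [0, 1] and bin-representation score `s`
#' in [-1, 1].
#'
#' @param w,c,s Vectors of the three components.
#' @return Numeric vector of total ranks.
#' @export
rankVariant <- function(w, c, s) {
  if (!all(w %in% c(10, 5, 0))) stop("class weight must be 10, 5 or 0")
  if (any(c < 0 | c > 1)) stop("concordance must be in [0, 1]")
  if (any(s < -1 | s > 1)) stop("bin score must be in [-1, 1]")
  35 * w + 90 * c + 10 * s
}

#' Resolve duplicate probes to one probe per variant
#'
#' The probe with the higher rank wins; ties are broken by a seeded
#' random draw, so the resolution is reproducible.
#'
#' @param probes data.frame with columns `id` (variant), `probe_id`,
#'   `rank`.
#' @param seed Integer seed.
#' @return data.frame with one row per variant.
#' @export
resolveDuplicateProbes <- function(probes, seed = 1L) {
  withSeed(substreamSeed(seed, "probe-ties"), {
    tie <- stats::runif(nrow(probes))
    o <- order(probes$id, -probes$rank, tie)
    p <- probes[o, , drop = FALSE]
    p[!duplicated(p$id), , drop = FALSE]
  })
}

#' Assemble the final array design
#'
#' Forwarded variants (stable PolyHighResolution and selected OTV-stable
#' sets) are included unconditionally; the remainder is filled by
#' descending rank with seeded tie-breaking up to `targetSize`. An
#' exclusion list (e.g. erroneously mapped legacy SNPs) is removed first.
#'
#' @param forwarded Character vector of unconditionally included ids.
#' @param ranked data.frame with columns `id` and `rank` for the
#'   remaining candidates.
#' @param targetSize Total number of variants on the array.
#' @param exclude Character vector of ids removed before selection.
#' @param seed Integer seed for rank ties.
#' @return Character vector of selected ids (forwarded first, then by
#'   descending rank).
#' @export
assembleFinal <- function(forwarded, ranked, targetSize,
                          exclude = character(), seed = 1L) {
  forwarded <- setdiff(unique(forwarded), exclude)
  ranked <- ranked[!ranked$id %in% c(forwarded, exclude), , drop = FALSE]
  if (targetSize < length(forwarded))
    stop("target size smaller than the forwarded set")
  nFill <- targetSize - length(forwarded)
  if (nFill > nrow(ranked)) {
    warning("candidate pool smaller than target; returning all candidates")
    nFill <- nrow(ranked)
  }
  filled <- withSeed(substreamSeed(seed, "final-ties"), {
    tie <- stats::runif(nrow(ranked))
    ranked$id[order(-ranked$rank, tie)][seq_len(nFill)]
  })
  c(forwarded, filled)
}

#' Annotate variants against gene models
#'
#' Each variant receives one or more labels: exon/UTR/intron labels when
#' the gene models carry feature structure, a plain `genic` label when
#' only gene intervals are available (the coding/intron/UTR distinction
#' then collapses, and the summary says so), `upstream-5kb` /
#' `downstream-5kb` within `flank` bp of a gene (strand-aware), and
#' `intergenic` otherwise. Gene-tagging percentages are reported at both
#' stringencies (gene body only, and including flanks).
#'
#' @param variants `GRanges` of variant positions.
#' @param geneModels `GRanges` of genes; if a `type` metadata column with
#'   exon/intron/UTR features is present it is used, else plain intervals.
#' @param flank Flank width in bp (default 5000).
#' @return list with `labels` (per-variant character list), `summary`
#'   (genes tagged at both stringencies, with percentages) and
#'   `collapsed` (logical: plain-interval mode).
#' @export
annotateVariants <- function(variants, geneModels, flank = 5000) {
  if (any(start(geneModels) > end(geneModels)))
    stop("malformed gene intervals")
  hasFeatures <- "type" %in% names(mcols(geneModels)) &&
    any(mcols(geneModels)$type %in% c("exon", "CDS", "UTR",
                                      "five_prime_UTR", "three_prime_UTR"))
  geneIds <- if ("gene_id" %in% names(mcols(geneModels)))
    mcols(geneModels)$gene_id else paste0("gene", seq_along(geneModels))

  if (hasFeatures) {
    genesOnly <- geneModels[mcols(geneModels)$type %in% "gene"]
    if (!length(genesOnly)) genesOnly <- geneModels
  } else {
    genesOnly <- geneModels
  }
  gOnly_ids <- if ("gene_id" %in% names(mcols(genesOnly)))
    mcols(genesOnly)$gene_id else paste0("gene", seq_along(genesOnly))
  nGenes <- length(unique(gOnly_ids))

  labels <- rep(list(character()), length(variants))
  hitsBody <- GenomicRanges::findOverlaps(variants, genesOnly)
  for (k in seq_along(hitsBody)) {
    i <- S4Vectors::queryHits(hitsBody)[k]
    lab <- if (hasFeatures) {
      j <- S4Vectors::subjectHits(hitsBody)[k]
      feats <- geneModels[mcols(geneModels)$gene_id %in% gOnly_ids[j] &
                          !mcols(geneModels)$type %in% "gene"]
      types <- as.character(mcols(feats)$type[
        IRanges::overlapsAny(feats, variants[i])])
      if (!length(types)) "intron"
      else if (any(types %in% c("CDS", "exon"))) "coding"
      else "UTR"
    } else "genic"
    labels[[i]] <- union(labels[[i]], lab)
  }

  up <- GenomicRanges::flank(genesOnly, flank, start = TRUE)
  dn <- GenomicRanges::flank(genesOnly, flank, start = FALSE)
  upHit <- IRanges::overlapsAny(variants, up)
  dnHit <- IRanges::overlapsAny(variants, dn)
  for (i in which(upHit))
    labels[[i]] <- union(labels[[i]], "upstream-5kb")
  for (i in which(dnHit))
    labels[[i]] <- union(labels[[i]], "downstream-5kb")
  none <- lengths(labels) == 0L
  labels[none] <- list("intergenic")

  taggedBody <- unique(gOnly_ids[S4Vectors::subjectHits(hitsBody)])
  withFlanks <- GenomicRanges::resize(
    genesOnly, width(genesOnly) + 2 * flank, fix = "center")
  hitsFlank <- GenomicRanges::findOverlaps(variants, withFlanks)
  taggedFlank <- unique(gOnly_ids[S4Vectors::subjectHits(hitsFlank)])

  list(labels = labels,
       summary = data.frame(
         stringency = c("gene_body", "with_flanks"),
         genes_tagged = c(length(taggedBody), length(taggedFlank)),
         genes_total = nGenes,
         percent = 100 * c(length(taggedBody), length(taggedFlank)) /
           nGenes),
       collapsed = !hasFeatures)
}

#' Spacing and density statistics of an array design
#'
#' Mean, median and maximal neighbor spacing in kb, per chromosome and
#' overall; the overall mean density can also be computed directly as
#' genome size over variant count. With a genetic map (data.frame with
#' columns `chrom`, `pos`, `cM`), cM positions are linearly interpolated
#' at the variant positions (constant beyond the map ends) and the mean
#' cM spacing is reported.
#'
#' @param variants `GRanges` of selected variant positions.
#' @param chromLengths Named numeric vector of chromosome lengths.
#' @param geneticMap Optional genetic map data.frame.
#' @return list with `perChrom` (data.frame), `overall` (named vector,
#'   kb), and optionally `meanCM`.
#' @export
densityStats <- function(variants, chromLengths, geneticMap = NULL) {
  if (!length(variants)) stop("design is empty")
  chr <- as.character(seqnames(variants))
  pos <- start(variants)
  perChrom <- do.call(rbind, lapply(unique(chr), function(c0) {
    p <- sort(pos[chr == c0])
    gaps <- diff(p) / 1000
    data.frame(chrom = c0, n = length(p),
               mean_kb = if (length(gaps)) mean(gaps) else NA,
               median_kb = if (length(gaps)) stats::median(gaps) else NA,
               max_kb = if (length(gaps)) max(gaps) else NA)
  }))
  allGaps <- unlist(lapply(unique(chr), function(c0)
    diff(sort(pos[chr == c0])))) / 1000
  overall <- c(n = length(variants),
               mean_kb = mean(allGaps),
               median_kb = stats::median(allGaps),
               max_kb = max(allGaps),
               density_kb = sum(as.double(chromLengths)) / 1000 /
                 length(variants))
  out <- list(perChrom = perChrom, overall = overall)
  if (!is.null(geneticMap)) {
    cmPos <- unlist(lapply(unique(chr), function(c0) {
      mapC <- geneticMap[geneticMap$chrom == c0, , drop = FALSE]
      p <- sort(pos[chr == c0])
      if (nrow(mapC) < 2) return(rep(NA_real_, length(p)))
      stats::approx(mapC$pos, mapC$cM, xout = p, rule = 2)$y
    }))
    out$meanCM <- mean(abs(diff(cmPos)), na.rm = TRUE)
  }
  out
}
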