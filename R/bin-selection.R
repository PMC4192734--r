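#' Partition a genome into fixed-width bins
#'
#' Bins tile each chromosome without overlap; the last bin of a chromosome
#' is truncated. With a single unnamed aggregate length the genome is
#' binned as one sequence (the mode in which a 2.066 Gb genome yields
#' 20,660 bins of 100 kb); per-chromosome lengths are the operational
#' default.
#'
#' @param chromLengths Numeric vector of chromosome lengths (named), or a
#'   single aggregate genome size.
#' @param binWidth Bin width in bp (default 100 kb).
#' @return A `GRanges` of bins with metadata column `bin_id`.
#' @export
#' @examples
#' length(partitionBins(2066e6, 1e5))   # 20,660
partitionBins <- function(chromLengths, binWidth = 1e5) {
  if (binWidth <= 0) stop("bin width must be positive")
  if (any(chromLengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(names(chromLengths)))
    names(chromLengths) <- if (length(chromLengths) == 1L) "genome" else
      paste0("chr", seq_along(chromLengths))
  grl <- lapply(names(chromLengths), function(chr) {
    L <- chromLengths[[chr]]
    n <- ceiling(L / binWidth)
    st <- (seq_len(n) - 1) * binWidth + 1
    en <- pmin(seq_len(n) * binWidth, L)
    GRanges(chr, IRanges(st, en))
  })
  bins <- do.call(c, grl)
  mcols(bins)$bin_id <- paste0(as.character(seqnames(bins)), ":",
                               start(bins) - 1)
  bins
}

#' Average per-bin budget after subtracting fixed content
#'
#' @param totalCapacity Total screening-array capacity (default 1.23 M).
#' @param fixedCoding Number of fixed coding variants.
#' @param fixedLegacyProbes Number of fixed legacy-array probes (two per
#'   legacy SNP).
#' @param nBins Number of 100 kb bins.
#' @return Rounded average budget per bin.
#' @export
#' @examples
#' computeBinBudget()   # 48
computeBinBudget <- function(totalCapacity = 1.23e6,
                             fixedCoding = 150394,
                             fixedLegacyProbes = 2 * 48324,
                             nBins = 20660) {
  stopifnot(totalCapacity > 0, nBins > 0)
  rem <- totalCapacity - fixedCoding - fixedLegacyProbes
  if (rem < 0) stop("capacity smaller than the fixed variant set")
  round(rem / nBins)
}

#' Classify a pool allele frequency as intermediate (A) or extreme (B)
#'
#' Class A for frequencies in [0.2, 0.8] (boundaries inclusive), class B
#' for frequencies below 0.2 or above 0.8; `NA` propagates.
#'
#' @param freq Numeric vector of non-reference allele frequencies.
#' @return Character vector "A"/"B"/NA.
#' @export
classifyFrequency <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must be in [0, 1]")
  ifelse(is.na(freq), NA_character_,
         ifelse(freq >= 0.2 & freq <= 0.8, "A", "B"))
}

#' Quota cell of a candidate from its pool frequency classes
#'
#' "Specific for Flint" is the Dent "A" | Flint "B" combination and
#' "specific for Dent" the Dent "B" | Flint "A" one, exactly as the
#' selection scheme defines them; "common" is A|A and "rare" B|B.
#' Candidates with an undefined class in either pool get NA.
#'
#' @param dentClass,flintClass Character vectors of "A"/"B"/NA.
#' @return Character vector in {flint_specific, dent_specific, common,
#'   rare, NA}.
#' @export
quotaCell <- function(dentClass, flintClass) {
  out <- rep(NA_character_, length(dentClass))
  out[dentClass == "A" & flintClass == "B"] <- "flint_specific"
  out[dentClass == "B" & flintClass == "A"] <- "dent_specific"
  out[dentClass == "A" & flintClass == "A"] <- "common"
  out[dentClass == "B" & flintClass == "B"] <- "rare"
  out
}

# Largest-remainder (Hamilton) apportionment of `total` among cells with
# the given quota fractions.
.largestRemainder <- function(total, quotas) {
  raw <- total * quotas / sum(quotas)
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  base
}

# Apportion `total` draws among quota cells given available counts,
# redistributing shortfall proportionally to the remaining cells.
.apportionWithShortfall <- function(total, quotas, avail) {
  take <- stats::setNames(rep(0, length(quotas)), names(quotas))
  active <- rep(TRUE, length(quotas))
  remaining <- total
  repeat {
    if (remaining <= 0 || !any(active)) break
    alloc <- .largestRemainder(remaining, ifelse(active, quotas, 0))
    got <- pmin(alloc, avail - take)
    take <- take + got
    remaining <- remaining - sum(got)
    newActive <- active & (take < avail)
    if (identical(newActive, active) && sum(got) == 0) break
    active <- newActive
  }
  take
}

#' Select candidates for one 100 kb bin
#'
#' Three fill cases: (i) all recommended-or-neutral candidates are taken
#' when fewer than `budget` exist; (ii) recommended candidates are fixed
#' when their number does not exceed the budget and the remainder is drawn
#' from neutral candidates per the quota cells; (iii) recommended
#' candidates are themselves drawn per quotas when at least `budget` are
#' present. Quota draws are seeded-random within each cell; shortfall in a
#' cell is redistributed proportionally to the remaining cells.
#'
#' @param candidates data.frame with columns `id`, `category`
#'   ("recommended"/"neutral"/other) and `cell` (from [quotaCell()]).
#' @param budget Per-bin budget.
#' @param quotas Named quota fractions for the four cells.
#' @param seed Integer seed.
#' @return Character vector of selected candidate ids.
#' @export
assembleBin <- function(candidates, budget = 48,
                        quotas = c(flint_specific = 1/3,
                                   dent_specific = 1/3,
                                   common = 1/6, rare = 1/6),
                        seed = 1L) {
  if (budget < 0) stop("budget must be non-negative")
  if (nrow(candidates) == 0L) return(character())
  rec <- candidates[candidates$category == "recommended", , drop = FALSE]
  neu <- candidates[candidates$category == "neutral", , drop = FALSE]
  eligible <- rbind(rec, neu)
  if (nrow(eligible) < budget) return(eligible$id)        # case (i)

  drawPerQuota <- function(pool, n, streamTag) {
    if (n <= 0 || nrow(pool) == 0L) return(character())
    cellOf <- pool$cell
    cellOf[is.na(cellOf)] <- "rare"      # undefined classes fall to rare
    avail <- vapply(names(quotas),
                    function(cl) sum(cellOf == cl), numeric(1))
    take <- .apportionWithShortfall(min(n, nrow(pool)), quotas, avail)
    withSeed(substreamSeed(seed, streamTag), {
      unlist(lapply(names(quotas), function(cl) {
        ids <- pool$id[cellOf == cl]
        if (take[[cl]] >= length(ids)) ids
        else sample(ids, take[[cl]])
      }), use.names = FALSE)
    })
  }

  if (nrow(rec) <= budget) {                              # case (ii)
    c(rec$id, drawPerQuota(neu, budget - nrow(rec), "bin-neutral"))
  } else {                                                # case (iii)
    drawPerQuota(rec, budget, "bin-recommended")
  }
}

#' Fill under-represented 50 kb bins
#'
#' For 100 kb bins filled below their budget, each constituent 50 kb bin
#' holding fewer than `threshold` selected variants is topped up: first
#' with seeded-random picks from recommended candidates having at least
#' `minCalledLines` called lines and a homozygous-reference count in
#' `[homRefMin, homRefMaxExcl)` (at most `balancedCap` such picks per
#' 50 kb bin), then from any remaining candidates, until the bin holds
#' `threshold` variants or candidates are exhausted.
#'
#' @param selected Character vector of already selected candidate ids.
#' @param candidates data.frame with columns `id`, `chrom`, `pos`,
#'   `category`, `homRefCalls`, `calledLines`.
#' @param bins100 `GRanges` of the 100 kb bins.
#' @param budget100 Budget of a 100 kb bin.
#' @param threshold Target count per 50 kb bin.
#' @param balancedCap Maximal picks from the balanced-frequency step.
#' @param homRefMin,homRefMaxExcl Homozygous-reference call bounds
#'   (inclusive lower, exclusive upper).
#' @param minCalledLines Minimal number of called lines.
#' @param seed Integer seed.
#' @return Character vector of additional candidate ids.
#' @export
fillup50kb <- function(selected, candidates, bins100, budget100 = 48,
                       threshold = 8, balancedCap = 6,
                       homRefMin = 6, homRefMaxExcl = 22,
                       minCalledLines = 28, seed = 1L) {
  candGr <- GRanges(candidates$chrom, IRanges(candidates$pos, width = 1))
  hit100 <- GenomicRanges::findOverlaps(candGr, bins100, select = "first")
  selIdx <- candidates$id %in% selected
  cnt100 <- tabulate(hit100[selIdx], nbins = length(bins100))
  underfilled100 <- which(cnt100 < budget100)

  # 50 kb sub-bins of the underfilled 100 kb bins
  halves <- lapply(underfilled100, function(b) {
    st <- start(bins100)[b]; en <- end(bins100)[b]
    mid <- st + 50000 - 1
    GRanges(as.character(seqnames(bins100))[b],
            IRanges(c(st, min(mid, en) + 1)[c(TRUE, mid < en)],
                    c(min(mid, en), en)[c(TRUE, mid < en)]))
  })
  if (!length(halves)) return(character())
  bins50 <- do.call(c, halves)
  hit50 <- GenomicRanges::findOverlaps(candGr, bins50, select = "first")
  cnt50 <- tabulate(hit50[selIdx], nbins = length(bins50))

  additions <- character()
  withSeed(substreamSeed(seed, "fillup50"), {
    for (b in seq_along(bins50)) {
      need <- threshold - cnt50[b]
      if (need <= 0) next
      inBin <- which(hit50 == b & !selIdx & !candidates$id %in% additions)
      if (!length(inBin)) next
      balanced <- inBin[
        candidates$category[inBin] == "recommended" &
        candidates$calledLines[inBin] >= minCalledLines &
        candidates$homRefCalls[inBin] >= homRefMin &
        candidates$homRefCalls[inBin] < homRefMaxExcl]
      nBal <- min(need, balancedCap, length(balanced))
      pick <- if (nBal > 0) {
        if (nBal == length(balanced)) candidates$id[balanced]
        else sample(candidates$id[balanced], nBal)
      } else character()
      need <- need - length(pick)
      rest <- setdiff(candidates$id[inBin], pick)
      if (need > 0 && length(rest) > 0) {
        pick <- c(pick, if (need >= length(rest)) rest
                        else sample(rest, need))
      }
      additions <- c(additions, pick)
    }
  })
  additions
}

#' Assemble the screening-array candidate list
#'
#' Includes all coding candidates not categorized "not possible" (keeping,
#' for dual-probe coding variants, the probe with the higher p-convert
#' value), both probe sets of every legacy-array SNP unless "not
#' possible", and the bin-selected novel candidates restricted to
#' recommended/neutral categories.
#'
#' @param coding data.frame of coding probe candidates (columns `id`,
#'   `probe_id`, `pconvert`, `category`).
#' @param legacy data.frame of legacy-array probe candidates (two probes
#'   per SNP; same columns).
#' @param novel data.frame of bin-selected novel candidates.
#' @return list with `probes` (data.frame with a `origin` column) and
#'   `counts` per source.
#' @export
buildScreeningSet <- function(coding, legacy, novel) {
  if (anyDuplicated(novel$id))
    stop("duplicate novel candidate ids")
  keepCoding <- coding[coding$category != "not possible", , drop = FALSE]
  if (nrow(keepCoding) > 0) {
    # one probe per coding variant: the higher p-convert wins
    o <- order(keepCoding$id, -keepCoding$pconvert)
    keepCoding <- keepCoding[o, , drop = FALSE]
    keepCoding <- keepCoding[!duplicated(keepCoding$id), , drop = FALSE]
  }
  keepLegacy <- legacy[legacy$category != "not possible", , drop = FALSE]
  keepNovel <- novel[novel$category %in% c("recommended", "neutral"), ,
                     drop = FALSE]
  dupNew <- intersect(keepNovel$id, c(keepCoding$id, keepLegacy$id))
  if (length(dupNew))
    stop("novel candidate ids duplicate fixed content: ",
         paste(utils::head(dupNew, 3), collapse = ", "))
  probes <- rbind(
    if (nrow(keepCoding)) cbind(keepCoding, origin = "coding"),
    if (nrow(keepLegacy)) cbind(keepLegacy, origin = "legacy"),
    if (nrow(keepNovel)) cbind(keepNovel, origin = "novel"))
  list(probes = probes,
       counts = c(coding = nrow(keepCoding),
                  legacy = nrow(keepLegacy),
                  novel = nrow(keepNovel),
                  total = nrow(probes)))
}

#' Categorize p-convert values
#'
#' The p-convert computation is proprietary and external; values enter the
#' pipeline as inputs and are categorized with configurable thresholds.
#'
#' @param pconvert Numeric vector in [0, 1]; NA means "not possible".
#' @param recommendedMin,neutralMin Category thresholds.
#' @return Character vector of categories.
#' @export
pconvertCategory <- function(pconvert, recommendedMin = 0.6,
                             neutralMin = 0.4) {
  ifelse(is.na(pconvert), "not possible",
         ifelse(pconvert >= recommendedMin, "recommended",
                ifelse(pconvert >= neutralMin, "neutral",
                       "not recommended")))
}
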