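#' Transform raw two-channel signals to contrast/size coordinates
#'
#' Raw signals are floored at `floor` before taking logs, so the transform
#' is finite for zero signals. Contrast is `x = log2(A/B)` and size is
#' `y = (log2 A + log2 B) / 2`.
#'
#' @param signalA,signalB Numeric vectors or matrices of raw signals (>= 0).
#' @param floor Minimal raw signal before the log transform.
#' @return A list with components `x` (contrast) and `y` (size), shaped
#'   like the inputs.
#' @export
#' @examples
#' intensityTransform(1024, 1024)   # x = 0, y = 10
intensityTransform <- function(signalA, signalB, floor = 1) {
  if (any(signalA < 0, na.rm = TRUE) || any(signalB < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  a <- log2(pmax(signalA, floor))
  b <- log2(pmax(signalB, floor))
  list(x = a - b, y = (a + b) / 2)
}

#' A-priori cluster parameters for genotype calling
#'
#' Generic a-priori centers in contrast/size space: AA at (+delta, y0),
#' AB at (0, y0 + hetLift), BB at (-delta, y0). `y0 = NA` means "use the
#' upper quartile of the size coordinate" per variant — the genotype
#' clusters carry the bulk of the signal while off-target clusters sit
#' below, so the upper quartile stays anchored on the genotype clusters
#' even when a low-intensity cluster holds the majority of samples.
#'
#' @param delta A-priori homozygote contrast.
#' @param hetLift A-priori size lift of the AB cluster.
#' @param y0 Baseline size, or NA for the per-variant data median.
#' @param sd0 Initial within-cluster SD.
#' @return Named list of prior settings.
#' @export
clusterPriors <- function(delta = 1.5, hetLift = 0.3, y0 = NA, sd0 = 0.3) {
  as.list(environment())
}

# Gaussian-mixture EM for one variant in (x, y) with per-sample het prior
# scaling. Components are AA/AB/BB (+ optional OO) plus a uniform
# background (noise) component that renders off-cluster samples no-calls
# and keeps scattered points from inflating cluster variances. Returns
# the fitted model, calls and confidences.
.fitVariant <- function(x, y, penalties, priors = clusterPriors(),
                        confidenceMin = 0.95, maxIter = 30,
                        withOO = FALSE, ooInit = NULL,
                        minClusterN = 0.5, sdFloor = 0.05,
                        bgDensity = 1 / 48, bgWeight0 = 0.02) {
  ns <- length(x)
  y0 <- if (is.na(priors$y0)) stats::quantile(y, 0.75, names = FALSE)
        else priors$y0
  labs <- c("AA", "AB", "BB", "OO", "BG")
  centers <- rbind(AA = c(priors$delta, y0),
                   AB = c(0, y0 + priors$hetLift),
                   BB = c(-priors$delta, y0),
                   OO = if (is.null(ooInit)) c(0, y0 - 2) else ooInit)
  sds <- matrix(priors$sd0, 4, 2, dimnames = list(rownames(centers), NULL))
  present <- c(rep(TRUE, 3), withOO)
  names(present) <- rownames(centers)
  weights <- ifelse(present, (1 - bgWeight0) / sum(present), 0)
  weights <- c(weights, BG = bgWeight0)

  # per-sample prior multiplier on the AB component
  hetMult <- 2^(-penalties / 2)

  resp <- matrix(0, ns, 5, dimnames = list(NULL, labs))
  for (iter in seq_len(maxIter)) {
    # E-step: per-sample prior weights, AB down-weighted by inbred penalty
    logw <- matrix(rep(log(pmax(weights, 1e-300)), each = ns), ns, 5,
                   dimnames = list(NULL, labs))
    logw[, "AB"] <- logw[, "AB"] + log(hetMult)
    ll <- matrix(-Inf, ns, 5, dimnames = list(NULL, labs))
    for (j in which(present)) {
      ll[, j] <- stats::dnorm(x, centers[j, 1], sds[j, 1], log = TRUE) +
        stats::dnorm(y, centers[j, 2], sds[j, 2], log = TRUE)
    }
    ll[, "BG"] <- log(bgDensity)
    lp <- ll + logw
    m <- apply(lp, 1, max)
    p <- exp(lp - m)
    p[!is.finite(p)] <- 0
    resp <- p / rowSums(p)

    # M-step
    nk <- colSums(resp)
    newPresent <- present & nk[seq_len(4)] >= minClusterN
    if (!any(newPresent)) newPresent <- present   # degenerate guard
    present <- newPresent
    oldCenters <- centers
    for (j in which(present)) {
      centers[j, 1] <- sum(resp[, j] * x) / nk[j]
      centers[j, 2] <- sum(resp[, j] * y) / nk[j]
      sds[j, 1] <- max(sdFloor,
        sqrt(sum(resp[, j] * (x - centers[j, 1])^2) / nk[j]))
      sds[j, 2] <- max(sdFloor,
        sqrt(sum(resp[, j] * (y - centers[j, 2])^2) / nk[j]))
    }
    tot <- sum(nk[c(which(present), 5L)])
    weights <- c(ifelse(present, nk[seq_len(4)] / tot, 0),
                 BG = nk[[5]] / tot)
    if (max(abs(centers[present, ] - oldCenters[present, ])) < 1e-5) break
  }

  # enforce AA contrast > BB contrast by relabelling if needed
  if (present["AA"] && present["BB"] &&
      centers["AA", 1] < centers["BB", 1]) {
    sw <- c("AA", "BB")
    centers[sw, ] <- centers[rev(sw), ]
    sds[sw, ] <- sds[rev(sw), ]
    weights[sw] <- weights[rev(sw)]
    resp[, sw] <- resp[, rev(sw)]
  }

  post <- resp
  best <- apply(post, 1, which.max)
  conf <- post[cbind(seq_len(ns), best)]
  call <- labs[best]
  call[conf < confidenceMin | call == "BG"] <- NA_character_

  model <- new("ClusterModel", centers = centers, sds = sds,
               weights = weights[seq_len(4)] /
                 max(sum(weights[seq_len(4)][present]), 1e-12),
               present = present,
               n = colSums(resp)[seq_len(4)])
  list(model = model, call = call, confidence = conf)
}

#' Call genotypes for one variant from intensity points
#'
#' Expectation-maximization of a two-dimensional Gaussian mixture with
#' generic a-priori cluster centers. The per-sample inbred penalty `p`
#' multiplies the heterozygote prior weight by `2^(-p/2)` (renormalized
#' per sample), so that fully inbred samples lying between the AB and a
#' homozygote cluster are pulled to the homozygote. A call is emitted when
#' the maximal posterior reaches `confidenceMin`, otherwise the sample is
#' a no-call.
#'
#' @param x,y Contrast and size coordinates of the samples (one variant).
#' @param penalties Per-sample inbred penalties in [0, 16].
#' @param priors A-priori settings from [clusterPriors()].
#' @param confidenceMin Minimal posterior for a call.
#' @param maxIter Maximal EM iterations.
#' @return A list with `model` ([ClusterModel-class]), `call` (character
#'   vector) and `confidence`.
#' @export
callGenotypes <- function(x, y, penalties = 0,
                          priors = clusterPriors(),
                          confidenceMin = 0.95, maxIter = 30) {
  if (length(x) < 2L) stop("at least two samples are required")
  if (length(penalties) == 1L) penalties <- rep(penalties, length(x))
  if (any(penalties < 0 | penalties > 16))
    stop("inbred penalties must be in [0, 16]")
  .fitVariant(x, y, penalties, priors, confidenceMin, maxIter)
}

#' Re-call a variant with an off-target (OO) cluster
#'
#' Off-target variants appear as additional clusters of relatively low
#' signal intensity. The re-call runs when the fitted heterozygote
#' cluster sits far below the homozygote line (HetSO below the OTV cut)
#' or when the initial fit left a coherent low-size cluster of no-call
#' samples (at least `minLowN` no-calls more than one size unit below the
#' homozygote centers, with SD at most `lowSpreadMax` in both
#' coordinates). An additional low-size cluster is then added —
#' initialized below the homozygote centers — and the variant is
#' re-fitted with four components; members of the low cluster receive
#' genotype OO.
#'
#' @param x,y Intensity coordinates.
#' @param fit Result of [callGenotypes()] for this variant.
#' @param penalties Per-sample inbred penalties.
#' @param priors A-priori settings.
#' @param hetsoOtvCut HetSO threshold below which OTV re-calling runs.
#' @param confidenceMin,maxIter As in [callGenotypes()].
#' @param minLowN Minimal size of a coherent low-intensity no-call
#'   cluster that triggers the re-call.
#' @param lowSpreadMax Maximal SD of that cluster in each coordinate.
#' @return A list like [callGenotypes()] plus `isOtv` (logical: was the
#'   OO cluster fitted with members) and `degenerate` (all samples OO).
#' @export
detectOTV <- function(x, y, fit, penalties = 0,
                      priors = clusterPriors(),
                      hetsoOtvCut = -0.3,
                      confidenceMin = 0.95, maxIter = 30,
                      minLowN = 2, lowSpreadMax = 0.5) {
  if (length(penalties) == 1L) penalties <- rep(penalties, length(x))
  hs <- hetSO(fit$model)
  homPresent <- fit$model@present[c("AA", "BB")]
  homY <- fit$model@centers[c("AA", "BB"), 2][homPresent]
  yRef <- if (length(homY)) min(homY)
          else if (!is.na(priors$y0)) priors$y0
          else stats::quantile(y, 0.75, names = FALSE)
  lowIdx <- which(is.na(fit$call) & y < yRef - 1)
  coherentLow <- length(lowIdx) >= minLowN &&
    stats::sd(x[lowIdx]) <= lowSpreadMax &&
    stats::sd(y[lowIdx]) <= lowSpreadMax
  if ((is.na(hs) || hs >= hetsoOtvCut) && !coherentLow) {
    return(c(fit, list(isOtv = FALSE, degenerate = FALSE)))
  }
  homY <- fit$model@centers[c("AA", "BB"), 2][
    fit$model@present[c("AA", "BB")]]
  yInit <- if (length(homY)) min(homY) - 1.5 else stats::median(y) - 1.5
  refit <- .fitVariant(x, y, penalties, priors, confidenceMin, maxIter,
                       withOO = TRUE, ooInit = c(0, yInit))
  nOO <- sum(refit$call == "OO", na.rm = TRUE)
  degenerate <- nOO == length(x)
  c(refit, list(isOtv = refit$model@present["OO"] && nOO > 0,
                degenerate = degenerate))
}

# cluster metrics -----------------------------------------------------------

.pooledSd <- function(s1, s2) sqrt((s1^2 + s2^2) / 2)

#' Cluster-quality metrics of a fitted model
#'
#' `fld()` is the Fisher's-linear-discriminant-style separation between the
#' heterozygote cluster and the nearest homozygote cluster in contrast,
#' `|x_AB - x_hom| / s` with `s` the (unweighted) pooled within-cluster
#' contrast SD of the two clusters; `homFld()` is the analogue between the
#' AA and BB clusters. `hetSO()` is the vertical (size) offset of the AB
#' center from the line through the AA and BB centers (or from the single
#' homozygote's size when only one is present); strongly negative values
#' indicate off-target behavior. `homRO()` is the minimum over present
#' homozygote clusters of the signed contrast distance in the expected
#' direction (`x_AA` for AA, `-x_BB` for BB); positive values mean the
#' homozygote clusters sit on their expected sides. Metrics are `NA` when
#' a required cluster is absent.
#'
#' @param model A [ClusterModel-class].
#' @return A single numeric value or `NA`.
#' @export
fld <- function(model) {
  if (!model@present["AB"]) return(NA_real_)
  homs <- c("AA", "BB")[model@present[c("AA", "BB")]]
  if (!length(homs)) return(NA_real_)
  xAB <- model@centers["AB", 1]
  d <- abs(model@centers[homs, 1] - xAB)
  h <- homs[which.min(d)]
  unname(abs(model@centers[h, 1] - xAB) /
    .pooledSd(model@sds["AB", 1], model@sds[h, 1]))
}

#' @rdname fld
#' @export
homFld <- function(model) {
  if (!all(model@present[c("AA", "BB")])) return(NA_real_)
  unname(abs(model@centers["AA", 1] - model@centers["BB", 1]) /
    .pooledSd(model@sds["AA", 1], model@sds["BB", 1]))
}

#' @rdname fld
#' @export
hetSO <- function(model) {
  if (!model@present["AB"]) return(NA_real_)
  xAB <- model@centers["AB", 1]; yAB <- model@centers["AB", 2]
  hasAA <- model@present["AA"]; hasBB <- model@present["BB"]
  if (hasAA && hasBB) {
    xA <- model@centers["AA", 1]; yA <- model@centers["AA", 2]
    xB <- model@centers["BB", 1]; yB <- model@centers["BB", 2]
    if (xA == xB) return(unname(yAB - (yA + yB) / 2))
    unname(yAB - (yA + (yB - yA) * (xAB - xA) / (xB - xA)))
  } else if (hasAA) {
    unname(yAB - model@centers["AA", 2])
  } else if (hasBB) {
    unname(yAB - model@centers["BB", 2])
  } else {
    NA_real_
  }
}

#' @rdname fld
#' @export
homRO <- function(model) {
  vals <- c(if (model@present["AA"]) model@centers["AA", 1],
            if (model@present["BB"]) -model@centers["BB", 1])
  if (!length(vals)) return(NA_real_)
  unname(min(vals))
}

#' Per-variant metrics from a fit and its calls
#'
#' @param fit Result of [callGenotypes()] or [detectOTV()].
#' @return One-row data.frame with callRate (%), FLD, homFLD, HetSO,
#'   HomRO, nMinorAllele, nClusters (genotype clusters, OO excluded).
#' @export
clusterMetrics <- function(fit) {
  call <- fit$call
  model <- fit$model
  nA <- 2 * sum(call == "AA", na.rm = TRUE) + sum(call == "AB", na.rm = TRUE)
  nB <- 2 * sum(call == "BB", na.rm = TRUE) + sum(call == "AB", na.rm = TRUE)
  data.frame(
    callRate = 100 * mean(!is.na(call)),
    FLD = fld(model),
    homFLD = homFld(model),
    HetSO = hetSO(model),
    HomRO = homRO(model),
    nMinorAllele = min(nA, nB),
    nClusters = sum(model@present[c("AA", "AB", "BB")]),
    minorHomPresent = if (nA <= nB) any(call == "AA", na.rm = TRUE)
                      else any(call == "BB", na.rm = TRUE),
    singleClusterIsHet = sum(model@present[c("AA", "AB", "BB")]) == 1L &&
      model@present["AB"]
  )
}

#' Default SNPolisher-style classification thresholds
#'
#' @return Named list of thresholds.
#' @export
classifyThresholds <- function() {
  list(CR.cut = 90, FLD.cut = 3.6, HetSO.cut = -0.1, HetSO.OTV.cut = -0.3,
       HomRO2.cut = 0.3, HomRO3.cut = -0.9, nMinorAllele.cut = 2)
}

#' Classify variants into the six cluster-quality categories
#'
#' Decision tree: (1) a single genotype cluster yields MonoHighResolution
#' when call rate and HomRO pass (a lone heterozygote cluster fails);
#' (2) call rate below `CR.cut` yields CallRateBelowThreshold; (3) HetSO
#' below the OTV cut routes to OTV, while other FLD/HetSO/HomRO failures
#' yield Other — the HomRO cut is `HomRO2.cut` with two genotype clusters
#' and `HomRO3.cut` with three; (4) polymorphic variants lacking a
#' minor-allele homozygote or with fewer than `nMinorAllele.cut` minor
#' alleles are NoMinorHom; (5) everything else is PolyHighResolution.
#'
#' Classification is a pure function of the metrics and thresholds.
#'
#' @param metrics data.frame from [clusterMetrics()] (one or more rows).
#' @param thresholds List from [classifyThresholds()].
#' @return Character vector of categories.
#' @export
classifyVariants <- function(metrics, thresholds = classifyThresholds()) {
  th <- thresholds
  vapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    if (m$nClusters <= 1L) {
      if (isTRUE(m$singleClusterIsHet)) return("Other")
      ok <- m$callRate >= th$CR.cut &&
        (is.na(m$HomRO) || m$HomRO >= th$HomRO2.cut)
      return(if (ok) "MonoHighResolution" else "Other")
    }
    if (m$callRate < th$CR.cut) return("CallRateBelowThreshold")
    homROcut <- if (m$nClusters >= 3L) th$HomRO3.cut else th$HomRO2.cut
    otvHit <- (!is.na(m$HetSO) && m$HetSO < th$HetSO.OTV.cut) ||
      isTRUE(m[["otvTriggered"]])
    if (otvHit) return("OTV")
    if ((!is.na(m$FLD) && m$FLD < th$FLD.cut) ||
        (!is.na(m$HetSO) && m$HetSO < th$HetSO.cut) ||
        (!is.na(m$HomRO) && m$HomRO < homROcut)) return("Other")
    if (!isTRUE(m$minorHomPresent) || m$nMinorAllele < th$nMinorAllele.cut)
      return("NoMinorHom")
    "PolyHighResolution"
  }, character(1))
}

#' Compare category assignments with and without inbred correction
#'
#' @param without,with Character vectors of categories from the analyses
#'   without and with inbred correction.
#' @return data.frame with columns `without`, `with`, `stable` and
#'   `transition` ("stable", "promotion" to PolyHighResolution, or
#'   "changed").
#' @export
compareCorrection <- function(without, with) {
  stopifnot(length(without) == length(with))
  stable <- without == with
  transition <- ifelse(stable, "stable",
                ifelse(with == "PolyHighResolution", "promotion", "changed"))
  data.frame(without = without, with = with, stable = stable,
             transition = transition)
}

#' Call an entire intensity set
#'
#' Runs [callGenotypes()] per variant, computes cluster metrics, performs
#' OTV re-calling for variants whose HetSO falls below the OTV cut, and
#' classifies every variant. With `inbredCorrection = FALSE` all penalties
#' are zero regardless of the sample sheet.
#'
#' @param intensities An [IntensitySet-class].
#' @param penalties Per-sample inbred penalties (named by sample id or in
#'   column order).
#' @param inbredCorrection Logical; apply the penalties?
#' @param priors,confidenceMin,maxIter Passed to [callGenotypes()].
#' @param thresholds Classification thresholds.
#' @param signalFloor Raw-signal floor before the log transform.
#' @return A list with `calls` (a [GenotypeCallSet-class] including OO
#'   genotypes), `metrics` (data.frame with one row per variant and a
#'   `category` column), and `models` (list of [ClusterModel-class]).
#' @export
callIntensitySet <- function(intensities, penalties = 0,
                             inbredCorrection = TRUE,
                             priors = clusterPriors(),
                             confidenceMin = 0.95, maxIter = 30,
                             thresholds = classifyThresholds(),
                             signalFloor = 1) {
  stopifnot(is(intensities, "IntensitySet"))
  A <- SummarizedExperiment::assay(intensities, "signalA")
  B <- SummarizedExperiment::assay(intensities, "signalB")
  nv <- nrow(A); ns <- ncol(A)
  if (length(penalties) == 1L) penalties <- rep(penalties, ns)
  if (!is.null(names(penalties)) && !is.null(colnames(A)))
    penalties <- penalties[colnames(A)]
  if (!inbredCorrection) penalties <- rep(0, ns)

  tr <- intensityTransform(A, B, floor = signalFloor)
  # anchor the generic a-priori size level on the whole set (plate-level
  # normalization): a per-variant anchor would drift onto low-intensity
  # off-target clusters when they hold the majority of samples
  if (is.na(priors$y0)) priors$y0 <- stats::median(tr$y)
  calls <- matrix(NA_character_, nv, ns, dimnames = dimnames(A))
  confs <- matrix(NA_real_, nv, ns, dimnames = dimnames(A))
  models <- vector("list", nv)
  metrics <- vector("list", nv)
  for (i in seq_len(nv)) {
    fit3 <- callGenotypes(tr$x[i, ], tr$y[i, ], penalties,
                          priors, confidenceMin, maxIter)
    # metrics and classification reflect the three-cluster analysis; the
    # OTV re-fit only contributes the OO genotype calls
    met <- clusterMetrics(fit3)
    fit <- detectOTV(tr$x[i, ], tr$y[i, ], fit3, penalties, priors,
                     hetsoOtvCut = thresholds$HetSO.OTV.cut,
                     confidenceMin = confidenceMin, maxIter = maxIter)
    met$otvTriggered <- isTRUE(fit$isOtv)
    if (met$otvTriggered)   # OO genotypes are calls
      met$callRate <- 100 * mean(!is.na(fit$call))
    metrics[[i]] <- met
    calls[i, ] <- fit$call
    confs[i, ] <- fit$confidence
    models[[i]] <- fit$model
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- rownames(A)
  metrics$category <- classifyVariants(metrics, thresholds)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(call = calls, confidence = confs),
    rowData = SummarizedExperiment::rowData(intensities))
  gcs <- new("GenotypeCallSet", se)
  list(calls = gcs, metrics = metrics, models = models)
}
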