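---
title: "Methods: from sequence variants to a high-density maize genotyping array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from sequence variants to a high-density maize genotyping array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpArrayDesign)
```

# Overview

`snpArrayDesign` implements the complete computational design of a
high-density (600k-scale) SNP genotyping array for maize, from raw
dual-caller sequence variants to the final probe list, together with the
downstream validation analyses. The pipeline has five analytical stages —
discovery filtering, bin-based candidate selection, intensity-based
genotype clustering with quality classification, the voting system for
final content, and panel analyses — plus a first-class synthetic-data
generator that plants known truth so that every stage is testable without
any external dataset.

The design problem is shaped by maize biology. Temperate maize breeding
exploits two diverged germplasm pools (Dent and Flint), panels are almost
entirely inbred lines with only residual heterozygosity, and the ancient
polyploid genome retains large tracts of paralogous sequence that produce
spurious heterozygous sequencing calls. All three facts drive specific
machinery in the pipeline: pool-balanced selection quotas, an
inbred-penalty correction during genotype calling, and aggressive
copy-number / mapping-quality filters with heterozygote masking during
discovery.

# Discovery filtering

Raw caller records enter as VCF-style sites with per-line genotypes,
depths, site quality, genomic copy number (from k-mer counts), and the
fraction of mapping-quality-zero reads. The cascade applies, in order:

1. **Caller intersection** — only sites supported by both callers.
2. **Round 1** — site quality ≥ 50; total depth 50 ≤ DP < 3000
   (half-open, calibrated to a 30-line panel with four deep ~50x lines
   and 26 shallow ~12x lines); at least one line carrying the reference
   allele (interpreted as ≥ 1 homozygous-reference call, consistent with
   the homozygous-call accounting used throughout); at least two lines
   with homozygous non-reference calls.
3. **Round 2** — copy number < 50; MQ0 fraction ≤ 0.05; site coverage at
   most six-fold the panel-wide mean site depth (the panel mean is used
   because no per-line convention is available); quality ≥ 100.
4. **Spacing** — a site is kept when its nearest neighboring variant is
   ≥ 20 bp away on at least one side; chromosome ends count as clear.
   Simple neighbor distance is used rather than probe-window logic.
5. **Bi-allelic restriction**, then **heterozygote masking**: every
   heterozygous genotype becomes missing (idempotent). The rationale is
   empirical: against an independent array truth set, heterozygous
   sequencing calls in this material have a false-discovery rate orders
   of magnitude above homozygous calls, so only homozygous calls are
   carried forward.

Every filter reports input/pass/fail counts that must reconcile, and the
whole cascade is certified in the test suite against a naive single-pass
oracle.

# Bin-based candidate selection

The genome is tiled with 100 kb bins (a 2.066 Gb genome gives 20,660).
Screening capacity of about 1.23 M probes, minus fixed content (150,394
coding variants and two probe sets for each of 48,324 legacy-array SNPs),
leaves an average budget of 48 variants per bin. Non-reference allele
frequencies computed separately in Dent and Flint classify each candidate
as intermediate ("A", within [0.2, 0.8]) or extreme ("B"), and the four
pool-class combinations fill quota cells: one third Flint-specific
(Dent A | Flint B — the naming is kept exactly as the scheme defines it,
counter-intuitive as it reads), one third Dent-specific (B | A), one
sixth common (A | A), one sixth rare (B | B).

Three fill cases apply per bin: all recommended-or-neutral candidates
when fewer than 48 exist; recommended fixed plus neutral drawn by quota;
or recommended drawn by quota when 48 or more are available. Quota
integerization uses largest-remainder (Hamilton) apportionment, which is
deterministic and sums exactly to the budget. When a cell has too few
candidates its shortfall is redistributed proportionally over the
remaining cells by repeated largest-remainder passes until stable.
Candidates with an undefined frequency class (no calls in a pool) are
treated as extreme and fall into the rare cell. A second pass tops up
50 kb sub-bins holding fewer than 8 selections: first up to six
"balanced" picks (recommended candidates with 6–21 homozygous-reference
calls among at least 28 called lines), then any remaining candidates.
One documented pass implements the top-up; the alternative reading (a
separate extra pass for under-represented bins) produces the same
selection rule.

p-convert values — the predicted probability that a probe converts into a
working assay — are proprietary upstream inputs. The package only
categorizes them, with configurable thresholds defaulting to
recommended ≥ 0.6 and neutral ≥ 0.4.

# Genotype clustering

Two-channel signals are transformed to contrast
`x = log2(A/B)` and size `y = (log2 A + log2 B)/2`, with raw signals
floored at 1. Calling is per-variant expectation-maximization of a
two-dimensional Gaussian mixture with generic a-priori centers
AA `(+1.5, y0)`, AB `(0, y0 + 0.3)`, BB `(-1.5, y0)` and initial SD 0.3.
The size anchor `y0` is fixed at the median size over the entire
intensity set — a plate-level anchor, mirroring array normalization. A
per-variant anchor was rejected because it drifts onto low-intensity
off-target clusters whenever they hold the majority of samples, which
misplaces every a-priori center.

Two numerical safeguards matter:

* **Background component.** The mixture carries a uniform background
  (noise) component with constant density 1/48 over the plausible signal
  region and initial weight 0.02, in the spirit of robust
  mixture-model clustering with a noise term. Samples won by the
  background are no-calls. Without it, scattered failed-hybridization
  samples are absorbed into inflated cluster variances and receive
  confident (wrong) calls; with it, cluster variances stay tight.
* **Cluster dropout.** Components whose effective occupancy falls below
  half a sample are dropped; SDs are floored at 0.05. AA/BB labels are
  swapped if needed so the AA center always has the higher contrast.

**Inbred correction.** Each sample carries an inbred penalty from 0
(fully heterozygous material, F1 hybrids) through 12 (inbreds of unclear
homozygosity) to 14–16 (pure inbreds and doubled haploids). The penalty
`p` multiplies the sample's heterozygote prior weight by `2^(-p/2)`
(renormalized per sample), so ambiguous points between the AB and a
homozygote cluster resolve to the homozygote for inbred samples. The
mapping is configurable; only the endpoints of the scale are fixed by
convention. A call is emitted when the maximal posterior reaches 0.95.

**Off-target variants (OTVs).** Variants whose flanking sequence carries
an additional polymorphism in some samples show an extra cluster at
relatively low signal intensity. OTV re-calling runs when either (a) the
fitted heterozygote cluster sits more than 0.3 below the homozygote line
(HetSO below the OTV cut), or (b) the initial fit leaves a coherent
low-size cluster of no-calls (at least two no-call samples more than one
size unit below the homozygote centers with SD ≤ 0.5 in both
coordinates). Condition (b) exists because the background component —
not the AB cluster — captures carrier clouds, so the HetSO signature
alone would miss them; it is the geometric reading of "additional
relatively low signal intensity clusters". The re-fit adds an OO
component initialized below the homozygote centers; its members are
called OO.

**Cluster metrics.** FLD is the contrast separation between the AB
cluster and the nearest homozygote cluster divided by the unweighted
pooled within-cluster contrast SD of the two clusters compared; homFLD
is the analogue between AA and BB. (The vendor's exact formula is
unpublished; an occupancy-weighted pooled SD was rejected because a huge
clean cluster would mask a diffuse heterozygote cluster.) HetSO is the
vertical offset of the AB center from the line through the homozygote
centers (or from the single homozygote's size). HomRO is the minimum
over present homozygote clusters of the signed contrast in the expected
direction.

**Classification** uses the thresholds CR.cut = 90, FLD.cut = 3.6,
HetSO.cut = −0.1, HetSO.OTV.cut = −0.3, HomRO2.cut = 0.3 (two genotype
clusters), HomRO3.cut = −0.9 (three), nMinorAllele.cut = 2, applied as a
deterministic tree: one-cluster variants are MonoHighResolution when call
rate and HomRO pass (a lone heterozygote cluster is a failure); the call
rate of 90 — the reduced variant call-frequency threshold appropriate for
a genome rich in presence/absence variation — gates
CallRateBelowThreshold; HetSO below the OTV cut (or a successful OO
re-fit) yields OTV; other metric failures yield Other; polymorphic
variants without a minor-allele homozygote or with fewer than two minor
alleles are NoMinorHom; the rest are PolyHighResolution. For one-cluster
variants the two-cluster HomRO cut is used, as no separate one-cluster
threshold is published. For OTV-re-fitted variants the call rate counts
OO genotypes as calls; all other metrics come from the three-cluster
analysis.

The whole analysis is run twice — with and without the inbred penalties —
and the category transition feeds the selection stage.

# Final array selection

* Variants classified PolyHighResolution in **both** analyses are
  forwarded unconditionally.
* OTV-stable variants (OTV in both analyses) are forwarded when
  polymorphic, with ≤ 10% missing calls, FLD > 3.5, HetSO > −3.5 and
  HomRO > 1; when FLD/HetSO are undefined (two-cluster case) a
  homFLD > 5 rule substitutes.
* The remainder is ranked by `35·w + 90·c + 10·s`: class weight
  `w` = 10 for OTV-stable or NoMinorHom-to-PHR promotions, 5 for any
  other promotion to PHR under inbred correction, 0 otherwise;
  `c` ∈ [0, 1] is the concordance of array calls with the sequencing
  calls of the discovery lines; `s` ∈ [−1, 1] is the bin-representation
  score `(m − n)/(m + n)` against the mean of up to five bins on each
  side (positive for under-represented bins). The multipliers make the
  class weight dominant (0–350), concordance strong (0–90) and bin
  representation a tiebreaker (−10–10).
* Duplicate probes resolve to the higher rank, ties by a seeded draw;
  known-bad legacy probes enter as an exclusion list; the top candidates
  by rank fill the target size after the forwarded sets.

Annotation assigns coding/intron/UTR labels when gene models carry
feature structure; with plain intervals the distinction collapses to
"genic" and the summary says so. Gene tagging is reported with and
without 5 kb flanks. Density statistics summarize physical neighbor
spacing per chromosome and, given a genetic map, linearly interpolated
cM spacing (constant beyond map ends).

# Panel analyses

Replicate concordance, trio Mendelian consistency (offspring compatible
with one allele from each parent; missing calls skip the trio at that
variant), polymorphism partitions with Venn cells, and MAF spectra are
straightforward counting on the dosage matrix; heterozygotes contribute
half an allele. Rogers' distance reduces, for bi-allelic loci, to the
mean absolute dosage difference divided by two over loci non-missing in
both samples; PCoA is classical scaling of that matrix. Missing data
handling for structure/LD analyses drops variants with ≥ 10% missing and
imputes the rest with the per-variant modal genotype — deterministic and
dependency-free, replacing haplotype-based imputation whose effect here
is limited to these analyses. LD is the squared Pearson correlation of
0/1/2 dosages (pairwise-complete) within 50 Mb windows. LD-decay
distance bins pairs into log-spaced distance bins (50 per decade),
enforces monotone non-increase by isotonic regression, and reports the
smallest distance where the fitted curve crosses r² = 0.2 by linear
interpolation between bin midpoints; a curve already below the threshold
returns 0 (flagged), one never crossing returns undefined. Per-window
crossings averaged per chromosome are the reporting unit. Greedy
left-to-right LD pruning (drop when r² > 0.8 against any retained
variant in the window) is deterministic and oracle-tested.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised:

* **Genome** — toy chromosomes with a telomere-enriched polymorphism
  profile (`1 + 3·(2|pos − L/2|/L)²`, piecewise constant per kb) and an
  optional NOR-like masked interval at 7–28% of the last chromosome that
  receives zero variants.
* **Panel** — per-variant pool frequencies drawn from Beta(0.8, 0.8) and
  shifted apart on the logit scale by a divergence of 1.5 (random sign
  per variant); genotypes from the inbreeding model
  `P(het) = 2p(1−p)(1−f)`; hybrids by gamete draw from their simulated
  parents; replicates copy truth exactly. The default validation panel
  has 285 samples: 73 Dent and 79 Flint public inbreds (f = 0.99,
  penalty 14, every tenth line penalty 12; ten Flint entries are doubled
  haploids with f = 1), 23 Dent x Flint trios' F1 hybrids (f = 0,
  penalty 0), 13 admixed (sub)tropical lines, 89 proprietary-style lines
  (penalty 12), two outgroup accessions, three technical replicates and
  three biological replicate pairs. The discovery panel has 13 Dent and
  17 Flint inbreds with mean coverages 50x for the first two lines of
  each pool and 12x for the rest.
* **Sequencing calls** — Poisson depths, a configurable genotype error
  rate (default 0.2%), caller-disagreement rate 5%; paralog-confounded
  variants (default 10%) emit heterozygous calls at rate 0.8, carry copy
  number ≥ 50 and elevated MQ0 fractions, reproducing the het-call FDR
  pathology.
* **Intensities** — signals are generated on the log scale (clusters in
  contrast/size coordinates with lognormal noise, SD 0.12, separation
  1.5) and emitted as raw two channels, so the caller applies its own
  transform. Planted categories are consistent with the genotype
  composition: monomorphic truth gives one cluster; missing minor
  homozygotes give NoMinorHom geometry; 7.5% of variants carry a
  flanking off-target variant whose frequency comes from a
  rare-allele-heavy Beta(0.25, 1.25) (a crude proxy for an unascertained
  frequency spectrum), and carriers (≥ 1 flanking allele) emit from a
  low cluster 2.5 size units down; 7% of sufficiently heterozygous
  variants are planted as "Other" (AB contrast SD inflated six-fold and
  the AB center lowered 0.2, inside the band between the HetSO cut and
  the OTV cut); 5% are planted as low-call-rate variants in which a
  quarter of samples scatter broadly (failed hybridization). The
  per-category frequencies among failed variants are free parameters of
  the fixture, chosen once at plausible magnitudes.

All randomness flows from one top-level seed through named substreams
(`substreamSeed()`), so identical seeds give byte-identical fixtures and
individual stages can be re-run reproducibly.

**What passing tests show — and what they do not.** The generator plants
well-separated clusters, independent variants, noise-free Mendelian
transmission and a clean OTV geometry. Recovery of ≥ 99% of genotypes
and ≥ 90% of planted categories under these conditions certifies the
algorithmic machinery (the EM caller, the metric definitions, the
classification tree, the selection logic), not performance on real
hybridization data, where batch effects, plate normalization, partial
probe failures and linked variants occur. Dataset-dependent headline
figures of a real array campaign (overall call rates, the fraction of
category changes under inbred correction, absolute LD levels) depend on
the real material and are deliberately not calibration targets; only
their directions are asserted.

# Problem sizes and runtime choices

The test suite runs panels of 57–285 samples and 60–4,000 variants;
oracle-equivalence checks use seeded sets of up to 4,000 records; the
acceptance script simulates 2,000 variants x 285 samples for the dual
clustering analysis and 3,000 variants x 30 lines for sequencing-call
emulation. These sizes were chosen so the whole pipeline, run twice for
the dual analysis, completes in about a minute on a single core while
keeping binomial standard errors on recovered fractions below about one
percentage point.

# Known limitations

* The EM caller is a stand-in for the proprietary vendor algorithm; it
  reproduces the documented behavior (generic a-priori positions,
  a-posteriori refinement, inbred correction, OTV genotypes), not its
  internals, and the FLD/HetSO/HomRO formulas are geometric stand-ins
  for unpublished vendor definitions.
* p-convert computation, read alignment, variant calling, base-quality
  recalibration, k-mer copy-number estimation, admixture-model
  clustering and haplotype imputation are out of scope; their outputs
  are inputs here, or simple deterministic substitutes are used and
  named in the output.
* Mode imputation underestimates heterozygosity in high-missingness
  regions; it is only used for structure/LD analyses after the ≥ 10%
  missingness exclusion.
* The synthetic intensity model has diagonal Gaussian clusters and no
  batch or plate effects; classification thresholds tuned on real Axiom
  data are used as given, not re-estimated.
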