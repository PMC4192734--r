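# snpArrayDesign

Design and validation pipeline for high-density SNP genotyping arrays,
modeled on the computational workflow behind the 600k-scale maize
(Dent/Flint) genotyping array.

Building a genotyping array from whole-genome sequencing data is a
selection problem under several constraints at once: sequencing calls in
the ancient polyploid maize genome are contaminated by paralog-driven
false heterozygotes; array capacity forces a physically balanced subset
of candidates that still segregates in both major germplasm pools; and
probe performance can only be judged after a screening round, from the
geometry of two-channel intensity clusters on a nearly fully inbred
panel. `snpArrayDesign` implements every computational stage of that
workflow as a tested R package for people who design or evaluate
genotyping arrays, or who need a transparent re-implementation of
Axiom-style cluster metrics and classification:

* **Discovery filtering** — dual-caller intersection; quality, depth,
  copy-number (CN ≥ 50), MQ0-fraction and spacing filters; bi-allelic
  restriction; heterozygote masking; FDR of het vs hom calls against a
  truth set.
* **Bin-based selection** — 100 kb bin tiling (20,660 bins on a 2.066 Gb
  genome), a per-bin budget of 48 after fixed coding and legacy-array
  content, pool allele-frequency classes (intermediate "A" in
  [0.2, 0.8], extreme "B"), quota cells {Flint-specific 1/3,
  Dent-specific 1/3, common 1/6, rare 1/6} with largest-remainder
  apportionment, and a 50 kb fill-up pass.
* **Genotype clustering** — a 2-D Gaussian-mixture EM caller on contrast
  (`log2 A/B`) and size (`(log2 A + log2 B)/2`) coordinates with generic
  a-priori cluster positions, a per-sample inbred penalty (0–16) scaling
  the heterozygote prior by `2^(-p/2)`, off-target-variant (OTV)
  re-calling with an OO cluster, the cluster metrics FLD, homFLD, HetSO
  and HomRO, and the six-way classification
  (PolyHighResolution, NoMinorHom, MonoHighResolution, OTV,
  CallRateBelowThreshold, Other) at the published thresholds
  (CR.cut = 90, FLD.cut = 3.6, HetSO.cut = −0.1, HetSO.OTV.cut = −0.3,
  HomRO2.cut = 0.3, HomRO3.cut = −0.9, nMinorAllele.cut = 2).
* **Array design** — forwarding of category-stable variants, the voting
  system `rank = 35·w + 90·c + 10·s` (class-transition weight, sequence
  concordance, bin-representation score), duplicate-probe resolution,
  top-k assembly, gene-model annotation with 5 kb flanks, and density
  statistics.
* **Panel analyses** — replicate concordance, trio Mendelian checks,
  polymorphism partitions, MAF spectra (ascertainment of targets vs
  flanking OTVs), Rogers distances with PCoA, greedy LD pruning
  (r² > 0.8) and LD-decay estimation (distance at r² = 0.2, isotonic
  fit over log-spaced bins).
* **Synthetic data** — a seeded generator for toy genomes (telomeric
  polymorphism gradient, NOR-like gap), structured inbred panels with
  trios and replicates, paralog-confounded sequencing calls, and
  clustered two-channel intensities with planted categories and OTV
  carrier sets, so the entire pipeline is testable with known truth.

## Worked example

Simulate a screening study, call genotypes with and without inbred
correction, and assemble a small array:

```r
library(snpArrayDesign)

st <- simulateStudy(seed = 42, nVariants = 300,
                    panel = validationPanelConfig(
                      nDent = 20, nFlint = 20, nTrios = 6,
                      nAdmixed = 4, nOutgroup = 1, nProprietary = 0))
dual <- runDualClustering(st$intensities, st$panel)
table(dual$with$metrics$category)
#> CallRateBelowThreshold     MonoHighResolution                  Other
#>                     16                     18                      6
#>                    OTV     PolyHighResolution
#>                     11                    249

planted <- SummarizedExperiment::rowData(st$intensities)$plantedCategory
mean(dual$without$metrics$category == planted)   # planted-category recovery
#> 0.98

cats <- data.frame(id = rownames(dual$without$metrics),
                   without = dual$without$metrics$category,
                   with = dual$with$metrics$category)
fw  <- forwardPhrStable(cats)                       # 248 variants
otv <- selectOtvStable(cats, dual$with$metrics,
                       genoCalls(dual$with$calls))  # 11 variants
rest <- cats[!cats$id %in% c(fw, otv), ]
rank <- rankVariant(classWeight(rest$without, rest$with),
                    rep(0.97, nrow(rest)), 0)
design <- assembleFinal(c(fw, otv),
                        data.frame(id = rest$id, rank = rank),
                        targetSize = 280, seed = 42)
length(design)
#> 280
```

The 249 PolyHighResolution variants are clean three-cluster assays; the
11 OTV variants carry a low-intensity OO cluster whose members lack the
probe's flanking sequence, and their presence/absence can itself be used
as a second marker. The final design keeps every category-stable variant
and fills the rest by rank. Design arithmetic is available directly:
`length(partitionBins(2.066e9, 1e5))` gives the 20,660 bins of 100 kb and
`computeBinBudget()` the average budget of 48 variants per bin.

Noise-free trios are fully consistent, as they should be:

```r
s <- panelSamples(st$truth); hyb <- s[s$pool == "hybrid", ]
trioMendelian(trueGenotypes(st$truth),
              data.frame(parent1 = hyb$parent1, parent2 = hyb$parent2,
                         offspring = hyb$id))$overall
#> 100
```

A thin command-line wrapper with `simulate`, `discover-filter`,
`bin-select`, `cluster`, `design` and `panel` subcommands is installed at
`inst/scripts/array_design_cli.R`.

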