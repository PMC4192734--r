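#' Write sequencing-call records as VCF
#'
#' Emits VCF v4.2 with one sample column per line, GT and DP FORMAT
#' fields, and INFO keys DP, CN (genomic copy number), MQ0F (fraction of
#' mapping-quality-zero reads), SAMCALL and GATKCALL (caller-support
#' flags) and TYPE. The file is bgzip-compressed when the path ends in
#' `.gz`.
#'
#' @param records A [SeqVariantSet-class].
#' @param path Output path (`.vcf` or `.vcf.gz`).
#' @return The path, invisibly.
#' @export
writeSeqVcf <- function(records, path) {
  info <- variantInfo(records)
  rd <- mcols(info)
  G <- seqGenotypes(records)
  DPm <- seqDepths(records)

  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Genomic copy number from k-mer counts\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of MQ0 reads\">",
    "##INFO=<ID=SAMCALL,Number=0,Type=Flag,Description=\"Supported by SAMtools\">",
    "##INFO=<ID=GATKCALL,Number=0,Type=Flag,Description=\"Supported by GATK\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNP or indel\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")

  infoStr <- sprintf("DP=%d;CN=%d;MQ0F=%.6g;TYPE=%s%s%s",
                     rd$DP, rd$CN, rd$MQ0F, rd$type,
                     ifelse(rd$samCall, ";SAMCALL", ""),
                     ifelse(rd$gatkCall, ";GATKCALL", ""))
  fix <- cbind(CHROM = as.character(seqnames(info)),
               POS = as.character(start(info)),
               ID = rd$id, REF = rd$ref, ALT = rd$alt,
               QUAL = as.character(rd$qual), FILTER = "PASS",
               INFO = infoStr)
  if (nrow(G) == 0L) {      # header-only VCF; vcfR needs >= 1 record
    hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                   "FILTER", "INFO", "FORMAT", colnames(G)),
                 collapse = "\t")
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    writeLines(c(meta, hdr), con)
    close(con)
    return(invisible(path))
  }
  gtCode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gtChar <- matrix("./.", nrow(G), ncol(G))
  ok <- !is.na(G)
  gtChar[ok] <- gtCode[as.character(G[ok])]
  dpChar <- matrix(".", nrow(G), ncol(G))
  dpChar[!is.na(DPm)] <- as.character(DPm[!is.na(DPm)])
  gt <- cbind(FORMAT = "GT:DP",
              matrix(paste(gtChar, dpChar, sep = ":"),
                     nrow(G), ncol(G), dimnames = dimnames(G)))

  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read sequencing-call records from VCF
#'
#' Inverse of [writeSeqVcf()]: parses GT/DP genotypes and the INFO keys
#' into a [SeqVariantSet-class]. Multi-allelic ALT fields are preserved
#' as comma-separated strings (genotype dosage then refers to the first
#' alternative allele).
#'
#' @param path VCF path.
#' @return A [SeqVariantSet-class].
#' @export
readSeqVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  infoNum <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    as.numeric(x)
  }
  infoFlag <- function(key)
    grepl(paste0("(^|;)", key, "(;|$)"), v@fix[, "INFO"])
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  typeInfo <- vcfR::extract.info(v, element = "TYPE")
  gr <- GRanges(fix[, "CHROM"],
                IRanges(as.integer(fix[, "POS"]), width = 1))
  mcols(gr) <- DataFrame(
    id = ids, ref = fix[, "REF"], alt = fix[, "ALT"],
    type = ifelse(is.na(typeInfo), "SNP", typeInfo),
    qual = as.numeric(fix[, "QUAL"]),
    DP = as.integer(infoNum("DP")),
    CN = as.integer(infoNum("CN")),
    MQ0F = infoNum("MQ0F"),
    samCall = infoFlag("SAMCALL"),
    gatkCall = infoFlag("GATKCALL"))
  names(gr) <- ids
  rownames(geno) <- ids
  if (!is.null(dp)) rownames(dp) <- ids
  SeqVariantSet(gr, geno, dp)
}

#' Write and read the long-format intensity table
#'
#' Columns: variant_id, sample_id, signal_A, signal_B.
#'
#' @param intensities An [IntensitySet-class].
#' @param path TSV path.
#' @return The path, invisibly (writer); an [IntensitySet-class]
#'   (reader).
#' @export
writeIntensityTable <- function(intensities, path) {
  A <- SummarizedExperiment::assay(intensities, "signalA")
  B <- SummarizedExperiment::assay(intensities, "signalB")
  long <- data.table::data.table(
    variant_id = rep(rownames(A), times = ncol(A)),
    sample_id = rep(colnames(A), each = nrow(A)),
    signal_A = as.vector(A),
    signal_B = as.vector(B))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' @rdname writeIntensityTable
#' @export
readIntensityTable <- function(path) {
  long <- data.table::fread(path, sep = "\t")
  vids <- unique(long$variant_id)
  sids <- unique(long$sample_id)
  A <- matrix(NA_real_, length(vids), length(sids),
              dimnames = list(vids, sids))
  B <- A
  A[cbind(long$variant_id, long$sample_id)] <- long$signal_A
  B[cbind(long$variant_id, long$sample_id)] <- long$signal_B
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signalA = A, signalB = B))
  new("IntensitySet", se)
}

#' Write and read the sample sheet
#'
#' Columns: id, pool, subgroup, inbred_penalty, replicate_of, parent1,
#' parent2 (and f, admix_w for round-tripping simulated panels).
#'
#' @param panel A [PanelConfig-class] or its samples data.frame.
#' @param path TSV path.
#' @return The path, invisibly (writer); a [PanelConfig-class] (reader).
#' @export
writeSampleSheet <- function(panel, path) {
  s <- if (is(panel, "PanelConfig")) panelSamples(panel) else panel
  out <- data.frame(id = s$id, pool = s$pool, subgroup = s$subgroup,
                    inbred_penalty = s$penalty,
                    replicate_of = s$replicate_of,
                    parent1 = s$parent1, parent2 = s$parent2,
                    f = s$f, admix_w = s$admix_w)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  s <- as.data.frame(data.table::fread(path, sep = "\t",
                                       na.strings = c("NA", "")))
  df <- data.frame(id = as.character(s$id), pool = s$pool,
                   subgroup = s$subgroup,
                   f = if ("f" %in% names(s)) s$f else 0,
                   penalty = as.numeric(s$inbred_penalty),
                   replicate_of = as.character(s$replicate_of),
                   parent1 = as.character(s$parent1),
                   parent2 = as.character(s$parent2),
                   admix_w = if ("admix_w" %in% names(s)) s$admix_w
                             else NA_real_)
  PanelConfig(df)
}

#' Write gene intervals as BED
#'
#' BED is 0-based half-open; the 1-based inclusive gene intervals are
#' converted on export and back-converted by the reader.
#'
#' @param genes `GRanges` of genes.
#' @param path BED path.
#' @return The path, invisibly (writer); a `GRanges` (reader).
#' @export
writeGenesBed <- function(genes, path) {
  out <- genes
  nm <- if ("gene_id" %in% names(mcols(out))) mcols(out)$gene_id
        else paste0("gene", seq_along(out))
  mcols(out) <- DataFrame(name = nm)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' @rdname writeGenesBed
#' @export
readGenesBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if ("name" %in% names(mcols(gr))) {
    mcols(gr) <- DataFrame(gene_id = mcols(gr)$name)
  }
  gr
}

#' Write a complete fixture set to a directory
#'
#' Emits the sequencing calls as VCF, intensities and sample sheet as
#' TSV, genes as BED, the true genotypes as TSV, and a JSON manifest
#' listing the seed and settings, so every downstream stage can be
#' exercised from files. Everything round-trips through the module
#' readers.
#'
#' @param study Result of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (the manifest path included),
#'   invisibly.
#' @export
writeFixtureSet <- function(study, dir) {
  if (nrow(panelSamples(study$truth)) == 0L) stop("empty panel")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "sequencing_calls.vcf.gz"),
    intensities = file.path(dir, "intensities.tsv"),
    samples = file.path(dir, "sample_sheet.tsv"),
    genes = file.path(dir, "genes.bed"),
    truth = file.path(dir, "true_genotypes.tsv"),
    manifest = file.path(dir, "manifest.json"))
  writeSeqVcf(study$seqCalls, paths$vcf)
  writeIntensityTable(study$intensities, paths$intensities)
  writeSampleSheet(study$panel, paths$samples)
  writeGenesBed(genes(study$genome), paths$genes)
  tg <- data.table::as.data.table(trueGenotypes(study$truth),
                                  keep.rownames = "variant_id")
  data.table::fwrite(tg, paths$truth, sep = "\t")
  manifest <- list(seed = study$seed,
                   nVariants = length(variantInfo(study$truth)),
                   nSamples = nrow(panelSamples(study$truth)),
                   settings = study$settings,
                   files = lapply(paths, basename))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             paths$manifest)
  invisible(paths)
}
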