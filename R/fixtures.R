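# Packaged reference data: the published table of 41 pathogenic CNVs in 39
# schizophrenia carriers (hg19, 1-based start + size on disk, converted to
# the internal 0-based half-open convention on load), the known-locus table
# derived from it, and hg19 chromosome lengths.

#' hg19 chromosome lengths
#'
#' Named vector of GRCh37/hg19 chromosome lengths in bp (1..22, X), labels
#' without "chr" prefix.
#'
#' @return named numeric vector.
#' @export
hg19_chrom_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560)
}

#' The packaged pathogenic-CNV reference table
#'
#' Loads the 41 clinically adjudicated pathogenic CNVs identified in 39
#' unrelated schizophrenia carriers, annotated with IQ group, sex,
#' cytoband, copy state, segmental-duplication breakpoint flag and RefSeq
#' gene count. On-disk coordinates are hg19 1-based start plus size;
#' they are converted to 0-based half-open on load. The three whole-X
#' aneuploidies carry no published start position and are represented as
#' intervals of the published size from position 1, flagged
#' `karyotype_level` (they bypass the probe filter downstream).
#'
#' @return data.table with columns `no`, `sample_id`, `group`, `sex`,
#'   `chrom`, `cytoband`, `start`, `end` (0-based half-open), `size_bp`,
#'   `state`, `segdup` (logical), `genes_n`, `karyotype_level` (logical).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_pathogenic_cnvs.tsv",
                      package = "cnviq", mustWork = TRUE)
  x <- fread(path, sep = "\t", header = TRUE,
             colClasses = list(character = c("sample_id", "chrom")))
  cc <- coords_from_1based(x$start_1based, x$size_bp)
  x[, `:=`(start = cc$start, end = cc$end,
           segdup = segdup == 1L, karyotype_level = karyotype_level == 1L)]
  x[, start_1based := NULL]
  setcolorder(x, c("no", "sample_id", "group", "sex", "chrom", "cytoband",
                   "start", "end", "size_bp", "state", "segdup", "genes_n",
                   "karyotype_level"))
  x[]
}

#' Known pathogenic locus table derived from the packaged reference CNVs
#'
#' One entry per distinct (chromosome, start, end, state) among the packaged
#' pathogenic CNVs, each assigned tier `pathogenic` and a default matching
#' criterion of reciprocal overlap >= 0.5 with state match. Entries are kept
#' per coordinate variant rather than merged per cytoband because nested or
#' atypical events at recurrent loci (e.g. the short nested 22q11.2
#' deletions) fall below 0.5 reciprocal overlap with the canonical interval.
#' The engine is an approximation of expert ACMG review; supply your own
#' table to override tiers or matching stringency.
#'
#' @param scale coordinate scale factor (default 1; the synthetic genome
#'   uses 0.1).
#' @param min_recip matching criterion recorded per entry (default 0.5).
#' @return data.table: `label`, `chrom`, `start`, `end`, `state`, `tier`,
#'   `min_recip`, `karyotype_level`.
#' @export
table1_known_loci <- function(scale = 1, min_recip = 0.5) {
  t1 <- table1_fixture()
  loci <- unique(t1[, .(chrom, start, end, state, cytoband, karyotype_level)])
  loci[, label := paste0(cytoband, "_", state, "_",
                         format(start + 1, scientific = FALSE, trim = TRUE),
                         "_", format(end - start, scientific = FALSE, trim = TRUE))]
  stopifnot(!anyDuplicated(loci$label))
  loci[, `:=`(start = floor(start * scale), end = ceiling(end * scale),
              tier = "pathogenic", min_recip = min_recip)]
  loci[, cytoband := NULL]
  setcolorder(loci, c("label", "chrom", "start", "end", "state", "tier",
                      "min_recip", "karyotype_level"))
  loci[]
}
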