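# Tab-separated readers/writers for the formats the pipeline consumes.
# Every reader documents its coordinate convention; internal storage is
# always 0-based half-open.

#' Read a BED-like interval file
#'
#' Tab-separated, no header by default (chrom, start, end, then any extra
#' columns). BED proper is 0-based half-open; set `based = 1` for 1-based
#' inclusive input, which is converted on load.
#'
#' @param path file path.
#' @param col_names optional column names for extra columns beyond the first
#'   three.
#' @param based 0 (BED, default) or 1 (1-based inclusive start/end).
#' @param header does the file carry a header line?
#' @return data.table with normalized `chrom`, 0-based `start`, `end`.
#' @export
read_bed <- function(path, col_names = NULL, based = 0, header = FALSE) {
  x <- fread(path, header = header, sep = "\t")
  if (!header) {
    nm <- c("chrom", "start", "end")
    extra <- ncol(x) - 3
    if (extra > 0) {
      more <- if (!is.null(col_names)) col_names else paste0("V", seq_len(extra))
      nm <- c(nm, more[seq_len(extra)])
    }
    setnames(x, seq_along(nm), nm)
  }
  x[, chrom := norm_chrom(chrom)]
  if (based == 1) {
    x[, start := start - 1L]  # end stays: 1-based inclusive end == half-open end
  }
  validate_intervals(as.data.frame(x), path)
  x[]
}

#' Write intervals as a BED-like file
#'
#' @param x data.frame with `chrom`, `start`, `end` (internal 0-based).
#' @param path output path.
#' @param based 0 writes BED half-open (default); 1 writes 1-based inclusive.
#' @export
write_bed <- function(x, path, based = 0) {
  x <- as.data.table(as.data.frame(x))
  if (based == 1) x[, start := start + 1L]
  fwrite(x, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a per-caller CNV call table
#'
#' Tab-separated with header: `sample_id`, `chrom`, `start`, `end`, `state`
#' (loss/gain), `probes`, `caller`, `platform`. Coordinates 0-based half-open
#' unless `based = 1`.
#'
#' @param path file path.
#' @param based coordinate convention of the file (0 or 1).
#' @return data.table of calls.
#' @export
read_cnv_calls <- function(path, based = 0) {
  x <- fread(path, sep = "\t", header = TRUE)
  req <- c("sample_id", "chrom", "start", "end", "state", "probes",
           "caller", "platform")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("calls file missing columns: ", paste(miss, collapse = ", "))
  x[, chrom := norm_chrom(chrom)]
  if (based == 1) x[, start := start - 1L]
  if (!all(x$state %in% c("loss", "gain"))) {
    stop("state must be 'loss' or 'gain'")
  }
  if (any(x$probes < 1)) stop("probes must be >= 1")
  validate_intervals(as.data.frame(x), path)
  x[]
}

#' Read an exon annotation table
#'
#' Tab-separated BED4-like: chrom, start, end, gene symbol. GFF-style exon
#' annotation should be reduced to these four columns before loading.
#'
#' @param path file path.
#' @param based coordinate convention (0 default).
#' @param header header line present?
#' @return data.table with `chrom`, `start`, `end`, `gene`.
#' @export
read_exons <- function(path, based = 0, header = FALSE) {
  read_bed(path, col_names = "gene", based = based, header = header)
}

#' Read gene-sets in GMT format
#'
#' Tab-separated: set name, description, then one gene symbol per field.
#' Symbols are uppercased; empty sets are dropped with a warning.
#'
#' @param path file path.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    list(name = f[1], genes = genes)
  })
  out <- lapply(sets, `[[`, "genes")
  names(out) <- vapply(sets, `[[`, character(1), "name")
  empty <- lengths(out) == 0
  if (any(empty)) {
    warning("dropping empty gene-sets: ", paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  out
}

#' Write gene-sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject phenotype table
#'
#' Tab-separated with header. Expected columns: `sample_id`, `sex` (M/F),
#' `platform`, optional `fsiq`, `viq`, `piq` (integer scores),
#' `descriptive_range` (ID/borderline/average), `years_education`, and
#' logical flags `special_education`, `school_difficulties`,
#' `early_leaving_mitigated`. Missing values use `na_token`.
#'
#' @param path file path.
#' @param na_token string representing a missing value (default ".").
#' @return data.table of phenotypes.
#' @export
read_phenotypes <- function(path, na_token = ".") {
  x <- fread(path, sep = "\t", header = TRUE, na.strings = na_token)
  if (!all(c("sample_id", "sex", "platform") %in% names(x))) {
    stop("phenotype file must have sample_id, sex, platform")
  }
  for (col in c("special_education", "school_difficulties",
                "early_leaving_mitigated")) {
    if (col %in% names(x)) x[, (col) := as.logical(get(col))]
  }
  x[]
}

#' Read a known-locus table
#'
#' Tab-separated with header: `label`, `chrom`, `start`, `end`, `state`
#' (loss/gain/either), `tier`, `min_recip`. Coordinates 0-based half-open
#' unless `based = 1`.
#'
#' @param path file path.
#' @param based coordinate convention.
#' @return data.table usable as the `known` argument of [classify_cnvs()].
#' @export
read_known_loci <- function(path, based = 0) {
  x <- fread(path, sep = "\t", header = TRUE)
  x[, chrom := norm_chrom(chrom)]
  if (based == 1) x[, start := start - 1L]
  stopifnot(all(x$state %in% c("loss", "gain", "either")))
  if (anyDuplicated(x$label)) stop("known-locus labels must be unique")
  validate_intervals(as.data.frame(x), path)
  x[]
}
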