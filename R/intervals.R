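#' @import data.table
NULL

# All intervals in this package are 0-based half-open [start, end) on a
# chromosome labelled without any "chr" prefix. length = end - start.

#' Normalize chromosome labels
#'
#' Strips any leading "chr" prefix so that "chr1" and "1" compare equal.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Validate a table of genomic intervals
#'
#' Checks the half-open interval invariants: integer-like coordinates,
#' `start >= 0` and `start < end`. Called internally by every interval
#' operation; exported so callers can validate eagerly on ingest.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x` invisibly, with `chrom` normalized.
#' @export
validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    stop(what, " table must have columns chrom, start, end")
  }
  if (nrow(x) > 0) {
    if (anyNA(x$start) || anyNA(x$end)) {
      stop(what, ": NA coordinates are not allowed")
    }
    if (any(x$start < 0)) stop(what, ": start must be >= 0")
    if (any(x$start >= x$end)) {
      stop(what, ": start must be < end (half-open, zero-length forbidden)")
    }
  }
  x$chrom <- norm_chrom(x$chrom)
  invisible(x)
}

#' Interval lengths
#'
#' @param x data.frame with `start`, `end` (0-based half-open).
#' @return integer-ish vector of lengths `end - start`.
#' @export
interval_length <- function(x) {
  x$end - x$start
}

#' Convert 1-based inclusive (start, size) coordinates to 0-based half-open
#'
#' Published CNV tables give a 1-based start position and a size in bp.
#' The conversion is exact and invertible: `(s, z) -> [s - 1, s - 1 + z)`.
#'
#' @param start1 1-based start position(s).
#' @param size interval size(s) in bp.
#' @return data.frame with `start`, `end` in the internal convention.
#' @seealso [coords_to_1based()]
#' @export
coords_from_1based <- function(start1, size) {
  stopifnot(all(start1 >= 1), all(size >= 1))
  data.frame(start = start1 - 1, end = start1 - 1 + size)
}

#' Convert 0-based half-open coordinates back to 1-based (start, size)
#'
#' Exact inverse of [coords_from_1based()].
#'
#' @param start,end 0-based half-open coordinates.
#' @return data.frame with `start1`, `size`.
#' @export
coords_to_1based <- function(start, end) {
  stopifnot(all(start < end))
  data.frame(start1 = start + 1, size = end - start)
}

#' Reciprocal overlap between two intervals
#'
#' The standard criterion for declaring two CNV calls the same event:
#' `min(ovl / len(a), ovl / len(b))` where `ovl` is the intersection length.
#' Zero when chromosomes differ or the intervals are disjoint. Vectorized
#' with recycling over the rows of `a` and `b`.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
reciprocal_overlap <- function(a, b) {
  a <- validate_intervals(a, "a")
  b <- validate_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  if (n == 0) return(numeric(0))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ovl <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ovl <- pmax(ovl, 0)
  ovl[a$chrom[ai] != b$chrom[bi]] <- 0
  la <- (a$end - a$start)[ai]
  lb <- (b$end - b$start)[bi]
  pmin(ovl / la, ovl / lb)
}

#' Fraction of a target interval covered by the union of a track
#'
#' Coverage uses union semantics: overlapping track intervals are flattened
#' before measuring, so no base is counted twice. An empty track gives 0.
#'
#' @param target data.frame of one or more intervals (`chrom`, `start`, `end`).
#' @param track data.frame of track intervals (e.g. segmental duplications).
#' @return numeric vector, one covered fraction in `[0, 1]` per target row.
#' @export
covered_fraction <- function(target, track) {
  target <- validate_intervals(target, "target")
  if (nrow(target) == 0) return(numeric(0))
  if (is.null(track) || nrow(track) == 0) return(rep(0, nrow(target)))
  track <- validate_intervals(track, "track")
  vapply(seq_len(nrow(target)), function(i) {
    tc <- track[track$chrom == target$chrom[i], , drop = FALSE]
    if (nrow(tc) == 0) return(0)
    s <- pmax(tc$start, target$start[i])
    e <- pmin(tc$end, target$end[i])
    keep <- s < e
    if (!any(keep)) return(0)
    union_length(s[keep], e[keep]) / (target$end[i] - target$start[i])
  }, numeric(1))
}

# Total length of the union of intervals [s_i, e_i) (same chromosome assumed).
union_length <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  tot + (cur_e - cur_s)
}

#' Gene symbols whose exons intersect a target interval
#'
#' A gene counts as overlapped when the union of its exons intersects the
#' target by at least 1 bp (the usual "genic CNV" definition).
#'
#' @param target a single-row data.frame (`chrom`, `start`, `end`).
#' @param exons exon track: data.frame with `chrom`, `start`, `end`, `gene`.
#' @return sorted character vector of gene symbols (possibly empty).
#' @export
genes_overlapped <- function(target, exons) {
  target <- validate_intervals(target, "target")
  stopifnot(nrow(target) == 1)
  if (is.null(exons) || nrow(exons) == 0) return(character(0))
  exons <- validate_intervals(exons, "exons")
  hit <- exons$chrom == target$chrom &
    exons$start < target$end & exons$end > target$start
  sort(unique(exons$gene[hit]))
}

#' Per-subject (CNV, gene) overlap pairs
#'
#' Overlap join between a CNV table and an exon track, deduplicated to
#' distinct (row id, gene) pairs. This is the workhorse behind gene-content
#' annotation and gene-set burden counting.
#'
#' @param cnvs data.table/data.frame with `chrom`, `start`, `end` and an id
#'   column named by `id_col`.
#' @param exons exon track with `chrom`, `start`, `end`, `gene`.
#' @param id_col name of the identifier column carried through (default
#'   `"sample_id"`).
#' @return data.table with columns `id_col`, `gene`, distinct pairs.
#' @export
gene_hits <- function(cnvs, exons, id_col = "sample_id") {
  cnvs <- as.data.table(validate_intervals(as.data.frame(cnvs), "cnvs"))
  out0 <- data.table(id = character(0), gene = character(0))
  setnames(out0, "id", id_col)
  if (nrow(cnvs) == 0 || is.null(exons) || nrow(exons) == 0) return(out0)
  ex <- as.data.table(validate_intervals(as.data.frame(exons), "exons"))
  setkey(ex, chrom, start, end)
  ov <- foverlaps(cnvs[, .(chrom, start, end, id = get(id_col))],
                  ex, type = "any", nomatch = NULL)
  if (nrow(ov) == 0) return(out0)
  out <- unique(ov[, .(id, gene)])
  setnames(out, "id", id_col)
  out[]
}

#' Join fragmented CNV calls
#'
#' Large CNVs are sometimes reported by calling algorithms as several
#' adjacent fragments. Adjacent same-state calls are merged iteratively when
#' the gap between them is smaller than both `max_gap_bp` and
#' `max_gap_fraction` of the merged span. The operation is idempotent and the
#' output is sorted and non-overlapping.
#'
#' @param calls data.frame of intervals for ONE sample, chromosome and copy
#'   state; extra columns `probes` (max is kept) and `callers` (union) are
#'   carried through when present. A `state` column, if present, must be
#'   constant.
#' @param max_gap_bp absolute gap ceiling in bp (default 50 kb).
#' @param max_gap_fraction gap ceiling as a fraction of the merged span
#'   (default 0.2).
#' @return data.frame of merged intervals.
#' @export
join_fragments <- function(calls, max_gap_bp = 50000, max_gap_fraction = 0.2) {
  calls <- as.data.frame(validate_intervals(as.data.frame(calls), "calls"))
  if (nrow(calls) <= 1) return(calls)
  if (length(unique(calls$chrom)) > 1) {
    stop("join_fragments: calls span more than one chromosome")
  }
  if ("state" %in% names(calls) && length(unique(calls$state)) > 1) {
    stop("join_fragments: mixed copy states")
  }
  if ("sample_id" %in% names(calls) && length(unique(calls$sample_id)) > 1) {
    stop("join_fragments: calls from more than one sample")
  }
  calls <- calls[order(calls$start, calls$end), , drop = FALSE]
  repeat {
    merged_any <- FALSE
    i <- 1
    while (i < nrow(calls)) {
      gap <- calls$start[i + 1] - calls$end[i]
      span <- max(calls$end[i + 1], calls$end[i]) - calls$start[i]
      if (gap <= 0 || (gap < max_gap_bp && gap < max_gap_fraction * span)) {
        calls$end[i] <- max(calls$end[i], calls$end[i + 1])
        if ("probes" %in% names(calls)) {
          calls$probes[i] <- max(calls$probes[i], calls$probes[i + 1])
        }
        if ("callers" %in% names(calls)) {
          calls$callers[i] <- paste(
            sort(unique(unlist(strsplit(
              c(calls$callers[i], calls$callers[i + 1]), ",")))),
            collapse = ",")
        }
        calls <- calls[-(i + 1), , drop = FALSE]
        merged_any <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!merged_any) break
  }
  rownames(calls) <- NULL
  calls
}
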