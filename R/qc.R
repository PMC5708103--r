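# Consensus QC: reduce raw multi-caller CNV calls to an artifact-free
# consensus set. Fixed pipeline order: consensus -> size/probe/segdup
# thresholds -> batch-artifact removal -> fragment joining.

#' Multi-caller consensus CNV calls
#'
#' A consensus CNV is emitted wherever at least two distinct calling
#' algorithms produced same-sample, same-state calls with reciprocal overlap
#' at or above `min_recip`. Pairing is greedy by descending overlap (ties by
#' leftmost start) and each raw call supports at most one consensus CNV.
#' The consensus interval is the union (default) or intersection of the
#' supporting calls; probe support is the maximum across supporting calls.
#'
#' @param calls data.table of raw calls (`sample_id`, `chrom`, `start`,
#'   `end`, `state`, `probes`, `caller`, `platform`).
#' @param min_recip minimum reciprocal overlap for caller agreement,
#'   in (0, 1] (default 0.5).
#' @param interval `"union"` (default) or `"intersection"` consensus
#'   coordinates.
#' @return data.table of consensus CNVs with `callers` (comma-joined sorted
#'   caller labels) and `n_callers`.
#' @export
consensus_calls <- function(calls, min_recip = 0.5,
                            interval = c("union", "intersection")) {
  interval <- match.arg(interval)
  stopifnot(min_recip > 0, min_recip <= 1)
  calls <- as.data.table(as.data.frame(calls))
  validate_intervals(as.data.frame(calls), "calls")
  calls[, chrom := norm_chrom(chrom)]
  plat <- unique(calls[, .(sample_id, platform)])
  if (anyDuplicated(plat$sample_id)) {
    stop("calls from more than one platform for a single sample")
  }
  out <- vector("list", 0)
  groups <- split(calls, by = c("sample_id", "chrom", "state"), drop = TRUE)
  for (g in groups) {
    if (length(unique(g$caller)) < 2) next
    n <- nrow(g)
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    if (nrow(idx) == 0) next
    i <- idx[, 1]; j <- idx[, 2]
    keep <- g$caller[i] != g$caller[j]
    i <- i[keep]; j <- j[keep]
    if (!length(i)) next
    ro <- reciprocal_overlap(g[i, .(chrom, start, end)],
                             g[j, .(chrom, start, end)])
    ok <- ro >= min_recip
    i <- i[ok]; j <- j[ok]; ro <- ro[ok]
    if (!length(i)) next
    ord <- order(-ro, pmin(g$start[i], g$start[j]))
    used <- rep(FALSE, n)
    for (k in ord) {
      a <- i[k]; b <- j[k]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      members <- c(a, b)
      # absorb further unused calls from additional callers agreeing with
      # the forming consensus
      span <- data.frame(chrom = g$chrom[a],
                         start = min(g$start[members]),
                         end = max(g$end[members]))
      for (m in seq_len(n)) {
        if (used[m] || g$caller[m] %in% g$caller[members]) next
        if (reciprocal_overlap(span, g[m, .(chrom, start, end)]) >= min_recip) {
          used[m] <- TRUE
          members <- c(members, m)
          span$start <- min(g$start[members]); span$end <- max(g$end[members])
        }
      }
      cs <- if (interval == "union") {
        c(min(g$start[members]), max(g$end[members]))
      } else {
        c(max(g$start[members]), min(g$end[members]))
      }
      out[[length(out) + 1]] <- data.table(
        sample_id = g$sample_id[1], chrom = g$chrom[1],
        start = cs[1], end = cs[2], state = g$state[1],
        probes = max(g$probes[members]),
        callers = paste(sort(unique(g$caller[members])), collapse = ","),
        n_callers = length(unique(g$caller[members])),
        platform = g$platform[1])
    }
  }
  if (!length(out)) {
    return(data.table(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      state = character(0), probes = integer(0),
                      callers = character(0), n_callers = integer(0),
                      platform = character(0)))
  }
  res <- rbindlist(out)
  setorder(res, sample_id, chrom, start, end)
  res[]
}

#' Size, probe and segmental-duplication thresholds
#'
#' Keeps consensus CNVs with length strictly greater than `min_size_bp`,
#' probe support of at least `min_probes`, and segmental-duplication
#' coverage strictly below `max_segdup_frac` (union coverage of the CNV by
#' the segdup track). Rows flagged `karyotype_level` (whole-chromosome
#' events) bypass the probe filter. Rejections are returned in the
#' `"rejected"` attribute with the failed criterion.
#'
#' @param cnvs consensus CNV table.
#' @param segdups segmental-duplication track (`chrom`, `start`, `end`);
#'   may be NULL or empty.
#' @param min_size_bp size threshold, exclusive (default 10,000).
#' @param min_probes probe threshold, inclusive (default 10).
#' @param max_segdup_frac segdup coverage ceiling, exclusive (default 0.75).
#' @return filtered data.table; `attr(, "rejected")` holds the dropped rows
#'   with a `reject_reason` column.
#' @export
apply_thresholds <- function(cnvs, segdups = NULL, min_size_bp = 10000,
                             min_probes = 10, max_segdup_frac = 0.75) {
  cnvs <- as.data.table(as.data.frame(cnvs))
  if (nrow(cnvs) == 0) {
    attr(cnvs, "rejected") <- cnvs
    return(cnvs)
  }
  len <- cnvs$end - cnvs$start
  karyo <- if ("karyotype_level" %in% names(cnvs)) {
    isTRUE_v(cnvs$karyotype_level)
  } else rep(FALSE, nrow(cnvs))
  sd_frac <- covered_fraction(as.data.frame(cnvs), segdups)
  reason <- rep(NA_character_, nrow(cnvs))
  reason[sd_frac >= max_segdup_frac] <- "segdup_coverage"
  reason[!karyo & cnvs$probes < min_probes] <- "probe_count"
  reason[len <= min_size_bp] <- "size"
  keep <- is.na(reason)
  rej <- cnvs[!keep]
  if (nrow(rej)) rej[, reject_reason := reason[!keep]]
  res <- cnvs[keep]
  attr(res, "rejected") <- rej
  res
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Remove locus-specific batch artifacts
#'
#' Drops every CNV whose exact (chrom, start, end, state) key is present in
#' more than `max_frac` of the cohort (distinct samples), the signature of a
#' platform/batch artifact. Removal is all-or-none per key.
#'
#' @param cnvs consensus CNV table spanning the whole cohort.
#' @param cohort_n number of subjects in the cohort (> 0).
#' @param max_frac frequency ceiling (default 0.01, i.e. > 1% removed).
#' @return filtered data.table; removed rows in `attr(, "rejected")`.
#' @export
remove_batch_artifacts <- function(cnvs, cohort_n, max_frac = 0.01) {
  if (cohort_n <= 0) stop("cohort_n must be > 0")
  cnvs <- as.data.table(as.data.frame(cnvs))
  if (nrow(cnvs) == 0) {
    attr(cnvs, "rejected") <- cnvs
    return(cnvs)
  }
  carriers <- cnvs[, .(n_samples = uniqueN(sample_id)),
                   by = .(chrom, start, end, state)]
  bad <- carriers[n_samples > max_frac * cohort_n]
  flag <- cnvs[bad, on = .(chrom, start, end, state), which = TRUE, nomatch = NULL]
  keep <- !seq_len(nrow(cnvs)) %in% flag
  rej <- cnvs[!keep]
  if (nrow(rej)) rej[, reject_reason := "batch_artifact"]
  res <- cnvs[keep]
  attr(res, "rejected") <- rej
  res
}

#' Full consensus QC pipeline
#'
#' Applies, in fixed order: multi-caller consensus, size/probe/segdup
#' thresholds, batch-artifact removal, and per-sample fragment joining.
#' Output is invariant to the input ordering of calls.
#'
#' @param calls raw per-caller call table (see [read_cnv_calls()]).
#' @param segdups segmental-duplication track.
#' @param cohort_n cohort size for the batch filter.
#' @param min_recip caller-agreement reciprocal overlap (default 0.5).
#' @param min_size_bp,min_probes,max_segdup_frac threshold parameters, see
#'   [apply_thresholds()].
#' @param batch_max_frac batch-artifact frequency ceiling (default 0.01).
#' @param join_max_gap_bp,join_max_gap_fraction fragment-joining parameters,
#'   see [join_fragments()].
#' @return data.table of QC-passed CNVs; all rejected rows, with reasons, in
#'   `attr(, "rejected")`.
#' @export
cnv_qc_pipeline <- function(calls, segdups = NULL, cohort_n,
                            min_recip = 0.5, min_size_bp = 10000,
                            min_probes = 10, max_segdup_frac = 0.75,
                            batch_max_frac = 0.01,
                            join_max_gap_bp = 50000,
                            join_max_gap_fraction = 0.2) {
  cons <- consensus_calls(calls, min_recip = min_recip)
  thr <- apply_thresholds(cons, segdups, min_size_bp = min_size_bp,
                          min_probes = min_probes,
                          max_segdup_frac = max_segdup_frac)
  rejected <- attr(thr, "rejected")
  bat <- remove_batch_artifacts(thr, cohort_n, max_frac = batch_max_frac)
  rejected <- rbindlist(list(rejected, attr(bat, "rejected")), fill = TRUE)
  if (nrow(bat) == 0) {
    attr(bat, "rejected") <- rejected
    return(bat)
  }
  joined <- rbindlist(lapply(
    split(bat, by = c("sample_id", "chrom", "state"), drop = TRUE),
    join_fragments, max_gap_bp = join_max_gap_bp,
    max_gap_fraction = join_max_gap_fraction))
  setcolorder(joined, names(bat))
  setorder(joined, sample_id, chrom, start, end)
  # post-hoc guard: no surviving CNV may violate a threshold
  stopifnot(all(joined$end - joined$start > min_size_bp))
  attr(joined, "rejected") <- rejected
  joined[]
}
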