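# Rarity adjudication against a population control panel, clinical
# reportability triage, and a deterministic tiered classification rule
# engine approximating ACMG-style CNV interpretation.

TIER_LEVELS <- c("pathogenic", "VUS_likely_pathogenic", "VUS",
                 "VUS_likely_benign", "benign", "unclassified")

#' Construct a control CNV panel
#'
#' @param calls data.frame of control CNVs: `subject`, `chrom`, `start`,
#'   `end`, `state` (0-based half-open). The subject column makes carrier
#'   counting per-subject rather than per-call.
#' @param panel_size declared number of control subjects (may exceed the
#'   number of subjects with calls).
#' @return object of class `control_panel`.
#' @export
control_panel <- function(calls, panel_size) {
  stopifnot(panel_size > 0)
  calls <- as.data.table(as.data.frame(calls))
  if (nrow(calls) > 0) {
    stopifnot(all(c("subject", "chrom", "start", "end", "state") %in% names(calls)))
    validate_intervals(as.data.frame(calls), "control panel")
    calls[, chrom := norm_chrom(chrom)]
    stopifnot(all(calls$state %in% c("loss", "gain")))
  } else {
    calls <- data.table(subject = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        state = character(0))
  }
  structure(list(calls = calls, panel_size = as.integer(panel_size)),
            class = "control_panel")
}

#' @export
print.control_panel <- function(x, ...) {
  cat(sprintf("control panel: %d calls in %d declared subjects\n",
              nrow(x$calls), x$panel_size))
  invisible(x)
}

#' Adjudicate CNV rarity against a control panel
#'
#' For each CNV, counts DISTINCT control subjects carrying a same-state CNV
#' with reciprocal overlap of at least `min_recip`, and flags the CNV rare
#' when `carriers / panel_size < max_freq`.
#'
#' @param cnvs CNV table (`chrom`, `start`, `end`, `state`).
#' @param panel a [control_panel()].
#' @param max_freq population frequency ceiling for "rare" (default 0.001,
#'   i.e. < 0.1%).
#' @param min_recip reciprocal overlap for carrier matching (default 0.5).
#' @return data.table with one row per input CNV: `carriers`, `rare`.
#' @export
is_rare <- function(cnvs, panel, max_freq = 0.001, min_recip = 0.5) {
  stopifnot(inherits(panel, "control_panel"))
  cnvs <- as.data.table(as.data.frame(cnvs))
  n <- nrow(cnvs)
  if (n == 0) return(data.table(carriers = integer(0), rare = logical(0)))
  validate_intervals(as.data.frame(cnvs), "cnvs")
  cnvs[, chrom := norm_chrom(chrom)]
  carriers <- integer(n)
  pc <- panel$calls
  if (nrow(pc) > 0) {
    q <- cnvs[, .(row_id = .I, chrom, start, end, state)]
    pk <- copy(pc)
    setkey(pk, chrom, start, end)
    ov <- foverlaps(q, pk, by.x = c("chrom", "start", "end"),
                    type = "any", nomatch = NULL)
    # foverlaps: panel coords in (start, end), query coords in (i.start, i.end)
    if (nrow(ov) > 0) {
      ov <- ov[state == i.state]
    }
    if (nrow(ov) > 0) {
      inter <- pmin(ov$end, ov$i.end) - pmax(ov$start, ov$i.start)
      ro <- pmin(inter / (ov$end - ov$start), inter / (ov$i.end - ov$i.start))
      ov <- ov[ro >= min_recip]
      if (nrow(ov) > 0) {
        cnt <- unique(ov[, .(row_id, subject)])[, .N, by = row_id]
        carriers[cnt$row_id] <- cnt$N
      }
    }
  }
  data.table(carriers = carriers,
             rare = carriers / panel$panel_size < max_freq)
}

#' Clinical reportability triage
#'
#' A CNV is assessed for clinical relevance when it is rare AND either
#' exonic with length above `min_exonic_bp` (default 100 kb) or non-coding
#' with length above `min_noncoding_bp` (default 500 kb).
#'
#' @param rare logical vector: rarity flags.
#' @param exonic logical vector: overlaps >= 1 bp of coding sequence.
#' @param length_bp numeric vector of CNV lengths.
#' @param min_exonic_bp exonic size threshold, exclusive (default 1e5).
#' @param min_noncoding_bp non-coding size threshold, exclusive (default 5e5).
#' @return logical vector of reportability flags.
#' @export
triage_reportable <- function(rare, exonic, length_bp,
                              min_exonic_bp = 1e5, min_noncoding_bp = 5e5) {
  rare & ((exonic & length_bp > min_exonic_bp) |
            (!exonic & length_bp > min_noncoding_bp))
}

#' Classify CNVs into clinical tiers
#'
#' Deterministic rule cascade approximating expert ACMG-style review:
#' \enumerate{
#'   \item rarity is adjudicated against the control panel; non-reportable
#'     CNVs (common, or below the triage size thresholds) stay
#'     \code{unclassified};
#'   \item reportable CNVs matching a known-locus entry (same chromosome,
#'     state match unless the entry says \code{either}, reciprocal overlap at
#'     or above the entry's \code{min_recip}) take the entry's tier; when
#'     several entries match, the most severe tier wins and the conflict is
#'     recorded in the rule trace;
#'   \item remaining reportable CNVs become \code{VUS}.
#' }
#' The clinical two-tier collapse (pathogenic or VUS-likely-pathogenic) is
#' exposed as `is_pathogenic`. The engine is an explicit approximation of
#' cytogeneticist judgment; tiers are overridable by supplying a different
#' known-locus table.
#'
#' @param cnvs CNV table (`chrom`, `start`, `end`, `state`; optional
#'   `sample_id`, `genes_n`, `karyotype_level`).
#' @param panel a [control_panel()]; an empty panel treats every CNV as
#'   having zero control carriers.
#' @param known known-locus table (`label`, `chrom`, `start`, `end`,
#'   `state`, `tier`, `min_recip`), e.g. [table1_known_loci()].
#' @param exons optional exon track; when supplied, gene content is
#'   recomputed (`genes` comma list, `genes_n`). Otherwise an existing
#'   `genes_n` column is used for the exonic flag.
#' @param max_freq,min_recip rarity parameters, see [is_rare()].
#' @param min_exonic_bp,min_noncoding_bp triage thresholds, see
#'   [triage_reportable()].
#' @return data.table: input columns plus `length_bp`, `carriers`, `rare`,
#'   `exonic`, `reportable`, `tier`, `is_pathogenic`, `rule_trace`.
#' @export
classify_cnvs <- function(cnvs, panel, known, exons = NULL,
                          max_freq = 0.001, min_recip = 0.5,
                          min_exonic_bp = 1e5, min_noncoding_bp = 5e5) {
  cnvs <- as.data.table(as.data.frame(cnvs))
  if (nrow(cnvs) == 0) {
    cnvs[, `:=`(length_bp = integer(0), carriers = integer(0),
                rare = logical(0), exonic = logical(0),
                reportable = logical(0), tier = character(0),
                is_pathogenic = logical(0), rule_trace = character(0))]
    return(cnvs[])
  }
  validate_intervals(as.data.frame(cnvs), "cnvs")
  cnvs[, chrom := norm_chrom(chrom)]
  cnvs[, length_bp := end - start]
  rr <- is_rare(cnvs, panel, max_freq = max_freq, min_recip = min_recip)
  cnvs[, `:=`(carriers = rr$carriers, rare = rr$rare)]
  if (!is.null(exons)) {
    cnvs[, .row := .I]
    hits <- gene_hits(cnvs, exons, id_col = ".row")
    gn <- hits[, .(genes = paste(sort(unique(gene)), collapse = ","),
                   genes_n = uniqueN(gene)), by = .row]
    cnvs[, `:=`(genes = "", genes_n = 0L)]
    cnvs[gn$.row, `:=`(genes = gn$genes, genes_n = gn$genes_n)]
    cnvs[, .row := NULL]
  } else if (!"genes_n" %in% names(cnvs)) {
    stop("supply an exon track or a genes_n column for the exonic flag")
  }
  cnvs[, exonic := genes_n > 0]
  cnvs[, reportable := triage_reportable(rare, exonic, length_bp,
                                         min_exonic_bp, min_noncoding_bp)]
  known <- as.data.table(as.data.frame(known))
  stopifnot(all(known$tier %in% TIER_LEVELS))
  tier <- rep("unclassified", nrow(cnvs))
  trace <- ifelse(cnvs$rare,
                  ifelse(cnvs$reportable, "rare;reportable", "rare;below_triage_size"),
                  "common")
  rep_idx <- which(cnvs$reportable)
  for (i in rep_idx) {
    cand <- known[chrom == cnvs$chrom[i] &
                    (state == "either" | state == cnvs$state[i])]
    if (nrow(cand) > 0) {
      ro <- reciprocal_overlap(cnvs[i, .(chrom, start, end)],
                               cand[, .(chrom, start, end)])
      cand <- cand[ro >= cand$min_recip]
    }
    if (nrow(cand) > 0) {
      sev <- match(cand$tier, TIER_LEVELS)
      best <- which.min(sev)
      tier[i] <- cand$tier[best]
      trace[i] <- paste0(trace[i], ";known_locus:", cand$label[best])
      if (nrow(cand) > 1) {
        trace[i] <- paste0(trace[i], ";conflict:",
                           paste(sort(cand$label[-best]), collapse = "|"))
      }
    } else {
      tier[i] <- "VUS"
      trace[i] <- paste0(trace[i], ";no_known_match")
    }
  }
  cnvs[, `:=`(tier = tier,
              is_pathogenic = tier %in% c("pathogenic", "VUS_likely_pathogenic"),
              rule_trace = trace)]
  # invariant guards
  stopifnot(all(!cnvs$is_pathogenic | cnvs$reportable),
            all(!cnvs$reportable | cnvs$rare))
  cnvs[]
}

#' Per-group diagnostic yield summary
#'
#' Counts, per IQ group, the subjects carrying at least one pathogenic CNV,
#' at least one VUS, at least one clinically reportable CNV, and two or more
#' reportable CNVs. Subjects are counted once per category regardless of how
#' many qualifying CNVs they carry; denominators are full group sizes
#' including CNV-free subjects.
#'
#' @param classified classified CNV table ([classify_cnvs()] output) with a
#'   `sample_id` column.
#' @param groups data.frame `sample_id`, `group` covering every cohort
#'   subject (CNV-free subjects included). Every sample in `classified`
#'   must appear here.
#' @return data.table with one row per group plus an `all` row: `n`,
#'   carrier counts and percentage yields per category.
#' @export
yield_summary <- function(classified, groups) {
  classified <- as.data.table(as.data.frame(classified))
  groups <- as.data.table(as.data.frame(groups))
  stopifnot(all(c("sample_id", "group") %in% names(groups)))
  if (nrow(classified) > 0 &&
      !all(classified$sample_id %in% groups$sample_id)) {
    stop("classified CNVs include subjects without an assigned group")
  }
  per_subj <- if (nrow(classified) > 0) {
    classified[, .(n_pathogenic = sum(is_pathogenic),
                   n_vus = sum(tier == "VUS"),
                   n_reportable = sum(reportable)), by = sample_id]
  } else {
    data.table(sample_id = character(0), n_pathogenic = integer(0),
               n_vus = integer(0), n_reportable = integer(0))
  }
  m <- merge(groups, per_subj, by = "sample_id", all.x = TRUE)
  for (col in c("n_pathogenic", "n_vus", "n_reportable")) {
    m[is.na(get(col)), (col) := 0L]
  }
  summarize <- function(d, label) {
    data.table(group = label, n = nrow(d),
               pathogenic_carriers = sum(d$n_pathogenic >= 1),
               vus_carriers = sum(d$n_vus >= 1),
               reportable_carriers = sum(d$n_reportable >= 1),
               multi_reportable_carriers = sum(d$n_reportable >= 2))
  }
  out <- rbindlist(c(lapply(split(m, m$group), function(d)
    summarize(d, d$group[1])), list(summarize(m, "all"))))
  out[, `:=`(pathogenic_yield_pct = 100 * pathogenic_carriers / n,
             vus_yield_pct = 100 * vus_carriers / n,
             reportable_yield_pct = 100 * reportable_carriers / n)]
  out[]
}

#' Descriptive statistics of a classified CNV table
#'
#' Recomputes, from the table itself: CNV count, distinct carriers, loss and
#' gain counts, size median/min/max, and the number with breakpoints in
#' segmental duplications (logical `segdup` column, when present).
#'
#' @param classified CNV table with `sample_id`, `state`, `start`, `end`
#'   and optionally `segdup`.
#' @return named list of summary statistics.
#' @export
classified_cnv_stats <- function(classified) {
  x <- as.data.table(as.data.frame(classified))
  len <- x$end - x$start
  list(n_cnvs = nrow(x),
       n_carriers = uniqueN(x$sample_id),
       n_loss = sum(x$state == "loss"),
       n_gain = sum(x$state == "gain"),
       median_size = stats::median(len),
       min_size = min(len),
       max_size = max(len),
       n_segdup = if ("segdup" %in% names(x)) sum(isTRUE_v(x$segdup)) else NA_integer_)
}
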