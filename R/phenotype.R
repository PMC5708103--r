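# IQ-subgroup assignment from test scores, descriptive ranges and
# educational attainment.

GROUP_LEVELS <- c("average", "borderline", "ID", "NVLD", "unassignable")

#' Assign subjects to IQ groups
#'
#' Deterministic per-subject rule cascade:
#' \enumerate{
#'   \item NVLD when PIQ is at least 15 points below VIQ (both present) and
#'     full-scale IQ (or, when FSIQ is absent, the VIQ/PIQ mean used as a
#'     proxy) is at least 71; a 15-point gap with FSIQ of 70 or below is
#'     assigned ID instead;
#'   \item scores: FSIQ (or proxy) of 70 or below gives ID, 71-84 borderline,
#'     85 and above average;
#'   \item a descriptive range (ID/borderline/average) is taken verbatim;
#'   \item education: a history of special education gives ID; 8-11 years of
#'     formal education with reported school difficulties (including
#'     repeated grades) gives borderline; 12 or more years with no reported
#'     difficulties gives average; early school leaving for external reasons
#'     (incarceration, vocation, family, illness onset) despite good
#'     performance gives average;
#'   \item otherwise the subject is unassignable.
#' }
#' Scores always override education and descriptive ranges; a contradiction
#' (e.g. an average-range score with an ID descriptive range) is noted in
#' the rule trace.
#'
#' @param pheno phenotype data.frame (see [read_phenotypes()] for columns;
#'   missing columns are treated as all-missing).
#' @return data.table: `pheno` plus `assigned_group` and `assign_rule` (the
#'   winning evidence source).
#' @export
assign_iq_group <- function(pheno) {
  p <- as.data.table(as.data.frame(pheno))
  n <- nrow(p)
  opt_num <- function(col) if (col %in% names(p)) as.numeric(p[[col]]) else rep(NA_real_, n)
  opt_chr <- function(col) if (col %in% names(p)) as.character(p[[col]]) else rep(NA_character_, n)
  opt_lgl <- function(col) if (col %in% names(p)) isTRUE_v(p[[col]]) else rep(FALSE, n)
  fsiq <- opt_num("fsiq"); viq <- opt_num("viq"); piq <- opt_num("piq")
  rng <- opt_chr("descriptive_range")
  yrs <- opt_num("years_education")
  spec <- opt_lgl("special_education")
  diffs <- opt_lgl("school_difficulties")
  mitig <- opt_lgl("early_leaving_mitigated")

  eff_fsiq <- ifelse(!is.na(fsiq), fsiq,
                     ifelse(!is.na(viq) & !is.na(piq), (viq + piq) / 2, NA_real_))
  group <- rep("unassignable", n)
  rule <- rep("none", n)
  for (i in seq_len(n)) {
    gap_nvld <- !is.na(viq[i]) && !is.na(piq[i]) && (viq[i] - piq[i] >= 15)
    if (gap_nvld && (is.na(eff_fsiq[i]) || eff_fsiq[i] >= 71)) {
      group[i] <- "NVLD"; rule[i] <- "score:viq_piq_gap"
    } else if (gap_nvld && eff_fsiq[i] <= 70) {
      group[i] <- "ID"; rule[i] <- "score:fsiq_le70_overrides_nvld"
    } else if (!is.na(eff_fsiq[i])) {
      group[i] <- if (eff_fsiq[i] <= 70) "ID"
        else if (eff_fsiq[i] < 85) "borderline" else "average"
      rule[i] <- if (!is.na(fsiq[i])) "score:fsiq" else "score:viq_piq_mean"
    } else if (!is.na(rng[i])) {
      stopifnot(rng[i] %in% c("ID", "borderline", "average"))
      group[i] <- rng[i]; rule[i] <- "descriptive_range"
    } else if (spec[i]) {
      group[i] <- "ID"; rule[i] <- "education:special_education"
    } else if (!is.na(yrs[i]) && yrs[i] >= 8 && yrs[i] <= 11 && diffs[i]) {
      group[i] <- "borderline"; rule[i] <- "education:8_11yrs_difficulties"
    } else if (!is.na(yrs[i]) && yrs[i] >= 12 && !diffs[i]) {
      group[i] <- "average"; rule[i] <- "education:ge12yrs_no_difficulties"
    } else if (mitig[i]) {
      group[i] <- "average"; rule[i] <- "education:early_leaving_mitigated"
    }
    # note score-vs-range contradictions without changing the outcome
    if (startsWith(rule[i], "score") && !is.na(rng[i]) && rng[i] != group[i] &&
        !(group[i] == "NVLD")) {
      rule[i] <- paste0(rule[i], ";conflict:descriptive_range_", rng[i])
    }
  }
  p[, `:=`(assigned_group = group, assign_rule = rule)]
  p[]
}

#' Cohort census by IQ group
#'
#' Tabulates assigned groups and the two composite strata used downstream:
#' LIQ (borderline plus ID) and expanded LIQ (LIQ plus NVLD, the grouping
#' used for the genome-wide burden analyses after pathogenic-CNV exclusion).
#'
#' @param assigned data.frame with an `assigned_group` column.
#' @return list with `counts` (data.table of group, n, pct), `n`,
#'   `liq_n`, `expanded_liq_n`.
#' @export
group_census <- function(assigned) {
  a <- as.data.table(as.data.frame(assigned))
  if (nrow(a) == 0) {
    return(list(counts = data.table(group = character(0), n = integer(0),
                                    pct = numeric(0)),
                n = 0L, liq_n = 0L, expanded_liq_n = 0L))
  }
  counts <- a[, .N, by = .(group = assigned_group)]
  setnames(counts, "N", "n")
  counts[, pct := 100 * n / nrow(a)]
  counts <- counts[order(match(group, GROUP_LEVELS))]
  liq <- sum(a$assigned_group %in% c("borderline", "ID"))
  list(counts = counts[], n = nrow(a), liq_n = liq,
       expanded_liq_n = liq + sum(a$assigned_group == "NVLD"))
}
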