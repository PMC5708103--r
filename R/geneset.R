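# Gene-set exonic burden enrichment: per-subject gene-set burden as a
# logistic-regression predictor of group membership, deviance
# (likelihood-ratio) test, and BH-FDR across sets, separately per CNV type.

#' Per-subject gene-set exonic burden
#'
#' Counts, for each subject, the DISTINCT gene-set genes whose exons are hit
#' by at least one of the subject's CNVs of the given copy state. Input CNVs
#' are expected to be rare, autosomal and QC-passed already.
#'
#' @param cnvs CNV table (`sample_id`, `chrom`, `start`, `end`, `state`).
#' @param set_genes character vector of gene symbols in the set.
#' @param exons exon track (`chrom`, `start`, `end`, `gene`).
#' @param state `"loss"` or `"gain"`.
#' @param sample_ids subjects to report (zero burden for subjects without
#'   qualifying CNVs); defaults to the samples present in `cnvs`.
#' @return named integer vector of burdens, one per subject.
#' @export
subject_set_burden <- function(cnvs, set_genes, exons, state,
                               sample_ids = NULL) {
  stopifnot(state %in% c("loss", "gain"))
  cnvs <- as.data.table(as.data.frame(cnvs))
  if (is.null(sample_ids)) sample_ids <- unique(cnvs$sample_id)
  out <- stats::setNames(integer(length(sample_ids)), sample_ids)
  st <- state
  sub <- cnvs[cnvs$state == st]
  if (nrow(sub) == 0) return(out)
  hits <- gene_hits(sub, exons)
  hits <- hits[gene %in% toupper(set_genes) | gene %in% set_genes]
  if (nrow(hits) == 0) return(out)
  cnt <- hits[, .(g = uniqueN(gene)), by = sample_id]
  cnt <- cnt[sample_id %in% sample_ids]
  out[cnt$sample_id] <- cnt$g
  out
}

#' Logistic-regression deviance test for gene-set burden
#'
#' Likelihood-ratio chi-square (1 df) comparing the covariate-only logistic
#' model of group membership with the model adding the gene-set burden.
#' Separation of the burden term is flagged; the deviance test itself
#' remains the reported p-value (the likelihood-ratio statistic is finite
#' under separation, unlike the Wald statistic).
#'
#' @param burden per-subject integer burden vector.
#' @param response 0/1 (or logical) group indicator, same length.
#' @param covars data.frame of covariates (e.g. sex, platform, total genes
#'   overlapped); columns constant across subjects are dropped.
#' @return list: `deviance`, `p`, `or` (per-gene odds ratio), `separation`.
#' @export
deviance_test <- function(burden, response, covars = NULL) {
  y <- as.integer(as.logical(response) | response > 0)
  stopifnot(length(burden) == length(y), length(unique(y)) == 2)
  d <- data.frame(.y = y, .burden = burden)
  cov_names <- character(0)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    keep <- vapply(covars, function(v) length(unique(v)) > 1, logical(1))
    covars <- covars[, keep, drop = FALSE]
    cov_names <- names(covars)
    d <- cbind(d, covars)
  }
  rhs0 <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
  f0 <- stats::glm(stats::as.formula(paste(".y ~", rhs0)), data = d,
                   family = stats::binomial())
  f1 <- suppressWarnings(
    stats::glm(stats::as.formula(paste(".y ~ .burden +", rhs0)), data = d,
               family = stats::binomial()))
  dev <- max(0, f0$deviance - f1$deviance)
  beta <- stats::coef(f1)[".burden"]
  list(deviance = dev,
       p = stats::pchisq(dev, df = 1, lower.tail = FALSE),
       or = unname(exp(beta)),
       separation = is.na(beta) || abs(beta) > 15)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1, mapped back to input
#' order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of adjusted q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment across a collection of sets
#'
#' For each gene-set and the given CNV type, computes the per-subject
#' gene-set exonic burden, fits the logistic deviance test of expanded-LIQ
#' vs average group membership with sex, platform and the total number of
#' genes overlapped by rare CNVs per subject as covariates, and adjusts
#' p-values across sets by BH-FDR (deletions and duplications are corrected
#' separately by virtue of separate calls per `state`). A set is flagged
#' significant when `q < 0.10` and `p < 0.05`.
#'
#' @param cnvs rare autosomal CNV table (`sample_id`, `chrom`, `start`,
#'   `end`, `state`).
#' @param subjects data.frame: `sample_id`, `response` (1 = expanded-LIQ,
#'   0 = average), `sex`, `platform`, one row per analysis subject.
#' @param gene_sets named list of gene symbol vectors (see [read_gmt()]).
#' @param exons exon track.
#' @param state `"loss"` or `"gain"`.
#' @param total_genes_scope covariate scope for "total genes overlapped":
#'   `"state"` (default; same CNV type as tested) or `"all"` (both types).
#' @return data.table, one row per set: per-group CNV and carrier counts,
#'   `deviance`, `p`, `q`, `or`, `significant`.
#' @export
run_gsea <- function(cnvs, subjects, gene_sets, exons, state,
                     total_genes_scope = c("state", "all")) {
  total_genes_scope <- match.arg(total_genes_scope)
  stopifnot(state %in% c("loss", "gain"))
  subjects <- as.data.table(as.data.frame(subjects))
  stopifnot(all(c("sample_id", "response", "sex", "platform") %in% names(subjects)))
  cnvs <- as.data.table(as.data.frame(cnvs))
  cnvs <- cnvs[sample_id %in% subjects$sample_id]
  gene_sets <- gene_sets[order(names(gene_sets))]  # order-invariant output
  empty <- lengths(gene_sets) == 0
  if (any(empty)) {
    warning("skipping empty gene-sets: ",
            paste(names(gene_sets)[empty], collapse = ", "))
    gene_sets <- gene_sets[!empty]
  }
  if (length(gene_sets) == 0) {
    return(data.table(set = character(0), n_genes = integer(0),
                      cnvs_liq = integer(0), carriers_liq = integer(0),
                      pct_liq = numeric(0), cnvs_avg = integer(0),
                      carriers_avg = integer(0), pct_avg = numeric(0),
                      deviance = numeric(0), p = numeric(0), q = numeric(0),
                      or = numeric(0), significant = logical(0)))
  }
  setorder(subjects, sample_id)
  ids <- subjects$sample_id
  st <- state
  tot_src <- if (total_genes_scope == "state") cnvs[cnvs$state == st] else cnvs
  tot_hits <- gene_hits(tot_src, exons)
  total_genes <- stats::setNames(integer(length(ids)), ids)
  if (nrow(tot_hits) > 0) {
    tg <- tot_hits[, .(g = uniqueN(gene)), by = sample_id]
    total_genes[tg$sample_id] <- tg$g
  }
  sub_state <- cnvs[cnvs$state == st]
  state_hits <- gene_hits(sub_state, exons)
  cnv_gene <- if (nrow(sub_state) > 0) {
    h <- gene_hits(sub_state[, .cnv := .I][], exons, id_col = ".cnv")
    merge(h, sub_state[, .(.cnv, sample_id)], by = ".cnv")
  } else data.table(.cnv = integer(0), gene = character(0),
                    sample_id = character(0))
  resp <- stats::setNames(subjects$response, subjects$sample_id)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- toupper(gene_sets[[nm]])
    burden <- stats::setNames(integer(length(ids)), ids)
    bh <- state_hits[gene %in% gs]
    if (nrow(bh) > 0) {
      bc <- bh[, .(g = uniqueN(gene)), by = sample_id]
      bc <- bc[sample_id %in% ids]
      burden[bc$sample_id] <- bc$g
    }
    dt <- deviance_test(burden, resp[ids],
                        covars = data.frame(sex = subjects$sex,
                                            platform = subjects$platform,
                                            total_genes = total_genes))
    cg <- cnv_gene[gene %in% gs]
    cnv_by_grp <- function(r) {
      s <- ids[resp[ids] == r]
      list(cnvs = uniqueN(cg[sample_id %in% s, .cnv]),
           carriers = sum(burden[s] > 0),
           n = length(s))
    }
    liq <- cnv_by_grp(1); avg <- cnv_by_grp(0)
    data.table(set = nm, n_genes = length(gs),
               cnvs_liq = liq$cnvs, carriers_liq = liq$carriers,
               pct_liq = 100 * liq$carriers / liq$n,
               cnvs_avg = avg$cnvs, carriers_avg = avg$carriers,
               pct_avg = 100 * avg$carriers / avg$n,
               deviance = dt$deviance, p = dt$p, or = dt$or,
               separation = dt$separation)
  })
  res <- rbindlist(rows)
  res[, q := bh_fdr(p)]
  res[, significant := q < 0.10 & p < 0.05]
  setcolorder(res, c("set", "n_genes", "cnvs_liq", "carriers_liq", "pct_liq",
                     "cnvs_avg", "carriers_avg", "pct_avg", "deviance",
                     "p", "q", "or", "separation", "significant"))
  res[]
}
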