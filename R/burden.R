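# Group-comparison statistics: Woolf odds-ratio intervals, Fisher exact
# tests, covariate-adjusted logistic burden regression, rank tests and
# proportion intervals.

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' For the 2x2 table (a = exposed carriers, b = exposed non-carriers,
#' c = unexposed carriers, d = unexposed non-carriers):
#' `OR = (a d) / (b c)` with
#' `CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Any zero cell triggers the Haldane-Anscombe correction (+0.5 to all
#' cells), flagged in the result.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @return list: `or`, `ci_low`, `ci_high`, `corrected` (logical).
#' @export
odds_ratio_woolf <- function(a, b, c, d, alpha = 0.05) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: the p-value sums hypergeometric probabilities
#' of all tables (with the observed margins) no more probable than the
#' observed one.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Mann-Whitney U test
#'
#' Midrank tie handling; exact enumeration when `n1 * n2 <= 400` and there
#' are no ties, otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @return list: `U` (statistic for `x`), `p` (two-sided).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Confidence interval for a binomial proportion
#'
#' Wilson score interval (default) or exact Clopper-Pearson interval.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `> 0`.
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param conf_level confidence level (default 0.95).
#' @return numeric vector `c(low, high)` of proportions.
#' @export
proportion_ci <- function(k, n, method = c("wilson", "clopper_pearson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be > 0")
  stopifnot(k >= 0, k <= n)
  alpha <- 1 - conf_level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, centre - half), min(1, centre + half))
  } else {
    low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
    c(low, high)
  }
}

#' Covariate-adjusted logistic burden regression
#'
#' Fits `response ~ predictor + covariates` by maximum-likelihood logistic
#' regression (IRLS via [stats::glm()]) and reports the per-unit odds ratio
#' for the predictor with a Wald confidence interval and p-value.
#' Non-convergence, a constant predictor, and (quasi-)separation are
#' flagged, never silently returned. Callers performing the genome-wide
#' burden comparison are expected to have excluded pathogenic-CNV carriers
#' beforehand.
#'
#' @param data data.frame with the response, predictor and covariates.
#' @param response name of the 0/1 (or logical/factor) response column.
#' @param predictor name of the per-subject burden column.
#' @param covariates character vector of covariate columns (default sex and
#'   platform); covariates constant in `data` are dropped with a message.
#' @param conf_level Wald CI level (default 0.95).
#' @param label optional predictor label carried into the result.
#' @return data.table row: `label`, `n`, `or`, `ci_low`, `ci_high`, `p`,
#'   `converged`, `degenerate`, `separation`, `covariates`.
#' @export
logistic_burden <- function(data, response, predictor,
                            covariates = c("sex", "platform"),
                            conf_level = 0.95, label = predictor) {
  d <- as.data.frame(data)
  stopifnot(all(c(response, predictor) %in% names(d)))
  y <- d[[response]]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.integer(as.logical(y) | y > 0)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("response must have at least 2 subjects per level")
  }
  covariates <- covariates[covariates %in% names(d)]
  keep <- vapply(covariates, function(cv) length(unique(d[[cv]])) > 1, logical(1))
  if (any(!keep)) {
    message("dropping constant covariates: ",
            paste(covariates[!keep], collapse = ", "))
    covariates <- covariates[keep]
  }
  degenerate <- length(unique(d[[predictor]])) < 2
  if (degenerate) {
    return(data.table(label = label, n = length(y), or = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      converged = FALSE, degenerate = TRUE,
                      separation = FALSE,
                      covariates = paste(covariates, collapse = "+")))
  }
  rhs <- paste(c(predictor, covariates), collapse = " + ")
  d$.y <- y
  fit <- suppressWarnings(
    stats::glm(stats::as.formula(paste(".y ~", rhs)), data = d,
               family = stats::binomial()))
  co <- summary(fit)$coefficients
  beta <- co[predictor, "Estimate"]
  se <- co[predictor, "Std. Error"]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  eps <- 1e-8
  separation <- abs(beta) > 15 ||
    (all(fit$fitted.values > 1 - eps | fit$fitted.values < eps))
  data.table(label = label, n = length(y), or = exp(beta),
             ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
             p = co[predictor, "Pr(>|z|)"],
             converged = fit$converged, degenerate = FALSE,
             separation = separation,
             covariates = paste(covariates, collapse = "+"))
}

#' Per-subject rare-CNV burden predictors
#'
#' Builds the per-subject predictors of the genome-wide burden analyses:
#' CNV count, total length in megabases, and distinct genes overlapped -
#' for all CNVs, deletions and duplications separately. Restricted to
#' autosomes by default (chromosome labels "1".."22"); subjects with no
#' CNVs get zero burden.
#'
#' @param cnvs rare CNV table (`sample_id`, `chrom`, `start`, `end`,
#'   `state`).
#' @param subjects data.frame with `sample_id` covering the full analysis
#'   population.
#' @param exons exon track for gene-content predictors (optional; gene
#'   columns are omitted when NULL).
#' @param autosomes_only drop sex-chromosome CNVs first (default TRUE).
#' @return data.table, one row per subject: `n_all`, `n_loss`, `n_gain`,
#'   `mb_all`, `mb_loss`, `mb_gain` and, with `exons`, `genes_all`,
#'   `genes_loss`, `genes_gain`.
#' @export
subject_burden_table <- function(cnvs, subjects, exons = NULL,
                                 autosomes_only = TRUE) {
  cnvs <- as.data.table(as.data.frame(cnvs))
  subjects <- as.data.table(as.data.frame(subjects))
  stopifnot("sample_id" %in% names(subjects))
  if (nrow(cnvs) > 0) {
    cnvs[, chrom := norm_chrom(chrom)]
    if (autosomes_only) cnvs <- cnvs[chrom %in% as.character(1:22)]
  }
  out <- subjects[, .(sample_id)]
  agg <- if (nrow(cnvs) > 0) {
    cnvs[, .(n_all = .N,
             n_loss = sum(state == "loss"),
             n_gain = sum(state == "gain"),
             mb_all = sum(end - start) / 1e6,
             mb_loss = sum((end - start)[state == "loss"]) / 1e6,
             mb_gain = sum((end - start)[state == "gain"]) / 1e6),
         by = sample_id]
  } else NULL
  out <- merge(out, agg, by = "sample_id", all.x = TRUE)
  if (!is.null(exons)) {
    gcount <- function(sub) {
      h <- gene_hits(sub, exons)
      h[, .(g = uniqueN(gene)), by = sample_id]
    }
    for (spec in list(c("genes_all", "both"), c("genes_loss", "loss"),
                      c("genes_gain", "gain"))) {
      sub <- if (spec[2] == "both") cnvs else cnvs[state == spec[2]]
      g <- if (nrow(sub) > 0) gcount(sub) else
        data.table(sample_id = character(0), g = integer(0))
      setnames(g, "g", spec[1])
      out <- merge(out, g, by = "sample_id", all.x = TRUE)
    }
  }
  for (col in setdiff(names(out), "sample_id")) {
    out[is.na(get(col)), (col) := 0]
  }
  out[]
}
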