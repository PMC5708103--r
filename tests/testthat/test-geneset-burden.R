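toy_exons <- data.frame(
  chrom = "1",
  start = c(1e6, 2e6, 3e6, 4e6, 5e6),
  end   = c(1e6, 2e6, 3e6, 4e6, 5e6) + 2e4,
  gene  = c("GA", "GB", "GC", "GD", "GE"))

test_that("gene-set burden counts distinct set genes hit by same-state CNVs", {
  set_genes <- c("GA", "GB", "GC")
  none <- subject_set_burden(
    data.frame(sample_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), state = character(0)),
    set_genes, toy_exons, "gain", sample_ids = "s1")
  expect_equal(unname(none), 0L)
  # one duplication spanning 3 set genes and 2 non-set genes
  span_all <- data.frame(sample_id = "s1", chrom = "1", start = 9e5,
                         end = 5.1e6, state = "gain")
  expect_equal(unname(subject_set_burden(span_all, set_genes, toy_exons, "gain")), 3L)
  # two CNVs hitting the same set gene count that gene once
  two_hits <- data.frame(sample_id = "s1", chrom = "1",
                         start = c(9.9e5, 1.005e6), end = c(1.005e6, 1.1e6),
                         state = "gain")
  expect_equal(unname(subject_set_burden(two_hits, set_genes, toy_exons, "gain")), 1L)
  # deletions do not contribute to the duplication burden
  expect_equal(unname(subject_set_burden(
    data.frame(sample_id = "s1", chrom = "1", start = 9e5, end = 5.1e6,
               state = "loss"), set_genes, toy_exons, "gain", "s1")), 0L)
})

test_that("deviance test reduces to the 2x2 likelihood-ratio chi-square", {
  y <- rep(c(1, 1, 0, 0), c(30, 70, 15, 85))
  b <- rep(c(1, 0, 1, 0), c(30, 70, 15, 85))
  dt <- deviance_test(b, y)
  m0 <- glm(y ~ 1, family = binomial())
  m1 <- glm(y ~ b, family = binomial())
  expect_equal(dt$deviance, m0$deviance - m1$deviance, tolerance = 1e-10)
  expect_equal(dt$p, pchisq(m0$deviance - m1$deviance, 1, lower.tail = FALSE))
  # burden unrelated to response: deviance ~ 0, p ~ 1
  null <- deviance_test(rep(1, 40), rep(0:1, 20))
  expect_lt(null$deviance, 1e-8)
  expect_gt(null$p, 0.999)
})

test_that("BH adjustment matches the step-up definition and published values", {
  expect_equal(bh_fdr(0.03), 0.03)
  # published duplication p-values, m = 6: smallest adjusted 6 * 0.013 = 0.078
  p6 <- c(0.013, 0.058, 0.078, 0.371, 0.471, 0.761)
  q6 <- bh_fdr(p6)
  expect_equal(min(q6), 0.078)
  expect_equal(q6, oracle_bh(p6))
  # the same smallest p at m = 17 adjusts to ~0.22
  p17 <- c(p6, seq(0.5, 0.99, length.out = 11))
  expect_equal(bh_fdr(p17)[1], 17 * 0.013, tolerance = 1e-9)
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(3:20, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # adjustment preserves the ranking of the raw p-values
  expect_equal(order(q6), order(p6))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("gene-set scan is invariant to set and subject ordering", {
  coh <- generate_cohort(generator_config(
    seed = 21, group_sizes = c(average = 80L, borderline = 30L, ID = 15L, NVLD = 8L),
    emit_raw_calls = FALSE, emit_panel = FALSE))
  sub <- as.data.frame(coh$subjects[!coh$subjects$pathogenic_carrier, ])
  sub$response <- as.integer(sub$true_group %in% c("borderline", "ID", "NVLD"))
  rare <- as.data.frame(coh$cnvs[coh$cnvs$role != "common", ])
  cols <- c("sample_id", "response", "sex", "platform")
  r1 <- run_gsea(rare, sub[, cols], coh$gene_sets, coh$genome$exons, "gain")
  set.seed(4)
  r2 <- run_gsea(rare[sample(nrow(rare)), ],
                 sub[sample(nrow(sub)), cols],
                 coh$gene_sets[sample(length(coh$gene_sets))],
                 coh$genome$exons, "gain")
  expect_equal(r1, r2)
  expect_true(all(r1$q >= r1$p))
})

test_that("the planted duplication-target set dominates the scan", {
  hits <- 0
  for (s in 1:5) {
    coh <- generate_cohort(generator_config(
      seed = 400 + s, emit_raw_calls = FALSE, emit_panel = FALSE))
    sub <- as.data.frame(coh$subjects[!coh$subjects$pathogenic_carrier, ])
    sub$response <- as.integer(sub$true_group %in% c("borderline", "ID", "NVLD"))
    rare <- as.data.frame(coh$cnvs[coh$cnvs$role != "common", ])
    res <- run_gsea(rare, sub[, c("sample_id", "response", "sex", "platform")],
                    coh$gene_sets, coh$genome$exons, "gain")
    if (res$set[which.min(res$p)] == "planted_set") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("empty gene-sets are skipped with a warning", {
  cnvs <- data.frame(sample_id = "s1", chrom = "1", start = 9e5, end = 1.1e6,
                     state = "gain")
  sub <- data.frame(sample_id = c("s1", paste0("t", 1:9)),
                    response = rep(0:1, 5), sex = rep(c("M", "F"), 5),
                    platform = "A6.0")
  expect_warning(
    res <- run_gsea(cnvs, sub, list(ok = "GA", bad = character(0)),
                    toy_exons, "gain"),
    "empty gene-sets")
  expect_equal(res$set, "ok")
})
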