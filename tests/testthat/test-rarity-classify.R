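mk_panel <- function(n_carriers, panel_size = 10113, chrom = "1",
                     start = 1e6, end = 1.2e6, state = "loss") {
  calls <- if (n_carriers > 0) {
    data.frame(subject = paste0("c", seq_len(n_carriers)), chrom = chrom,
               start = start, end = end, state = state)
  } else {
    data.frame(subject = character(0), chrom = character(0),
               start = integer(0), end = integer(0), state = character(0))
  }
  control_panel(calls, panel_size)
}

cnv1 <- data.frame(sample_id = "s1", chrom = "1", start = 1e6, end = 1.2e6,
                   state = "loss")

test_that("rarity uses the < 0.1% carrier-frequency rule", {
  expect_true(is_rare(cnv1, mk_panel(0))$rare)
  # 10 / 10113 = 0.0989% < 0.1%; 11 / 10113 = 0.1088% >= 0.1%
  r10 <- is_rare(cnv1, mk_panel(10))
  expect_equal(r10$carriers, 10)
  expect_true(r10$rare)
  r11 <- is_rare(cnv1, mk_panel(11))
  expect_equal(r11$carriers, 11)
  expect_false(r11$rare)
})

test_that("carrier matching needs same state and 50% reciprocal overlap", {
  # overlap 0.4 of the control call: not a carrier
  shifted <- mk_panel(20, start = 1e6 + 0.6 * 2e5, end = 1.2e6 + 0.6 * 2e5)
  expect_equal(is_rare(cnv1, shifted)$carriers, 0)
  wrong_state <- mk_panel(20, state = "gain")
  expect_equal(is_rare(cnv1, wrong_state)$carriers, 0)
  # duplicated calls for one control subject count once
  dup <- control_panel(data.frame(
    subject = "c1", chrom = "1", start = c(1e6, 1e6 + 5000),
    end = c(1.2e6, 1.2e6 + 5000), state = "loss"), 10113)
  expect_equal(is_rare(cnv1, dup)$carriers, 1)
})

test_that("raising the frequency ceiling is monotone", {
  set.seed(41)
  panel_calls <- do.call(rbind, lapply(1:30, function(i) {
    s <- sample.int(5e6, 1)
    data.frame(subject = paste0("c", sample.int(50, 1)), chrom = "1",
               start = s, end = s + sample(c(1e5, 2e5), 1),
               state = sample(c("loss", "gain"), 1))
  }))
  panel <- control_panel(panel_calls, 5000)
  cnvs <- data.frame(sample_id = paste0("s", 1:40), chrom = "1",
                     start = panel_calls$start[1:40 %% 30 + 1],
                     end = panel_calls$end[1:40 %% 30 + 1],
                     state = panel_calls$state[1:40 %% 30 + 1])
  strict <- is_rare(cnvs, panel, max_freq = 0.001)$rare
  loose <- is_rare(cnvs, panel, max_freq = 0.01)$rare
  expect_true(all(loose[strict]))  # rare at 0.1% implies rare at 1%
})

test_that("reportability triage applies the 100 kb / 500 kb gates", {
  # the published 189,279 bp exonic loss is reportable
  expect_true(triage_reportable(TRUE, TRUE, 189279))
  expect_false(triage_reportable(TRUE, TRUE, 90000))
  expect_false(triage_reportable(TRUE, FALSE, 400000))
  expect_true(triage_reportable(TRUE, FALSE, 600000))
  expect_false(triage_reportable(FALSE, TRUE, 5e6))  # rarity gates everything
})

test_that("classification cascade: known locus, VUS fallback, rarity gate", {
  known <- table1_known_loci()
  panel0 <- mk_panel(0)
  del22 <- data.frame(sample_id = "s1", chrom = "22", start = 18890045,
                      end = 18890045 + 2831545, state = "loss", genes_n = 46)
  cl <- classify_cnvs(del22, panel0, known)
  expect_equal(cl$tier, "pathogenic")
  expect_true(cl$is_pathogenic)
  expect_match(cl$rule_trace, "known_locus:22q11.21")
  # reportable duplication at an unlisted locus -> VUS
  dup9 <- data.frame(sample_id = "s2", chrom = "9", start = 1e6,
                     end = 1e6 + 4e5, state = "gain", genes_n = 3)
  expect_equal(classify_cnvs(dup9, panel0, known)$tier, "VUS")
  # common CNV at a known pathogenic locus stays unclassified
  common_panel <- mk_panel(200, chrom = "22", start = 18890045,
                           end = 18890045 + 2831545, state = "loss")
  cl_common <- classify_cnvs(del22, common_panel, known)
  expect_equal(cl_common$tier, "unclassified")
  expect_false(cl_common$reportable)
})

test_that("classification is a pure function of its inputs", {
  known <- table1_known_loci()
  t1 <- table1_fixture()
  a <- classify_cnvs(t1, mk_panel(0), known)
  b <- classify_cnvs(t1, mk_panel(0), known)
  expect_identical(a, b)
})

test_that("reference-table statistics are recomputed correctly", {
  t1 <- table1_fixture()
  cl <- classify_cnvs(t1, mk_panel(0), table1_known_loci())
  expect_true(all(cl$is_pathogenic))
  st <- classified_cnv_stats(cl)
  expect_equal(st$n_cnvs, 41)
  expect_equal(st$n_carriers, 39)
  expect_equal(st$n_loss, 22)
  expect_equal(st$n_gain, 19)
  expect_equal(st$median_size, 2831545)
  expect_equal(st$min_size, 189279)
  expect_equal(st$max_size, 155065370)
  expect_equal(st$n_segdup, 25)
})

test_that("yields count subjects once and use full group denominators", {
  t1 <- table1_fixture()
  cl <- classify_cnvs(t1, mk_panel(0), table1_known_loci())
  carriers <- unique(t1[, c("sample_id", "group")])
  sizes <- c(average = 325, borderline = 130, ID = 62, NVLD = 29)
  free <- do.call(rbind, lapply(names(sizes), function(g) {
    k <- sizes[[g]] - sum(carriers$group == g)
    data.frame(sample_id = paste0("free_", g, "_", seq_len(k)), group = g)
  }))
  groups <- rbind(as.data.frame(carriers), free)
  ys <- yield_summary(cl, groups)
  getg <- function(g, col) ys[[col]][ys$group == g]
  expect_equal(getg("average", "pathogenic_carriers"), 9)
  expect_equal(getg("borderline", "pathogenic_carriers"), 9)
  expect_equal(getg("ID", "pathogenic_carriers"), 15)
  expect_equal(getg("NVLD", "pathogenic_carriers"), 6)
  expect_equal(getg("all", "pathogenic_carriers"), 39)
  expect_equal(getg("all", "n"), 546)
  # the double-carrier subject (two pathogenic CNVs) is counted once
  expect_equal(sum(cl$sample_id == "565"), 2)
  # subject without a group is an error
  expect_error(yield_summary(cl, groups[-1, ]), "without an assigned group")
  # empty classified table gives zero yields
  ys0 <- yield_summary(cl[0, ], groups)
  expect_true(all(ys0$pathogenic_carriers == 0))
})
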