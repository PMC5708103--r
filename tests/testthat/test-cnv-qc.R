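mk_call <- function(sample_id, chrom, start, end, state, probes, caller,
                    platform = "A6.0") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             state = state, probes = probes, caller = caller,
             platform = platform)
}

test_that("consensus requires two distinct callers", {
  one <- mk_call("s1", "1", 0, 100000, "loss", 20, "iPattern")
  expect_equal(nrow(consensus_calls(one)), 0)
  two <- rbind(one, mk_call("s1", "1", 0, 100000, "loss", 25, "Birdsuite"))
  cons <- consensus_calls(two)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$callers, "Birdsuite,iPattern")
  expect_equal(cons$probes, 25)  # max over supporting calls
  # same caller twice is not agreement
  dup <- rbind(one, mk_call("s1", "1", 0, 100000, "loss", 25, "iPattern"))
  expect_equal(nrow(consensus_calls(dup)), 0)
})

test_that("greedy pairing: overlapping pair merges, lone call is dropped", {
  calls <- rbind(
    mk_call("s1", "1", 0, 100000, "loss", 20, "iPattern"),
    mk_call("s1", "1", 10000, 110000, "loss", 18, "Birdsuite"),
    mk_call("s1", "1", 500000, 600000, "loss", 15, "Birdsuite"))
  cons <- consensus_calls(calls, min_recip = 0.5)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 0)       # union of the supporting calls
  expect_equal(cons$end, 110000)
  # intersection mode
  cons_i <- consensus_calls(calls, min_recip = 0.5, interval = "intersection")
  expect_equal(c(cons_i$start, cons_i$end), c(10000, 100000))
})

test_that("consensus respects state, sample and platform boundaries", {
  calls <- rbind(
    mk_call("s1", "1", 0, 100000, "loss", 20, "iPattern"),
    mk_call("s1", "1", 0, 100000, "gain", 20, "Birdsuite"))
  expect_equal(nrow(consensus_calls(calls)), 0)
  cross <- rbind(
    mk_call("s1", "1", 0, 100000, "loss", 20, "iPattern"),
    mk_call("s2", "1", 0, 100000, "loss", 20, "Birdsuite"))
  expect_equal(nrow(consensus_calls(cross)), 0)
  mixed_platform <- rbind(
    mk_call("s1", "1", 0, 100000, "loss", 20, "iPattern", "A6.0"),
    mk_call("s1", "1", 0, 100000, "loss", 20, "ChAS", "CytoScanHD"))
  expect_error(consensus_calls(mixed_platform), "platform")
})

mk_cnv <- function(start, end, probes = 20, sample_id = "s1", chrom = "1",
                   state = "loss") {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             state = state, probes = probes)
}

test_that("thresholds are strict/inclusive exactly as specified", {
  segdups <- data.frame(chrom = "1", start = 5e6, end = 5e6 + 75000)
  cnvs <- rbind(
    mk_cnv(0, 9500),                      # size 9.5 kb: rejected (> 10 kb rule)
    mk_cnv(0, 10000),                     # exactly 10 kb: still rejected
    mk_cnv(0, 10001),                     # 10,001 bp: kept
    mk_cnv(1e6, 1e6 + 50000, probes = 9), # 9 probes: rejected
    mk_cnv(2e6, 2e6 + 50000, probes = 10),# 10 probes: kept
    mk_cnv(5e6, 5e6 + 100000),            # exactly 75% segdup: rejected
    mk_cnv(5e6 - 135, 5e6 + 100000))      # 74.9% segdup: kept
  res <- apply_thresholds(cnvs, segdups)
  expect_equal(res$start, c(0, 2e6, 5e6 - 135))
  rej <- attr(res, "rejected")
  expect_equal(nrow(rej), 4)
  expect_setequal(rej$reject_reason[rej$end - rej$start <= 10000], "size")
  expect_true("probe_count" %in% rej$reject_reason)
  expect_true("segdup_coverage" %in% rej$reject_reason)
})

test_that("karyotype-level events bypass the probe filter only", {
  cnv <- mk_cnv(0, 15000000, probes = 1)
  cnv$karyotype_level <- TRUE
  expect_equal(nrow(apply_thresholds(cnv, NULL)), 1)
  cnv$karyotype_level <- FALSE
  expect_equal(nrow(apply_thresholds(cnv, NULL)), 0)
})

test_that("batch-artifact removal is all-or-none per exact key", {
  key_cnv <- function(ids) do.call(rbind, lapply(ids, function(i)
    mk_cnv(1e6, 1e6 + 30000, sample_id = i)))
  # 6 of 546 samples (1.1% > 1%): all removed
  cnvs6 <- rbind(key_cnv(paste0("s", 1:6)), mk_cnv(5e6, 5e6 + 30000))
  res6 <- remove_batch_artifacts(cnvs6, cohort_n = 546)
  expect_equal(nrow(res6), 1)
  expect_equal(res6$start, 5e6)
  # 5 of 546 (0.92%): retained
  cnvs5 <- key_cnv(paste0("s", 1:5))
  expect_equal(nrow(remove_batch_artifacts(cnvs5, cohort_n = 546)), 5)
  # singleton retained; invalid cohort size refused
  expect_equal(nrow(remove_batch_artifacts(key_cnv("s1"), 546)), 1)
  expect_error(remove_batch_artifacts(cnvs5, 0), "cohort_n")
  # a shifted copy (different key) does not count toward the same locus
  shifted <- rbind(key_cnv(paste0("s", 1:5)),
                   mk_cnv(1e6 + 1, 1e6 + 30001, sample_id = "s6"))
  expect_equal(nrow(remove_batch_artifacts(shifted, 546)), 6)
})

test_that("QC pipeline output is invariant to input ordering", {
  coh <- generate_cohort(generator_config(
    seed = 5, group_sizes = c(average = 60L, borderline = 24L, ID = 12L, NVLD = 6L),
    emit_panel = FALSE))
  calls <- coh$calls
  qc1 <- cnv_qc_pipeline(calls, coh$genome$segdups, cohort_n = 102)
  set.seed(1)
  qc2 <- cnv_qc_pipeline(calls[sample(nrow(calls))], coh$genome$segdups,
                         cohort_n = 102)
  attr(qc1, "rejected") <- NULL
  attr(qc2, "rejected") <- NULL
  expect_equal(qc1, qc2)
})

test_that("QC recovers every planted CNV and removes every artifact", {
  coh <- generate_cohort(generator_config(
    seed = 9, group_sizes = c(average = 60L, borderline = 24L, ID = 12L, NVLD = 6L),
    emit_panel = FALSE))
  qc <- cnv_qc_pipeline(coh$calls, coh$genome$segdups, cohort_n = 102)
  key <- function(d) paste(d$sample_id, d$chrom, d$start, d$end, d$state)
  truth <- coh$ledger[!startsWith(coh$ledger$role, "artifact") &
                        coh$ledger$role != "batch_artifact"]
  expect_setequal(key(qc), key(truth))       # 100% recall, 0% leakage
  # no surviving CNV violates a threshold
  expect_true(all(qc$end - qc$start > 10000))
  expect_true(all(qc$probes >= 10))
  expect_true(all(covered_fraction(as.data.frame(qc), coh$genome$segdups) < 0.75))
})
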