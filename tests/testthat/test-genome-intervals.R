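iv <- function(chrom, start, end) data.frame(chrom = chrom, start = start, end = end)

test_that("reciprocal overlap handles identity, disjoint and partial cases", {
  a <- iv("1", 0, 100)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(a, iv("1", 200, 300)), 0.0)
  expect_equal(reciprocal_overlap(a, iv("2", 0, 100)), 0.0)
  expect_equal(reciprocal_overlap(a, iv("1", 50, 150)), 0.5)
  # asymmetric sizes: min of the two fractions
  expect_equal(reciprocal_overlap(iv("1", 0, 1000), iv("1", 0, 100)), 0.1)
  expect_error(reciprocal_overlap(iv("1", 100, 100), a), "start must be <")
})

test_that("reciprocal overlap is symmetric on random interval pairs", {
  set.seed(11)
  for (i in 1:200) {
    a <- random_interval()
    b <- random_interval()
    expect_identical(reciprocal_overlap(a, b), reciprocal_overlap(b, a))
  }
})

test_that("covered fraction uses union semantics", {
  target <- iv("1", 0, 100)
  expect_equal(covered_fraction(target, NULL), 0)
  empty_track <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0))
  expect_equal(covered_fraction(target, empty_track), 0)
  expect_equal(covered_fraction(target, iv("1", 0, 200)), 1)
  # overlapping track intervals must not double-count
  expect_equal(covered_fraction(target, iv("1", c(0, 30), c(40, 60))), 0.6)
  expect_equal(covered_fraction(target, iv("2", 0, 100)), 0)
})

test_that("covered fraction matches a per-base bitmap oracle", {
  set.seed(23)
  for (i in 1:50) {
    target <- data.frame(chrom = "1", start = 0, end = sample(500:5000, 1))
    k <- sample(1:8, 1)
    s <- sample.int(target$end, k, replace = TRUE) - 1
    w <- sample.int(2000, k, replace = TRUE)
    track <- data.frame(chrom = sample(c("1", "2"), k, replace = TRUE),
                        start = s, end = s + w)
    expect_equal(covered_fraction(target, track),
                 oracle_covered_fraction(target, track))
  }
})

test_that("genes overlapped requires >= 1 bp of exon overlap", {
  exons <- data.frame(
    chrom = "1",
    start = c(100, 300, 1000, 1200, 5000, 6000),
    end   = c(200, 400, 1100, 1300, 5100, 6100),
    gene  = c("A", "A", "B", "B", "C", "C"))
  expect_identical(genes_overlapped(iv("1", 7000, 8000), exons), character(0))
  expect_identical(genes_overlapped(iv("1", 150, 180), exons), "A")
  # spans exons of A and B but only intron space of C (between its exons)
  expect_identical(genes_overlapped(iv("1", 350, 1250), exons), c("A", "B"))
  expect_identical(genes_overlapped(iv("1", 5150, 5900), exons), character(0))
})

test_that("fragment joining merges joinable gaps only and is idempotent", {
  single <- iv("1", 0, 50000)
  expect_equal(join_fragments(single), single)
  # 20 kb gap: < 50 kb and < 20% of the 2 Mb span
  frag <- iv("1", c(0, 1020000), c(1000000, 2000000))
  joined <- join_fragments(frag)
  expect_equal(nrow(joined), 1)
  expect_equal(joined$start, 0)
  expect_equal(joined$end, 2000000)
  # 300 kb gap exceeds both ceilings
  far <- iv("1", c(0, 400000), c(100000, 500000))
  expect_equal(join_fragments(far), far[order(far$start), ])
  # idempotence
  expect_equal(join_fragments(joined), joined)
  # mixed states refused
  bad <- cbind(frag, state = c("loss", "gain"))
  expect_error(join_fragments(bad), "mixed copy states")
})

test_that("fragment joining never reduces coverage and keeps output sorted", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    s <- sort(sample.int(5e6, k))
    w <- sample.int(2e5, k)
    calls <- data.frame(chrom = "1", start = s, end = s + w)
    res <- join_fragments(calls)
    expect_true(all(diff(res$start) > 0))
    expect_true(all(res$end[-nrow(res)] <= res$start[-1]))
    cov_in <- sum(sapply(seq_len(nrow(res)), function(j)
      oracle_covered_fraction(res[j, ], calls) * (res$end[j] - res$start[j])))
    expect_gte(sum(res$end - res$start) + 1e-9, cov_in)
    # every input base remains covered by the output
    for (j in seq_len(nrow(calls))) {
      expect_equal(oracle_covered_fraction(calls[j, ], res), 1)
    }
  }
})

test_that("1-based/0-based conversion round-trips over the reference table", {
  t1 <- table1_fixture()
  back <- coords_to_1based(t1$start, t1$end)
  expect_equal(back$size, t1$size_bp, ignore_attr = TRUE)
  again <- coords_from_1based(back$start1, back$size)
  expect_equal(again$start, t1$start)
  expect_equal(again$end, t1$end)
})

test_that("chromosome labels are normalized on ingest", {
  expect_identical(norm_chrom(c("chr1", "1", "chrX")), c("1", "1", "X"))
  expect_equal(reciprocal_overlap(iv("chr1", 0, 100), iv("1", 0, 100)), 1)
})
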