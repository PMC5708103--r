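# Independent brute-force oracles used to cross-check the package
# implementations on small instances. These deliberately share no code with
# the functions they verify.

# per-base bitmap coverage of target by the union of track intervals
oracle_covered_fraction <- function(target, track) {
  bases <- seq(target$start + 1, target$end)  # 1-indexed base ids
  covered <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != target$chrom) next
    hit <- bases > track$start[i] & bases <= track$end[i]
    covered <- covered | hit
  }
  mean(covered)
}

# two-sided Fisher p by full enumeration of tables with fixed margins,
# point-probability method
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  prob <- function(x) {
    stats::dhyper(x, c1, n - c1, r1)
  }
  p_obs <- prob(a)
  xs <- max(0, r1 - (n - c1)):min(r1, c1)
  sum(prob(xs)[prob(xs) <= p_obs * (1 + 1e-7)])
}

# step-up BH by direct definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_of <- function(xi) {
    xs <- pool[xi]; ys <- pool[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  us <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# random valid interval on a small chromosome set
random_interval <- function(chroms = c("1", "2"), max_pos = 10000) {
  s <- sample.int(max_pos - 2, 1)
  w <- sample.int(max_pos - s, 1)
  data.frame(chrom = sample(chroms, 1), start = s, end = s + w)
}
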