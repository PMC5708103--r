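# Self-contained synthetic cohort generator. Emulates the study design the
# pipeline assumes: an IQ-stratified schizophrenia cohort on two genotyping
# platforms, a background rare-CNV rate, a minority of subjects carrying
# large known-locus pathogenic CNVs enriched in the low-IQ strata, an
# elevated genic-duplication rate in the expanded low-IQ stratum, raw
# two-caller call emission with fragmentation and injected artifacts, and a
# population control panel. A ground-truth ledger accompanies every cohort.

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline targets: group sizes
#' 325/130/62/29 (average / borderline / ID / NVLD), pathogenic-carrier
#' probabilities 9/325, 9/130, 15/62 and 6/29, a genic-duplication
#' enrichment odds ratio of 1.42 per gene in the expanded low-IQ stratum,
#' and a 10,113-subject control panel. The synthetic genome is hg19 at
#' `scale` (default 1/10) with `n_genes` well-separated genes.
#'
#' @param seed integer RNG seed; a fixed seed makes all outputs identical.
#' @param group_sizes named integer vector (average, borderline, ID, NVLD).
#' @param platform_mix probability a subject is on platform `A6.0` (the
#'   remainder are `CytoScanHD`).
#' @param prop_male probability of sex `M`.
#' @param pathogenic_rates named per-group carrier probabilities.
#' @param genic_dup_rate Poisson mean of distinct genes duplicated per
#'   average-IQ subject; multiplied by `dup_enrichment_or` in the expanded
#'   low-IQ stratum (exponential tilting, so the per-gene logistic odds
#'   ratio equals `dup_enrichment_or` exactly).
#' @param dup_enrichment_or planted per-gene duplication odds ratio.
#' @param genic_del_rate Poisson mean of distinct genes deleted (both strata).
#' @param nongenic_rate Poisson mean of non-genic rare CNVs per state.
#' @param common_cnv_rate Poisson mean of common-polymorphism CNVs.
#' @param panel_size declared control-panel size.
#' @param n_common_loci,common_freq_range common CNV loci count and
#'   population-frequency range (all above the 0.1% rarity line).
#' @param n_rare_panel_loci,rare_panel_max_carriers loci present in the
#'   panel below the rarity line (1..max carriers).
#' @param artifact_rate Poisson mean of single-caller artifact calls.
#' @param n_batch_loci,batch_frac batch-artifact loci and the fraction of
#'   subjects carrying them at identical coordinates (> 1% so the batch
#'   filter fires).
#' @param frag_prob probability a large (> 150 kb) true CNV is emitted
#'   fragmented by both callers.
#' @param caller_jitter_bp maximum inward endpoint jitter of the second
#'   caller.
#' @param n_genes,n_gene_sets,set_size_range synthetic gene complement and
#'   gene-set collection; set 1 (`planted_set`) receives duplication-target
#'   weighting `planted_set_weight` in low-IQ subjects.
#' @param planted_set_weight sampling weight multiplier for planted-set
#'   genes when choosing duplication targets in low-IQ subjects.
#' @param scale genome scale factor relative to hg19.
#' @param emit_raw_calls,emit_panel emit per-caller raw calls / the control
#'   panel (turn off for fast distribution-level replicates).
#' @return validated config list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    group_sizes = c(average = 325L, borderline = 130L, ID = 62L, NVLD = 29L),
    platform_mix = 0.5, prop_male = 0.6,
    pathogenic_rates = c(average = 9 / 325, borderline = 9 / 130,
                         ID = 15 / 62, NVLD = 6 / 29),
    genic_dup_rate = 0.8, dup_enrichment_or = 1.42, genic_del_rate = 0.8,
    nongenic_rate = 0.5, common_cnv_rate = 0.5,
    panel_size = 10113L,
    n_common_loci = 25L, common_freq_range = c(0.003, 0.03),
    n_rare_panel_loci = 40L, rare_panel_max_carriers = 9L,
    artifact_rate = 0.7, n_batch_loci = 3L, batch_frac = 0.02,
    frag_prob = 0.3, caller_jitter_bp = 2000L,
    n_genes = 500L, n_gene_sets = 17L, set_size_range = c(20L, 80L),
    planted_set_weight = 3,
    scale = 0.1,
    emit_raw_calls = TRUE, emit_panel = TRUE) {
  cfg <- as.list(environment())
  stopifnot(all(names(cfg$group_sizes) == c("average", "borderline", "ID", "NVLD")),
            all(cfg$group_sizes >= 0),
            all(cfg$pathogenic_rates >= 0 & cfg$pathogenic_rates <= 1),
            cfg$platform_mix >= 0, cfg$platform_mix <= 1,
            cfg$prop_male >= 0, cfg$prop_male <= 1,
            cfg$genic_dup_rate >= 0, cfg$dup_enrichment_or > 0,
            cfg$panel_size > 0, cfg$batch_frac >= 0, cfg$batch_frac <= 1,
            cfg$scale > 0, cfg$scale <= 1, cfg$n_genes > 0)
  class(cfg) <- "generator_config"
  cfg
}

# Sample n intervals of widths in width_range on the autosomes, uniformly
# by length, rejecting any candidate within `margin` of the intervals in
# `avoid` (data.frame chrom/start/end). Used for all intergenic placement.
place_intervals <- function(n, width_range, chrom_lengths, avoid = NULL,
                            margin = 60000) {
  chroms <- names(chrom_lengths)
  probs <- chrom_lengths / sum(chrom_lengths)
  a_ch <- if (is.null(avoid)) character(0) else as.character(avoid$chrom)
  a_s <- if (is.null(avoid)) numeric(0) else as.numeric(avoid$start)
  a_e <- if (is.null(avoid)) numeric(0) else as.numeric(avoid$end)
  o_ch <- character(n); o_s <- numeric(n); o_e <- numeric(n)
  got <- 0
  guard <- 0
  while (got < n) {
    guard <- guard + 1
    if (guard > 50 * n + 1000) stop("placement rejection sampling stalled")
    ch <- sample(chroms, 1, prob = probs)
    w <- round(stats::runif(1, width_range[1], width_range[2]))
    s <- floor(stats::runif(1, 0, chrom_lengths[[ch]] - w))
    hit <- a_ch == ch & a_s - margin < s + w & a_e + margin > s
    if (!any(hit)) {
      got <- got + 1
      o_ch[got] <- ch; o_s[got] <- s; o_e[got] <- s + w
      a_ch <- c(a_ch, ch); a_s <- c(a_s, s); a_e <- c(a_e, s + w)
    }
  }
  data.table(chrom = o_ch, start = o_s, end = o_e)
}

#' Build the miniature synthetic genome
#'
#' hg19 chromosome lengths at `cfg$scale`, a complement of well-separated
#' protein-coding gene models (autosomes; 2-4 exons each), a
#' segmental-duplication track, common/rare control-panel loci, batch
#' artifact loci, disjoint non-genic placement pools, and the known
#' pathogenic loci mapped proportionally from their published hg19
#' coordinates. Uses the current RNG stream; [generate_cohort()] seeds it.
#'
#' @param cfg a [generator_config()].
#' @return list: `chrom_lengths`, `genes`, `exons`, `segdups`,
#'   `common_loci`, `rare_panel_loci`, `batch_loci`, `nongenic_pool`,
#'   `artifact_pool`, `known_loci`.
#' @export
synthetic_genome <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  lens <- round(hg19_chrom_lengths() * cfg$scale)
  auto <- lens[as.character(1:22)]
  # genes: evenly spaced with jitter, guaranteeing wide separation so one
  # genic CNV hits exactly one gene
  n_per <- stats::setNames(pmax(1L, round(cfg$n_genes * auto / sum(auto))),
                           names(auto))
  genes <- rbindlist(lapply(names(auto), function(ch) {
    k <- n_per[[ch]]
    spacing <- auto[[ch]] / (k + 1)
    centre <- spacing * seq_len(k) +
      round(stats::runif(k, -0.15 * spacing, 0.15 * spacing))
    w <- round(stats::runif(k, 15000, 40000))
    data.table(chrom = ch, start = pmax(0, round(centre - w / 2)),
               end = pmax(0, round(centre - w / 2)) + w)
  }))
  known <- table1_known_loci(scale = cfg$scale)
  # background genes keep clear of the known pathogenic loci so a background
  # genic CNV can never reach 0.5 reciprocal overlap with a locus entry
  kn_auto <- known[chrom %in% names(auto)]
  clear <- !vapply(seq_len(nrow(genes)), function(i) {
    sel <- kn_auto$chrom == genes$chrom[i]
    any(kn_auto$start[sel] - 80000 < genes$end[i] &
          kn_auto$end[sel] + 80000 > genes$start[i])
  }, logical(1))
  genes <- genes[clear]
  genes[, gene := sprintf("G%04d", seq_len(.N))]
  # one synthetic gene inside each autosomal known locus, so planted
  # pathogenic CNVs are exonic; excluded from background CNV targeting
  locus_genes <- kn_auto[, .(chrom,
                             start = floor((start + end) / 2) - 5000,
                             end = floor((start + end) / 2) + 5000)]
  locus_genes <- unique(locus_genes)
  locus_genes[, gene := sprintf("LG%02d", seq_len(.N))]
  mk_exons <- function(gtab) {
    rbindlist(lapply(seq_len(nrow(gtab)), function(i) {
      span <- gtab$end[i] - gtab$start[i]
      k <- sample(2:4, 1)
      # exon lattice inside the span; first exon at the span start
      bounds <- round(seq(0, span, length.out = k + 1))
      data.table(chrom = gtab$chrom[i],
                 start = gtab$start[i] + utils::head(bounds, -1),
                 end = gtab$start[i] + utils::head(bounds, -1) +
                   pmax(200, round((bounds[-1] - utils::head(bounds, -1)) * 0.4)),
                 gene = gtab$gene[i])
    }))
  }
  exons <- rbind(mk_exons(genes), mk_exons(locus_genes))
  avoid <- rbind(genes[, .(chrom, start, end)],
                 known[, .(chrom, start, end)])
  segdups <- place_intervals(30, c(40000, 120000), auto, avoid)
  avoid <- rbind(avoid, segdups)
  common_loci <- place_intervals(cfg$n_common_loci, c(20000, 100000), auto, avoid)
  common_loci[, `:=`(locus = sprintf("common%02d", .I),
                     freq = stats::runif(.N, cfg$common_freq_range[1],
                                         cfg$common_freq_range[2]))]
  avoid <- rbind(avoid, common_loci[, .(chrom, start, end)])
  rare_panel_loci <- place_intervals(cfg$n_rare_panel_loci, c(15000, 60000),
                                     auto, avoid)
  rare_panel_loci[, locus := sprintf("rarepanel%02d", .I)]
  avoid <- rbind(avoid, rare_panel_loci[, .(chrom, start, end)])
  batch_loci <- place_intervals(cfg$n_batch_loci, c(28000, 32000), auto, avoid)
  avoid <- rbind(avoid, batch_loci[, .(chrom, start, end)])
  nongenic_pool <- place_intervals(120, c(12000, 80000), auto, avoid)
  avoid <- rbind(avoid, nongenic_pool[, .(chrom, start, end)])
  artifact_pool <- place_intervals(120, c(12000, 40000), auto, avoid)
  list(chrom_lengths = lens, genes = genes[], exons = exons[],
       segdups = segdups[], common_loci = common_loci[],
       rare_panel_loci = rare_panel_loci[], batch_loci = batch_loci[],
       nongenic_pool = nongenic_pool[], artifact_pool = artifact_pool[],
       known_loci = known)
}

# group-consistent phenotype fields for one subject
synth_phenotype <- function(group) {
  p <- list(fsiq = NA_integer_, viq = NA_integer_, piq = NA_integer_,
            descriptive_range = NA_character_, years_education = NA_integer_,
            special_education = FALSE, school_difficulties = FALSE,
            early_leaving_mitigated = FALSE)
  path <- stats::runif(1)
  if (group == "NVLD") {
    p$viq <- sample(90:110, 1)
    p$piq <- p$viq - sample(15:30, 1)
    p$years_education <- sample(10:16, 1)
  } else if (path < 0.4) {                    # numeric score on record
    p$fsiq <- switch(group, average = sample(85:115, 1),
                     borderline = sample(71:84, 1), ID = sample(45:70, 1))
    p$years_education <- switch(group, average = sample(11:17, 1),
                                borderline = sample(7:12, 1), ID = sample(6:12, 1))
    p$school_difficulties <- group != "average" && stats::runif(1) < 0.7
    p$special_education <- group == "ID" && stats::runif(1) < 0.7
  } else if (path < 0.5) {                    # descriptive range only
    p$descriptive_range <- group
  } else if (group == "average" && path < 0.55) {  # early leaver, mitigated
    p$years_education <- sample(8:11, 1)
    p$early_leaving_mitigated <- TRUE
  } else {                                    # educational attainment
    if (group == "average") {
      p$years_education <- sample(12:19, 1)
    } else if (group == "borderline") {
      p$years_education <- sample(8:11, 1)
      p$school_difficulties <- TRUE
    } else {                                  # ID
      p$special_education <- TRUE
      p$years_education <- sample(6:12, 1)
      p$school_difficulties <- stats::runif(1) < 0.5
    }
  }
  p
}

#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from `cfg$seed` (fixed seed implies identical output),
#' builds the miniature genome, assigns subjects to IQ strata with
#' group-consistent phenotypes, plants pathogenic known-locus CNVs with the
#' configured per-group carrier probabilities, draws background rare CNVs
#' (genic duplications exponentially tilted in the expanded low-IQ stratum
#' so the per-gene logistic odds ratio equals `dup_enrichment_or`), plants
#' common CNVs matched to control-panel loci, and optionally emits raw
#' two-caller calls with fragmentation plus injected artifacts and the
#' control panel. A ground-truth ledger (`role` per planted event) is
#' always produced.
#'
#' @param cfg a [generator_config()].
#' @return list: `subjects` (phenotypes + `true_group` + `pathogenic_carrier`),
#'   `cnvs` (truth table of QC-survivor events: pathogenic, rare, common),
#'   `ledger` (all planted events incl. artifacts, with `role`),
#'   `calls` (raw per-caller calls or NULL), `panel` ([control_panel()] or
#'   NULL), `genome`, `gene_sets`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  genome <- synthetic_genome(cfg)
  genes <- genome$genes
  n <- sum(cfg$group_sizes)
  subjects <- data.table(
    sample_id = sprintf("S%04d", seq_len(n)),
    true_group = rep(names(cfg$group_sizes), cfg$group_sizes),
    sex = ifelse(stats::runif(n) < cfg$prop_male, "M", "F"),
    platform = ifelse(stats::runif(n) < cfg$platform_mix, "A6.0", "CytoScanHD"))
  ph <- rbindlist(lapply(subjects$true_group, synth_phenotype))
  subjects <- cbind(subjects, ph)
  liq <- subjects$true_group %in% c("borderline", "ID", "NVLD")

  # gene-sets: set 1 is the planted duplication-target set
  set_sizes <- sample(cfg$set_size_range[1]:cfg$set_size_range[2],
                      cfg$n_gene_sets, replace = TRUE)
  gene_sets <- lapply(set_sizes, function(k) sample(genes$gene, k))
  names(gene_sets) <- c("planted_set",
                        sprintf("null_set_%02d", seq_len(cfg$n_gene_sets - 1)))

  events <- vector("list", 0)
  add <- function(ev) events[[length(events) + 1]] <<- ev

  # pathogenic known-locus CNVs
  known <- genome$known_loci
  carrier <- stats::runif(n) < cfg$pathogenic_rates[subjects$true_group]
  subjects[, pathogenic_carrier := carrier]
  for (i in which(carrier)) {
    k <- known[sample(nrow(known), 1)]
    len <- k$end - k$start
    jmax <- if (k$karyotype_level) 0 else floor(min(1000, 0.04 * len))
    j1 <- if (jmax > 0) sample(0:jmax, 1) else 0
    j2 <- if (jmax > 0) sample(0:jmax, 1) else 0
    add(data.table(sample_id = subjects$sample_id[i], chrom = k$chrom,
                   start = k$start + j1, end = k$end - j2, state = k$state,
                   role = "pathogenic", locus = k$label,
                   karyotype_level = k$karyotype_level))
  }

  # rare genic CNVs; duplications tilted in the expanded low-IQ stratum
  dup_w <- rep(1, nrow(genes))
  dup_w[genes$gene %in% gene_sets$planted_set] <- cfg$planted_set_weight
  lam_dup <- cfg$genic_dup_rate * ifelse(liq, cfg$dup_enrichment_or, 1)
  n_dup <- stats::rpois(n, lam_dup)
  n_del <- stats::rpois(n, cfg$genic_del_rate)
  gsubj <- integer(0); ggene <- integer(0); gstate <- character(0)
  for (i in seq_len(n)) {
    picks <- integer(0)
    if (n_dup[i] > 0) {
      w <- if (liq[i]) dup_w else NULL
      picks <- sample.int(nrow(genes), min(n_dup[i], nrow(genes)), prob = w)
    }
    dels <- integer(0)
    if (n_del[i] > 0) {
      dels <- sample(setdiff(seq_len(nrow(genes)), picks),
                     min(n_del[i], nrow(genes) - length(picks)))
    }
    k <- length(picks) + length(dels)
    if (k > 0) {
      gsubj <- c(gsubj, rep(i, k))
      ggene <- c(ggene, picks, dels)
      gstate <- c(gstate, rep(c("gain", "loss"),
                              c(length(picks), length(dels))))
    }
  }
  if (length(gsubj)) {
    m1 <- sample(2000:6000, length(gsubj), replace = TRUE)
    m2 <- sample(2000:6000, length(gsubj), replace = TRUE)
    add(data.table(sample_id = subjects$sample_id[gsubj],
                   chrom = genes$chrom[ggene],
                   start = genes$start[ggene] - m1,
                   end = genes$end[ggene] + m2,
                   state = gstate, role = "rare_genic",
                   locus = genes$gene[ggene], karyotype_level = FALSE))
  }

  # rare non-genic CNVs (disjoint placement pool; zero control carriers)
  pool <- genome$nongenic_pool
  for (st in c("loss", "gain")) {
    k_ng <- stats::rpois(n, cfg$nongenic_rate)
    psub <- integer(0); prow <- integer(0)
    for (i in which(k_ng > 0)) {
      rows <- sample(nrow(pool), min(k_ng[i], nrow(pool)))
      psub <- c(psub, rep(i, length(rows))); prow <- c(prow, rows)
    }
    if (length(psub)) {
      j1 <- sample(0:2000, length(psub), replace = TRUE)
      j2 <- sample(0:2000, length(psub), replace = TRUE)
      add(data.table(sample_id = subjects$sample_id[psub],
                     chrom = pool$chrom[prow],
                     start = pool$start[prow] + j1,
                     end = pool$end[prow] + j2, state = st,
                     role = "rare_nongenic",
                     locus = sprintf("ng%03d", prow),
                     karyotype_level = FALSE))
    }
  }

  # common CNVs at control-panel polymorphism loci
  cl <- genome$common_loci
  k_cm <- stats::rpois(n, cfg$common_cnv_rate)
  common_state <- ifelse(seq_len(nrow(cl)) %% 2 == 0, "loss", "gain")
  csub <- integer(0); crow <- integer(0)
  for (i in which(k_cm > 0)) {
    rows <- sample(nrow(cl), min(k_cm[i], nrow(cl)))
    csub <- c(csub, rep(i, length(rows))); crow <- c(crow, rows)
  }
  if (length(csub)) {
    len <- cl$end[crow] - cl$start[crow]
    j1 <- floor(stats::runif(length(csub)) * (0.08 * len + 1))
    j2 <- floor(stats::runif(length(csub)) * (0.08 * len + 1))
    add(data.table(sample_id = subjects$sample_id[csub],
                   chrom = cl$chrom[crow], start = cl$start[crow] + j1,
                   end = cl$end[crow] - j2, state = common_state[crow],
                   role = "common", locus = cl$locus[crow],
                   karyotype_level = FALSE))
  }

  truth <- rbindlist(events)
  if (nrow(truth) > 0) {
    truth[, probes := pmax(10L, as.integer(round((end - start) / 2000)))]
    truth <- merge(truth, subjects[, .(sample_id, platform)], by = "sample_id")
    setorder(truth, sample_id, chrom, start, end)
  }

  ledger <- copy(truth)
  calls <- NULL
  if (cfg$emit_raw_calls) {
    art <- synth_artifacts(cfg, genome, subjects)
    ledger <- rbindlist(list(ledger, art), fill = TRUE)
    calls <- emit_caller_calls(cfg, truth, art)
  }
  panel <- if (cfg$emit_panel) synth_panel(cfg, genome) else NULL

  list(subjects = subjects[], cnvs = truth[], ledger = ledger[],
       calls = calls, panel = panel, genome = genome, gene_sets = gene_sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# artifact events (only ever visible in raw calls; QC must remove them all)
synth_artifacts <- function(cfg, genome, subjects) {
  n <- nrow(subjects)
  out <- vector("list", 0)
  add <- function(ev) out[[length(out) + 1]] <<- ev
  ap <- genome$artifact_pool
  k_art <- stats::rpois(n, cfg$artifact_rate)
  for (i in which(k_art > 0)) {
    rows <- sample(nrow(ap), min(k_art[i], nrow(ap)))
    for (r in rows) {
      j <- sample(0:2000, 2, replace = TRUE)
      add(data.table(sample_id = subjects$sample_id[i], chrom = ap$chrom[r],
                     start = ap$start[r] + j[1], end = ap$end[r] + j[2],
                     state = sample(c("loss", "gain"), 1),
                     role = "artifact_single_caller",
                     probes = 12L))
    }
  }
  sd_big <- genome$segdups[genome$segdups$end - genome$segdups$start >= 40000]
  for (i in which(stats::runif(n) < 0.1)) {
    r <- sample(nrow(sd_big), 1)
    w <- sample(12000:28000, 1)
    s <- sd_big$start[r] + sample(0:(sd_big$end[r] - sd_big$start[r] - w), 1)
    add(data.table(sample_id = subjects$sample_id[i], chrom = sd_big$chrom[r],
                   start = s, end = s + w, state = sample(c("loss", "gain"), 1),
                   role = "artifact_segdup", probes = 14L))
  }
  for (i in which(stats::runif(n) < 0.1)) {
    r <- sample(nrow(ap), 1)
    j <- sample(2001:4000, 2, replace = TRUE)
    add(data.table(sample_id = subjects$sample_id[i], chrom = ap$chrom[r],
                   start = ap$start[r] + j[1], end = ap$end[r] + j[2],
                   state = sample(c("loss", "gain"), 1),
                   role = "artifact_low_probe",
                   probes = sample(3:9, 1)))
  }
  for (i in which(stats::runif(n) < 0.1)) {
    r <- sample(nrow(ap), 1)
    w <- sample(3000:9500, 1)
    add(data.table(sample_id = subjects$sample_id[i], chrom = ap$chrom[r],
                   start = ap$start[r], end = ap$start[r] + w,
                   state = sample(c("loss", "gain"), 1),
                   role = "artifact_small", probes = 10L))
  }
  bl <- genome$batch_loci
  n_batch <- ceiling(cfg$batch_frac * n)
  for (r in seq_len(nrow(bl))) {
    who <- sample(n, n_batch)
    st <- sample(c("loss", "gain"), 1)
    for (i in who) {
      add(data.table(sample_id = subjects$sample_id[i], chrom = bl$chrom[r],
                     start = bl$start[r], end = bl$end[r], state = st,
                     role = "batch_artifact", probes = 15L))
    }
  }
  art <- rbindlist(out)
  if (nrow(art) > 0) {
    art[, `:=`(locus = NA_character_, karyotype_level = FALSE)]
    art <- merge(art, subjects[, .(sample_id, platform)], by = "sample_id")
  }
  art
}

platform_callers <- function(platform) {
  if (platform == "A6.0") c("iPattern", "Birdsuite") else c("ChAS", "iPattern")
}

# Emit raw per-caller calls. True events (and common CNVs and the
# two-caller artifact classes) are produced by both platform callers; the
# second caller jitters endpoints inward. Large true events may be
# co-fragmented by both callers with a joinable gap. Single-caller
# artifacts come from one caller only.
emit_caller_calls <- function(cfg, truth, artifacts) {
  rows <- vector("list", 0)
  add <- function(x) rows[[length(rows) + 1]] <<- x
  emit_pair <- function(ev, fragment) {
    callers <- platform_callers(ev$platform)
    len <- ev$end - ev$start
    if (fragment) {
      cut <- ev$start + round(len * stats::runif(1, 0.4, 0.6))
      gap <- round(min(20000, 0.08 * len))
      pieces <- data.table(start = c(ev$start, cut + gap),
                           end = c(cut, ev$end))
    } else {
      pieces <- data.table(start = ev$start, end = ev$end)
    }
    for (ci in 1:2) {
      for (pi in seq_len(nrow(pieces))) {
        s <- pieces$start[pi]; e <- pieces$end[pi]
        if (ci == 2) {
          plen <- e - s
          jmax <- floor(min(cfg$caller_jitter_bp, 0.04 * plen))
          if (jmax > 0) {
            s <- s + sample(0:jmax, 1); e <- e - sample(0:jmax, 1)
          }
        }
        add(data.table(sample_id = ev$sample_id, chrom = ev$chrom,
                       start = s, end = e, state = ev$state,
                       probes = pmax(ev$probes_fixed %||% 10L,
                                     as.integer(round((e - s) / 2000))),
                       caller = callers[ci], platform = ev$platform))
      }
    }
  }
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      ev <- as.list(truth[i])
      ev$probes_fixed <- 10L
      frag <- !ev$karyotype_level && (ev$end - ev$start) > 150000 &&
        stats::runif(1) < cfg$frag_prob
      emit_pair(ev, frag)
    }
  }
  if (!is.null(artifacts) && nrow(artifacts) > 0) {
    for (i in seq_len(nrow(artifacts))) {
      ev <- as.list(artifacts[i])
      callers <- platform_callers(ev$platform)
      if (ev$role == "artifact_single_caller") {
        add(data.table(sample_id = ev$sample_id, chrom = ev$chrom,
                       start = ev$start, end = ev$end, state = ev$state,
                       probes = ev$probes, caller = sample(callers, 1),
                       platform = ev$platform))
      } else {
        # two-caller artifacts: identical coordinates from both callers,
        # fixed probe counts so each targets exactly one QC filter
        for (ci in 1:2) {
          add(data.table(sample_id = ev$sample_id, chrom = ev$chrom,
                         start = ev$start, end = ev$end, state = ev$state,
                         probes = ev$probes, caller = callers[ci],
                         platform = ev$platform))
        }
      }
    }
  }
  calls <- rbindlist(rows)
  setorder(calls, sample_id, chrom, start, end, caller)
  calls[]
}

# control panel: common polymorphism loci at > 0.1% carrier frequency plus
# sparse rare loci below it
synth_panel <- function(cfg, genome) {
  cl <- genome$common_loci
  common_state <- ifelse(seq_len(nrow(cl)) %% 2 == 0, "loss", "gain")
  rows <- vector("list", 0)
  for (r in seq_len(nrow(cl))) {
    k <- stats::rbinom(1, cfg$panel_size, cl$freq[r])
    k <- max(k, ceiling(0.0015 * cfg$panel_size))  # keep above the rarity line
    len <- cl$end[r] - cl$start[r]
    j1 <- sample(0:floor(0.04 * len), k, replace = TRUE)
    j2 <- sample(0:floor(0.04 * len), k, replace = TRUE)
    rows[[length(rows) + 1]] <- data.table(
      subject = sprintf("ctrl_%s_%04d", cl$locus[r], seq_len(k)),
      chrom = cl$chrom[r], start = cl$start[r] + j1, end = cl$end[r] - j2,
      state = common_state[r], locus = cl$locus[r])
  }
  rl <- genome$rare_panel_loci
  for (r in seq_len(nrow(rl))) {
    k <- sample(seq_len(cfg$rare_panel_max_carriers), 1)
    rows[[length(rows) + 1]] <- data.table(
      subject = sprintf("ctrl_%s_%04d", rl$locus[r], seq_len(k)),
      chrom = rl$chrom[r], start = rl$start[r], end = rl$end[r],
      state = if (r %% 2 == 0) "loss" else "gain", locus = rl$locus[r])
  }
  control_panel(rbindlist(rows), cfg$panel_size)
}
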