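---
title: "Methods: rare CNV burden and diagnostic yield in IQ-stratified cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare CNV burden and diagnostic yield in IQ-stratified cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnviq)
```

## The analysis this package implements

Rare copy-number variants (CNVs) are an established risk factor for
schizophrenia, and several of the recurrent risk loci also depress IQ in
unaffected carriers. `cnviq` implements an end-to-end analysis for asking
how the diagnostic yield of microarray testing, and the genome-wide burden
of rare CNVs, differ across intellectual-functioning strata of a
schizophrenia cohort: average IQ (FSIQ >= 85), borderline intellectual
functioning (FSIQ 71-84), intellectual disability (ID; FSIQ <= 70), and
non-verbal learning disability (NVLD; performance IQ at least 15 points
below verbal IQ).

The pipeline has five stages, each an exported module:

1. **Consensus QC** (`cnv_qc_pipeline()`): raw per-caller CNV calls are
   reduced to a consensus set - an event must be reported by at least two
   calling algorithms on the same sample with reciprocal overlap >= 0.5,
   must exceed 10 kb, span at least 10 consecutive array probes, and be
   covered < 75% by segmental duplications; calls with identical
   coordinates and copy state in > 1% of the cohort are removed as
   locus-specific batch artifacts, and fragmented large events are
   re-joined.
2. **Rarity adjudication** (`is_rare()`): a CNV is rare when fewer than
   0.1% of a population control panel (declared size 10,113 subjects)
   carry a same-state CNV at >= 50% reciprocal overlap, counted per control
   subject, not per call.
3. **Reportability triage and tiered classification** (`classify_cnvs()`):
   rare exonic CNVs > 100 kb and rare non-coding CNVs > 500 kb are
   clinically reportable; reportable CNVs matching a known pathogenic locus
   take that locus's tier, the remainder are variants of unknown
   significance (VUS). The two top tiers (pathogenic, VUS-likely-pathogenic)
   collapse into the operational "pathogenic" category.
4. **IQ-group assignment** (`assign_iq_group()`) from test scores,
   descriptive ranges and educational attainment, with scores always
   overriding education.
5. **Statistics**: per-group diagnostic yields (`yield_summary()`), 2x2
   odds ratios with Woolf confidence intervals (`odds_ratio_woolf()`),
   Fisher exact and Mann-Whitney tests, covariate-adjusted logistic burden
   regression (`logistic_burden()`), and gene-set exonic burden enrichment
   by logistic-regression deviance tests with Benjamini-Hochberg FDR
   (`run_gsea()`).

## Statistical models

**Woolf odds-ratio interval.** For a 2x2 table $(a, b, c, d)$ the odds
ratio is $\widehat{OR} = ad/bc$ with
$\mathrm{CI} = \exp\!\big(\ln \widehat{OR} \pm z_{1-\alpha/2}
\sqrt{1/a + 1/b + 1/c + 1/d}\big)$. Any zero cell triggers the
Haldane-Anscombe +0.5 correction to all four cells, flagged in the result.
The log-normal (Woolf) interval was chosen as the default because it
reproduces the interval the yield comparison is expected to print from its
carrier counts; Fisher's exact test is available alongside for the p-value.

**Burden regression.** The genome-wide burden comparison fits
$\mathrm{logit}\, P(\text{low-IQ}) = \beta_0 + \beta_1 x + \gamma^\top z$
by maximum likelihood, where $x$ is a per-subject burden scalar (CNV
count, total length in Mb, or distinct genes overlapped; all CNVs,
deletions and duplications separately) and $z$ contains sex and genotyping
platform. Pathogenic-CNV carriers are excluded by the caller before the
fit, and only autosomal CNVs contribute. The regression population is the
full remaining cohort, including subjects with zero burden - restricting to
carriers would condition on the outcome of the exposure.
Non-convergence, constant predictors and separation are flagged explicitly.

**Gene-set deviance test.** For each gene-set the per-subject burden is
the number of *distinct* set genes whose exons are hit by at least one
rare CNV of the tested state. Significance is a likelihood-ratio
chi-square (1 df) between the covariate-only and covariate-plus-burden
logistic models; covariates are sex, platform, and the total number of
genes overlapped by rare CNVs of the same state per subject. The deviance
statistic stays finite under separation, which the per-set Wald statistic
does not; separation is still flagged. BH-FDR is applied separately per
CNV type, and a set is reported enriched when q < 0.10 and p < 0.05.
The total-genes covariate is computed over the same state as the tested
burden by default (`total_genes_scope = "state"`); the all-state total is
available because published descriptions of this covariate are ambiguous.

## Tunable parameters

| Parameter | Default | Where | Rationale |
|---|---|---|---|
| caller-agreement reciprocal overlap | 0.5 | `consensus_calls()` | no published agreement fraction exists; the rarity criterion's 0.5 is reused |
| minimum size | > 10 kb (strict) | `apply_thresholds()` | literal reading of the "> 10 kb" filter |
| minimum probes | >= 10 | `apply_thresholds()` | "ten consecutive array probes" read as at-least |
| segdup coverage | < 0.75 (strict) | `apply_thresholds()` | literal "< 75%" |
| batch-artifact ceiling | > 1% of cohort | `remove_batch_artifacts()` | identical-coordinate recurrence is a platform signature |
| fragment-join gap | < 50 kb and < 20% of span | `join_fragments()` | codifies a manual joining step; both knobs configurable |
| rarity | < 0.1% of 10,113 controls at >= 0.5 reciprocal overlap | `is_rare()` | conservative population-rarity definition |
| reportability | exonic > 100 kb, non-coding > 500 kb | `triage_reportable()` | clinical triage thresholds |
| FSIQ cuts | <= 70 / 71-84 / >= 85 | `assign_iq_group()` | standard ID / borderline / average bands |
| NVLD rule | VIQ - PIQ >= 15 | `assign_iq_group()` | neuropsychological NVLD criterion |
| enrichment flags | q < 0.10 and p < 0.05 | `run_gsea()` | stated significance convention |

Interpretation choices worth calling out, because the underlying written
methods are ambiguous:

* The "50% overlap" rarity criterion is implemented as **reciprocal**
  overlap (the field standard for matching CNV events); a one-way match
  can be obtained by constructing the query accordingly, and the
  consensus step exposes its own `min_recip`.
* Consensus coordinates are the **union** of the supporting calls
  (callers tend to fragment true events); intersection is available via
  `interval = "intersection"`. Probe support is the maximum over
  supporting calls - the most optimistic evidence.
* NVLD takes precedence over the score bands only when FSIQ (or, when
  FSIQ is absent, the VIQ/PIQ mean used as a proxy) is >= 71; a
  qualifying VIQ>PIQ gap with FSIQ <= 70 is assigned ID. The NVLD label
  describes a discrepancy profile, not global impairment, so global
  impairment wins.
* When only VIQ and PIQ are available and the gap is below 15, their mean
  proxies FSIQ.
* Repeated grades are treated as one form of "reported school
  difficulties" rather than a separate field.
* The known-locus table (`table1_known_loci()`) keeps one entry per
  distinct published coordinate variant instead of one merged entry per
  cytoband: nested and atypical deletions at recurrent loci (e.g. the
  short 22q11.2 A-B deletion) would otherwise fail the 0.5
  reciprocal-overlap match against the canonical interval. The rule
  engine is an explicit approximation of expert ACMG review - tier
  outcomes are only as good as the supplied locus table, which is fully
  user-overridable.
* Non-reportable CNVs keep the tier `unclassified` rather than `benign`:
  the pipeline has no evidence model for benignity, only for rarity and
  locus matching.

## The synthetic cohort generator

`generate_cohort()` produces fully self-contained inputs with the
statistical structure the analysis assumes, so every stage is testable
without any external data. The defaults encode the study conditions the
pipeline targets:

* 546 subjects in strata of 325 / 130 / 62 / 29
  (average / borderline / ID / NVLD), two genotyping platforms mixed
  50/50, 60% male;
* pathogenic-carrier probabilities 9/325, 9/130, 15/62 and 6/29 per
  stratum, realised as independent Bernoulli draws; carriers receive one
  CNV drawn from the known-locus table;
* a genic-duplication burden odds ratio of 1.42 per gene in the expanded
  low-IQ stratum. This is planted by **exponential tilting**: distinct
  duplicated genes per subject are Poisson(0.8) in the average stratum and
  Poisson(0.8 x 1.42) in the low-IQ strata. Tilting a Poisson by
  $e^{\beta x}$ is again Poisson with mean scaled by $e^{\beta}$, so the
  prospective logistic model of group on gene count has slope exactly
  $\ln 1.42$ - the planted value is the estimand, not an approximation;
* genic deletions at Poisson(0.8) in both strata (no planted effect),
  non-genic rare CNVs at Poisson(0.5) per copy state, and common
  polymorphic CNVs at Poisson(0.5) per subject matched to control-panel
  loci whose panel frequencies are kept above the 0.1% rarity line;
* a 10,113-subject control panel; rare panel loci carry at most 9
  carriers (just below 0.1%);
* two simulated callers per platform: the second caller jitters endpoints
  inward by up to 2 kb, and large true events are co-fragmented with a
  joinable gap at rate 0.3; artifacts are planted as single-caller calls,
  segdup-embedded calls, low-probe calls, sub-10 kb calls, and
  identical-coordinate batch events in 2% of subjects. By construction
  every true event survives the QC thresholds and every artifact violates
  exactly one of them, which is what makes the 100%-recall / 0%-leakage
  invariant a meaningful end-to-end assertion rather than a tautology;
* one gene-set out of 17 (`planted_set`) receives 3x weight when low-IQ
  subjects choose duplication targets, giving the enrichment scan a
  planted positive with realistic contamination of overlapping null sets.

The genome is hg19 scaled to 1/10 (22 autosomes + X), with ~500
well-separated synthetic genes of 2-4 exons. The published pathogenic loci
are mapped proportionally, so interval arithmetic, overlap fractions and
locus matching behave realistically at desk scale. Because the 100 kb /
500 kb reportability thresholds are absolute clinical values, analyses of
the scaled genome pass them scaled by the same factor (they are arguments
of `classify_cnvs()`). Two geometric guarantees keep recovery exact:
background genes keep an 80 kb clearance from known loci (so a background
genic CNV can never reach 0.5 reciprocal overlap with a locus entry), and
each autosomal known locus contains a dedicated synthetic gene excluded
from background targeting (so small planted pathogenic CNVs are exonic and
pass triage, as their real counterparts do).

What the generator does **not** emulate: probe-level intensities and
caller-specific error modes, linkage between CNVs, ancestry structure,
overlapping gene models, X-linked genes, inheritance, and real ACMG
evidence beyond locus identity. Passing the end-to-end tests therefore
shows the pipeline's logic is faithful to its stated rules under the
assumed data model - it is not a validation against real microarray data.

All randomness flows through one seeded generator (`cfg$seed`); a fixed
seed reproduces every output byte for byte. `emit_raw_calls = FALSE` and
`emit_panel = FALSE` skip the caller-emission and panel stages for
distribution-level replicates, where the QC-recovery invariants proven
elsewhere make the generated truth table and the QC output
interchangeable.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open internally; published 1-based start +
  size coordinates convert exactly and round-trip
  (`coords_from_1based()` / `coords_to_1based()`). Chromosome labels are
  normalized by stripping any `chr` prefix. Whole-chromosome aneuploidies
  carry `karyotype_level = TRUE` and bypass the probe filter only.
* Consensus pairing is greedy by descending reciprocal overlap with ties
  broken by leftmost start, and each raw call supports at most one
  consensus event; the output is therefore invariant to input order.
* Fragment joining iterates to a fixed point; it never reduces covered
  bases and refuses mixed chromosomes, states or samples.
* Mann-Whitney uses exact enumeration when $n_1 n_2 \le 400$ without
  ties, otherwise the tie-corrected normal approximation with continuity
  correction.
* Wilson is the default proportion interval, with Clopper-Pearson
  available; for 39/546 the two give [5.3%, 9.6%] and [5.1%, 9.7%]
  respectively - published intervals of this yield fall between the two
  conventions, so neither is asserted in tests beyond its own closed form.
* Empty panels, empty tracks, empty cohorts and zero-CNV subjects are all
  defined: zero carriers, zero coverage, empty summaries, zero burden.

## Problem sizes used in the shipped checks

The packaged tests calibrate the burden and deviance tests on 1,000 null
simulations at n = 440, recover the planted duplication odds ratio as the
median over 200 generated cohorts (the acceptance script repeats this
computation from scratch), and run the full raw-calls pipeline once at the
default 546-subject configuration. These sizes give binomial noise of
about +/- 0.02 on a 5% type-I rate and a tight median for a per-replicate
standard error of ~0.13 on the odds ratio, while keeping the whole suite
in the low minutes on one core.

## Known limitations

* The classification engine encodes locus identity, rarity and size only;
  it cannot reproduce judgment calls that depend on gene content,
  inheritance or literature evidence, and it labels everything
  non-matching as VUS.
* Education-based IQ assignment is a heuristic with known misclassification
  risk (particularly for NVLD, which requires scores by definition);
  the rule trace records which evidence source decided each subject.
* The burden models assume independent subjects; related individuals must
  be removed upstream.
* Percentages in gene-set result tables are computed from the explicit
  group denominators supplied to `run_gsea()`; published tables sometimes
  print percentages against other denominators (e.g. genic-CNV carriers),
  which are not reconstructed here.
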