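---
title: "Methods: BCR repertoire clonality, diversity and survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCR repertoire clonality, diversity and survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

This vignette describes the models and procedures the package
implements, the parameters that matter, what the synthetic-cohort
generator does and does not emulate, and the numerical and design
choices made where the design was genuinely open.

## Clone definition and quality control

A clonotype is the set of reads sharing one CDR3 amino-acid sequence
within a sample (IMGT junction: conserved Cys104 through Trp/Phe118,
anchors included). `read_clone_table()` consumes AIRR Rearrangement TSV
or MiXCR-like clone TSV; `aggregate_repertoire()` merges rows with
identical CDR3, summing read counts. Gene labels of merged rows are
decided by read-count-weighted majority vote with lexicographic
tie-breaking — how clones with identical CDR3 but different V
annotations should merge is not standardized anywhere, so the rule is
deterministic and flagged here rather than silent.

Records are filtered before any statistic is computed: mean CDR3
quality below Q30 (`min_quality = 30`, Phred scale) or a non-functional
junction (stop codon `*`, or a `productive = FALSE` flag) drops the
record with a logged reason. Records *without* a quality annotation
pass the quality filter: many clone tables are exported after read-level
QC and carry no per-clone quality, and silently discarding them would
bias external data.

Analyses are stratified at the IGHV *subgroup* level (IGHV1, IGHV11,
IGHV12, …), extracted from the allele call as the prefix before the
first `-`, `*` or `S`; the full allele is retained in a secondary
column.

## CLL clone threshold

`derive_threshold()` implements a two-sided rule: pool the `top_k = 10`
largest clone fractions of each wild-type mouse, then recommend the
larger of (a) the upper end of the human-CLL convention (2.5–5% clone
fraction) and (b) the smallest whole-percent step strictly above the
pooled wild-type maximum. With a typical wild-type background
(top clones ≈ 1–4%), the recommendation is 5%; a hypothetical wild-type
background reaching 6% would push it to 7%. Clones at or above the
threshold are CLL clones (the boundary is inclusive); classification is
monoclonal (1), biclonal (2), oligoclonal (3–10). Zero or more than ten
CLL clones is reported as `polyclonal_excess` rather than forced into
one of the three biological classes — small external repertoires can
produce both situations.

The dominance threshold is 50% of reads, also inclusive; sources
describing such designs alternate between "> 50%" and "at least 50%",
so the comparator is exposed (`inclusive = FALSE` gives strict `>`),
and sub-studies that need a harsher cut (e.g. 77% for cell sorting) can
pass `dominance = 0.77`.

## Diversity

The normalized Herfindahl-Hirschman index of a fraction vector
$p_1,\dots,p_N$ is

$$H^* = \frac{\sum_i p_i^2 - 1/N}{1 - 1/N},\qquad N > 1,$$

with $H^* = 1$ for $N = 1$. $N$ counts distinct clonotypes after QC
filtering; zero-fraction clones cannot survive aggregation and are
excluded by construction. A perfectly even input returns exactly 0 (the
uniform case is short-circuited so the anchor carries no floating-point
residue). `fit_age_trend()` regresses $H^*$ on age in days by OLS and
reports slope, $R^2$ and the two-sided slope p-value ($t$, $n-2$ df).
Longitudinal samples enter as independent points — the pooled fit is
what such cohort analyses usually plot — but the mouse id is retained so
per-mouse fits remain possible. A constant response returns slope 0,
$R^2$ 0, p 1 rather than a 0/0.

## Junction statistics and CDR3 similarity

N-insertions are the summed non-templated N1 (V–D) and N2 (D–J)
nucleotides. A clone lacking either annotation is excluded with a log
entry — never silently scored 0, which would shift medians of exactly
the kind of comparison this statistic feeds. Group summaries report
median and IQR with the linear-interpolation percentile convention
(`quantile(type = 7)`), and groups are compared downstream by Wilcoxon
tests.

CDR3 similarity uses unit-cost Levenshtein distance on the amino-acid
junction (anchors included). Because clone sizes span orders of
magnitude, sequences are weighted before sampling: per IGHV subgroup,
each distinct CDR3 receives multiplicity round(K × cumulated clone
fraction), cumulated across all CLL clones of the cohort's subgroup
pool. Defaults K = 100 (so a 1% clone survives rounding) and m = 100
drawn sequences; rounding is half-away-from-zero; sequences rounding to
multiplicity 0 are dropped with a log entry. Sampling is *with*
replacement by default — pools can hold fewer than m distinct sequences,
and replacement decouples m from pool size — with a flag for
without-replacement draws. All m(m−1)/2 unordered pairs of draw indices
are scored; two draws of the same sequence count as a distance-0 pair
because they represent true repertoire mass, and only the self-pair of
a single draw index is excluded. The draw is a pure function of
(pool, m, seed) and leaves the caller's RNG state untouched.

## Cohort statistics

All standard tests delegate to the established implementations in base
R and the survival package behind the module's interface; the tests of
this package verify each against an independent brute-force oracle
(enumeration, hand risk-set tabulation, product-limit arithmetic).

- *Wilcoxon rank-sum*: exact p for small samples — closed-form when
  untied, full enumeration over midrank label assignments when tied and
  both groups have ≤ 10 values (two-sided = twice the smaller tail,
  capped at 1); otherwise the tie-corrected normal approximation with
  continuity correction. Enumeration beyond 10 per group is
  combinatorially infeasible, hence the cap; the exact/approximate
  switchover (`exact_max_n = 25`) is configurable.
- *Fisher's exact test*: two-sided p by the minimum-likelihood rule
  (sum of conditional hypergeometric masses ≤ the observed one, with a
  1e-7 relative guard against floating ties); the effect is the
  conditional-MLE odds ratio — the root of the noncentral-hypergeometric
  mean equation, which is unique because that mean is strictly
  increasing in the odds ratio. Zero margin cells yield 0 or `Inf`.
- *Kaplan-Meier*: product-limit estimator; the median is the smallest
  time with $S(t) \le 0.5$ and is absent when the curve never reaches
  0.5. The 95% CI of the median inverts the log-log pointwise band;
  when the band never recrosses 0.5 only the available bound is
  reported (the other side is `NA`), mirroring how such cohorts report
  one-sided bounds. Which CI transform (log, log-log, linear) underlies
  any given published bound is rarely stated; log-log is the choice
  here and is flagged.
- *Pairwise log-rank*: each unordered pair of strata gets the two-group
  log-rank chi-square (1 df), BH-adjusted across the full pairwise
  family; strata without events are skipped with a warning. The hazard
  ratio attached to each pair is the Mantel-Haenszel estimate
  $(O_a/E_a)/(O_b/E_b)$ from the same risk-set tabulation — no
  proportional-hazards regression is fitted anywhere, since the HR here
  annotates a log-rank comparison rather than modelling covariates.
- *Shapiro-Wilk screen*: report-only; the pipeline proceeds with
  non-parametric tests regardless, so a screen outcome can never
  silently switch the inferential machinery.

## The synthetic-cohort generator

`cohort_spec()` fixes the study conditions; `simulate_cohort()` is a
pure function of (spec, seed) via an isolated RNG scope, so identical
calls are byte-identical and the caller's RNG is untouched.

Defaults encode the emulated design: 85 TCL1 and 8 wild-type mice;
clonality mixture 47/31/22% mono/bi/oligoclonal; dominant-clone
probability 0.72; IGHV subgroup mixture 27/49/12% for
IGHV1/IGHV11/IGHV12 with a 12% "other" slice that exercises the
grouping code paths with random IGHV labels outside the three named
subgroups; sex linkage P(female) = 0.73 (IGHV1) and 0.43 (IGHV11),
0.48 otherwise (the cohort-level sex balance).

Per-law choices, each made once:

- **CLL fractions.** The dominant clone draws
  $0.5 + (c - 0.5)\,\mathrm{Beta}(2,3)$ (cap $c$ keeps room for the
  other clones); non-dominant top clones are uniform on roughly
  (0.10, 0.45). Further CLL clones descend with a per-clone floor of
  0.052 — slightly above the 5% threshold so read-count rounding can
  never drop a true CLL clone below it — and at least 2% of the
  repertoire is reserved for background. An oligoclonal draw of 10
  clones is incompatible with a ≥ 50% dominant clone (10 × 5% + 50% >
  100%), so dominant oligoclonal mice redraw their clone count from
  3–9.
- **Polyclonal background** (wild-type repertoires and the
  miscellaneous compartment of TCL1 mice): rank-Zipf fractions
  $f_r \propto r^{-0.42}$ over 170 clones with lognormal jitter
  (sdlog 0.08), renormalized. Calibrated so pooled wild-type top-10
  fractions have median ≈ 1.5% and never approach 5%, which makes the
  threshold rule recommend 5%.
- **Junction insertions.** IGHV1: negative binomial, size 21, mu 4.1 —
  solved numerically so the distribution quartiles are exactly
  (2, 4, 5), with CDF values F(3) = 0.43 and F(4) = 0.61 leaving the
  widest possible margin around 0.5, so the *sample* median of ≥ 200
  clones is 4 with high probability. IGHV11/IGHV12: point mass at 0
  with a 10% geometric tail (median 0, IQR 0–0). The drawn total is
  split binomially between N1 and N2.
- **Stereotypes.** IGHV11 and IGHV12 CLL clones carry an invariant
  subgroup-specific CDR3 with probability 0.9, else a one-residue
  variant; IGHV1 and background clones draw random junctions of length
  10–16 aa between C and W/F anchors. Two clones of one mouse can never
  share a CDR3 (they would merge on aggregation), so residual clashes
  are resolved by a point substitution and the ground-truth table
  records the realized sequence.
- **Survival.** Log-normal per stratum. Medians: IGHV1 322 d, IGHV11
  371 d, IGHV12 334 d (subgroup marginals, used when no sex is
  assigned); IGHV1♀ 308, IGHV1♂ 344, IGHV11♀ 378, IGHV11♂ 364; sex
  marginals 355 (M) / 337 (F). Dispersion sdlog = 0.15, chosen once so
  simulated spreads resemble typical reported median CIs at cohort
  size; no administrative censoring by default (follow-up to humane
  endpoint), with a configurable censoring fraction.
- **Longitudinal law.** The dominant clone grows logistically,
  $f(t) = f_\mathrm{end}/(1 + e^{-k(t - t_0)})$ with $k = 0.03$/day and
  $t_0$ 120 days before endpoint; monthly blood draws from day 60. This
  makes the HHI rise with age, qualitatively matching leukemic
  repertoire concentration.
- **Paired organs.** 18 mice contribute a lymph-node repertoire;
  when the spleen-dominant clone is IGHV11 the node swaps to a dominant
  IGHV1 clone with probability 4/9, the direction and rate of the
  emulated sub-study; concordant nodes keep the spleen CDR3. LN sizes
  are log-normal with medians 4.5 mm (IGHV1) and 2.6 mm (IGHV11) and
  sdlogs matched to the corresponding IQR ratios (0.38, 0.29).

What the generator does *not* emulate: sequencing reads, PCR or
amplification bias, somatic hypermutation (the emulated clones are
IGHV-unmutated), within-clone phylogenies, or transcriptome and
flow-cytometry read-outs. Passing tests therefore demonstrate that the
analysis recovers the latent structure the generator encodes — clone
hierarchies, subgroup laws, survival laws — not that it would be robust
to read-level artefacts a real MiXCR run might produce upstream.

## Problem sizes and runtime choices

Unit and property tests run on reduced cohorts (20–40 TCL1 mice, 3–6
wild-types) — the laws under test are per-mouse, so cohort size only
scales the evidence, and these sizes keep the full suite comfortably
fast. End-to-end checks use study-scale pieces where the claim demands
them: 8 wild-type mice for threshold calibration, ≥ 200 clones for the
insertion median, 500 mice per arm for survival recovery, and 20-seed
sweeps wherever a claim is about the *probability* of exact recovery.
The exhaustive Fisher verification covers every 2×2 table with total
N ≤ 40, deduplicated by transposition symmetry.

## Known limitations

- Clone identity is exact CDR3 amino-acid matching; near-identical
  clonotypes (one substitution) are distinct clones, and no clustering
  beyond exact identity is offered.
- The weighted CDR3 pool cumulates clone fractions across the whole
  cohort group; cumulating within-mouse first would weight mice
  unequally and is not implemented.
- Hazard ratios are Mantel-Haenszel annotations of log-rank
  comparisons, not covariate-adjusted estimates.
- The wild-type calibration assumes wild-type repertoires are genuinely
  polyclonal; a contaminated "wild-type" sample with a large clone
  raises the recommended threshold by design.
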