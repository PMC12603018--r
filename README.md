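# clonotrace

Clonality, diversity and survival analysis of B-cell receptor (BCR)
repertoires from murine CLL cohorts.

In the Eµ-TCL1 transgenic mouse — the standard model of aggressive,
IGHV-unmutated chronic lymphocytic leukemia — leukemic B-cell clones are
identified from bulk BCR sequencing by the amino-acid sequence of the
heavy-chain CDR3 (IMGT junction, Cys104…Trp/Phe118). `clonotrace`
implements the downstream analysis that turns per-sample clone tables
into cohort-level biology:

- **Clone calling.** Clonotypes are aggregated by CDR3 amino-acid
  identity. A *CLL clone* is a clonotype whose within-sample read
  fraction reaches a threshold calibrated against wild-type repertoires:
  the recommended cut-off exceeds both the pooled wild-type top-clone
  background and the human-CLL convention (2.5–5%), which lands at
  **5%** for a typical wild-type background. Repertoires are classified
  monoclonal / biclonal (2) / oligoclonal (3–10 CLL clones); the largest
  clone is *dominant* when it holds ≥ 50% of reads.
- **Diversity.** The normalized Herfindahl-Hirschman index
  H\* = (Σpᵢ² − 1/N)/(1 − 1/N), which scores a monoclonal repertoire 1
  and a perfectly even repertoire 0, plus its OLS trend against age.
- **CDR3 statistics.** Summed junction N-insertions (N1 + N2
  nucleotides) per IGHV subgroup; clone-fraction-weighted Levenshtein
  (edit-distance) resampling — each distinct CDR3 enters a pool with
  multiplicity round(K × cumulated clone fraction), m = 100 sequences
  are drawn and all pairwise distances summarized — and weighted V(D)J
  usage tables.
- **Cohort statistics.** Wilcoxon rank-sum (exact for small samples,
  including tied ones), Fisher's exact 2×2 with the conditional-MLE odds
  ratio, Kaplan-Meier curves with log-log median CIs, pairwise log-rank
  tests with Benjamini-Hochberg adjustment, Mantel-Haenszel hazard
  ratios (O₁/E₁)/(O₂/E₂), and a Shapiro-Wilk normality screen.
- **Synthetic cohorts.** A generator that emulates the statistical
  structure of such a cohort — clonality mixture, IGHV subgroup
  structure with invariant stereotyped CDR3s for IGHV11/IGHV12 and
  N-insertion-rich diverse CDR3s for IGHV1, sex-linked subgroup odds,
  per-stratum survival laws, longitudinal growth of the dominant clone,
  and paired spleen/lymph-node repertoires with directional
  dominant-clone switching — so the entire pipeline is testable without
  access to deposited sequencing data.

Inputs are AIRR Rearrangement TSV or MiXCR-like clone TSV tables plus a
per-sample metadata table; see `?read_clone_table` and `?run_pipeline`.

## Worked example

```r
library(clonotrace)

spec   <- cohort_spec(n_tcl1 = 30, n_wt = 6, n_longitudinal = 5,
                      n_ln_pairs = 10)
cohort <- simulate_cohort(spec, seed = 42)
wt     <- simulate_wt(spec, seed = 43)
res    <- run_pipeline(cohort$samples, cohort$metadata,
                       wt_samples = wt, seed = 44)

res$threshold_report
#> <threshold_report> pooled top-clone fractions 1.13%-3.19% (median 1.45%);
#>   recommended threshold 5%
```

The wild-type calibration reproduces the expected behaviour: top
wild-type clones sit in the low percent range, so the 5% human
convention sets the CLL threshold.

```r
res$insertion_summary
#> # A tibble: 3 × 5
#>   subgroup     n median   q25   q75
#> 1 IGHV1       17      5     3     6
#> 2 IGHV11      47      0     0     0
#> 3 IGHV12       9      0     0     0

res$lv_summary
#>   subgroup     m median   q25   q75
#> 1 IGHV1      100     10     9    12
#> 2 IGHV11     100      0     0     1
#> 3 IGHV12     100      0     0     0
```

IGHV1 clones carry several non-templated junction nucleotides and
diverse CDR3s (high pairwise edit distance); the stereotyped
IGHV11/IGHV12 clones carry essentially none and collapse to edit
distance 0.

```r
res$survival$subgroup$comparisons
#>   group_a group_b statistic   p_value p_adjusted effect method
#> 1 IGHV1   IGHV11      16.2  0.0000567   0.000170  6.43  logrank
#> 2 IGHV1   IGHV12       3.31 0.0690      0.0690    3.21  logrank
#> 3 IGHV11  IGHV12      11.3  0.000767    0.00115   0.171 logrank

res$age_trend
#> slope 1.28e-03 per day, R² 0.38, p 3.2e-10, n 84
```

Mice with a dominant IGHV1 clone die earlier than IGHV11 mice (hazard
ratio > 1 with BH-adjusted significance), repertoire concentration
rises with age, and the paired-organ stage reports dominant-clone
switches, which run exclusively IGHV11 (spleen) → IGHV1 (lymph node):

```r
attr(res$paired_organs, "switches")
#>   spl_subgroup ln_subgroup     n
#> 1 IGHV11       IGHV1           3
```

A thin command-line front end over the same functions ships in
`inst/cli/clonotrace.R` (verbs `simulate`, `classify`, `diversity`,
`pipeline`).

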