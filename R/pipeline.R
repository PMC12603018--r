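# Orchestration: wild-type calibration -> QC filter -> clone calling ->
# clonality / diversity / CDR3 / survival / paired-organ stages, with a
# reproducibility manifest. Every number in the result bundle is produced
# by a module operation; this file only wires them together.

#' Paired spleen / lymph-node dominant-clone concordance
#'
#' @param spl_callsets,ln_callsets Named lists of `cll_callset` objects
#'   keyed by mouse id. Mice present in only one list are reported in the
#'   `unpaired` attribute, not treated as errors.
#' @return Tibble with `mouse_id`, `spl_subgroup`, `ln_subgroup`,
#'   `spl_fraction`, `ln_fraction`, `concordant`; attributes `unpaired`
#'   (character) and `switches` (tibble of switch directions with counts).
#' @export
paired_organ_report <- function(spl_callsets, ln_callsets) {
  paired <- intersect(names(spl_callsets), names(ln_callsets))
  unpaired <- c(setdiff(names(spl_callsets), paired),
                setdiff(names(ln_callsets), paired))
  tab <- purrr::map_dfr(paired, function(id) {
    s <- spl_callsets[[id]]
    l <- ln_callsets[[id]]
    tibble::tibble(
      mouse_id = id,
      spl_subgroup = dominant_subgroup(s),
      ln_subgroup = dominant_subgroup(l),
      spl_fraction = if (is.null(s$dominant_clone)) NA_real_
        else s$dominant_clone$fraction,
      ln_fraction = if (is.null(l$dominant_clone)) NA_real_
        else l$dominant_clone$fraction,
      concordant = identical(dominant_subgroup(s), dominant_subgroup(l))
    )
  })
  switches <- if (nrow(tab)) {
    tab |>
      dplyr::filter(!.data$concordant) |>
      dplyr::count(.data$spl_subgroup, .data$ln_subgroup, name = "n")
  } else {
    tibble::tibble(spl_subgroup = character(0), ln_subgroup = character(0),
                   n = integer(0))
  }
  attr(tab, "unpaired") <- unpaired
  attr(tab, "switches") <- switches
  tab
}

.read_sample_dir <- function(dir, dialect) {
  paths <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  paths <- paths[!basename(paths) %in% c("metadata.tsv", "ground_truth.tsv")]
  out <- lapply(paths, read_clone_table, dialect = dialect)
  names(out) <- vapply(out, function(x) {
    if (nrow(x)) x$sample_id[1] else NA_character_
  }, character(1))
  out
}

#' Run the full repertoire analysis pipeline
#'
#' Stages: (1) wild-type threshold calibration (skipped when no WT samples
#' are supplied; the default 5% threshold is then used); (2) Q30 /
#' productivity filtering and aggregation into repertoires; (3) CLL clone
#' calling and clonality classification; (4) normalized-HHI diversity and
#' its age trend; (5) junction N-insertion summaries with pairwise Wilcoxon
#' comparisons and clone-fraction-weighted Levenshtein resampling per IGHV
#' subgroup; (6) weighted and unweighted V(D)J usage; (7) Kaplan-Meier /
#' pairwise log-rank survival analysis by clonality class, by dominant
#' subgroup, and by subgroup-by-sex, plus Fisher's exact test of sex by
#' subgroup; (8) paired spleen/lymph-node concordance and LN-size
#' comparison. Results are returned as a bundle of tibbles and written as
#' TSVs with a YAML manifest when `out_dir` is given.
#'
#' @param samples Named list of clone-record tibbles, or a directory of
#'   clone-table TSVs.
#' @param metadata Per-sample metadata tibble (or TSV path): `sample_id`,
#'   `mouse_id`, `sex`, `age_days`, `survival_days`, `event`, `organ`,
#'   optional `ln_size_mm`.
#' @param wt_samples Optional wild-type samples (same forms) for threshold
#'   calibration.
#' @param dialect Clone-table dialect when reading from directories.
#' @param threshold CLL threshold; `NULL` (default) uses the wild-type
#'   calibration when available, else 0.05.
#' @param dominance Dominant-clone threshold, default 0.5.
#' @param min_quality Phred QC threshold, default 30.
#' @param lv_groups IGHV subgroups entering the Levenshtein stage.
#' @param lv_k,lv_m Weighted-pool scale constant and draw size.
#' @param seed Seed for the Levenshtein resampling stage.
#' @param out_dir Optional output directory for TSVs and the manifest.
#' @return A result bundle (list of tibbles / fitted objects), invisibly
#'   when `out_dir` is given.
#' @export
run_pipeline <- function(samples, metadata, wt_samples = NULL,
                         dialect = c("airr", "mixcr"), threshold = NULL,
                         dominance = 0.5, min_quality = 30,
                         lv_groups = c("IGHV1", "IGHV11", "IGHV12"),
                         lv_k = 100, lv_m = 100, seed = 1,
                         out_dir = NULL) {
  dialect <- match.arg(dialect)
  if (is.character(samples)) {
    if (!dir.exists(samples)) {
      stop("stage input: sample directory not found: ", samples,
           call. = FALSE)
    }
    samples <- .read_sample_dir(samples, dialect)
  }
  if (is.character(metadata)) {
    if (!file.exists(metadata)) {
      stop("stage input: metadata file not found: ", metadata,
           call. = FALSE)
    }
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
  }
  if (is.character(wt_samples)) {
    wt_samples <- .read_sample_dir(wt_samples, dialect)
  }
  warnings_log <- list()
  note <- function(stage, msg) {
    warnings_log[[length(warnings_log) + 1]] <<-
      tibble::tibble(stage = stage, message = msg)
  }

  # stage: wild-type calibration -------------------------------------
  threshold_report <- NULL
  if (!is.null(wt_samples)) {
    wt_reps <- lapply(names(wt_samples), function(sid) {
      kept <- filter_records(wt_samples[[sid]],
                             min_quality = min_quality)$kept
      aggregate_repertoire(kept, sid, "SPL")
    })
    threshold_report <- derive_threshold(wt_reps)
    if (is.null(threshold)) {
      threshold <- threshold_report$recommended_threshold
    }
  }
  if (is.null(threshold)) threshold <- 0.05

  # stage: QC filter + aggregation ------------------------------------
  organ_of <- stats::setNames(metadata$organ, metadata$sample_id)
  rejected <- list()
  repertoires <- lapply(names(samples), function(sid) {
    fl <- filter_records(samples[[sid]], min_quality = min_quality)
    if (nrow(fl$rejected)) rejected[[sid]] <<- fl$rejected
    organ <- organ_of[[sid]]
    if (is.null(organ) || is.na(organ)) {
      stop("stage qc: sample missing from metadata: ", sid, call. = FALSE)
    }
    aggregate_repertoire(fl$kept, sid, organ)
  })
  names(repertoires) <- names(samples)

  # stage: clone calling ---------------------------------------------
  callsets <- lapply(repertoires, call_cll, threshold = threshold,
                     dominance = dominance)
  clonality <- clonality_table(callsets) |>
    dplyr::left_join(metadata[, c("sample_id", "mouse_id", "sex", "organ")],
                     by = "sample_id")
  spl_ids <- clonality$sample_id[clonality$organ == "SPL"]
  spl_clonality <- clonality[clonality$sample_id %in% spl_ids, ]

  # stage: diversity ---------------------------------------------------
  hhi <- diversity_points(repertoires, metadata)
  tcl1_long <- metadata$sample_id[metadata$organ %in% c("SPL", "blood")]
  trend_pts <- hhi[hhi$sample_id %in% tcl1_long, ]
  age_trend <- if (nrow(trend_pts) >= 3 &&
                   length(unique(trend_pts$age_days)) >= 2) {
    fit_age_trend(trend_pts)
  } else {
    note("diversity", "too few points for an age trend")
    NULL
  }

  # stage: junction insertions + LV ------------------------------------
  spl_callsets <- callsets[spl_ids]
  cll_clones <- purrr::map_dfr(spl_callsets, function(cs) cs$cll_clones)
  insertion_summary <- NULL
  insertion_tests <- NULL
  lv <- list()
  if (nrow(cll_clones)) {
    jstats <- junction_stats(cll_clones)
    if (length(attr(jstats, "excluded"))) {
      note("cdr3", sprintf("%d clone(s) without junction annotation",
                           length(attr(jstats, "excluded"))))
    }
    present <- intersect(lv_groups, jstats$subgroup)
    insertion_summary <- group_insertion_summary(jstats, present)
    prs <- if (length(present) >= 2) utils::combn(present, 2,
                                                  simplify = FALSE)
      else list()
    insertion_tests <- purrr::map_dfr(prs, function(pr) {
      wilcoxon_ranksum(
        jstats$n_insertions[jstats$subgroup == pr[1]],
        jstats$n_insertions[jstats$subgroup == pr[2]],
        group_a = pr[1], group_b = pr[2])
    })
    if (nrow(insertion_tests)) {
      insertion_tests$p_adjusted <- bh_adjust(insertion_tests$p_value)
    }
    for (g in present) {
      grp <- cll_clones[cll_clones$v_gene == g, ]
      pool <- build_weighted_pool(grp$cdr3_aa, grp$fraction, K = lv_k,
                                  group = g)
      if (sum(pool$pool$multiplicity) >= 2) {
        lv[[g]] <- lv_resample(pool, m = lv_m, seed = seed)
      } else {
        note("cdr3", paste("LV pool too small for", g))
      }
    }
  }
  lv_summary <- purrr::imap_dfr(lv, function(s, g) {
    tibble::tibble(subgroup = g, m = s$m, median = s$median,
                   q25 = s$q25, q75 = s$q75)
  })

  # stage: VDJ usage ----------------------------------------------------
  vdj <- vdj_usage(spl_callsets, weighted = FALSE)
  vdj_weighted <- vdj_usage(spl_callsets, weighted = TRUE)

  # stage: survival -----------------------------------------------------
  mouse_meta <- metadata |>
    dplyr::filter(.data$organ == "SPL") |>
    dplyr::distinct(.data$mouse_id, .keep_all = TRUE)
  surv_base <- spl_clonality |>
    dplyr::left_join(
      mouse_meta[, c("mouse_id", "survival_days", "event")],
      by = "mouse_id") |>
    dplyr::filter(!is.na(.data$survival_days))
  km_by <- function(records) {
    recs <- split(records, records$stratum)
    lapply(recs, function(r) km_fit(r$time_days, r$event))
  }
  run_family <- function(records, family) {
    n_ev <- tapply(records$event, records$stratum, sum)
    if (length(n_ev) < 2 || sum(n_ev >= 1) < 2) {
      note("survival", paste("too few strata with events for", family))
      return(NULL)
    }
    list(km = km_by(records),
         comparisons = logrank_pairwise(records))
  }
  surv_clonality <- run_family(
    tibble::tibble(time_days = surv_base$survival_days,
                   event = surv_base$event,
                   stratum = surv_base$clonality_class),
    "clonality")
  dom <- surv_base[!is.na(surv_base$dominant_v) &
                     surv_base$dominant_v %in% lv_groups, ]
  surv_subgroup <- if (nrow(dom)) run_family(
    tibble::tibble(time_days = dom$survival_days,
                   event = dom$event, stratum = dom$dominant_v),
    "dominant subgroup") else NULL
  dom2 <- dom[dom$dominant_v %in% c("IGHV1", "IGHV11"), ]
  surv_subgroup_sex <- if (nrow(dom2)) run_family(
    tibble::tibble(time_days = dom2$survival_days, event = dom2$event,
                   stratum = paste(dom2$dominant_v, dom2$sex, sep = ".")),
    "subgroup x sex") else NULL
  sex_fisher <- NULL
  if (nrow(dom2) &&
      all(c("IGHV1", "IGHV11") %in% dom2$dominant_v)) {
    tab <- with(dom2, table(factor(dominant_v, c("IGHV11", "IGHV1")),
                            factor(sex, c("M", "F"))))
    sex_fisher <- fisher_2x2(tab, group_a = "IGHV11", group_b = "IGHV1")
  }

  # stage: paired organs -------------------------------------------------
  ln_ids <- clonality$sample_id[clonality$organ == "LN"]
  paired <- NULL
  ln_size_test <- NULL
  if (length(ln_ids)) {
    by_mouse <- function(ids) {
      cs <- callsets[ids]
      names(cs) <- clonality$mouse_id[match(ids, clonality$sample_id)]
      cs
    }
    paired <- paired_organ_report(by_mouse(spl_ids), by_mouse(ln_ids))
    ln_meta <- metadata[metadata$organ == "LN" &
                          !is.na(metadata$ln_size_mm), ]
    if (nrow(ln_meta)) {
      ln_sub <- paired$ln_subgroup[match(ln_meta$mouse_id,
                                         paired$mouse_id)]
      a <- ln_meta$ln_size_mm[ln_sub %in% "IGHV1"]
      b <- ln_meta$ln_size_mm[ln_sub %in% "IGHV11"]
      if (length(a) && length(b)) {
        ln_size_test <- wilcoxon_ranksum(a, b, group_a = "IGHV1",
                                         group_b = "IGHV11")
      }
    }
  }

  bundle <- list(
    threshold = threshold,
    threshold_report = threshold_report,
    clonality = clonality,
    callsets = callsets,
    hhi = hhi,
    age_trend = age_trend,
    insertion_summary = insertion_summary,
    insertion_tests = insertion_tests,
    lv = lv,
    lv_summary = lv_summary,
    vdj = vdj,
    vdj_weighted = vdj_weighted,
    survival = list(clonality = surv_clonality,
                    subgroup = surv_subgroup,
                    subgroup_sex = surv_subgroup_sex,
                    sex_fisher = sex_fisher),
    paired_organs = paired,
    ln_size_test = ln_size_test,
    warnings = dplyr::bind_rows(warnings_log),
    rejected = dplyr::bind_rows(rejected)
  )

  if (!is.null(out_dir)) {
    .write_bundle(bundle, out_dir, samples, metadata,
                  config = list(threshold = threshold,
                                dominance = dominance,
                                min_quality = min_quality,
                                lv_k = lv_k, lv_m = lv_m, seed = seed,
                                dialect = dialect))
    return(invisible(bundle))
  }
  bundle
}

.write_bundle <- function(bundle, out_dir, samples, metadata, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")),
                       na = "", progress = FALSE)
    }
  }
  wr(bundle$clonality, "clonality")
  wr(bundle$hhi, "hhi")
  wr(bundle$insertion_summary, "insertion_summary")
  wr(bundle$insertion_tests, "insertion_tests")
  wr(bundle$lv_summary, "lv_summary")
  wr(bundle$vdj, "vdj_usage")
  wr(bundle$vdj_weighted, "vdj_usage_weighted")
  for (fam in c("clonality", "subgroup", "subgroup_sex")) {
    f <- bundle$survival[[fam]]
    if (!is.null(f)) wr(f$comparisons, paste0("survival_", fam))
  }
  if (!is.null(bundle$survival$sex_fisher)) {
    wr(bundle$survival$sex_fisher, "sex_fisher")
  }
  if (!is.null(bundle$paired_organs)) {
    wr(bundle$paired_organs, "paired_organs")
  }
  wr(bundle$warnings, "warnings")
  input_hash <- vapply(samples, function(s) {
    rlang::hash(s)
  }, character(1))
  manifest <- list(
    package = "clonotrace",
    version = as.character(utils::packageVersion("clonotrace")),
    config = config,
    n_samples = length(samples),
    input_hashes = as.list(input_hash),
    age_trend = bundle$age_trend,
    threshold = bundle$threshold
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
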