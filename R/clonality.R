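# CLL clone calling: wild-type-calibrated threshold derivation, clone
# calling at the threshold, clonality classification and dominant-clone
# selection.

#' Derive the CLL-clone threshold from wild-type repertoires
#'
#' Collects the `top_k` largest clone fractions of each wild-type mouse,
#' pools them, and recommends a threshold that (i) exceeds the wild-type
#' background — the smallest whole-percent step strictly above the pooled
#' maximum — and (ii) respects the established human-CLL convention of
#' 2.5–5% clone fraction, i.e. is never below the upper end of
#' `human_range`.
#'
#' @param wt_repertoires List of `repertoire` objects from wild-type mice.
#' @param top_k Number of top clones pooled per mouse (all clones if fewer).
#' @param human_range Human-CLL threshold convention as `c(lo, hi)`
#'   fractions; default `c(0.025, 0.05)`.
#' @return An object of class `threshold_report`: list with `top_fractions`
#'   (tibble `sample_id`, `rank`, `fraction`), `pooled_range`,
#'   `pooled_median` and `recommended_threshold`.
#' @export
derive_threshold <- function(wt_repertoires, top_k = 10,
                             human_range = c(0.025, 0.05)) {
  if (length(wt_repertoires) == 0L) {
    stop("need at least one wild-type repertoire", call. = FALSE)
  }
  stopifnot(top_k >= 1, length(human_range) == 2, human_range[2] > 0)
  top_fractions <- purrr::map_dfr(wt_repertoires, function(r) {
    stopifnot(inherits(r, "repertoire"))
    f <- sort(r$clones$fraction, decreasing = TRUE)
    f <- f[seq_len(min(top_k, length(f)))]
    tibble::tibble(sample_id = r$sample_id, rank = seq_along(f), fraction = f)
  })
  pooled <- top_fractions$fraction
  pooled_max <- max(pooled)
  # smallest whole-percent value strictly above the wild-type background
  step_above <- (floor(pooled_max * 100 + 1e-9) + 1L) / 100
  structure(
    list(
      top_fractions = top_fractions,
      pooled_range = range(pooled),
      pooled_median = stats::median(pooled),
      recommended_threshold = max(human_range[2], step_above)
    ),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> pooled top-clone fractions %.2f%%-%.2f%% (median %.2f%%); recommended threshold %.0f%%\n",
    100 * x$pooled_range[1], 100 * x$pooled_range[2],
    100 * x$pooled_median, 100 * x$recommended_threshold))
  invisible(x)
}

#' Call CLL clones and classify clonality
#'
#' Clones whose fraction meets `threshold` (inclusive) are CLL clones; the
#' remainder is the miscellaneous B-cell background. Clonality class is
#' monoclonal (1 CLL clone), biclonal (2), oligoclonal (3–10) or
#' `polyclonal_excess` (0 or more than 10). The largest clone is the
#' dominant clone when its fraction meets `dominance`.
#'
#' @param repertoire A `repertoire` object.
#' @param threshold CLL-clone fraction threshold in (0,1); default 0.05.
#' @param dominance Dominant-clone fraction threshold; default 0.50.
#' @param inclusive Comparator at the dominance boundary: `TRUE` uses `>=`
#'   ("at least 50%"), `FALSE` uses strict `>`.
#' @return An object of class `cll_callset`: list with `sample_id`,
#'   `cll_clones` (tibble), `misc_fraction`, `clonality_class`,
#'   `dominant_clone` (one-row tibble or `NULL`), `threshold_used`,
#'   `dominance_used`.
#' @export
call_cll <- function(repertoire, threshold = 0.05, dominance = 0.50,
                     inclusive = TRUE) {
  stopifnot(inherits(repertoire, "repertoire"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (!(dominance > 0 && dominance <= 1)) {
    stop("dominance must lie in (0, 1]", call. = FALSE)
  }
  cl <- repertoire$clones
  if (nrow(cl) == 0L) stop("empty repertoire", call. = FALSE)
  cll <- cl[cl$fraction >= threshold, , drop = FALSE]
  n <- nrow(cll)
  clonality_class <- if (n == 1L) "monoclonal" else if (n == 2L) "biclonal"
    else if (n >= 3L && n <= 10L) "oligoclonal" else "polyclonal_excess"
  top <- cl[which.max(cl$fraction), , drop = FALSE]
  dominant <- if ((inclusive && top$fraction >= dominance) ||
                  (!inclusive && top$fraction > dominance)) top else NULL
  structure(
    list(
      sample_id = repertoire$sample_id,
      cll_clones = cll,
      misc_fraction = 1 - sum(cll$fraction),
      clonality_class = clonality_class,
      dominant_clone = dominant,
      threshold_used = threshold,
      dominance_used = dominance
    ),
    class = "cll_callset"
  )
}

#' @export
print.cll_callset <- function(x, ...) {
  dom <- if (is.null(x$dominant_clone)) "none"
    else sprintf("%s (%s, %.1f%%)", x$dominant_clone$cdr3_aa,
                 x$dominant_clone$v_gene, 100 * x$dominant_clone$fraction)
  cat(sprintf("<cll_callset> %s: %d CLL clone(s) at >=%.0f%%, %s; dominant: %s\n",
              x$sample_id, nrow(x$cll_clones), 100 * x$threshold_used,
              x$clonality_class, dom))
  invisible(x)
}

#' IGHV subgroup of the dominant clone
#'
#' @param callset A `cll_callset`.
#' @return Subgroup label of the dominant clone, or `NA_character_` when no
#'   clone meets the dominance threshold.
#' @export
dominant_subgroup <- function(callset) {
  stopifnot(inherits(callset, "cll_callset"))
  if (is.null(callset$dominant_clone)) NA_character_
  else callset$dominant_clone$v_gene
}

#' Per-sample clonality summary table
#'
#' @param callsets List of `cll_callset` objects.
#' @return Tibble with one row per sample: `sample_id`, `n_cll_clones`,
#'   `clonality_class`, `dominant_cdr3`, `dominant_v`, `dominant_fraction`.
#' @export
clonality_table <- function(callsets) {
  purrr::map_dfr(callsets, function(cs) {
    tibble::tibble(
      sample_id = cs$sample_id,
      n_cll_clones = nrow(cs$cll_clones),
      clonality_class = cs$clonality_class,
      dominant_cdr3 = if (is.null(cs$dominant_clone)) NA_character_
        else cs$dominant_clone$cdr3_aa,
      dominant_v = dominant_subgroup(cs),
      dominant_fraction = if (is.null(cs$dominant_clone)) NA_real_
        else cs$dominant_clone$fraction
    )
  })
}
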