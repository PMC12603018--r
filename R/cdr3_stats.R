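# Junction N-insertion statistics, clone-fraction-weighted Levenshtein
# resampling of CDR3 amino-acid sequences, and weighted V(D)J-usage tallies.

#' Summed junction N-insertions
#'
#' Total non-templated nucleotides of a junction: N1 (V-D) plus N2 (D-J).
#' Missing annotations are an error — a clone without junction decomposition
#' must be excluded upstream, never silently scored 0.
#'
#' @param n1_len,n2_len Non-negative integer vectors of N-region lengths.
#' @return Integer vector `n1_len + n2_len`.
#' @export
n_insertions <- function(n1_len, n2_len) {
  if (any(is.na(n1_len)) || any(is.na(n2_len))) {
    stop("missing junction N-length annotation", call. = FALSE)
  }
  stopifnot(all(n1_len >= 0), all(n2_len >= 0))
  n1_len + n2_len
}

#' Junction statistics of a set of CLL clones
#'
#' @param clones Clone tibble (e.g. `cll_clones` of a callset, or several
#'   bound together) with `cdr3_aa`, `v_gene`, `n1_len`, `n2_len`.
#' @return Tibble with `cdr3_aa`, `subgroup`, `n_insertions`,
#'   `cdr3_len_aa`; clones lacking either N-length are excluded and listed
#'   in the `excluded` attribute.
#' @export
junction_stats <- function(clones) {
  ok <- !is.na(clones$n1_len) & !is.na(clones$n2_len)
  excluded <- clones$cdr3_aa[!ok]
  kept <- clones[ok, , drop = FALSE]
  out <- tibble::tibble(
    cdr3_aa = kept$cdr3_aa,
    subgroup = kept$v_gene,
    n_insertions = n_insertions(kept$n1_len, kept$n2_len),
    cdr3_len_aa = nchar(kept$cdr3_aa)
  )
  attr(out, "excluded") <- excluded
  out
}

#' Per-subgroup median and IQR of N-insertions
#'
#' Quartiles use the linear-interpolation percentile convention
#' (`quantile(type = 7)`).
#'
#' @param stats Tibble from [junction_stats()] (needs `subgroup` and
#'   `n_insertions`).
#' @param groups Optional subgroup labels to report; others are pooled out.
#'   Requested groups with no clones are omitted with a warning.
#' @return Tibble with `subgroup`, `n`, `median`, `q25`, `q75`.
#' @export
group_insertion_summary <- function(stats, groups = NULL) {
  if (!is.null(groups)) {
    absent <- setdiff(groups, stats$subgroup)
    if (length(absent)) {
      warning("no clones in group(s): ", paste(absent, collapse = ", "),
              call. = FALSE)
    }
    stats <- stats[stats$subgroup %in% groups, , drop = FALSE]
  }
  stats |>
    dplyr::group_by(subgroup = .data$subgroup) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$n_insertions),
      q25 = unname(stats::quantile(.data$n_insertions, 0.25, type = 7)),
      q75 = unname(stats::quantile(.data$n_insertions, 0.75, type = 7)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$subgroup)
}

#' Levenshtein distance between CDR3 amino-acid sequences
#'
#' Unit-cost edit distance (insertions, deletions, substitutions), computed
#' on the full IMGT junction string including the C104 and W/F118 anchors.
#'
#' @param a,b Non-empty amino-acid strings (vectors recycle pairwise).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("CARW", "W")  # 3
#' @export
levenshtein <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)) || any(is.na(a)) || any(is.na(b))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  as.integer(mapply(function(x, y) utils::adist(x, y), a, b))
}

# round half away from zero (base round() is banker's rounding)
.round_half_up <- function(x) floor(x + 0.5)

#' Build a clone-fraction-weighted CDR3 pool
#'
#' Implements the normalization used for Levenshtein-distance resampling
#' and alluvial plotting: the frequency of each distinct CDR3 sequence is
#' its clone fraction cumulated across all contributing samples, multiplied
#' by a scale constant `K` and rounded (half away from zero) to an integer
#' multiplicity. Sequences whose multiplicity rounds to 0 are dropped and
#' listed in the `dropped` attribute.
#'
#' @param cdr3_aa Character vector of CDR3 amino-acid sequences.
#' @param fraction Matching clone fractions in (0, 1].
#' @param K Scale constant; default 100 so a 1% clone survives rounding.
#' @param group Optional group label (e.g. the IGHV subgroup of the pool).
#' @return An object of class `weighted_cdr3_pool`: list with `group`, `K`,
#'   and `pool`, a tibble of `cdr3_aa`, `cum_fraction`, `multiplicity`.
#' @export
build_weighted_pool <- function(cdr3_aa, fraction, K = 100, group = NULL) {
  if (length(cdr3_aa) == 0L) stop("empty pool input", call. = FALSE)
  stopifnot(length(cdr3_aa) == length(fraction), K >= 1,
            all(fraction > 0), all(fraction <= 1))
  pool <- tibble::tibble(cdr3_aa = cdr3_aa, fraction = fraction) |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(cum_fraction = sum(.data$fraction), .groups = "drop") |>
    dplyr::mutate(multiplicity = .round_half_up(K * .data$cum_fraction)) |>
    dplyr::arrange(dplyr::desc(.data$multiplicity), .data$cdr3_aa)
  dropped <- pool$cdr3_aa[pool$multiplicity == 0]
  pool <- pool[pool$multiplicity > 0, , drop = FALSE]
  structure(
    list(group = group, K = K, pool = pool),
    class = "weighted_cdr3_pool",
    dropped = dropped
  )
}

#' @export
print.weighted_cdr3_pool <- function(x, ...) {
  cat(sprintf("<weighted_cdr3_pool>%s %d distinct sequences, total multiplicity %d (K = %d)\n",
              if (is.null(x$group)) "" else paste0(" ", x$group),
              nrow(x$pool), sum(x$pool$multiplicity), x$K))
  invisible(x)
}

#' Resample CDR3 sequences and measure pairwise Levenshtein distances
#'
#' Draws `m` sequences from the weighted multiset (with replacement by
#' default, so `m` is independent of pool size) and computes the unit-cost
#' edit distance for every unordered pair of draw indices. Two draws of the
#' same sequence count as a distance-0 pair — they represent true repertoire
#' mass; only the self-pair of one draw index is excluded.
#'
#' @param pool A `weighted_cdr3_pool`.
#' @param m Number of sequences to draw; default 100.
#' @param seed Integer seed; the draw is deterministic given `(pool, m,
#'   seed)` and the RNG state of the caller is left untouched.
#' @param replace Sample with replacement (default `TRUE`).
#' @return An object of class `lv_sample`: list with `sequences` (the `m`
#'   draws), `distances` (length `m (m-1) / 2`), `median`, `q25`, `q75`,
#'   `m`, `seed`.
#' @export
lv_resample <- function(pool, m = 100, seed, replace = TRUE) {
  stopifnot(inherits(pool, "weighted_cdr3_pool"), m >= 2)
  total <- sum(pool$pool$multiplicity)
  if (total < 2L) stop("pool too small to sample pairs", call. = FALSE)
  if (!replace && m > total) {
    stop("m exceeds pool size and replace = FALSE", call. = FALSE)
  }
  draws <- withr::with_seed(seed, {
    if (replace) {
      sample(pool$pool$cdr3_aa, m, replace = TRUE,
             prob = pool$pool$multiplicity)
    } else {
      sample(rep(pool$pool$cdr3_aa, times = pool$pool$multiplicity), m)
    }
  })
  # adist on the unique sequences, then expand: far fewer DP runs than m^2
  uniq <- unique(draws)
  dmat <- utils::adist(uniq)
  idx <- match(draws, uniq)
  full <- dmat[idx, idx, drop = FALSE]
  distances <- as.integer(full[upper.tri(full)])
  structure(
    list(
      sequences = draws,
      distances = distances,
      median = stats::median(distances),
      q25 = unname(stats::quantile(distances, 0.25, type = 7)),
      q75 = unname(stats::quantile(distances, 0.75, type = 7)),
      m = m,
      seed = seed
    ),
    class = "lv_sample"
  )
}

#' @export
print.lv_sample <- function(x, ...) {
  cat(sprintf("<lv_sample> m = %d (seed %s): median LV %.2f (IQR %.2f-%.2f)\n",
              x$m, format(x$seed), x$median, x$q25, x$q75))
  invisible(x)
}

#' V(D)J gene-usage table of CLL clones
#'
#' Tallies CLL clones over (IGHV subgroup, IGHD, IGHJ) combinations, either
#' as clone counts or as summed clone fractions (the weighting used for
#' alluvial plotting). Rows are ordered by descending mass, then
#' lexicographically.
#'
#' @param callsets List of `cll_callset` objects.
#' @param weighted Sum clone fractions instead of counting clones.
#' @return Tibble with `v_subgroup`, `d_gene`, `j_gene` and `count` or
#'   `weight`.
#' @export
vdj_usage <- function(callsets, weighted = FALSE) {
  empty <- tibble::tibble(v_subgroup = character(0), d_gene = character(0),
                          j_gene = character(0))
  empty[[if (weighted) "weight" else "count"]] <- numeric(0)
  if (length(callsets) == 0L) return(empty)
  clones <- purrr::map_dfr(callsets, function(cs) cs$cll_clones)
  if (nrow(clones) == 0L) return(empty)
  out <- clones |>
    dplyr::group_by(v_subgroup = .data$v_gene, d_gene = .data$d_gene,
                    j_gene = .data$j_gene)
  out <- if (weighted) {
    dplyr::summarise(out, weight = sum(.data$fraction), .groups = "drop")
  } else {
    dplyr::summarise(out, count = dplyr::n(), .groups = "drop")
  }
  mass <- if (weighted) out$weight else out$count
  out[order(-mass, out$v_subgroup, out$d_gene, out$j_gene), , drop = FALSE]
}
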