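# Normalized Herfindahl-Hirschman index of a repertoire and its trend
# against age.

#' Normalized Herfindahl-Hirschman index
#'
#' The raw HHI of a clone-fraction vector is \eqn{H = \sum_i p_i^2}. It is
#' rescaled to \eqn{H^* = (H - 1/N) / (1 - 1/N)} for \eqn{N > 1} clones so
#' that a perfectly even repertoire scores 0 and a monoclonal repertoire
#' (\eqn{N = 1}) scores 1.
#'
#' @param fractions Positive clone fractions summing to 1 (tolerance 1e-6).
#' @return Normalized HHI in \[0, 1\].
#' @examples
#' hhi_normalized(1)             # 1
#' hhi_normalized(rep(0.25, 4))  # 0
#' hhi_normalized(c(0.7, 0.3))
#' @export
hhi_normalized <- function(fractions) {
  if (length(fractions) < 1L || any(!is.finite(fractions)) ||
      any(fractions <= 0)) {
    stop("fractions must be positive and finite", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-6) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  n <- length(fractions)
  if (n == 1L) return(1)
  # a perfectly even repertoire is the exact minimum; short-circuit so the
  # anchor is hit without floating-point residue
  if (max(fractions) == min(fractions)) return(0)
  h <- sum(fractions^2)
  (h - 1 / n) / (1 - 1 / n)
}

#' Diversity points of a set of repertoires
#'
#' @param repertoires List of `repertoire` objects.
#' @param metadata Per-sample metadata tibble with at least `sample_id`,
#'   `mouse_id` and `age_days`.
#' @return Tibble with `sample_id`, `mouse_id`, `age_days`, `n_clones`,
#'   `hhi_norm`.
#' @export
diversity_points <- function(repertoires, metadata) {
  stopifnot(all(c("sample_id", "mouse_id", "age_days") %in% names(metadata)))
  pts <- purrr::map_dfr(repertoires, function(r) {
    tibble::tibble(sample_id = r$sample_id,
                   n_clones = nrow(r$clones),
                   hhi_norm = hhi_normalized(r$clones$fraction))
  })
  dplyr::inner_join(
    pts,
    dplyr::distinct(metadata[, c("sample_id", "mouse_id", "age_days")]),
    by = "sample_id"
  )[, c("sample_id", "mouse_id", "age_days", "n_clones", "hhi_norm")]
}

#' Ordinary least-squares trend of diversity against age
#'
#' Fits `hhi_norm ~ age_days` by OLS, pooling all samples as independent
#' points, and reports the slope with its two-sided t-test p-value (n-2
#' degrees of freedom) and the coefficient of determination.
#'
#' @param points Tibble from [diversity_points()] (needs `age_days` and
#'   `hhi_norm`).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_points`.
#' @export
fit_age_trend <- function(points) {
  stopifnot(all(c("age_days", "hhi_norm") %in% names(points)))
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(unique(points$age_days)) < 2L) {
    stop("degenerate design: all ages identical", call. = FALSE)
  }
  fit <- stats::lm(hhi_norm ~ age_days, data = points)
  # summary() warns on an exactly collinear response; the fit itself is fine
  sm <- suppressWarnings(summary(fit))
  # a flat response carries no evidence of a trend: R^2 0, p 1
  degenerate <- stats::var(points$hhi_norm) == 0
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (degenerate) 0 else sm$r.squared,
    p_value = if (degenerate) 1
      else unname(sm$coefficients["age_days", "Pr(>|t|)"]),
    n_points = nrow(points)
  )
}
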