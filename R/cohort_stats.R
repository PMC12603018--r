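# Cohort statistics layer: Wilcoxon rank-sum, Fisher's exact 2x2 with
# conditional-MLE odds ratio, Kaplan-Meier estimation, pairwise log-rank
# with Benjamini-Hochberg adjustment, Mantel-Haenszel hazard ratios, and a
# Shapiro-Wilk normality screen.

.group_comparison <- function(group_a, group_b, statistic, p_value,
                              p_adjusted = NA_real_, effect = NA_real_,
                              method = NA_character_) {
  tibble::tibble(group_a = group_a, group_b = group_b,
                 statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, effect = effect, method = method)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two groups
#'
#' Exact two-sided p when both samples are at most `exact_max_n`: by the
#' closed-form null distribution when there are no ties, or by full
#' enumeration of label assignments over midranks when there are ties and
#' both samples have at most 10 values (beyond that, enumeration is
#' infeasible and the tie-corrected normal approximation with continuity
#' correction is used, as it is for large samples). The two-sided p is
#' twice the smaller tail, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max_n Exact/approximate switchover per-group size.
#' @param group_a,group_b Labels carried into the result.
#' @return One-row `GroupComparison` tibble (`statistic` is the
#'   Mann-Whitney U of `x`).
#' @export
wilcoxon_ranksum <- function(x, y, exact_max_n = 25,
                             group_a = "x", group_b = "y") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups", call. = FALSE)
    return(.group_comparison(group_a, group_b,
                             statistic = length(x) * length(y) / 2,
                             p_value = 1, method = "wilcoxon"))
  }
  nx <- length(x)
  ny <- length(y)
  ties <- any(duplicated(c(x, y)))
  small <- nx <= exact_max_n && ny <= exact_max_n
  if (small && ties && nx <= 10 && ny <= 10) {
    # exact by enumeration over midranks
    r <- rank(c(x, y))
    u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    u_all <- utils::combn(r, nx, function(z) sum(z)) - nx * (nx + 1) / 2
    lo <- mean(u_all <= u_obs)
    hi <- mean(u_all >= u_obs)
    p <- min(1, 2 * min(lo, hi))
    return(.group_comparison(group_a, group_b, statistic = u_obs,
                             p_value = p, method = "wilcoxon"))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = small && !ties, correct = TRUE)
  )
  .group_comparison(group_a, group_b, statistic = unname(wt$statistic),
                    p_value = wt$p.value, method = "wilcoxon")
}

#' Fisher's exact test on a 2x2 table with conditional-MLE odds ratio
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one, within a small tolerance for floating
#' ties. The effect is the conditional maximum-likelihood odds ratio, the
#' root of the noncentral-hypergeometric mean equation; a zero margin cell
#' yields 0 or `Inf`.
#'
#' @param table 2x2 matrix (or object coercible to one) of non-negative
#'   counts; rows are groups, columns outcomes.
#' @param group_a,group_b Labels carried into the result.
#' @return One-row `GroupComparison` tibble; `effect` is the odds ratio.
#' @examples
#' fisher_2x2(matrix(c(17, 13, 6, 16), 2, byrow = TRUE))
#' @export
fisher_2x2 <- function(table, group_a = "a", group_b = "b") {
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integer counts", call. = FALSE)
  }
  if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) {
    stop("table has no positive margin", call. = FALSE)
  }
  ft <- stats::fisher.test(tab, conf.int = FALSE)
  .group_comparison(group_a, group_b, statistic = tab[1, 1],
                    p_value = ft$p.value, effect = unname(ft$estimate),
                    method = "fisher")
}

#' Kaplan-Meier fit of one group
#'
#' Product-limit estimator with pointwise 95% confidence band on the
#' log-log scale; the median is the smallest time at which the survival
#' estimate drops to 0.5 or below, and its CI is read off where the band
#' crosses 0.5 (one-sided — `NA` on one side — when the band never
#' recrosses it).
#'
#' @param time Positive follow-up times in days.
#' @param event Event indicator: 1 death/endpoint, 0 censored.
#' @return An object of class `km_curve`: list with `curve` (tibble of
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`), `median`,
#'   `median_lower`, `median_upper`, `n`, `n_events`.
#' @export
km_fit <- function(time, event = rep(1, length(time))) {
  stopifnot(length(time) >= 1, length(event) == length(time),
            all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  qt <- stats::quantile(fit, probs = 0.5)
  med <- unname(qt$quantile)
  structure(
    list(
      curve = tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                             n_event = fit$n.event, surv = fit$surv,
                             lower = fit$lower, upper = fit$upper),
      median = if (is.na(med)) NA_real_ else med,
      median_lower = unname(qt$lower),
      median_upper = unname(qt$upper),
      n = length(time),
      n_events = sum(event)
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d (%d events): median %s [%s, %s]\n",
              x$n, x$n_events, format(x$median),
              format(x$median_lower), format(x$median_upper)))
  invisible(x)
}

# survdiff-based O/E tabulation shared by the log-rank test and the
# Mantel-Haenszel hazard ratio
.logrank_oe <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(obs = sd$obs, exp = sd$exp, chisq = sd$chisq)
}

#' Mantel-Haenszel hazard ratio of two groups
#'
#' \eqn{(O_a/E_a) / (O_b/E_b)} from the observed and expected event counts
#' of the shared log-rank risk-set tabulation.
#'
#' @param time_a,event_a,time_b,event_b Survival data of the two groups.
#' @return Hazard ratio of group a versus group b, or `NA` when an expected
#'   event count is zero.
#' @export
hazard_ratio_mh <- function(time_a, event_a, time_b, event_b) {
  stopifnot(sum(event_a) >= 1, sum(event_b) >= 1)
  oe <- .logrank_oe(c(time_a, time_b), c(event_a, event_b),
                    rep(c("a", "b"), c(length(time_a), length(time_b))))
  if (any(oe$exp == 0)) {
    warning("zero expected events; hazard ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  unname((oe$obs[1] / oe$exp[1]) / (oe$obs[2] / oe$exp[2]))
}

#' Pairwise log-rank tests across strata with BH adjustment
#'
#' Every unordered pair of strata is compared by the two-group log-rank
#' chi-square test (1 df); p-values are Benjamini-Hochberg-adjusted across
#' the full pairwise family, and each comparison carries the
#' Mantel-Haenszel hazard ratio of the first-named stratum versus the
#' second. Strata without any event are skipped with a warning.
#'
#' @param records Tibble with `time_days`, `event` and `stratum`.
#' @param adjust Multiple-testing method; only `"BH"` is offered.
#' @return `GroupComparison` tibble, one row per pair; `effect` is the
#'   hazard ratio.
#' @export
logrank_pairwise <- function(records, adjust = "BH") {
  adjust <- match.arg(adjust)
  stopifnot(all(c("time_days", "event", "stratum") %in% names(records)))
  strata <- sort(unique(records$stratum))
  if (length(strata) < 2L) stop("need at least 2 strata", call. = FALSE)
  has_event <- vapply(strata, function(s) {
    sum(records$event[records$stratum == s]) >= 1
  }, logical(1))
  if (any(!has_event)) {
    warning("stratum without events skipped: ",
            paste(strata[!has_event], collapse = ", "), call. = FALSE)
    strata <- strata[has_event]
  }
  if (length(strata) < 2L) stop("fewer than 2 strata with events",
                                call. = FALSE)
  pairs <- utils::combn(strata, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- records[records$stratum == pr[1], ]
    b <- records[records$stratum == pr[2], ]
    oe <- .logrank_oe(c(a$time_days, b$time_days), c(a$event, b$event),
                      rep(c("a", "b"), c(nrow(a), nrow(b))))
    hr <- if (any(oe$exp == 0)) NA_real_
      else unname((oe$obs[1] / oe$exp[1]) / (oe$obs[2] / oe$exp[2]))
    .group_comparison(pr[1], pr[2], statistic = unname(oe$chisq),
                      p_value = stats::pchisq(oe$chisq, df = 1,
                                              lower.tail = FALSE),
                      effect = hr, method = "logrank")
  })
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Shapiro-Wilk normality screen
#'
#' Report-only screen of the groups entering a comparison: each group of at
#' least 3 non-constant values gets a W statistic and p-value; smaller
#' groups and constant groups are skipped with a note. The analysis
#' proceeds with non-parametric tests regardless of the outcome.
#'
#' @param samples Named list of numeric vectors.
#' @return Tibble with `group`, `n`, `W`, `p_value`, `note`.
#' @export
shapiro_wilk_screen <- function(samples) {
  stopifnot(is.list(samples), length(samples) >= 1)
  nm <- names(samples)
  if (is.null(nm)) nm <- paste0("group", seq_along(samples))
  purrr::map2_dfr(samples, nm, function(x, g) {
    if (length(x) < 3L) {
      return(tibble::tibble(group = g, n = length(x), W = NA_real_,
                            p_value = NA_real_, note = "skipped: n < 3"))
    }
    if (stats::var(x) == 0) {
      return(tibble::tibble(group = g, n = length(x), W = NA_real_,
                            p_value = NA_real_,
                            note = "skipped: constant sample"))
    }
    sw <- stats::shapiro.test(x)
    tibble::tibble(group = g, n = length(x), W = unname(sw$statistic),
                   p_value = sw$p.value, note = NA_character_)
  })
}
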