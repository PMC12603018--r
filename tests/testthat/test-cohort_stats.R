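test_that("wilcoxon rank-sum reproduces exact small-sample p-values", {
  # untied: all C(4,2) = 6 rank assignments, extreme ordering -> 2/6
  expect_equal(wilcoxon_ranksum(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  # identical samples are uninformative
  expect_warning(res <- wilcoxon_ranksum(c(2, 2, 2), c(2, 2, 2)),
                 "identical")
  expect_equal(res$p_value, 1)
  # tied small samples: full enumeration over midranks (2/70)
  expect_equal(wilcoxon_ranksum(c(0, 0, 0, 1), c(3, 4, 5, 6))$p_value,
               2 / 70, tolerance = 1e-12)
})

test_that("wilcoxon agrees with the enumeration oracle up to 8+8", {
  set.seed(8)
  for (i in 1:15) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    # mixed integer draws so ties occur in roughly half the cases
    x <- sample(0:6, nx, replace = TRUE)
    y <- sample(2:9, ny, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    expect_equal(wilcoxon_ranksum(x, y)$p_value, wilcox_enum_p(x, y),
                 tolerance = 1e-9,
                 label = paste("x =", paste(x, collapse = ","),
                               "y =", paste(y, collapse = ",")))
  }
})

test_that("fisher_2x2 matches its worked examples", {
  # sex-by-subgroup table: conditional-MLE OR ~3.4, p ~0.049
  res <- fisher_2x2(matrix(c(17, 13, 6, 16), 2, byrow = TRUE))
  expect_equal(round(res$effect, 1), 3.4)
  expect_equal(round(res$p_value, 3), 0.049)
  # symmetric table
  res2 <- fisher_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res2$effect, 1, tolerance = 1e-6)
  expect_equal(res2$p_value, 1)
  # enumeration by hand: masses 0.05, 0.45, 0.45, 0.05 -> p = 1
  expect_equal(fisher_2x2(matrix(c(2, 1, 1, 2), 2))$p_value, 1,
               tolerance = 1e-9)
  # zero margin cell: infinite or zero OR
  expect_equal(fisher_2x2(matrix(c(5, 0, 0, 5), 2))$effect, Inf)
  expect_error(fisher_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_2x2(matrix(0, 2, 2)), "margin")
})

test_that("fisher_2x2 equals the enumeration oracle on random tables", {
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (all(rowSums(tab) == 0) || all(colSums(tab) == 0)) next
    res <- fisher_2x2(tab)
    expect_equal(res$p_value,
                 fisher_enum_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
    or <- fisher_cmle_or(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    if (is.finite(or) && or > 0) {
      # fisher.test maximizes the conditional likelihood numerically;
      # agreement with the mean-equation root is to optimizer precision
      expect_equal(res$effect, or, tolerance = 1e-3)
    }
  }
})

test_that("conditional-MLE mean equation is monotone in the odds ratio", {
  # uniqueness of the root: E_psi[a] strictly increases with psi
  a <- 17; b <- 13; c <- 6; d <- 16
  support <- max(0, (a + b) + (a + c) - (a + b + c + d)):min(a + b, a + c)
  base <- dhyper(support, a + c, b + d, a + b)
  mean_a <- function(psi) {
    w <- base * psi^support
    sum(support * w) / sum(w)
  }
  psis <- c(0.1, 0.5, 1, 2, 3.4, 10, 50)
  means <- vapply(psis, mean_a, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_lt(mean_a(1), a)     # observed table is above the null mean
  expect_gt(mean_a(50), a)    # bracketing
})

test_that("km_fit reproduces the hand product-limit table", {
  km <- km_fit(1:5, rep(1, 5))
  hand <- km_hand(1:5, rep(1, 5))
  expect_equal(km$curve$time, hand$time)
  expect_equal(km$curve$surv, hand$surv, tolerance = 1e-12)
  expect_equal(km$curve$surv[km$curve$time == 3], 0.4)
  expect_equal(km$median, 3)
  # single event
  expect_equal(km_fit(100, 1)$median, 100)
  # all censored: the curve never reaches 0.5
  expect_true(is.na(km_fit(c(10, 20, 30), c(0, 0, 0))$median))
})

test_that("km_fit equals the empirical survivor function without censoring", {
  set.seed(19)
  for (i in 1:10) {
    t <- sample(1:500, 40, replace = TRUE)
    km <- km_fit(t, rep(1, 40))
    ecdf_surv <- vapply(km$curve$time, function(u) mean(t > u), numeric(1))
    expect_equal(km$curve$surv, ecdf_surv, tolerance = 1e-12)
  }
})

test_that("km curve is a proper survival function", {
  set.seed(23)
  t <- rlnorm(60, log(300), 0.3)
  ev <- rbinom(60, 1, 0.8)
  km <- km_fit(t, ev)
  expect_true(all(diff(km$curve$surv) <= 1e-12))
  expect_true(all(km$curve$surv >= 0 & km$curve$surv <= 1))
  if (!is.na(km$median)) {
    crossing <- km$curve$time[km$curve$surv <= 0.5]
    expect_equal(km$median, min(crossing))
  }
})

test_that("pairwise log-rank matches the risk-set oracle and BH family", {
  rec <- tibble::tibble(
    time_days = c(1, 2, 3, 10, 20, 30),
    event = 1,
    stratum = rep(c("A", "B"), each = 3)
  )
  cmp <- logrank_pairwise(rec)
  oe <- logrank_oe_hand(c(1, 2, 3), c(1, 1, 1), c(10, 20, 30), c(1, 1, 1))
  # chi-square from the hand O/E tabulation (variance via survdiff's form
  # is not re-derived here; O/E feed the hazard ratio)
  expect_equal(cmp$effect,
               (oe$obs_a / oe$exp_a) / (oe$obs_b / oe$exp_b),
               tolerance = 1e-9)
  expect_lt(cmp$p_value, 0.05)
  # identical strata: no signal
  rec2 <- tibble::tibble(time_days = rep(c(5, 10, 15), 2), event = 1,
                         stratum = rep(c("A", "B"), each = 3))
  cmp2 <- logrank_pairwise(rec2)
  expect_equal(cmp2$statistic, 0, tolerance = 1e-9)
  expect_equal(cmp2$p_value, 1)
  expect_equal(cmp2$effect, 1, tolerance = 1e-9)
  # relabeling invariance of the chi-square
  rec3 <- rec
  rec3$stratum <- c("B", "B", "B", "A", "A", "A")
  expect_equal(logrank_pairwise(rec3)$statistic, cmp$statistic,
               tolerance = 1e-9)
  # p from the chi-square(1) upper tail
  expect_equal(cmp$p_value, pchisq(cmp$statistic, 1, lower.tail = FALSE))
  # stratum without events is skipped with a warning
  rec4 <- dplyr::bind_rows(rec, tibble::tibble(time_days = c(5, 6),
                                               event = 0, stratum = "C"))
  expect_warning(cmp4 <- logrank_pairwise(rec4), "C")
  expect_equal(nrow(cmp4), 1L)
  expect_error(logrank_pairwise(rec[rec$stratum == "A", ]), "2 strata")
})

test_that("BH adjustment across three strata follows step-up arithmetic", {
  set.seed(31)
  rec <- tibble::tibble(
    time_days = c(rlnorm(20, log(300), 0.2), rlnorm(20, log(360), 0.2),
                  rlnorm(20, log(420), 0.2)),
    event = 1,
    stratum = rep(c("A", "B", "C"), each = 20)
  )
  cmp <- logrank_pairwise(rec)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$p_adjusted, bh_step_up(cmp$p_value), tolerance = 1e-12)
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
})

test_that("Mantel-Haenszel hazard ratio behaves as an O/E ratio", {
  # identical groups
  expect_equal(hazard_ratio_mh(c(5, 10, 15), c(1, 1, 1),
                               c(5, 10, 15), c(1, 1, 1)), 1,
               tolerance = 1e-9)
  # strictly earlier events in A
  expect_gt(hazard_ratio_mh(c(1, 2, 3, 4), rep(1, 4),
                            c(10, 20, 30, 40), rep(1, 4)), 1)
  # hand example vs the risk-set oracle
  hr <- hazard_ratio_mh(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  oe <- logrank_oe_hand(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(hr, (oe$obs_a / oe$exp_a) / (oe$obs_b / oe$exp_b),
               tolerance = 1e-9)
})

test_that("hazard ratio recovery on synthetic two-arm cohorts", {
  set.seed(77)
  for (h in c(1, 2)) {
    hrs <- vapply(1:5, function(r) {
      ta <- rexp(200, rate = 0.01 * h)
      tb <- rexp(200, rate = 0.01)
      hazard_ratio_mh(ta, rep(1, 200), tb, rep(1, 200))
    }, numeric(1))
    expect_equal(mean(hrs), h, tolerance = 0.15 * h)
  }
})

test_that("bh_adjust matches step-up arithmetic and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_step_up(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)), "0, 1")
})

test_that("Shapiro-Wilk screen reports W per group and skips degenerates", {
  set.seed(51)
  smooth <- seq(0.1, 2, length.out = 20)
  outlier <- c(rep(1, 19), 50)
  rep_tab <- shapiro_wilk_screen(list(smooth = smooth, outlier = outlier))
  expect_lt(rep_tab$W[rep_tab$group == "outlier"],
            rep_tab$W[rep_tab$group == "smooth"])
  deg <- shapiro_wilk_screen(list(const = rep(3, 10), tiny = c(1, 2)))
  expect_equal(deg$note, c("skipped: constant sample", "skipped: n < 3"))
  # n = 5 hand vector against the classic coefficient-table formula:
  # W = (a1 (x(5)-x(1)) + a2 (x(4)-x(2)))^2 / sum((x - mean)^2)
  x <- c(1, 2, 3, 5, 12)
  a <- c(0.6646, 0.2413)
  xs <- sort(x)
  w_hand <- (a[1] * (xs[5] - xs[1]) + a[2] * (xs[4] - xs[2]))^2 /
    sum((x - mean(x))^2)
  got <- shapiro_wilk_screen(list(g = x))
  expect_equal(got$W, w_hand, tolerance = 0.01)
})
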