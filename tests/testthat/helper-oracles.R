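# Independent oracles used to check package results. Each is written
# directly from the defining formula or by brute-force enumeration, never
# by calling the code path it checks.

# Levenshtein distance by the textbook dynamic-programming matrix
lev_dp <- function(a, b) {
  s <- strsplit(a, "")[[1]]
  t <- strsplit(b, "")[[1]]
  n <- length(s)
  m <- length(t)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (s[i] != t[j]))
    }
  }
  d[n + 1, m + 1]
}

# Two-sided Fisher p by full enumeration of the conditional distribution:
# sum of hypergeometric masses no larger than the observed one
fisher_enum_p <- function(a, b, c, d, tol = 1e-7) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  mass <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(mass[mass <= p_obs * (1 + tol)])
}

# Conditional-MLE odds ratio by root-solving the noncentral-hypergeometric
# mean equation E_psi[a] = a_obs
fisher_cmle_or <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  base <- dhyper(support, c1, n - c1, r1)
  mean_a <- function(log_psi) {
    w <- base * exp(support * log_psi)
    sum(support * w) / sum(w)
  }
  uniroot(function(lp) mean_a(lp) - a, c(-40, 40), tol = 1e-10)$root |> exp()
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# nx labels to the pooled midranks; two-sided = twice the smaller tail
wilcox_enum_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sums <- combn(seq_along(r), nx, function(idx) sum(r[idx]))
  u_all <- sums - nx * (nx + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Hand product-limit table: S(t) over event times (no approximation)
km_hand <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    deaths <- sum(time == ut[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Log-rank observed/expected by direct risk-set tabulation over the pooled
# event times of two groups
logrank_oe_hand <- function(ta, ea, tb, eb) {
  times <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  oa <- ea_sum <- 0
  for (t in times) {
    na <- sum(ta >= t)
    nb <- sum(tb >= t)
    da <- sum(ta == t & ea == 1)
    db <- sum(tb == t & eb == 1)
    oa <- oa + da
    ea_sum <- ea_sum + (da + db) * na / (na + nb)
  }
  list(obs_a = oa, exp_a = ea_sum,
       obs_b = sum(eb), exp_b = sum(ea) + sum(eb) - ea_sum)
}

# Benjamini-Hochberg step-up arithmetic from the definition
bh_step_up <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Slope/intercept/R^2 by the normal equations
ols_hand <- function(x, y) {
  xb <- mean(x)
  yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
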