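# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms / primitives than the
# package code paths they verify.

# Natural cubic smoothing spline by direct dense linear algebra
# (Green & Silverman / Reinsch): minimizes sum (y - g)^2 + lambda *
# integral g''(t)^2 dt with t in the units of x.
oracle_smooth_spline <- function(x, y, lambda) {
  n <- length(x)
  h <- diff(x)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    i <- j - 1
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j,     i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (j < n - 1) { R[i, i + 1] <- h[j] / 6; R[i + 1, i] <- h[j] / 6 }
  }
  K <- Q %*% solve(R) %*% t(Q)
  solve(diag(n) + lambda * K, y)
}

# One-way fixed-effects ANOVA from explicit sum-of-squares decomposition.
oracle_anova <- function(y, grp) {
  groups <- unique(grp)
  gm <- mean(y)
  ss_between <- sum(vapply(groups, function(g)
    sum(grp == g) * (mean(y[grp == g]) - gm)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((y[grp == g] - mean(y[grp == g]))^2), numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- length(y) - length(groups)
  F <- (ss_between / df_b) / (ss_within / df_w)
  list(F = F, df_between = df_b, df_within = df_w,
       p = stats::pf(F, df_b, df_w, lower.tail = FALSE))
}

# Smoke-impact classification by regex subsequence scan on the NA-dropped
# label string: smoke-impacted iff clear ... smoke ... clear in order.
oracle_classify <- function(labels, min_clear_weeks = 6L) {
  obs <- labels[!is.na(labels)]
  s <- paste(ifelse(obs == "smoke", "S", "c"), collapse = "")
  if (grepl("c.*S.*c", s)) return("smoke_impacted")
  if (!grepl("S", s) && sum(obs == "no_smoke") >= min_clear_weeks)
    return("non_impacted")
  "indeterminate"
}

# Number of maximal runs of consecutive smoke weeks (NA breaks a run),
# counted as 0 -> 1 transitions of the indicator.
oracle_n_smoke_runs <- function(labels) {
  ind <- as.integer(!is.na(labels) & labels == "smoke")
  sum(diff(c(0L, ind)) == 1L)
}

# Weekly compositing: highest density over non-missing days.
oracle_composite <- function(daily) {
  vals <- c(none = 0, low = 5, medium = 16, high = 27)
  obs <- daily[!is.na(daily)]
  if (!length(obs)) return(NA_character_)
  names(which.max(vals[obs]))
}

# random label strings for classifier fuzzing
random_labels <- function(len, na_rate = 0.2) {
  l <- sample(c("smoke", "no_smoke"), len, replace = TRUE,
              prob = c(0.3, 0.7))
  l[stats::runif(len) < na_rate] <- NA_character_
  l
}
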