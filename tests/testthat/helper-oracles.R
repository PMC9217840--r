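# Independent oracles used across tests. Each is a deliberately plain,
# loop-based implementation that shares no code with the package paths it
# checks.

# Barnard Z-pooled p-value by direct enumeration over all tables with the
# observed column totals, maximizing over an explicit nuisance grid.
oracle_barnard <- function(tab, grid_points = 101L) {
  n1 <- sum(tab[, 1]); n2 <- sum(tab[, 2])
  zstat <- function(x1, x2) {
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    if (se == 0) 0 else (p1 - p2) / se
  }
  z_obs <- abs(zstat(tab[1, 1], tab[1, 2]))
  in_region <- matrix(FALSE, n1 + 1, n2 + 1)
  for (x1 in 0:n1) for (x2 in 0:n2)
    in_region[x1 + 1, x2 + 1] <- abs(zstat(x1, x2)) >= z_obs - 1e-12
  best <- 0
  for (g in seq_len(grid_points)) {
    pi <- g / (grid_points + 1)
    d1 <- dbinom(0:n1, n1, pi); d2 <- dbinom(0:n2, n2, pi)
    tot <- 0
    for (x1 in 0:n1) for (x2 in 0:n2)
      if (in_region[x1 + 1, x2 + 1])
        tot <- tot + d1[x1 + 1] * d2[x2 + 1]
    if (tot > best) best <- tot
  }
  min(best, 1)
}

# Two-sided Fisher p by hypergeometric enumeration: sum probabilities of
# all tables (fixed margins) no more probable than the observed one.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) dhyper(a, c1, n - c1, r1), numeric(1))
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kaplan-Meier by the raw product over distinct event times.
oracle_km <- function(time, event, t_eval) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ev_times[ev_times <= t_eval]) {
    d <- sum(time == tt & event == 1)
    r <- sum(time >= tt)
    s <- s * (1 - d / r)
  }
  s
}

# Cox partial log-likelihood (Breslow form; exact when there are no tied
# event times) for a single binary/continuous covariate.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Right-censored Weibull log-likelihood (shape a, scale b, no covariates).
oracle_weibull_loglik <- function(a, b, time, event) {
  sum(event * (log(a / b) + (a - 1) * log(time / b)) - (time / b)^a)
}

# Wilcoxon rank-sum W statistic (matches wilcox.test's statistic) by
# explicit midranks.
oracle_wilcoxon_w <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# small deterministic two-class cohort for quick tests
tiny_cohort <- function(seed = 42, ...) {
  generate_cohort(sim_config(n_probes = 1500, n_dmp = 40, n_genes = 400,
                             seed = seed, ...))
}
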