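#' Validate a contingency table
#'
#' @param counts integer matrix of non-negative counts, at least 2x2, with
#'   a positive grand total.
#' @return the validated matrix.
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0) stop("grand total must be positive")
  counts
}

#' Pearson chi-squared test with the 2x2 continuity-correction convention
#'
#' Yates continuity correction is applied iff the table is 2x2 and
#' `continuity = "auto"` (the convention under which the training-cohort
#' characteristics table reproduces). `df = (r-1)(c-1)`.
#'
#' @param t contingency table (matrix).
#' @param continuity "auto" (Yates on 2x2 only), TRUE or FALSE.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_squared_test <- function(t, continuity = "auto") {
  t <- contingency_table(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("zero row or column margin")
  correct <- if (identical(continuity, "auto"))
    nrow(t) == 2L && ncol(t) == 2L else isTRUE(continuity)
  ht <- suppressWarnings(stats::chisq.test(t, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities no larger than
#' the observed table's.
#'
#' @param t 2x2 contingency table.
#' @return p-value.
#' @export
fisher_exact <- function(t) {
  t <- contingency_table(t)
  if (!all(dim(t) == c(2L, 2L))) stop("fisher_exact requires a 2x2 table")
  stats::fisher.test(t)$p.value
}

# Z-pooled score statistic for all tables with fixed column totals n1, n2;
# returns an (n1+1) x (n2+1) matrix indexed by x1 = 0..n1, x2 = 0..n2
zpooled_grid <- function(n1, n2) {
  x1 <- 0:n1; x2 <- 0:n2
  p1 <- outer(x1 / n1, rep(1, n2 + 1))
  p2 <- outer(rep(1, n1 + 1), x2 / n2)
  pp <- outer(x1, x2, "+") / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  z[!is.finite(z)] <- 0
  z
}

#' Barnard's unconditional exact test (Z-pooled) for a 2x2 table
#'
#' Treats the two column totals as fixed group sizes and the row as the
#' binary outcome. The test statistic is the pooled-variance score Z; the
#' p-value is the maximum, over a grid of nuisance success probabilities
#' pi in (0,1), of the total probability of all tables at least as extreme
#' (|Z| >= |Z_obs|, two-sided).
#'
#' @param t 2x2 table; columns are the two groups (fixed sizes), row 1 the
#'   outcome of interest.
#' @param grid_points number of equally spaced nuisance-grid points in
#'   (0,1) (default 1001).
#' @return list with `p`, `statistic` (observed Z) and `pi_max` (grid
#'   point attaining the maximum).
#' @export
barnard_test <- function(t, grid_points = 1001L) {
  t <- contingency_table(t)
  if (!all(dim(t) == c(2L, 2L))) stop("barnard_test requires a 2x2 table")
  n1 <- sum(t[, 1]); n2 <- sum(t[, 2])
  if (n1 == 0L || n2 == 0L) stop("both group sizes must be positive")
  z <- zpooled_grid(n1, n2)
  z_obs <- z[t[1, 1] + 1L, t[1, 2] + 1L]
  region <- abs(z) >= abs(z_obs) - 1e-12
  grid <- seq_len(grid_points) / (grid_points + 1)
  p_pi <- vapply(grid, function(pi) {
    d1 <- stats::dbinom(0:n1, n1, pi)
    d2 <- stats::dbinom(0:n2, n2, pi)
    sum((d1 %o% d2)[region])
  }, numeric(1))
  i <- which.max(p_pi)
  list(p = max(min(p_pi[i], 1), .Machine$double.xmin),
       statistic = z_obs, pi_max = grid[i])
}

#' Goodman-Kruskal lambda with a bootstrap confidence interval
#'
#' Proportional reduction in error when predicting the column category
#' from the row category: lambda = (sum_k max_j n_kj - max_j n_+j) /
#' (N - max_j n_+j). For predicting rows from columns, pass
#' `direction = "row"` (the table is transposed). The CI is a seeded
#' percentile bootstrap over the underlying pairs.
#'
#' @param t contingency table.
#' @param direction "column" (predict columns from rows, default) or "row".
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `lambda`, `ci95` (length-2 vector) and `undefined`
#'   (TRUE when N equals the max column margin, making lambda undefined).
#' @export
goodman_kruskal_lambda <- function(t, direction = c("column", "row"),
                                   n_boot = 2000L, seed = 1L) {
  direction <- match.arg(direction)
  t <- contingency_table(t)
  if (direction == "row") t <- t(t)
  lam <- function(tab) {
    denom <- sum(tab) - max(colSums(tab))
    if (denom == 0) return(NA_real_)
    (sum(apply(tab, 1L, max)) - max(colSums(tab))) / denom
  }
  l0 <- lam(t)
  if (is.na(l0))
    return(list(lambda = NA_real_, ci95 = c(NA_real_, NA_real_),
                undefined = TRUE))
  # reconstruct pairs and resample
  idx <- which(t > 0, arr.ind = TRUE)
  pairs <- idx[rep(seq_len(nrow(idx)), t[idx]), , drop = FALSE]
  n <- nrow(pairs)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    s <- pairs[sample.int(n, n, replace = TRUE), , drop = FALSE]
    tab <- matrix(0L, nrow(t), ncol(t))
    for (i in seq_len(nrow(s))) tab[s[i, 1], s[i, 2]] <-
        tab[s[i, 1], s[i, 2]] + 1L
    lam(tab)
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lambda = l0, ci95 = ci, undefined = FALSE)
}

#' Intraclass correlation ICC(2,1) for rater agreement
#'
#' Two-way random effects, absolute agreement, single rater, computed from
#' the ANOVA mean squares of the complete-case sample x rater matrix, with
#' the F-based 95% confidence interval of Shrout & Fleiss. Labels must be
#' coded numerically (e.g. SVZ- = 0, SVZ+ = 1).
#'
#' @param r numeric matrix, samples x raters; rows with any NA are dropped.
#' @return list with `icc`, `ci95`, `n` (complete cases), `k` (raters).
#' @export
icc <- function(r) {
  r <- as.matrix(r)
  if (ncol(r) < 2L) stop("need at least 2 raters")
  r <- r[stats::complete.cases(r), , drop = FALSE]
  n <- nrow(r); k <- ncol(r)
  if (n < 2L) stop("need at least 2 complete-case samples")
  grand <- mean(r)
  row_m <- rowMeans(r); col_m <- colMeans(r)
  ss_row <- k * sum((row_m - grand)^2)
  ss_col <- n * sum((col_m - grand)^2)
  ss_tot <- sum((r - grand)^2)
  ss_err <- ss_tot - ss_row - ss_col
  msr <- ss_row / (n - 1)
  msc <- ss_col / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # Shrout-Fleiss F-based CI for ICC(2,1)
  alpha <- 0.05
  a <- k * icc_val / (n * (1 - icc_val))
  b <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc_val, ci95 = c(lower, upper), n = n, k = k)
}

#' Consensus rating across raters
#'
#' A sample has a consensus label iff all its non-missing raters agree;
#' otherwise it is `no_consensus`. Samples with zero ratings are
#' `no_consensus` with a warning.
#'
#' @param r matrix or data.frame of categorical labels, samples x raters
#'   (NA = missing); row names are sample ids.
#' @return list with `consensus` (named character vector, "no_consensus"
#'   where raters disagree) and `consensus_fraction`.
#' @export
consensus_rating <- function(r) {
  r <- as.matrix(r)
  if (ncol(r) < 2L) stop("need at least 2 raters")
  cons <- apply(r, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    if (length(unique(v)) == 1L) v[1] else "no_consensus"
  })
  if (anyNA(cons)) {
    warning(sum(is.na(cons)), " sample(s) with zero ratings")
    cons[is.na(cons)] <- "no_consensus"
  }
  list(consensus = cons,
       consensus_fraction = mean(cons != "no_consensus"))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure at level `q`; returns monotone adjusted values and
#' significance flags.
#'
#' @param p_values numeric vector in [0,1] (NAs allowed, never significant).
#' @param q FDR level.
#' @return list with `adjusted` and `significant`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = !is.na(adj) & adj <= q)
}
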