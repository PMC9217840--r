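#' Log2 counts-per-million transform
#'
#' log2(count / library_total * 1e6 + 1), the transform used for all
#' "transformed-value" expression analyses (DE t-tests, correlations,
#' pathway scores).
#'
#' @param counts gene x sample integer count matrix (totals > 0).
#' @return transformed matrix of the same shape.
#' @export
log_cpm <- function(counts) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("library totals must be positive")
  log2(sweep(counts, 2L, tot, "/") * 1e6 + 1)
}

#' SAM-style moderated test with permutation FDR
#'
#' Per-CpG moderated statistic d_i = (mean_pos - mean_neg) / (s_i + s0),
#' where s_i is the pooled two-sample standard error and the fudge factor
#' s0 is the median of the s_i. Seeded label permutations give the
#' expected order statistics dbar_(i); for a threshold Delta, probes with
#' |d_(i) - dbar_(i)| > Delta are called, the effective cut is the
#' smallest |d| among called probes, and FDR(Delta) is the median over
#' permutations of the number of permuted |d| above the cut divided by the
#' number called. The smallest Delta with FDR <= `fdr_target` is chosen.
#'
#' @param m a `MethylationMatrix` (M-values are tested) or a plain numeric
#'   matrix of values, rows = features.
#' @param labels class labels per sample (two classes, each >= 3 samples).
#' @param n_perm label permutations (default 500; < 50 draws a warning).
#' @param fdr_target target FDR (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param positive positive-class label (default: label sorted last).
#' @return a `SamResult`: list with `d` (named statistic vector), `s0`,
#'   `delta`, `called` (probe ids), `direction` (named, for called
#'   probes: "hypo_in_pos"/"hyper_in_pos"), `fdr` (estimated at the
#'   chosen delta), `table` (per-Delta candidate summary).
#' @export
sam_test <- function(m, labels, n_perm = 500L, fdr_target = 0.05,
                     seed = 1L, positive = NULL) {
  x <- if (inherits(m, "MethylationMatrix")) m_values(m) else as.matrix(m)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  ip <- labels == positive
  if (sum(ip) < 3L || sum(!ip) < 3L)
    stop("each class needs at least 3 samples")
  if (n_perm < 50L) warning("n_perm < 50: FDR estimate will be unstable")
  d_of <- function(mask) {
    n1 <- sum(mask); n2 <- sum(!mask)
    x1 <- x[, mask, drop = FALSE]; x2 <- x[, !mask, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    sp2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / (n1 + n2 - 2)
    s <- sqrt(sp2 * (1 / n1 + 1 / n2))
    list(r = m1 - m2, s = s)
  }
  obs <- d_of(ip)
  s0 <- stats::median(obs$s)
  d <- obs$r / (obs$s + s0)
  names(d) <- rownames(x)
  set.seed(seed)
  n <- ncol(x)
  d_perm_sorted <- matrix(0, n_perm, nrow(x))
  abs_perm_sorted <- matrix(0, n_perm, nrow(x))
  for (b in seq_len(n_perm)) {
    mask <- seq_len(n) %in% sample.int(n, sum(ip))
    pb <- d_of(mask)
    db <- pb$r / (pb$s + s0)
    d_perm_sorted[b, ] <- sort(db)
    abs_perm_sorted[b, ] <- sort(abs(db))
  }
  dbar <- colMeans(d_perm_sorted)
  ord <- order(d)
  diffs <- abs(d[ord] - dbar)
  cand <- sort(unique(signif(diffs, 10)))
  eps <- 1e-12
  best <- NULL
  rows <- list()
  for (delta in cand) {
    called_idx <- ord[diffs >= delta]
    if (!length(called_idx)) { rows[[length(rows) + 1L]] <-
      data.frame(delta = delta, n_called = 0L, fdr = 0); next }
    cut <- min(abs(d[called_idx]))
    exceed <- vapply(seq_len(n_perm), function(b)
      nrow(x) - findInterval(cut - eps, abs_perm_sorted[b, ]),
      numeric(1))
    fdr <- stats::median(exceed) / length(called_idx)
    rows[[length(rows) + 1L]] <-
      data.frame(delta = delta, n_called = length(called_idx), fdr = fdr)
    if (fdr <= fdr_target && is.null(best))
      best <- list(delta = delta, called_idx = called_idx, fdr = fdr)
  }
  tab <- do.call(rbind, rows)
  if (is.null(best))
    best <- list(delta = Inf, called_idx = integer(0), fdr = 0)
  called <- names(d)[best$called_idx]
  direction <- stats::setNames(
    ifelse(d[best$called_idx] < 0, "hypo_in_pos", "hyper_in_pos"), called)
  structure(list(d = d, s0 = s0, delta = best$delta, called = called,
                 direction = direction, fdr = best$fdr, table = tab,
                 positive = positive),
            class = "SamResult")
}

#' @export
print.SamResult <- function(x, ...) {
  cat(sprintf("SamResult: %d called at delta = %.4g (est. FDR %.3f)\n",
              length(x$called), x$delta, x$fdr))
  invisible(x)
}

#' Cross-cohort consensus of SAM-called probes
#'
#' Intersection of the called sets of two cohorts, keeping only probes
#' with concordant direction, with the hypo/hyper split in the positive
#' class reported.
#'
#' @param sam_a,sam_b `SamResult`s over a shared probe universe.
#' @return list with `probes`, `direction` (named), `n_hypo`, `n_hyper`,
#'   `frac_hypo`.
#' @export
consensus_dmp <- function(sam_a, sam_b) {
  if (!length(intersect(names(sam_a$d), names(sam_b$d))))
    stop("the two results share no probes")
  common <- intersect(sam_a$called, sam_b$called)
  conc <- common[sam_a$direction[common] == sam_b$direction[common]]
  dir <- sam_a$direction[conc]
  n_hypo <- sum(dir == "hypo_in_pos")
  list(probes = conc, direction = dir, n_hypo = n_hypo,
       n_hyper = length(conc) - n_hypo,
       frac_hypo = if (length(conc)) n_hypo / length(conc) else NA_real_)
}

#' Differential expression by per-gene Welch t-test on log-CPM
#'
#' @param counts gene x sample count matrix.
#' @param labels class labels per sample.
#' @param fdr BH FDR level for the DEG set (default 0.05).
#' @param positive positive-class label (default: label sorted last).
#' @return data.frame per gene (statistic, p_value, bh_q, direction
#'   "up_in_pos"/"down_in_pos", is_deg, degenerate) plus attributes
#'   `deg_mean_contrast` (mean log-CPM difference pos - neg over the DEG
#'   set) and `n_deg`.
#' @export
differential_expression <- function(counts, labels, fdr = 0.05,
                                    positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  ip <- labels == positive
  lc <- log_cpm(counts)
  tt <- welch_rows(lc, ip, alpha = fdr)
  res <- data.frame(gene = rownames(counts), statistic = tt$statistic,
                    p_value = tt$p_value,
                    direction = ifelse(tt$mean_pos >= tt$mean_neg,
                                       "up_in_pos", "down_in_pos"),
                    degenerate = tt$degenerate,
                    stringsAsFactors = FALSE)
  res$p_value[res$degenerate] <- 1
  bh <- bh_fdr(res$p_value, fdr)
  res$bh_q <- bh$adjusted
  res$is_deg <- bh$significant
  deg <- res$is_deg
  attr(res, "n_deg") <- sum(deg)
  attr(res, "deg_mean_contrast") <- if (any(deg))
    mean(rowMeans(lc[deg, ip, drop = FALSE]) -
           rowMeans(lc[deg, !ip, drop = FALSE])) else NA_real_
  res
}

#' Pearson correlation between CpG methylation and gene expression
#'
#' For each (gene, CpG) pair of the map, Pearson correlation between the
#' CpG M-value and the gene's log-CPM across shared samples, with a
#' two-sided p-value. Pairs with zero variance in either vector get an
#' `undefined` marker.
#'
#' @param m a `MethylationMatrix`.
#' @param counts gene x sample count matrix.
#' @param gene_cpg_map data.frame with columns gene, cpg.
#' @return data.frame: gene, cpg, r, p, n, undefined.
#' @export
meth_expr_correlation <- function(m, counts, gene_cpg_map) {
  shared <- intersect(colnames(m$beta), colnames(counts))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  mm <- m_values(meth_subset(m, samples = shared))
  lc <- log_cpm(counts[, shared, drop = FALSE])
  rows <- lapply(seq_len(nrow(gene_cpg_map)), function(i) {
    g <- gene_cpg_map$gene[i]; cg <- gene_cpg_map$cpg[i]
    if (!g %in% rownames(lc) || !cg %in% rownames(mm)) return(NULL)
    x <- mm[cg, ]; y <- lc[g, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(gene = g, cpg = cg, r = NA_real_, p = NA_real_,
                        n = length(shared), undefined = TRUE))
    ct <- stats::cor.test(x, y)
    data.frame(gene = g, cpg = cg, r = unname(ct$estimate), p = ct$p.value,
               n = length(shared), undefined = FALSE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Rank genes by their number of consensus CpGs
#'
#' Counts consensus CpGs per annotated gene symbol, descending, ties by
#' symbol. CpGs annotated to several (nested/overlapping) genes via a
#' ";"-separated gene field increment each of them; unannotated CpGs are
#' counted under "unannotated".
#'
#' @param probes character vector of consensus CpG ids.
#' @param annotation probe annotation (probe_id, gene).
#' @return data.frame: gene, n_cpgs, ordered.
#' @export
gene_cpg_rank <- function(probes, annotation) {
  if (!length(probes))
    return(data.frame(gene = character(0), n_cpgs = integer(0)))
  g <- annotation$gene[match(probes, annotation$probe_id)]
  g[is.na(g) | g == ""] <- "unannotated"
  parts <- unlist(strsplit(g, ";", fixed = TRUE))
  tb <- table(parts)
  res <- data.frame(gene = names(tb), n_cpgs = as.integer(tb),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_cpgs, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pairwise co-alteration intersection across molecular layers
#'
#' Intersects gene-level calls from methylation (direction hypo/hyper),
#' expression (up/down) and copy number (gain/loss), listing for each
#' layer pair the shared genes with their direction combination (e.g.
#' "hypo_in_pos/up_in_pos" marks the inverse methylation-expression
#' relationship). Genes with a missing direction are excluded with a note.
#'
#' @param meth_genes named character vector: gene -> "hypo_in_pos"/"hyper_in_pos".
#' @param expr_genes named character vector: gene -> "up_in_pos"/"down_in_pos".
#' @param cnv_genes named character vector: gene -> "gain"/"loss".
#' @return list of data.frames `meth_expr`, `expr_cnv`, `meth_cnv`, each
#'   with columns gene, dir_a, dir_b, category.
#' @export
co_alteration_intersect <- function(meth_genes, expr_genes, cnv_genes) {
  clean <- function(v, nm) {
    drop <- is.na(v) | v == ""
    if (any(drop)) message(sum(drop), " ", nm,
                           " gene(s) without direction excluded")
    v[!drop]
  }
  meth_genes <- clean(meth_genes, "methylation")
  expr_genes <- clean(expr_genes, "expression")
  cnv_genes <- clean(cnv_genes, "CNV")
  pair <- function(a, b) {
    g <- intersect(names(a), names(b))
    data.frame(gene = g, dir_a = unname(a[g]), dir_b = unname(b[g]),
               category = paste(unname(a[g]), unname(b[g]), sep = "/"),
               stringsAsFactors = FALSE)
  }
  list(meth_expr = pair(meth_genes, expr_genes),
       expr_cnv = pair(expr_genes, cnv_genes),
       meth_cnv = pair(meth_genes, cnv_genes))
}

#' Negative-binomial expression test with library-size offset
#'
#' Per gene, negative-binomial regression of counts on the class
#' indicator with a log(total counts) offset. The dispersion starts from
#' a method-of-moments estimate and is refined by maximum likelihood
#' (glm.nb); if ML fails, the moments estimate is kept in a fixed-theta
#' GLM. The p-value is one-sided for *decreased* expression in the
#' positive class (configurable via `alternative`).
#'
#' @param counts gene x sample count matrix.
#' @param labels class labels per sample.
#' @param genes genes to test (default: all with a nonzero count).
#' @param positive positive-class label (default: label sorted last).
#' @param alternative "less" (decrease in positive class, default),
#'   "greater", or "two.sided".
#' @return data.frame: gene, coef (log fold-change pos vs neg), se, theta,
#'   p_one_sided.
#' @export
negbin_expression_test <- function(counts, labels, genes = NULL,
                                   positive = NULL,
                                   alternative = c("less", "greater",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  cls <- factor(ifelse(labels == positive, "pos", "neg"),
                levels = c("neg", "pos"))
  off <- log(colSums(counts))
  if (is.null(genes)) genes <- rownames(counts)[rowSums(counts) > 0]
  rows <- lapply(genes, function(g) {
    y <- counts[g, ]
    if (all(y == 0)) return(NULL)  # skipped
    mom_theta <- {
      mu <- mean(y); v <- stats::var(y)
      if (v > mu) mu^2 / (v - mu) else 1e4
    }
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ cls + offset(off))),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- suppressWarnings(
        stats::glm(y ~ cls + offset(off),
                   family = MASS::negative.binomial(theta = mom_theta)))
      theta <- mom_theta
    } else theta <- fit$theta
    co <- summary(fit)$coefficients
    est <- co["clspos", "Estimate"]; se <- co["clspos", "Std. Error"]
    z <- est / se
    p <- switch(alternative,
                less = stats::pnorm(z),
                greater = stats::pnorm(z, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    data.frame(gene = g, coef = est, se = se, theta = theta,
               p_one_sided = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Weighted pathway-activity scores with a group contrast
#'
#' Per-sample pathway score = sum over pathway genes of weight times the
#' z-scored log-CPM of the gene; the two-class contrast is tested with a
#' linear model (two-sided). Pathways with no gene present in the matrix
#' are skipped with a note; all-zero weights give an undefined p marker.
#'
#' @param counts gene x sample count matrix.
#' @param weights data.frame with columns pathway, gene, weight.
#' @param labels class labels per sample.
#' @param positive positive-class label (default: label sorted last).
#' @return list with `scores` (pathway x sample matrix) and `contrast`
#'   (data.frame pathway, estimate, p, n_genes).
#' @export
pathway_activity <- function(counts, weights, labels, positive = NULL) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  cls <- factor(ifelse(labels == positive, "pos", "neg"),
                levels = c("neg", "pos"))
  lc <- log_cpm(counts)
  z <- t(scale(t(lc)))
  z[!is.finite(z)] <- 0
  paths <- unique(weights$pathway)
  scores <- list(); rows <- list()
  for (pw in paths) {
    w <- weights[weights$pathway == pw, , drop = FALSE]
    w <- w[w$gene %in% rownames(z), , drop = FALSE]
    if (nrow(w) == 0L) {
      message("pathway '", pw, "' has no overlapping genes; skipped")
      next
    }
    sc <- colSums(z[w$gene, , drop = FALSE] * w$weight)
    scores[[pw]] <- sc
    if (all(w$weight == 0) || stats::sd(sc) == 0) {
      rows[[pw]] <- data.frame(pathway = pw, estimate = NA_real_,
                               p = NA_real_, n_genes = nrow(w),
                               stringsAsFactors = FALSE)
    } else {
      fit <- summary(stats::lm(sc ~ cls))$coefficients
      rows[[pw]] <- data.frame(pathway = pw,
                               estimate = fit["clspos", "Estimate"],
                               p = fit["clspos", "Pr(>|t|)"],
                               n_genes = nrow(w), stringsAsFactors = FALSE)
    }
  }
  contrast <- do.call(rbind, rows)
  rownames(contrast) <- NULL
  list(scores = if (length(scores)) do.call(rbind, scores) else NULL,
       contrast = contrast)
}
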