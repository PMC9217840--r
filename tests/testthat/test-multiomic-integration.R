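sam_matrix <- function(p, n1, n2, n_sig = 0, delta = 1.5, seed = 1,
                       sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(p * (n1 + n2), 0, sd), p, n1 + n2,
              dimnames = list(sprintf("cg%05d", seq_len(p)),
                              sprintf("S%03d", seq_len(n1 + n2))))
  if (n_sig > 0) x[seq_len(n_sig), seq_len(n1)] <-
      x[seq_len(n_sig), seq_len(n1)] - delta  # hypo in the positive class
  list(x = x, labels = rep(c("SVZM+", "SVZM-"), c(n1, n2)))
}

test_that("SAM calls little on null data and recovers planted effects", {
  d0 <- sam_matrix(2000, 27, 27, seed = 3)
  s0 <- sam_test(d0$x, d0$labels, n_perm = 100, seed = 5,
                 positive = "SVZM+")
  expect_lte(length(s0$called), 2 * 0.05 * 2000)

  d1 <- sam_matrix(2000, 27, 27, n_sig = 100, delta = 1.5, seed = 7)
  s1 <- sam_test(d1$x, d1$labels, n_perm = 100, seed = 9,
                 positive = "SVZM+")
  planted <- sprintf("cg%05d", 1:100)
  expect_gte(sum(s1$called %in% planted), 70)
  expect_true(all(s1$direction[intersect(s1$called, planted)] ==
                    "hypo_in_pos"))
  # false calls stay near the nominal FDR
  expect_lte(sum(!s1$called %in% planted), 0.25 * length(s1$called))
})

test_that("the SAM called set shrinks as delta grows", {
  d <- sam_matrix(500, 10, 10, n_sig = 30, seed = 11)
  s <- sam_test(d$x, d$labels, n_perm = 60, seed = 2, positive = "SVZM+")
  tab <- s$table[order(s$table$delta), ]
  expect_true(all(diff(tab$n_called) <= 0))
  expect_equal(tab$n_called[nrow(tab)] <= 1, TRUE)
  idx <- c(1, 2, 11, 12, 13)  # 2 vs 3 samples
  expect_error(sam_test(d$x[, idx], d$labels[idx], n_perm = 60),
               "at least 3")
})

test_that("cross-cohort consensus keeps concordant calls only", {
  d <- sam_matrix(800, 20, 20, n_sig = 60, delta = 1.8, seed = 13)
  d2 <- sam_matrix(800, 25, 25, n_sig = 60, delta = 1.8, seed = 17)
  s1 <- sam_test(d$x, d$labels, n_perm = 80, seed = 1, positive = "SVZM+")
  s2 <- sam_test(d2$x, d2$labels, n_perm = 80, seed = 2, positive = "SVZM+")
  cons <- consensus_dmp(s1, s2)
  planted <- sprintf("cg%05d", 1:60)
  expect_gte(sum(cons$probes %in% planted), 36)
  expect_lte(sum(!cons$probes %in% planted), 5)
  expect_true(all(cons$probes %in% s1$called) &&
                all(cons$probes %in% s2$called))
  # idempotence
  self <- consensus_dmp(s1, s1)
  expect_setequal(self$probes, s1$called)
  # discordant directions are excluded
  s2_flip <- s2
  s2_flip$direction[] <- ifelse(s2$direction == "hypo_in_pos",
                                "hyper_in_pos", "hypo_in_pos")
  expect_length(consensus_dmp(s1, s2_flip)$probes, 0)
})

test_that("differential expression recovers planted fold changes", {
  set.seed(19)
  n <- 100; g <- 400
  counts <- matrix(rnbinom(g * n, mu = 150, size = 10), g, n,
                   dimnames = list(sprintf("EXP%04d", 1:g),
                                   sprintf("S%03d", 1:n)))
  labels <- rep(c("SVZM+", "SVZM-"), each = n / 2)
  counts[1:40, labels == "SVZM+"] <-
    matrix(rnbinom(40 * n / 2, mu = 300, size = 10), 40)
  de <- differential_expression(counts, labels, positive = "SVZM+")
  expect_gte(mean(de$is_deg[1:40]), 0.8)
  expect_true(all(de$direction[1:40][de$is_deg[1:40]] == "up_in_pos"))
  expect_gt(attr(de, "deg_mean_contrast"), 0)
  # permuted labels: about 5% raw positives
  perm <- sample(labels)
  de0 <- differential_expression(counts, perm, positive = "SVZM+")
  expect_lt(mean(de0$p_value < 0.05), 0.12)
  # no DEGs: attributes degrade cleanly
  if (!any(de0$is_deg)) expect_true(is.na(attr(de0, "deg_mean_contrast")))
})

test_that("methylation-expression correlation behaves at its extremes", {
  set.seed(23)
  n <- 47
  m_vals <- matrix(rnorm(2 * n), 2, n,
                   dimnames = list(c("cg1", "cg2"), sprintf("S%02d", 1:n)))
  beta <- m_to_beta(m_vals)
  mm <- meth_matrix(beta)
  # counts engineered so log-CPM is (nearly) exactly linear in -M
  tot <- 1e8
  c1 <- round(2^(-m_vals[1, ] + 12))
  counts <- rbind(GENE1 = c1, FILL = tot - c1)
  mer <- meth_expr_correlation(mm, counts,
                               data.frame(gene = "GENE1", cpg = "cg1"))
  expect_lt(mer$r, -0.999)
  expect_lt(mer$p, 1e-10)
  # zero variance: undefined marker
  mm2 <- meth_matrix(matrix(0.5, 1, n,
                            dimnames = list("cgc", colnames(beta))))
  mer2 <- meth_expr_correlation(mm2, counts,
                                data.frame(gene = "GENE1", cpg = "cgc"))
  expect_true(mer2$undefined)
})

test_that("independent pairs rarely exceed the null |r| bound at n = 47", {
  set.seed(29)
  hits <- 0; reps <- 200
  for (i in seq_len(reps)) {
    if (abs(cor(rnorm(47), rnorm(47))) < 0.29) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("coupled synthetic genes recover the configured correlation", {
  b <- generate_cohort(sim_config(n_pos = 24, n_neg = 23, n_probes = 1000,
                                  n_dmp = 30, coupling_rho = -0.76,
                                  seed = 31))
  mer <- meth_expr_correlation(b$methylation, b$expression$counts,
                               b$expression$gene_cpg_map)
  expect_true(mean(mer$r) > -0.9 && mean(mer$r) < -0.6)
})

test_that("gene-level CpG ranking honours nested pairs and buckets", {
  ann <- data.frame(probe_id = sprintf("cg%02d", 1:12),
                    gene = c(rep("MABL_pair;MABL_pairb", 3),
                             rep("GENEA", 9 - 3), rep("", 3)),
                    stringsAsFactors = FALSE)
  # 9 CpGs of one gene top the ranking
  rk <- gene_cpg_rank(sprintf("cg%02d", 1:12), ann)
  expect_equal(rk$gene[1], "GENEA")
  expect_equal(rk$n_cpgs[1], 6)
  # nested pair: both genes incremented by the shared CpGs
  expect_equal(rk$n_cpgs[rk$gene == "MABL_pair"], 3)
  expect_equal(rk$n_cpgs[rk$gene == "MABL_pairb"], 3)
  expect_equal(rk$n_cpgs[rk$gene == "unannotated"], 3)
  expect_equal(nrow(gene_cpg_rank(character(0), ann)), 0)
  one <- gene_cpg_rank(sprintf("cg%02d", 4:12), ann)
  expect_equal(one$gene[1], "GENEA")
  expect_equal(one$n_cpgs[1], 6)
})

test_that("co-alteration intersections categorize direction combinations", {
  meth <- c(A = "hypo_in_pos", B = "hyper_in_pos", C = "hypo_in_pos")
  expr <- c(A = "up_in_pos", C = "down_in_pos", D = "up_in_pos")
  cnv <- c(A = "loss", E = "gain")
  res <- co_alteration_intersect(meth, expr, cnv)
  expect_setequal(res$meth_expr$gene, c("A", "C"))
  expect_equal(res$meth_expr$category[res$meth_expr$gene == "A"],
               "hypo_in_pos/up_in_pos")
  # gene in all three layers appears in all three tables
  expect_true(all(vapply(res, function(t) "A" %in% t$gene, logical(1))))
  # disjoint sets: empty intersections
  res0 <- co_alteration_intersect(c(X = "hypo_in_pos"),
                                  c(Y = "up_in_pos"), c(Z = "gain"))
  expect_true(all(vapply(res0, nrow, integer(1)) == 0))
})

test_that("negative-binomial test is offset-invariant and finds reductions", {
  set.seed(37)
  n <- 47
  labels <- rep(c("SVZM+", "SVZM-"), c(23, 24))
  mu <- ifelse(labels == "SVZM+", 100, 200)
  counts <- rbind(LRBA_like = rnbinom(n, mu = mu, size = 8),
                  FLAT = rnbinom(n, mu = 150, size = 8))
  colnames(counts) <- sprintf("S%02d", 1:n)
  res <- negbin_expression_test(counts, labels, positive = "SVZM+")
  expect_lt(res$p_one_sided[res$gene == "LRBA_like"], 0.05)
  expect_lt(res$coef[res$gene == "LRBA_like"], 0)
  # doubling every library leaves the class coefficient unchanged
  res2 <- negbin_expression_test(rbind(counts, PAD = colSums(counts)),
                                 labels, genes = c("LRBA_like", "FLAT"),
                                 positive = "SVZM+")
  expect_equal(res2$coef, res$coef, tolerance = 1e-6)
  # all-zero genes are skipped
  res3 <- negbin_expression_test(rbind(counts, ZERO = 0L), labels,
                                 positive = "SVZM+")
  expect_false("ZERO" %in% res3$gene)
})

test_that("null negative-binomial p-values average near one half", {
  set.seed(41)
  n <- 47; g <- 100
  counts <- matrix(rnbinom(g * n, mu = 150, size = 10), g, n,
                   dimnames = list(sprintf("N%03d", 1:g),
                                   sprintf("S%02d", 1:n)))
  labels <- rep(c("SVZM+", "SVZM-"), c(23, 24))
  res <- negbin_expression_test(counts, labels, positive = "SVZM+")
  expect_lt(abs(mean(res$p_one_sided) - 0.5), 0.1)
})

test_that("pathway scores are weighted z-sums with a sane group contrast", {
  set.seed(43)
  n <- 40; g <- 60
  labels <- rep(c("SVZM+", "SVZM-"), each = n / 2)
  counts <- matrix(rnbinom(g * n, mu = 200, size = 10), g, n,
                   dimnames = list(sprintf("PG%02d", 1:g),
                                   sprintf("S%02d", 1:n)))
  # planted coherent upregulation of a 10-gene pathway in the positives
  counts[1:10, labels == "SVZM+"] <-
    matrix(rnbinom(10 * n / 2, mu = 330, size = 10), 10)
  w <- rbind(data.frame(pathway = "planted", gene = sprintf("PG%02d", 1:10),
                        weight = 1),
             data.frame(pathway = "zero", gene = sprintf("PG%02d", 11:20),
                        weight = 0),
             data.frame(pathway = "onegene", gene = "PG30", weight = 1),
             data.frame(pathway = "absent", gene = "NOPE", weight = 1))
  res <- suppressMessages(pathway_activity(counts, w, labels,
                                           positive = "SVZM+"))
  ct <- res$contrast
  expect_lt(ct$p[ct$pathway == "planted"], 0.05)
  expect_gt(ct$estimate[ct$pathway == "planted"], 0)
  # all-zero weights: zero scores, undefined p
  expect_true(all(res$scores["zero", ] == 0))
  expect_true(is.na(ct$p[ct$pathway == "zero"]))
  # single gene with weight 1: score equals that gene's z-scored log-CPM
  lc <- log_cpm(counts)
  z30 <- as.numeric(scale(lc["PG30", ]))
  expect_equal(unname(res$scores["onegene", ]), z30, tolerance = 1e-12)
  expect_false("absent" %in% ct$pathway)
})
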