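calls_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "gene", "pipeline_id", "variant_class")
  df
}

test_that("silent calls are removed and everything else preserved", {
  cl <- calls_df(sprintf("S%02d", 1:10), "G1", "P1",
                 c(rep("silent", 3), rep("missense", 7)))
  out <- filter_silent(cl)
  expect_equal(nrow(out), 7)
  expect_true(all(out$variant_class == "missense"))
  # no silent: identity (modulo the derived silent column)
  cl2 <- calls_df("S01", "G1", "P1", "nonsense")
  expect_equal(nrow(filter_silent(cl2)), 1)
  expect_error(mutation_calls(calls_df("S01", "G1", "P1", "weird")),
               "unknown variant_class")
})

test_that("pipeline consensus applies the >= min_pipelines rule", {
  pls <- paste0("P", 1:4)
  cl <- rbind(calls_df("S01", "G1", pls, "missense"),        # 4/4
              calls_df("S02", "G1", pls[1:2], "missense"),   # 2/4
              calls_df("S03", "G1", pls[1:3], "silent"))     # silent only
  cons <- pipeline_consensus(cl, pls, min_pipelines = 3)
  expect_true(cons$mutated[cons$sample_id == "S01"])
  expect_equal(cons$n_pipelines[cons$sample_id == "S01"], 4)
  expect_false(cons$mutated[cons$sample_id == "S02"])
  # sample mutated only silently counts as unmutated
  expect_false("S03" %in% cons$sample_id[cons$mutated])
  expect_error(pipeline_consensus(cl, pls[1:2]), "unknown pipeline")
  expect_error(pipeline_consensus(cl, pls, min_pipelines = 5), "exceeds")
})

test_that("consensus sensitivity matches the binomial closed form", {
  set.seed(3)
  n_mut <- 1000; sens <- 0.9
  det <- matrix(runif(n_mut * 4) < sens, n_mut, 4)
  recs <- which(det, arr.ind = TRUE)
  cl <- calls_df(sprintf("S%04d", recs[, 1]), "G1",
                 paste0("P", recs[, 2]), "missense")
  cons <- pipeline_consensus(cl, paste0("P", 1:4), min_pipelines = 3,
                             samples = sprintf("S%04d", 1:n_mut))
  emp <- sum(cons$mutated) / n_mut
  theo <- pbinom(2, 4, 0.9, lower.tail = FALSE)
  expect_equal(theo, 0.9477, tolerance = 1e-4)
  expect_lt(abs(emp - theo), 0.03)
})

test_that("per-gene enrichment flags exclusivity and planted differences", {
  b <- generate_cohort(sim_config(n_pos = 50, n_neg = 50, n_probes = 200,
                                  n_dmp = 5, n_genes = 50, seed = 17))
  pls <- sort(unique(b$mutations$pipeline_id))
  cons <- pipeline_consensus(b$mutations, pls,
                             samples = b$samples$sample_id)
  enr <- per_gene_enrichment(cons, b$truth$labels, grid_points = 201)
  # MUT01 planted 35% vs 5%: significant, directed to the positive class
  m1 <- enr[enr$gene == "MUT01", ]
  expect_lt(m1$barnard_p, 0.01)
  expect_equal(m1$direction, "SVZM+")
  # MUT03 planted exclusive to SVZM+
  m3 <- enr[enr$gene == "MUT03", ]
  expect_true(m3$exclusive)
  expect_equal(m3$n_neg, 0)
  # flat genes mostly non-significant
  flat <- enr[!enr$gene %in% c("MUT01", "MUT02", "MUT03"), ]
  expect_gte(mean(flat$barnard_p > 0.05), 0.8)
  # direction flips when labels are swapped
  swapped <- ifelse(b$truth$labels == "SVZM+", "SVZM-", "SVZM+")
  names(swapped) <- names(b$truth$labels)
  enr2 <- per_gene_enrichment(cons, swapped, grid_points = 201)
  m1s <- enr2[enr2$gene == "MUT01", ]
  expect_equal(m1s$direction, "other")
  expect_equal(m1s$barnard_p, m1$barnard_p, tolerance = 1e-9)
})

test_that("equal mutation frequencies give a null Barnard p", {
  cl <- rbind(calls_df(sprintf("A%02d", 1:5), "G1", "P1", "missense"),
              calls_df(sprintf("B%02d", 1:5), "G1", "P1", "missense"))
  samples <- c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10))
  cons <- pipeline_consensus(cl, "P1", min_pipelines = 1, samples = samples)
  labels <- setNames(rep(c("SVZM+", "SVZM-"), each = 10), samples)
  enr <- per_gene_enrichment(cons, labels, grid_points = 201)
  expect_gt(enr$barnard_p, 0.9)
})

test_that("mutation burden uses Wilcoxon ranks correctly", {
  # identical distributions: p near 1
  samples <- sprintf("S%02d", 1:12)
  labels <- setNames(rep(c("SVZM+", "SVZM-"), each = 6), samples)
  cl <- calls_df(rep(samples, each = 2), rep(c("G1", "G2"), 12), "P1",
                 "missense")
  cons <- pipeline_consensus(cl, "P1", min_pipelines = 1, samples = samples)
  expect_warning(res <- mutation_burden_test(cons, labels), "tied")
  expect_equal(res$p, 1)

  # one class strictly larger, all counts distinct: minimal attainable p
  genes <- sprintf("G%02d", 1:12)
  cl2 <- do.call(rbind, lapply(seq_len(12), function(i)
    calls_df(samples[i],
             genes[seq_len(if (i <= 6) i + 6 else i - 6)],
             "P1", "missense")))
  cons2 <- pipeline_consensus(cl2, "P1", min_pipelines = 1,
                              samples = samples)
  res2 <- mutation_burden_test(cons2, labels)
  expect_equal(res2$p, 2 / choose(12, 6), tolerance = 1e-9)
  # statistic equals the brute-force rank computation
  cnt <- res2$counts
  expect_equal(res2$statistic,
               oracle_wilcoxon_w(cnt[samples[1:6]], cnt[samples[7:12]]))
})

test_that("type x class interaction finds a planted frameshift excess", {
  set.seed(23)
  n <- 60
  samples <- sprintf("S%03d", 1:n)
  labels <- setNames(rep(c("SVZM+", "SVZM-"), each = n / 2), samples)
  pls <- paste0("P", 1:4)
  mk <- function(type, rate_pos, rate_neg) {
    out <- list()
    for (s in samples) {
      rate <- if (labels[s] == "SVZM+") rate_pos else rate_neg
      k <- rpois(1, rate)
      if (k == 0) next
      for (p in pls)
        out[[length(out) + 1L]] <-
          calls_df(s, sprintf("G%03d", sample(50, k)), p, type)
    }
    do.call(rbind, out)
  }
  cl <- rbind(mk("missense", 2, 2), mk("frameshift_del", 3, 1))
  # identical per-pipeline sensitivity can make the random effect singular
  res <- suppressWarnings(mutation_type_interaction(cl, labels))
  fs <- res[res$type == "frameshift_del", ]
  expect_true(fs$significant)
  expect_gt(fs$estimate, 0)
  ms <- res[res$type == "missense", ]
  expect_false(ms$significant)
})

test_that("identical pipelines with no class effect give a null interaction", {
  set.seed(29)
  n <- 40
  samples <- sprintf("S%03d", 1:n)
  labels <- setNames(rep(c("SVZM+", "SVZM-"), each = n / 2), samples)
  cl <- do.call(rbind, lapply(paste0("P", 1:4), function(p)
    calls_df(samples, "G1", p, "missense")))
  res <- suppressWarnings(mutation_type_interaction(cl, labels))
  expect_true(all(abs(res$estimate) < 0.2))
  expect_false(any(res$significant))
})
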