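two_group_mm <- function(p_noise, p_signal, n1, n2, delta = 2, seed = 1,
                         sd = 0.4) {
  set.seed(seed)
  p <- p_noise + p_signal
  m <- matrix(rnorm(p * (n1 + n2), 0, sd), p, n1 + n2)
  if (p_signal > 0)
    m[seq_len(p_signal), seq_len(n1)] <-
      m[seq_len(p_signal), seq_len(n1)] + delta
  rownames(m) <- sprintf("cg%03d", seq_len(p))
  colnames(m) <- sprintf("S%03d", seq_len(n1 + n2))
  list(m = meth_matrix(m_to_beta(m)),
       labels = rep(c("SVZM+", "SVZM-"), c(n1, n2)))
}

test_that("differential methylation detects a planted 2-M-unit shift", {
  d <- two_group_mm(100, 20, 24, 30, delta = 2, seed = 11)
  res <- differential_methylation(d$m, d$labels, positive = "SVZM+")
  expect_true(all(res$p_value[seq_len(20)] < 0.001))
  expect_true(all(res$is_dmp[seq_len(20)]))
  expect_true(all(res$direction[seq_len(20)] == "hyper_in_pos"))
})

test_that("null probes give a calibrated type-I rate at alpha 0.001", {
  set.seed(21)
  p <- 10000; n <- 60
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("cg%05d", 1:p), sprintf("S%03d", 1:n)))
  res <- differential_methylation(meth_matrix(m_to_beta(m / 4)),
                                  rep(c("A", "B"), each = n / 2),
                                  alpha = 0.001)
  frac <- mean(res$p_value < 0.001)
  expect_lt(abs(frac - 0.001), 3 * sqrt(0.001 * 0.999 / p) + 1e-4)
})

test_that("degenerate zero-variance probes are flagged with p = 1", {
  b <- matrix(0.5, 2, 4, dimnames = list(c("cg1", "cg2"), paste0("S", 1:4)))
  b[2, ] <- c(0.2, 0.3, 0.2, 0.3)
  res <- differential_methylation(meth_matrix(b), c("A", "A", "B", "B"),
                                  positive = "B")
  expect_true(res$degenerate[1])
  expect_equal(res$p_value[1], 1)
  expect_error(differential_methylation(meth_matrix(b), c("A", "B", "B", "B")),
               "at least 2 samples")
})

test_that("alpha = 1 makes every probe a DMP", {
  d <- two_group_mm(30, 5, 10, 10, seed = 2)
  res <- differential_methylation(d$m, d$labels, alpha = 1 + 1e-9)
  expect_true(all(res$is_dmp))
})

test_that("stability pruning keeps a perfectly separating probe set", {
  d <- two_group_mm(0, 20, 15, 15, delta = 3, seed = 5, sd = 0.2)
  st <- stability_subset(d$m, d$labels)
  expect_equal(st$error, 0)
  expect_length(st$dropped, 0)
  expect_equal(st$probes, rownames(d$m$beta))
})

test_that("stability pruning removes label-scrambled decoy probes", {
  set.seed(33)
  n1 <- 20; n2 <- 20; n <- n1 + n2
  p_sig <- 40; p_dec <- 10
  sig <- matrix(rnorm(p_sig * n, 0, 0.3), p_sig, n)
  sig[, 1:n1] <- sig[, 1:n1] + 2
  # each decoy strongly separates its own random half of the samples,
  # actively misleading the clustering until enough decoys are pruned
  dec <- matrix(rnorm(p_dec * n, 0, 0.3), p_dec, n)
  for (j in seq_len(p_dec)) {
    scram <- sample(n, n / 2)
    dec[j, scram] <- dec[j, scram] + 10
  }
  m <- rbind(sig, dec)
  rownames(m) <- c(sprintf("sig%02d", 1:p_sig), sprintf("dec%02d", 1:p_dec))
  colnames(m) <- sprintf("S%03d", 1:n)
  labels <- rep(c("SVZM+", "SVZM-"), c(n1, n2))
  err2 <- function(mm) {
    cl <- cutree(hclust(dist(t(mm)), "complete"), 2)
    e <- sum((cl == 1) != (labels == "SVZM+"))
    min(e, length(labels) - e)
  }
  st <- stability_subset(meth_matrix(m_to_beta(m / 5)), labels)
  expect_gte(sum(grepl("^dec", st$dropped)), ceiling(p_dec / 2))
  expect_equal(sum(grepl("^sig", st$dropped)), 0)
  expect_lt(st$error, err2(m / 5))
  expect_equal(st$error, 0)
})

test_that("a single-probe input is returned unchanged with a warning", {
  d <- two_group_mm(0, 1, 5, 5, seed = 1)
  expect_warning(st <- stability_subset(d$m, d$labels), "fewer than 2")
  expect_equal(st$probes, rownames(d$m$beta))
})

test_that("random forest ranks the informative probe first, reproducibly", {
  d <- two_group_mm(10, 1, 20, 20, delta = 2.5, seed = 7)
  r1 <- rf_rank(d$m, d$labels, n_trees = 500, seed = 99)
  expect_equal(r1$probe_id[1], "cg001")
  r2 <- rf_rank(d$m, d$labels, n_trees = 500, seed = 99)
  expect_identical(r1, r2)
  expect_error(rf_rank(d$m, d$labels, n_trees = 0), "n_trees")
})

test_that("constant probes get zero importance and id-ordered ranks", {
  b <- matrix(0.4, 5, 10,
              dimnames = list(sprintf("cg%03d", 5:1), sprintf("S%02d", 1:10)))
  r <- rf_rank(meth_matrix(b), rep(c("A", "B"), 5), n_trees = 50, seed = 1)
  expect_true(all(r$importance == 0))
  expect_equal(r$probe_id, sort(rownames(b)))
})

test_that("signature selection takes top-k and orients by MRI majority", {
  d <- two_group_mm(50, 30, 24, 30, delta = 2, seed = 13)
  rk <- rf_rank(d$m, d$labels, n_trees = 300, seed = 3)
  sig <- select_signature(rk, d$m, d$labels, k = 15)
  expect_length(sig$probes, 15)
  expect_equal(sig$probes, rk$probe_id[1:15])
  expect_setequal(sig$orientation, c("SVZM+", "SVZM-"))
  expect_equal(dim(sig$centroids), c(2L, 15L))
  # positive-class centroid is higher on hyper-in-pos signal probes
  sig_signal <- intersect(sig$probes, sprintf("cg%03d", 1:30))
  expect_true(all(sig$centroids["SVZM+", sig_signal] >
                    sig$centroids["SVZM-", sig_signal]))
  # k = full ranking: identity
  sig_all <- select_signature(rk, d$m, d$labels, k = nrow(rk))
  expect_equal(sig_all$probes, rk$probe_id)
  expect_error(select_signature(rk, d$m, d$labels, k = nrow(rk) + 1), "k")
})

test_that("signature gene counts surface multi-CpG genes", {
  d <- two_group_mm(0, 15, 10, 10, seed = 3)
  rk <- rf_rank(d$m, d$labels, n_trees = 100, seed = 1)
  sig <- select_signature(rk, d$m, d$labels, k = 15)
  ann <- d$m$annotation
  ann$gene <- c(rep("LRBA_like", 5), rep("", 10))[match(ann$probe_id,
                                                    sprintf("cg%03d", 1:15))]
  counts <- signature_gene_counts(sig, ann)
  expect_equal(counts$n_cpgs[counts$gene == "LRBA_like"], 5)
})

test_that("centroid mode reproduces training cluster labels exactly", {
  d <- two_group_mm(20, 20, 24, 30, delta = 2, seed = 17)
  rk <- rf_rank(d$m, d$labels, n_trees = 300, seed = 5)
  sig <- select_signature(rk, d$m, d$labels, k = 15)
  lab <- classify_svzm(d$m, sig, "centroid")
  expect_equal(lab, sig$train_labels[names(lab)])
})

test_that("validation clustering recovers planted truth at strong effect", {
  b <- generate_cohort(sim_config(n_pos = 24, n_neg = 30, n_probes = 2000,
                                  n_dmp = 60, effect_delta = 2, seed = 21))
  disc <- discover_signature(b$methylation, b$truth$labels, seed = 2)
  v <- generate_cohort(sim_config(n_pos = 50, n_neg = 50, n_probes = 2000,
                                  n_dmp = 60, effect_delta = 2, seed = 22),
                       template = b, sample_prefix = "V")
  lab <- classify_svzm(v$methylation, disc$signature,
                       "validation_clustering")
  expect_gte(mean(lab == v$truth$labels[names(lab)]), 0.9)
  # identical samples get identical labels
  m2 <- v$methylation
  m2$beta[, 2] <- m2$beta[, 1]
  lab2 <- classify_svzm(m2, disc$signature, "validation_clustering")
  expect_equal(unname(lab2[1]), unname(lab2[2]))
})

test_that("classification is invariant to sample and probe order", {
  b <- generate_cohort(sim_config(n_pos = 20, n_neg = 20, n_probes = 800,
                                  n_dmp = 40, effect_delta = 2, seed = 31))
  disc <- discover_signature(b$methylation, b$truth$labels, seed = 4)
  lab <- classify_svzm(b$methylation, disc$signature, "centroid")
  perm_s <- sample(ncol(b$methylation$beta))
  perm_p <- sample(nrow(b$methylation$beta))
  m2 <- meth_matrix(b$methylation$beta[perm_p, perm_s],
                    b$methylation$annotation)
  lab2 <- classify_svzm(m2, disc$signature, "centroid")
  expect_equal(lab2[names(lab)], lab)
  # missing signature probes are reported by id
  m3 <- meth_subset(b$methylation,
                    probes = setdiff(rownames(b$methylation$beta),
                                     disc$signature$probes[1]))
  expect_error(classify_svzm(m3, disc$signature, "centroid"),
               disc$signature$probes[1], fixed = TRUE)
})

test_that("the signature model serializes losslessly to JSON", {
  d <- two_group_mm(10, 10, 12, 12, seed = 9)
  rk <- rf_rank(d$m, d$labels, n_trees = 100, seed = 2)
  sig <- select_signature(rk, d$m, d$labels, k = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(sig, path)
  sig2 <- read_signature_json(path)
  expect_equal(sig2$probes, sig$probes)
  expect_equal(sig2$centroids, sig$centroids, tolerance = 1e-12)
  lab1 <- classify_svzm(d$m, sig, "centroid")
  lab2 <- classify_svzm(d$m, sig2, "centroid")
  expect_equal(lab1, lab2)
})
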