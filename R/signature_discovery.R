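#' Per-CpG differential methylation between two classes
#'
#' Welch two-sample t-test on M-values, probe by probe. A probe is a DMP if
#' its p-value falls below `alpha` (default 0.001). Probes with zero
#' variance in both groups are flagged degenerate; their statistic is
#' computed with a pooled epsilon standard error and their p-value is 1
#' when the group means coincide.
#'
#' @param m a `MethylationMatrix`.
#' @param labels vector of class labels per sample (two classes).
#' @param alpha DMP p-value threshold.
#' @param positive label treated as the positive (SVZM+) class; defaults to
#'   the label sorted last, so that "SVZM+" beats "SVZM-".
#' @return data.frame with columns probe_id, mean_pos, mean_neg, statistic,
#'   df, p_value, direction ("hypo_in_pos"/"hyper_in_pos"), degenerate and
#'   is_dmp; one row per probe, in probe order.
#' @export
differential_methylation <- function(m, labels, alpha = 0.001,
                                     positive = NULL) {
  stopifnot(inherits(m, "MethylationMatrix"))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- lv[2L]
  if (!positive %in% lv) stop("positive label not present in labels")
  ip <- labels == positive
  if (sum(ip) < 2L || sum(!ip) < 2L)
    stop("each class needs at least 2 samples")
  mm <- m_values(m)
  welch_rows(mm, ip, alpha = alpha)
}

# vectorized Welch t over matrix rows; ip = logical positive-class mask
welch_rows <- function(mm, ip, alpha = 0.001, eps = 1e-8) {
  n1 <- sum(ip); n2 <- sum(!ip)
  x1 <- mm[, ip, drop = FALSE]; x2 <- mm[, !ip, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  degen <- v1 <= 0 & v2 <= 0
  se2 <- v1 / n1 + v2 / n2
  se2[degen] <- eps^2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[degen] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(stat), df)
  p[degen & m1 == m2] <- 1
  data.frame(probe_id = rownames(mm), mean_pos = m1, mean_neg = m2,
             statistic = stat, df = df, p_value = p,
             direction = ifelse(m1 < m2, "hypo_in_pos", "hyper_in_pos"),
             degenerate = degen, is_dmp = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

# 2-cluster misclassification of hierarchical clustering vs labels,
# with clusters mapped to labels by majority (best of the 2 mappings)
hcl_error <- function(d, labels, method = "complete") {
  cl <- stats::cutree(stats::hclust(d, method = method), k = 2L)
  lv <- sort(unique(labels))
  e1 <- sum((cl == 1L) != (labels == lv[1L]))
  min(e1, length(labels) - e1)
}

#' Clustering-stability probe pruning
#'
#' Greedy leave-one-probe-out pruning of a DMP set. At each step the
#' samples are 2-cluster hierarchically clustered (Euclidean distance,
#' complete linkage) on M-values with each single probe left out, and the
#' probe whose removal yields the lowest misclassification count against
#' the MRI labels (clusters mapped to labels by majority) is dropped,
#' provided its removal does not increase the current error. Among probes
#' tied for the lowest post-removal error, the least label-discriminative
#' probe (smallest |Welch t| on M-values) is dropped, so uninformative or
#' label-scrambled probes leave first. Pruning stops as soon as the
#' clustering classifies perfectly (error 0: every remaining probe is
#' kept), when every possible removal would strictly increase the error,
#' or when fewer than 2 probes would remain.
#'
#' @param m a `MethylationMatrix` restricted to DMP probes.
#' @param labels MRI class labels per sample (two classes).
#' @return list with `probes` (surviving probe ids), `error` (final
#'   misclassification count) and `dropped` (ids in drop order).
#' @export
stability_subset <- function(m, labels) {
  stopifnot(inherits(m, "MethylationMatrix"))
  labels <- as.character(labels)
  mm <- m_values(m)
  ids <- rownames(mm)
  if (length(ids) < 2L) {
    warning("fewer than 2 probes; returning input unchanged")
    return(list(probes = ids, error = NA_integer_, dropped = character(0)))
  }
  ip <- labels == sort(unique(labels))[2L]
  abs_t <- abs(welch_rows(mm, ip)$statistic)
  names(abs_t) <- ids
  dropped <- character(0)
  # squared-distance decomposition: leaving out probe j subtracts its
  # per-pair contribution from the full squared distance matrix
  repeat {
    p <- nrow(mm)
    d_full <- stats::dist(t(mm))
    err_now <- hcl_error(d_full, labels)
    if (p <= 2L || err_now == 0L) break
    d2 <- as.matrix(d_full)^2
    errs <- vapply(seq_len(p), function(j) {
      contrib <- outer(mm[j, ], mm[j, ], "-")^2
      hcl_error(stats::as.dist(sqrt(pmax(d2 - contrib, 0))), labels)
    }, integer(1))
    best_err <- min(errs)
    if (best_err > err_now) break
    cand <- which(errs == best_err)
    best_j <- cand[which.min(abs_t[rownames(mm)[cand]])]
    dropped <- c(dropped, rownames(mm)[best_j])
    mm <- mm[-best_j, , drop = FALSE]
  }
  list(probes = rownames(mm), error = hcl_error(stats::dist(t(mm)), labels),
       dropped = dropped)
}

#' Rank CpGs by random-forest importance
#'
#' Trains a random-forest classifier (samples x probes, M-values) against
#' the class labels and returns probes ordered by mean decrease in Gini
#' impurity, descending, with ties broken by probe id. Deterministic for a
#' fixed seed.
#'
#' @param m a `MethylationMatrix`.
#' @param labels class labels per sample (two classes, both present).
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed (required for reproducibility).
#' @return data.frame with columns probe_id and importance, ordered by
#'   decreasing importance.
#' @export
rf_rank <- function(m, labels, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(m, "MethylationMatrix"))
  if (n_trees < 1L) stop("n_trees must be >= 1")
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2L) stop("labels must contain exactly two classes")
  if (nrow(m$beta) < 2L) stop("need at least 2 probes")
  mm <- m_values(m)
  if (all(apply(mm, 1L, stats::var) == 0)) {
    # nothing to split on: every probe is constant across samples
    return(data.frame(probe_id = sort(rownames(mm)),
                      importance = 0, stringsAsFactors = FALSE))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x = t(mm), y = labels, ntree = n_trees)
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  data.frame(probe_id = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Select the k-CpG signature and fit the training clustering
#'
#' Takes the top-k probes of a random-forest ranking, 2-cluster
#' hierarchically clusters the training samples over these probes
#' (Euclidean distance, complete linkage, M-values), orients the two
#' clusters by MRI majority (the cluster with the larger fraction of
#' MRI-positive samples becomes SVZM+), and stores the per-cluster
#' centroids (mean M-vector) for classifying new cohorts.
#'
#' @param ranked data.frame from [rf_rank()].
#' @param m training `MethylationMatrix` (must contain the ranked probes).
#' @param mri_labels MRI class labels of the training samples.
#' @param k signature size (default 15).
#' @param positive MRI label treated as positive (default "SVZM+" if
#'   present, else the label sorted last).
#' @return a `SignatureModel`: list with `probes`, `importance`,
#'   `linkage_spec`, `centroids` (2 x k matrix, rows SVZM+ / SVZM-),
#'   `orientation` (cluster index -> label) and `train_labels`.
#' @export
select_signature <- function(ranked, m, mri_labels, k = 15L,
                             positive = NULL) {
  if (k < 1L || k > nrow(ranked))
    stop(sprintf("k must be in [1, %d]", nrow(ranked)))
  mri_labels <- as.character(mri_labels)
  lv <- sort(unique(mri_labels))
  if (is.null(positive))
    positive <- if ("SVZM+" %in% lv) "SVZM+" else lv[length(lv)]
  sig <- ranked$probe_id[seq_len(k)]
  mm <- m_values(meth_subset(m, probes = sig))
  cl <- stats::cutree(stats::hclust(stats::dist(t(mm)), "complete"), k = 2L)
  frac_pos <- vapply(1:2, function(g)
    mean(mri_labels[cl == g] == positive), numeric(1))
  if (frac_pos[1] == frac_pos[2])
    stop("cluster orientation tie: both clusters have equal MRI-positive ",
         "fraction; supply an explicit override")
  pos_cluster <- which.max(frac_pos)
  orientation <- ifelse(1:2 == pos_cluster, "SVZM+", "SVZM-")
  centroids <- rbind(
    "SVZM+" = rowMeans(mm[, cl == pos_cluster, drop = FALSE]),
    "SVZM-" = rowMeans(mm[, cl != pos_cluster, drop = FALSE]))
  structure(list(probes = sig,
                 importance = ranked$importance[seq_len(k)],
                 linkage_spec = list(metric = "euclidean",
                                     linkage = "complete"),
                 centroids = centroids,
                 orientation = orientation,
                 train_labels = stats::setNames(orientation[cl],
                                                colnames(mm))),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d CpGs (%s / %s linkage)\n",
              length(x$probes), x$linkage_spec$metric,
              x$linkage_spec$linkage))
  invisible(x)
}

#' Count signature CpGs per annotated gene
#'
#' @param sig a `SignatureModel`.
#' @param annotation probe annotation data.frame (probe_id, gene; gene may
#'   be ";"-separated for overlapping genes).
#' @return data.frame gene / n_cpgs, decreasing, ties by symbol.
#' @export
signature_gene_counts <- function(sig, annotation) {
  gene_cpg_rank(sig$probes, annotation)
}

#' Assign SVZM labels to a cohort from a signature model
#'
#' Three modes: `train_clustering` re-runs the training recipe
#' (hierarchical clustering, Euclidean distance, complete linkage, cut at
#' 2); `validation_clustering` clusters with the Chebyshev ("maximum")
#' distance and ward.D linkage, as used for an independent cohort; in both
#' modes the two clusters are oriented by proximity of their mean M-vector
#' to the stored training centroids. `centroid` mode assigns each sample
#' directly to its nearest training centroid.
#'
#' @param m a `MethylationMatrix` containing all signature probes.
#' @param sig a `SignatureModel`.
#' @param mode one of "train_clustering", "validation_clustering",
#'   "centroid".
#' @return named character vector of "SVZM+"/"SVZM-" labels per sample.
#' @export
classify_svzm <- function(m, sig,
                          mode = c("validation_clustering",
                                   "train_clustering", "centroid")) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "MethylationMatrix"), inherits(sig, "SignatureModel"))
  missing_p <- setdiff(sig$probes, rownames(m$beta))
  if (length(missing_p))
    stop("signature probes missing from matrix: ",
         paste(missing_p, collapse = ", "))
  mm <- m_values(meth_subset(m, probes = sig$probes))
  cent <- sig$centroids[, sig$probes, drop = FALSE]
  if (mode == "centroid") {
    d2 <- vapply(rownames(cent), function(lab)
      colSums((mm - cent[lab, ])^2), numeric(ncol(mm)))
    d2 <- matrix(d2, ncol = 2, dimnames = list(colnames(mm), rownames(cent)))
    lab <- rownames(cent)[max.col(-d2, ties.method = "first")]
    return(stats::setNames(lab, colnames(mm)))
  }
  dmat <- if (mode == "train_clustering") stats::dist(t(mm)) else
    stats::dist(t(mm), method = "maximum")
  link <- if (mode == "train_clustering") "complete" else "ward.D"
  cl <- stats::cutree(stats::hclust(dmat, link), k = 2L)
  # orient clusters by nearest training centroid (2x2 assignment,
  # minimizing total squared distance; the two clusters get distinct labels)
  cmeans <- vapply(1:2, function(g)
    rowMeans(mm[, cl == g, drop = FALSE]), numeric(nrow(mm)))
  d2 <- outer(1:2, rownames(cent),
              function(g, lab) vapply(seq_along(g), function(i)
                sum((cmeans[, g[i]] - cent[lab[i], ])^2), numeric(1)))
  straight <- d2[1, 1] + d2[2, 2]
  crossed <- d2[1, 2] + d2[2, 1]
  map <- if (straight <= crossed) rownames(cent) else rev(rownames(cent))
  stats::setNames(map[cl], colnames(mm))
}

#' Serialize a signature model to JSON
#'
#' @param sig a `SignatureModel`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "SignatureModel"))
  obj <- list(probes = sig$probes, importance = sig$importance,
              linkage_spec = sig$linkage_spec,
              centroids = list("SVZM+" = unname(sig$centroids["SVZM+", ]),
                               "SVZM-" = unname(sig$centroids["SVZM-", ])),
              orientation = sig$orientation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature model from JSON
#'
#' @param path path written by [write_signature_json()].
#' @return a `SignatureModel` (without training labels).
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- rbind("SVZM+" = obj$centroids[["SVZM+"]],
                "SVZM-" = obj$centroids[["SVZM-"]])
  colnames(cent) <- obj$probes
  structure(list(probes = obj$probes, importance = obj$importance,
                 linkage_spec = as.list(obj$linkage_spec), centroids = cent,
                 orientation = obj$orientation, train_labels = NULL),
            class = "SignatureModel")
}

#' Run the full signature-discovery procedure
#'
#' Chains the derivation pipeline on a training cohort: probe filtering,
#' (optional) MAD preselection, per-CpG differential methylation at
#' `alpha`, clustering-stability pruning, random-forest ranking, and
#' top-k signature selection.
#'
#' @param m training `MethylationMatrix` (unfiltered).
#' @param mri_labels MRI class labels.
#' @param alpha DMP threshold (default 0.001).
#' @param k signature size (default 15).
#' @param mad_top optional MAD preselection count (NULL = skip; applied
#'   after flag filtering).
#' @param n_trees,seed random-forest parameters.
#' @return list with `dmp` (test table), `stability` (pruning result),
#'   `ranking` and `signature` (a `SignatureModel`).
#' @export
discover_signature <- function(m, mri_labels, alpha = 0.001, k = 15L,
                               mad_top = NULL, n_trees = 500L, seed = 1L) {
  mf <- filter_probes(m)
  if (!is.null(mad_top) && mad_top < nrow(mf$beta))
    mf <- top_mad_probes(mf, mad_top)
  dmp <- differential_methylation(mf, mri_labels, alpha = alpha)
  dmp_ids <- dmp$probe_id[dmp$is_dmp]
  if (length(dmp_ids) < 2L)
    stop("fewer than 2 DMPs at alpha = ", alpha)
  stab <- stability_subset(meth_subset(mf, probes = dmp_ids), mri_labels)
  ranking <- rf_rank(meth_subset(mf, probes = stab$probes), mri_labels,
                     n_trees = n_trees, seed = seed)
  k_eff <- min(k, nrow(ranking))
  sig <- select_signature(ranking, mf, mri_labels, k = k_eff)
  list(dmp = dmp, stability = stab, ranking = ranking, signature = sig)
}
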