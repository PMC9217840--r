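VARIANT_CLASSES <- c("missense", "nonsense", "frameshift_ins",
                     "frameshift_del", "inframe_del", "splice_region",
                     "splice_site", "silent", "other")

#' Validate a multi-pipeline mutation call table
#'
#' @param calls data.frame with columns sample_id, gene, pipeline_id,
#'   variant_class (from the declared vocabulary), optional vaf.
#' @param pipelines declared pipeline ids (default: those present).
#' @return the validated data.frame with a logical `silent` column.
#' @export
mutation_calls <- function(calls, pipelines = NULL) {
  calls <- as.data.frame(calls)
  need <- c("sample_id", "gene", "pipeline_id", "variant_class")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(calls$variant_class), VARIANT_CLASSES)
  if (length(bad)) stop("unknown variant_class: ", paste(bad, collapse = ", "))
  if (!is.null(pipelines)) {
    badp <- setdiff(unique(calls$pipeline_id), pipelines)
    if (length(badp)) stop("unknown pipeline id: ",
                           paste(badp, collapse = ", "))
  }
  calls$silent <- calls$variant_class == "silent"
  calls
}

#' Drop silent mutation calls
#'
#' @param calls mutation call table.
#' @return the table without silent records; all else preserved.
#' @export
filter_silent <- function(calls) {
  calls <- mutation_calls(calls)
  calls[!calls$silent, , drop = FALSE]
}

#' Cross-pipeline consensus mutation indicator
#'
#' A (sample, gene) pair is consensus-mutated iff at least `min_pipelines`
#' distinct pipelines report a non-silent call for it.
#'
#' @param calls mutation call table.
#' @param pipelines declared pipeline ids (validated against the calls).
#' @param min_pipelines consensus threshold (default 3 of 4).
#' @param samples optionally, the full sample universe (so samples with no
#'   calls appear with zero counts downstream).
#' @return data.frame: sample_id, gene, n_pipelines (distinct pipelines
#'   with a non-silent call), mutated (consensus indicator).
#' @export
pipeline_consensus <- function(calls, pipelines, min_pipelines = 3L,
                               samples = NULL) {
  calls <- mutation_calls(calls, pipelines)
  if (min_pipelines > length(pipelines))
    stop("min_pipelines exceeds the number of pipelines")
  ns <- calls[!calls$silent, , drop = FALSE]
  if (nrow(ns)) {
    key <- paste(ns$sample_id, ns$gene, sep = "\r")
    cnt <- tapply(ns$pipeline_id, key, function(p) length(unique(p)))
    parts <- strsplit(names(cnt), "\r", fixed = TRUE)
    res <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                      gene = vapply(parts, `[`, "", 2L),
                      n_pipelines = as.integer(cnt),
                      stringsAsFactors = FALSE)
  } else {
    res <- data.frame(sample_id = character(0), gene = character(0),
                      n_pipelines = integer(0), stringsAsFactors = FALSE)
  }
  res$mutated <- res$n_pipelines >= min_pipelines
  attr(res, "samples") <- if (is.null(samples))
    unique(calls$sample_id) else samples
  rownames(res) <- NULL
  res
}

consensus_matrix <- function(consensus, samples = NULL) {
  if (is.null(samples)) samples <- attr(consensus, "samples")
  genes <- sort(unique(consensus$gene))
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  hit <- consensus[consensus$mutated & consensus$sample_id %in% samples, ,
                   drop = FALSE]
  if (nrow(hit)) m[cbind(hit$sample_id, hit$gene)] <- TRUE
  m
}

#' Per-gene mutation enrichment between two classes (Barnard)
#'
#' For every gene with at least one consensus mutation, builds the 2x2
#' table (mutated vs not x class) and computes the unconditional Barnard
#' p-value; records the direction (class with the higher mutation
#' frequency) and flags genes mutated in exactly one class as exclusive.
#'
#' @param consensus output of [pipeline_consensus()].
#' @param labels named class labels per sample.
#' @param positive positive-class label (default "SVZM+").
#' @param grid_points Barnard nuisance-grid size.
#' @return data.frame: gene, n_pos, n_neg, freq_pos, freq_neg, barnard_p,
#'   bh_q, direction, exclusive.
#' @export
per_gene_enrichment <- function(consensus, labels, positive = "SVZM+",
                                grid_points = 1001L) {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  samples <- intersect(attr(consensus, "samples"), names(labels))
  if (!any(labels[samples] == positive) || all(labels[samples] == positive))
    stop("both classes must be non-empty")
  mat <- consensus_matrix(consensus, samples)
  pos_s <- samples[labels[samples] == positive]
  neg_s <- setdiff(samples, pos_s)
  rows <- lapply(colnames(mat), function(g) {
    a <- sum(mat[pos_s, g]); b <- sum(mat[neg_s, g])
    if (a + b == 0L) return(NULL)  # zero-mutation gene: skipped
    tab <- rbind(mutated = c(a, b),
                 unmutated = c(length(pos_s) - a, length(neg_s) - b))
    bp <- barnard_test(tab, grid_points = grid_points)$p
    fp <- a / length(pos_s); fn <- b / length(neg_s)
    data.frame(gene = g, n_pos = a, n_neg = b, freq_pos = fp, freq_neg = fn,
               barnard_p = bp,
               direction = if (fp >= fn) positive else "other",
               exclusive = (a == 0L) != (b == 0L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) return(res)
  res$bh_q <- bh_fdr(res$barnard_p)$adjusted
  rownames(res) <- NULL
  res
}

#' Per-sample mutation burden comparison (Wilcoxon)
#'
#' Counts non-silent consensus mutations per sample and compares the two
#' classes with a two-sided Wilcoxon rank-sum test.
#'
#' @param consensus output of [pipeline_consensus()].
#' @param labels named class labels per sample.
#' @param positive positive-class label.
#' @return list with `counts` (named per-sample vector), `p`, `statistic`.
#' @export
mutation_burden_test <- function(consensus, labels, positive = "SVZM+") {
  samples <- intersect(attr(consensus, "samples"), names(labels))
  mat <- consensus_matrix(consensus, samples)
  counts <- rowSums(mat)
  grp <- labels[samples] == positive
  if (sum(grp) < 2L || sum(!grp) < 2L)
    stop("need at least 2 samples per class")
  if (length(unique(counts)) == 1L) {
    warning("all per-sample counts tied; p = 1")
    return(list(counts = counts, p = 1, statistic = NA_real_))
  }
  ht <- suppressWarnings(stats::wilcox.test(counts[grp], counts[!grp]))
  list(counts = counts, p = ht$p.value, statistic = unname(ht$statistic))
}

#' Mutation-type x class interaction via a linear mixed model
#'
#' Models per-sample, per-variant-type, per-pipeline non-silent call
#' counts as `count ~ type * class` with a random intercept per calling
#' pipeline (REML, Wald t-tests with Satterthwaite degrees of freedom).
#' With a singular random-effect variance the model falls back to fixed
#' effects with a warning. Types absent from the data are dropped.
#'
#' @param calls mutation call table (all pipelines, silent already
#'   excluded or not: silent calls are ignored).
#' @param labels named class labels per sample.
#' @param positive positive-class label.
#' @param response "count" (default) or "presence".
#' @return data.frame per variant type: type, estimate (class-interaction
#'   contrast relative to the reference type), se, p, significant.
#' @export
mutation_type_interaction <- function(calls, labels, positive = "SVZM+",
                                      response = c("count", "presence")) {
  response <- match.arg(response)
  calls <- mutation_calls(calls)
  calls <- calls[!calls$silent, , drop = FALSE]
  samples <- names(labels)
  types <- intersect(VARIANT_CLASSES, unique(calls$variant_class))
  pipelines <- sort(unique(calls$pipeline_id))
  grid <- expand.grid(sample_id = samples, type = types,
                      pipeline_id = pipelines, stringsAsFactors = FALSE)
  key <- paste(calls$sample_id, calls$variant_class, calls$pipeline_id)
  cnt <- table(key)
  gkey <- paste(grid$sample_id, grid$type, grid$pipeline_id)
  grid$count <- as.integer(cnt[gkey])
  grid$count[is.na(grid$count)] <- 0L
  if (response == "presence") grid$count <- as.integer(grid$count > 0L)
  grid$class <- factor(ifelse(labels[grid$sample_id] == positive,
                              "pos", "neg"), levels = c("neg", "pos"))
  grid$type <- factor(grid$type, levels = types)
  # type + type:class parameterization yields one class contrast per type
  fx <- if (length(types) > 1L) count ~ type + type:class else
    count ~ class
  fr <- if (length(types) > 1L)
    count ~ type + type:class + (1 | pipeline_id) else
    count ~ class + (1 | pipeline_id)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(fr, data = grid)),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    if (!is.null(fit))
      warning("singular random-effect variance; fixed-effects fallback")
    lmfit <- stats::lm(fx, data = grid)
    co <- summary(lmfit)$coefficients
  } else {
    co <- summary(fit)$coefficients
  }
  rows <- lapply(seq_along(types), function(i) {
    nm <- if (length(types) > 1L)
      paste0("type", types[i], ":classpos") else "classpos"
    if (!nm %in% rownames(co)) return(NULL)
    data.frame(type = types[i], estimate = co[nm, "Estimate"],
               se = co[nm, "Std. Error"],
               p = co[nm, ncol(co)], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  res$significant <- res$p < 0.05
  rownames(res) <- NULL
  attr(res, "singular") <- singular
  res
}

#' Read a MAF-like mutation TSV
#'
#' @param path TSV with columns sample_id, gene, pipeline_id,
#'   variant_class (and optionally vaf, silent).
#' @param pipelines declared pipeline set (optional).
#' @return validated call table.
#' @export
read_mutations_tsv <- function(path, pipelines = NULL) {
  mutation_calls(utils::read.delim(path, stringsAsFactors = FALSE),
                 pipelines)
}
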