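#' Methylation matrix container
#'
#' Bundles a CpG x sample beta-value matrix with per-probe annotation
#' (chromosome, position, gene symbol and exclusion flags). Beta values are
#' clipped into [clip, 1 - clip] at construction so that M-values
#' (log2(beta/(1-beta))) are always finite.
#'
#' @param beta numeric matrix, probes in rows, samples in columns, values in
#'   (0,1). Row names are probe ids, column names sample ids.
#' @param annotation data.frame with columns `probe_id`, `chrom`, `pos`
#'   (0-based), `gene` (symbol, possibly ";"-separated for overlapping genes,
#'   or ""), and logical flags `sex_chrom`, `snp_overlap`, `repetitive`.
#'   Row order must cover every probe in `beta`.
#' @param clip clipping bound applied to beta values (default 1e-3).
#' @return an object of class `MethylationMatrix`: a list with elements
#'   `beta` and `annotation`.
#' @export
meth_matrix <- function(beta, annotation = NULL, clip = 1e-3) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta))) stop("beta must have probe ids as row names")
  if (is.null(colnames(beta))) stop("beta must have sample ids as column names")
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids")
  if (any(!is.finite(beta))) stop("beta contains non-finite values")
  if (any(beta <= 0 | beta >= 1)) {
    n_clipped <- sum(beta < clip | beta > 1 - clip)
    message(sprintf("clipping %d beta values to [%g, %g]", n_clipped,
                    clip, 1 - clip))
  }
  beta <- pmin(pmax(beta, clip), 1 - clip)
  if (is.null(annotation)) {
    annotation <- data.frame(probe_id = rownames(beta), chrom = "chr1",
                             pos = seq_len(nrow(beta)) - 1L, gene = "",
                             sex_chrom = FALSE, snp_overlap = FALSE,
                             repetitive = FALSE, stringsAsFactors = FALSE)
  }
  need <- c("probe_id", "chrom", "pos", "gene",
            "sex_chrom", "snp_overlap", "repetitive")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(rownames(beta) %in% annotation$probe_id))
    stop("annotation does not cover every probe")
  annotation <- annotation[match(rownames(beta), annotation$probe_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(beta = beta, annotation = annotation),
            class = "MethylationMatrix")
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf("MethylationMatrix: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$beta)

#' Subset a methylation matrix by probes and/or samples
#'
#' @param x a `MethylationMatrix`.
#' @param probes probe ids or indices (default all).
#' @param samples sample ids or indices (default all).
#' @return a `MethylationMatrix`.
#' @export
meth_subset <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "MethylationMatrix"))
  b <- x$beta
  if (!is.null(probes)) b <- b[probes, , drop = FALSE]
  if (!is.null(samples)) b <- b[, samples, drop = FALSE]
  meth_matrix(b, x$annotation[match(rownames(b), x$annotation$probe_id), ,
                              drop = FALSE])
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)). Defined for beta strictly inside (0,1);
#' monotone increasing, with M = 0 at beta = 0.5.
#'
#' @param beta numeric vector or matrix of beta values in (0,1).
#' @return M-values with the same shape.
#' @export
beta_to_m <- function(beta) {
  if (any(!is.finite(beta)) || any(beta <= 0) || any(beta >= 1))
    stop("beta values must lie strictly inside (0, 1)")
  log2(beta / (1 - beta))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M).
#'
#' @param m numeric vector or matrix of M-values.
#' @return beta values in (0,1).
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("M-values must be finite")
  1 / (1 + 2^(-m))
}

#' M-value matrix of a MethylationMatrix
#'
#' @param x a `MethylationMatrix`.
#' @return matrix of M-values, probes x samples.
#' @export
m_values <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  beta_to_m(x$beta)
}

#' Remove probes on sex chromosomes, at SNPs, or in repetitive sequence
#'
#' Keeps exactly the probes whose `sex_chrom`, `snp_overlap` and
#' `repetitive` annotation flags are all FALSE, preserving probe order.
#'
#' @param x a `MethylationMatrix`.
#' @return filtered `MethylationMatrix`.
#' @export
filter_probes <- function(x) {
  stopifnot(inherits(x, "MethylationMatrix"))
  a <- x$annotation
  keep <- !(a$sex_chrom | a$snp_overlap | a$repetitive)
  if (!any(keep)) stop("no probes remain after filtering")
  meth_subset(x, probes = which(keep))
}

#' Select the most variable probes by median absolute deviation
#'
#' Ranks probes by the raw MAD of their beta values across samples (median
#' of absolute deviations from the probe median, no consistency constant)
#' and keeps the top `k`. Ties in MAD are broken by probe id (lexicographic),
#' so the selection is stable. Selected probes keep their original order.
#'
#' @param x a `MethylationMatrix`.
#' @param k number of probes to keep (k <= number of probes).
#' @return `MethylationMatrix` restricted to the k most variable probes.
#' @export
top_mad_probes <- function(x, k) {
  stopifnot(inherits(x, "MethylationMatrix"))
  n <- nrow(x$beta)
  if (k < 1 || k > n) stop(sprintf("k must be in [1, %d], got %s", n, k))
  mads <- apply(x$beta, 1L, function(v) stats::median(abs(v - stats::median(v))))
  ord <- order(-mads, rownames(x$beta))
  sel <- sort(ord[seq_len(k)])
  meth_subset(x, probes = sel)
}

#' Read a methylation beta matrix and probe annotation from TSV
#'
#' The beta TSV has probe ids in the first column and one column per sample;
#' the annotation TSV has columns probe_id, chrom, pos, gene, sex_chrom,
#' snp_overlap, repetitive.
#'
#' @param beta_path path to the beta-value TSV.
#' @param annotation_path optional path to the probe-annotation TSV.
#' @param clip beta clipping bound (see [meth_matrix()]).
#' @return a `MethylationMatrix`.
#' @export
read_methylation_tsv <- function(beta_path, annotation_path = NULL,
                                 clip = 1e-3) {
  b <- utils::read.delim(beta_path, row.names = 1L, check.names = FALSE)
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
    for (fl in c("sex_chrom", "snp_overlap", "repetitive"))
      ann[[fl]] <- as.logical(ann[[fl]])
    ann$gene[is.na(ann$gene)] <- ""
  }
  meth_matrix(as.matrix(b), ann, clip = clip)
}

#' Write a methylation matrix (and annotation) to TSV
#'
#' @param x a `MethylationMatrix`.
#' @param beta_path output path for the beta matrix TSV.
#' @param annotation_path optional output path for the annotation TSV.
#' @return invisibly, `beta_path`.
#' @export
write_methylation_tsv <- function(x, beta_path, annotation_path = NULL) {
  stopifnot(inherits(x, "MethylationMatrix"))
  df <- data.frame(probe_id = rownames(x$beta), x$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, beta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path))
    utils::write.table(x$annotation, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(beta_path)
}
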