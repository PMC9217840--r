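#' Segment a probe-level log-ratio track by recursive binary splitting
#'
#' CBS-style segmentation of one sample: within each chromosome, the split
#' maximizing the two-sample t-statistic between left and right probe sets
#' is accepted if its within-segment permutation p-value (max |t| over all
#' candidate splits, `n_perm` label permutations, seeded) falls below
#' `alpha_split`, and both sides keep at least `min_probes` probes; the
#' procedure recurses into both sides. Segmentation never crosses a
#' chromosome boundary. Coordinates are 0-based half-open
#' (start = first probe position, end = last probe position + 1).
#'
#' @param track data.frame with columns `chrom`, `pos` and one numeric
#'   log2-ratio column per sample, sorted by (chrom, pos).
#' @param samples sample columns to segment (default: all non-coordinate
#'   columns).
#' @param min_probes minimum probes per segment (default 5).
#' @param alpha_split split-acceptance p threshold (default 0.01).
#' @param n_perm permutations per split test (default 199).
#' @param seed RNG seed.
#' @return data.frame of segments: chrom, start, end, sample,
#'   mean_log2ratio, n_probes; segments within a chromosome are ordered
#'   and non-overlapping.
#' @export
segment_track <- function(track, samples = NULL, min_probes = 5L,
                          alpha_split = 0.01, n_perm = 199L, seed = 1L) {
  coord <- c("chrom", "pos")
  if (!all(coord %in% names(track))) stop("track needs chrom and pos columns")
  if (is.null(samples)) samples <- setdiff(names(track), coord)
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  for (idx in by_chrom)
    if (is.unsorted(track$pos[idx]))
      stop("track must be sorted by position within chromosome")
  set.seed(seed)
  out <- list()
  for (s in samples) {
    for (ch in names(by_chrom)) {
      idx <- by_chrom[[ch]]
      v <- track[[s]][idx]
      pos <- track$pos[idx]
      segs <- segment_recursive(v, min_probes, alpha_split, n_perm)
      for (sg in segs) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = pos[sg[1]], end = pos[sg[2]] + 1L,
          sample = s, mean_log2ratio = mean(v[sg[1]:sg[2]]),
          n_probes = sg[2] - sg[1] + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# best-split t statistics for all candidate cuts of v (left = 1..i)
split_tstats <- function(v, min_probes) {
  n <- length(v)
  i <- seq_len(n - 1L)
  cs <- cumsum(v)
  tot <- cs[n]
  ml <- cs[i] / i
  mr <- (tot - cs[i]) / (n - i)
  cs2 <- cumsum(v^2)
  ssl <- cs2[i] - i * ml^2
  ssr <- (cs2[n] - cs2[i]) - (n - i) * mr^2
  pool <- (ssl + ssr) / pmax(n - 2L, 1L)
  se <- sqrt(pool * (1 / i + 1 / (n - i)))
  t <- (ml - mr) / se
  t[!is.finite(t)] <- 0
  ok <- i >= min_probes & (n - i) >= min_probes
  t[!ok] <- 0
  t
}

# recursive binary segmentation of a numeric vector; returns list of
# c(start_index, end_index) pairs, ordered
segment_recursive <- function(v, min_probes, alpha_split, n_perm) {
  n <- length(v)
  if (n < 2L * min_probes) return(list(c(1L, n)))
  t_all <- split_tstats(v, min_probes)
  t_obs <- max(abs(t_all))
  if (t_obs == 0) return(list(c(1L, n)))
  t_perm <- vapply(seq_len(n_perm), function(b) {
    max(abs(split_tstats(v[sample.int(n)], min_probes)))
  }, numeric(1))
  p <- (1 + sum(t_perm >= t_obs)) / (1 + n_perm)
  if (p >= alpha_split) return(list(c(1L, n)))
  cut <- which.max(abs(t_all))
  left <- segment_recursive(v[1:cut], min_probes, alpha_split, n_perm)
  right <- segment_recursive(v[(cut + 1L):n], min_probes, alpha_split, n_perm)
  c(left, lapply(right, function(sg) sg + cut))
}

#' Automatic gain/loss thresholds from a normal-tissue reference
#'
#' Robust symmetric cuts around the reference segment-mean distribution:
#' loss_cut = median - k * MAD, gain_cut = median + k * MAD (MAD with the
#' 1.4826 consistency constant).
#'
#' @param reference_means numeric vector of segment means from normal
#'   reference samples (>= 20 values).
#' @param k multiplier (default 2.5).
#' @return list with `loss_cut` and `gain_cut`.
#' @export
auto_thresholds <- function(reference_means, k = 2.5) {
  if (length(reference_means) < 20L)
    stop("need at least 20 reference segment means")
  med <- stats::median(reference_means)
  md <- stats::mad(reference_means)  # constant = 1.4826
  if (md == 0)
    stop("reference MAD is zero; consider a k-quantile fallback")
  list(loss_cut = med - k * md, gain_cut = med + k * md)
}

#' Call gain/loss/neutral states on segments
#'
#' @param segments segment data.frame from [segment_track()].
#' @param thresholds list from [auto_thresholds()].
#' @return the segments with a `state` column added.
#' @export
call_states <- function(segments, thresholds) {
  segments$state <- ifelse(segments$mean_log2ratio < thresholds$loss_cut,
                           "loss",
                    ifelse(segments$mean_log2ratio > thresholds$gain_cut,
                           "gain", "neutral"))
  segments
}

#' Compare per-bin CNV state frequencies between two classes
#'
#' Each sample's state in a genomic bin is taken from the segment covering
#' the bin midpoint (no covering segment: neutral, flagged). Per bin, a
#' 2x2 Fisher test of altered (gain or loss) vs neutral against class.
#'
#' @param segments state-called segments (see [call_states()]).
#' @param labels named class-label vector (names = sample ids).
#' @param bin_width bin width in bp (default 1e7); bins tile each
#'   chromosome's segment extent.
#' @param positive label of the positive class (default "SVZM+").
#' @return data.frame per bin: chrom, start, end, freq_pos, freq_neg,
#'   fisher_p, n_uncovered.
#' @export
group_cnv_comparison <- function(segments, labels, bin_width = 1e7,
                                 positive = "SVZM+") {
  if (is.null(names(labels))) stop("labels must be named by sample id")
  samples <- intersect(unique(segments$sample), names(labels))
  if (!length(samples)) stop("no overlap between segments and labels")
  pos_s <- samples[labels[samples] == positive]
  neg_s <- setdiff(samples, pos_s)
  out <- list()
  for (ch in unique(segments$chrom)) {
    sc <- segments[segments$chrom == ch, , drop = FALSE]
    lo <- min(sc$start); hi <- max(sc$end)
    starts <- seq(lo, hi - 1, by = bin_width)
    for (b0 in starts) {
      b1 <- min(b0 + bin_width, hi)
      mid <- (b0 + b1) / 2
      st <- vapply(samples, function(s) {
        ss <- sc[sc$sample == s & sc$start <= mid & sc$end > mid, ,
                 drop = FALSE]
        if (nrow(ss) == 0L) NA_character_ else ss$state[1]
      }, character(1))
      n_unc <- sum(is.na(st))
      st[is.na(st)] <- "neutral"
      alt <- st != "neutral"
      tab <- rbind(altered = c(sum(alt[pos_s]), sum(alt[neg_s])),
                   neutral = c(sum(!alt[pos_s]), sum(!alt[neg_s])))
      p <- if (any(rowSums(tab) == 0)) 1 else stats::fisher.test(tab)$p.value
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = b0, end = b1,
        freq_pos = if (length(pos_s)) mean(alt[pos_s]) else NA_real_,
        freq_neg = if (length(neg_s)) mean(alt[neg_s]) else NA_real_,
        fisher_p = p, n_uncovered = n_unc, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write segments as BED-like TSV
#'
#' @param segments segment data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
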