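#' Simulation configuration for a linked multi-omic glioblastoma cohort
#'
#' Defines the statistical structure of a synthetic two-class (SVZM+ /
#' SVZM-) cohort: a 450K-style beta-value matrix with a planted set of
#' differentially methylated probes (DMPs), class-dependent Weibull
#' survival, expression counts negatively coupled to the methylation of
#' their mapped CpGs, arm-level copy-number events, per-gene mutations
#' observed through several noisy calling pipelines, and imperfect MRI
#' raters.
#'
#' Defaults mirror the training-cohort design: 24 SVZ+ vs 30 SVZ- samples,
#' a small minority of planted DMPs that are predominantly hypomethylated
#' in the positive class (frac_hypo = 0.98), a planted log hazard ratio of
#' 0.91 (HR about 2.5) on a Weibull baseline, four mutation-calling
#' pipelines with sensitivity 0.9 and false-call rate 0.01, and three MRI
#' raters.
#'
#' @param n_pos,n_neg number of SVZM+ / SVZM- samples.
#' @param n_probes total CpGs simulated.
#' @param n_dmp number of planted differential CpGs.
#' @param frac_hypo fraction of planted DMPs hypomethylated in SVZM+.
#' @param effect_delta mean between-group shift of planted DMPs, on the
#'   scale named by `effect_scale`.
#' @param effect_scale `"m"` (shift applied to the mean M-value, default) or
#'   `"beta"` (shift applied to the mean beta, then clipped).
#' @param beta_dispersion concentration of the per-CpG beta distribution
#'   (larger = less noise).
#' @param log_hr planted log hazard ratio, SVZM+ vs SVZM-.
#' @param weibull_shape,weibull_scale baseline Weibull parameters (months).
#' @param censor_rate administrative censoring fraction in [0,1).
#' @param n_genes expression genes; genes mapped to planted DMPs are
#'   negatively coupled to their CpG's M-value.
#' @param coupling_rho target methylation-expression correlation (negative).
#' @param nb_size negative-binomial size (inverse dispersion) of counts.
#' @param cnv_events list of events, each a list with `chrom`, `state`
#'   ("gain"/"loss"), `group` ("pos"/"neg"/"all") and `penetrance`.
#' @param n_cnv_ref number of normal reference samples for the CNV track.
#' @param n_pipelines number of mutation-calling pipelines.
#' @param mutation_rates data.frame with columns gene, rate_pos, rate_neg.
#' @param silent_frac fraction of true mutations that are silent.
#' @param pipeline_sensitivity,pipeline_false_rate per-pipeline detection
#'   probability for a true mutation and false-call probability.
#' @param n_raters number of MRI raters.
#' @param rater_error per-rater label-flip probability.
#' @param seed integer seed; a fixed seed gives a byte-identical bundle.
#' @return a validated `SimulationConfig` list.
#' @export
sim_config <- function(n_pos = 24L, n_neg = 30L,
                       n_probes = 10000L, n_dmp = 200L,
                       frac_hypo = 0.98, effect_delta = 1.5,
                       effect_scale = c("m", "beta"),
                       beta_dispersion = 50,
                       log_hr = 0.91, weibull_shape = 1.4,
                       weibull_scale = 18, censor_rate = 0.3,
                       n_genes = 2000L, coupling_rho = -0.7, nb_size = 10,
                       cnv_events = NULL, n_cnv_ref = 30L,
                       n_pipelines = 4L, mutation_rates = NULL,
                       silent_frac = 0.15,
                       pipeline_sensitivity = 0.9,
                       pipeline_false_rate = 0.01,
                       n_raters = 3L, rater_error = 0.15,
                       seed = 1L) {
  effect_scale <- match.arg(effect_scale)
  if (is.null(cnv_events))
    cnv_events <- list(
      list(chrom = "chr10", state = "loss", group = "neg", penetrance = 0.7),
      list(chrom = "chr19", state = "gain", group = "neg", penetrance = 0.6))
  if (is.null(mutation_rates)) {
    genes <- sprintf("MUT%02d", 1:30)
    rate_pos <- rep(0.08, 30); rate_neg <- rep(0.08, 30)
    rate_pos[1] <- 0.35; rate_neg[1] <- 0.05  # enriched in SVZM+
    rate_pos[2] <- 0.05; rate_neg[2] <- 0.35  # enriched in SVZM-
    rate_pos[3] <- 0.15; rate_neg[3] <- 0.00  # exclusive to SVZM+
    mutation_rates <- data.frame(gene = genes, rate_pos = rate_pos,
                                 rate_neg = rate_neg,
                                 stringsAsFactors = FALSE)
  }
  cfg <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              n_probes = as.integer(n_probes), n_dmp = as.integer(n_dmp),
              frac_hypo = frac_hypo, effect_delta = effect_delta,
              effect_scale = effect_scale,
              beta_dispersion = beta_dispersion, log_hr = log_hr,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              censor_rate = censor_rate, n_genes = as.integer(n_genes),
              coupling_rho = coupling_rho, nb_size = nb_size,
              cnv_events = cnv_events, n_cnv_ref = as.integer(n_cnv_ref),
              n_pipelines = as.integer(n_pipelines),
              mutation_rates = mutation_rates, silent_frac = silent_frac,
              pipeline_sensitivity = pipeline_sensitivity,
              pipeline_false_rate = pipeline_false_rate,
              n_raters = as.integer(n_raters), rater_error = rater_error,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop(sprintf("invalid configuration field '%s': must be a count > 0",
                   field))
  }
  for (f in c("n_pos", "n_neg", "n_probes", "n_genes", "n_pipelines",
              "n_raters")) chk_count(f)
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("invalid configuration field '%s': must lie in [0, 1]",
                   field))
  }
  for (f in c("frac_hypo", "censor_rate", "silent_frac",
              "pipeline_sensitivity", "pipeline_false_rate", "rater_error"))
    chk_frac(f)
  if (cfg$n_dmp < 0 || cfg$n_dmp > cfg$n_probes)
    stop("invalid configuration field 'n_dmp': must lie in [0, n_probes]")
  if (cfg$n_raters < 2) stop("invalid configuration field 'n_raters': >= 2")
  if (cfg$effect_delta < 0)
    stop("invalid configuration field 'effect_delta': must be >= 0")
  if (cfg$effect_scale == "beta" && cfg$effect_delta >= 1)
    stop("invalid configuration field 'effect_delta': beta shift must keep means in (0,1)")
  if (cfg$beta_dispersion <= 0)
    stop("invalid configuration field 'beta_dispersion': must be > 0")
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0)
    stop("invalid configuration field 'weibull_shape'/'weibull_scale': must be > 0")
  if (cfg$coupling_rho < -1 || cfg$coupling_rho > 1)
    stop("invalid configuration field 'coupling_rho': must lie in [-1, 1]")
  invisible(cfg)
}

# deterministic per-layer sub-seed, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1000003) %% 2147483647)
}

#' Generate a linked synthetic multi-omic cohort
#'
#' Draws every data layer the SVZM analysis consumes from a single seeded
#' generator (with one sub-stream per layer): methylation beta values with
#' planted DMPs, a sample sheet with survival and clinical covariates,
#' expression counts coupled to planted CpGs, a probe-level CNV log-ratio
#' track (tumors plus a normal reference panel), multi-pipeline mutation
#' calls, and MRI rater labels. The planted ground truth travels with the
#' bundle.
#'
#' @param config a `SimulationConfig` from [sim_config()].
#' @param template optional `CohortBundle` whose planted methylation
#'   structure (probe universe, baseline means, DMP identities and
#'   directions, probe annotation) is reused, so that a validation cohort
#'   shares the training cohort's differential probes; `config$n_probes`
#'   must match the template. Samples and all other layers are drawn
#'   fresh.
#' @param sample_prefix prefix for sample ids (default "S"; use a distinct
#'   prefix when two cohorts are combined downstream).
#' @return a `CohortBundle`: list with elements `methylation`, `samples`,
#'   `expression` (list: counts, gene_cpg_map), `cnv_input`,
#'   `cnv_reference`, `mutations`, `raters`, `truth`.
#' @export
generate_cohort <- function(config, template = NULL, sample_prefix = "S") {
  if (!inherits(config, "SimulationConfig")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_pos + cfg$n_neg
  sample_ids <- sprintf("%s%03d", sample_prefix, seq_len(n))
  truth_labels <- c(rep("SVZM+", cfg$n_pos), rep("SVZM-", cfg$n_neg))
  names(truth_labels) <- sample_ids
  pos <- truth_labels == "SVZM+"

  ## ---- methylation layer -------------------------------------------------
  set.seed(derive_seed(cfg$seed, 1L))
  if (!is.null(template)) {
    stopifnot(inherits(template, "CohortBundle"))
    tm <- template$truth$meth_internals
    if (length(tm$base_beta) != cfg$n_probes)
      stop("config n_probes does not match the template probe universe")
    probe_ids <- names(tm$base_beta)
    base_beta <- unname(tm$base_beta)
    dmp_ids <- template$truth$dmp_ids
    dmp_idx <- match(dmp_ids, probe_ids)
    hypo <- unname(template$truth$dmp_hypo_in_pos)
    cfg$n_dmp <- length(dmp_idx)
  } else {
    probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
    dmp_idx <- sort(sample.int(cfg$n_probes, cfg$n_dmp))
    dmp_ids <- probe_ids[dmp_idx]
    # bimodal baseline typical of array beta values; planted DMPs mid-range
    comp <- sample(1:3, cfg$n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    base_beta <- ifelse(comp == 1, stats::rbeta(cfg$n_probes, 2, 10),
                 ifelse(comp == 2, stats::rbeta(cfg$n_probes, 10, 2),
                                   stats::rbeta(cfg$n_probes, 5, 5)))
    base_beta <- pmin(pmax(base_beta, 0.05), 0.95)
    base_beta[dmp_idx] <- stats::runif(cfg$n_dmp, 0.35, 0.65)
    n_hypo <- round(cfg$frac_hypo * cfg$n_dmp)
    hypo <- rep(FALSE, cfg$n_dmp)
    if (n_hypo > 0) hypo[sample.int(cfg$n_dmp, n_hypo)] <- TRUE
  }
  mu <- matrix(base_beta, nrow = cfg$n_probes, ncol = 2)  # cols: pos, neg
  if (cfg$n_dmp > 0 && cfg$effect_delta > 0) {
    h <- cfg$effect_delta / 2
    sgn <- ifelse(hypo, -1, 1)           # hypo: lower in SVZM+
    if (cfg$effect_scale == "m") {
      bm <- beta_to_m(base_beta[dmp_idx])
      mu[dmp_idx, 1] <- m_to_beta(bm + sgn * h)
      mu[dmp_idx, 2] <- m_to_beta(bm - sgn * h)
    } else {
      mu[dmp_idx, 1] <- base_beta[dmp_idx] + sgn * h
      mu[dmp_idx, 2] <- base_beta[dmp_idx] - sgn * h
    }
  }
  mu <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  phi <- cfg$beta_dispersion
  beta <- matrix(0, cfg$n_probes, n, dimnames = list(probe_ids, sample_ids))
  mu_s <- mu[, ifelse(pos, 1L, 2L), drop = FALSE]
  beta[] <- stats::rbeta(length(mu_s), shape1 = c(mu_s) * phi,
                         shape2 = (1 - c(mu_s)) * phi)
  beta <- pmin(pmax(beta, 1e-3), 1 - 1e-3)

  # annotation: flags only on non-planted probes; planted probes annotated
  # to genes in blocks so gene-level CpG ranking has structure; the first
  # block is annotated to an overlapping (nested) gene pair
  if (!is.null(template)) {
    annotation <- template$methylation$annotation
  } else {
  chrom <- paste0("chr", 1 + (seq_len(cfg$n_probes) - 1L) %% 22L)
  posn <- as.integer(50000 * (seq_len(cfg$n_probes) - 1L))
  flag <- function(p) {
    f <- rep(FALSE, cfg$n_probes)
    cand <- setdiff(seq_len(cfg$n_probes), dmp_idx)
    f[sample(cand, round(p * length(cand)))] <- TRUE
    f
  }
  sex_chrom <- flag(0.02); snp_overlap <- flag(0.02); repetitive <- flag(0.01)
  gene <- rep("", cfg$n_probes)
  nongd <- setdiff(seq_len(cfg$n_probes), dmp_idx)
  bg <- sample(nongd, round(0.5 * length(nongd)))
  gene[bg] <- sprintf("G%04d", sample.int(2000, length(bg), replace = TRUE))
  dmp_genes <- character(0)
  if (cfg$n_dmp > 0) {
    sizes <- integer(0)
    while (sum(sizes) < cfg$n_dmp)
      sizes <- c(sizes, 1L + stats::rpois(1, 2))
    sizes[length(sizes)] <- cfg$n_dmp - sum(sizes[-length(sizes)])
    blk <- rep(seq_along(sizes), sizes)
    dmp_genes <- sprintf("DMG%03d", seq_along(sizes))
    gene[dmp_idx] <- dmp_genes[blk]
    # nested pair: block 1 CpGs map to two overlapping genes
    gene[dmp_idx[blk == 1L]] <- paste0(dmp_genes[1], ";", dmp_genes[1], "b")
  }
  annotation <- data.frame(probe_id = probe_ids, chrom = chrom, pos = posn,
                           gene = gene, sex_chrom = sex_chrom,
                           snp_overlap = snp_overlap,
                           repetitive = repetitive, stringsAsFactors = FALSE)
  }
  methylation <- meth_matrix(beta, annotation)

  ## ---- survival + clinical sample sheet ----------------------------------
  set.seed(derive_seed(cfg$seed, 2L))
  lp <- cfg$log_hr * as.numeric(pos)
  u <- stats::runif(n)
  t_event <- cfg$weibull_scale * (-log(u) / exp(lp))^(1 / cfg$weibull_shape)
  censored <- stats::runif(n) < cfg$censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  time <- pmax(time, 0.01)
  event <- as.integer(!censored)
  age <- round(pmin(pmax(stats::rnorm(n, 59, 9), 39), 81), 1)
  kps80 <- stats::rbinom(n, 1, 0.65)
  tmz <- stats::rbinom(n, 1, 0.65)
  mgmt <- stats::rbinom(n, 1, 0.45)
  dose60 <- stats::rbinom(n, 1, 0.8)
  surgery <- sample(c("subtotal", "total", "biopsy"), n, replace = TRUE,
                    prob = c(0.5, 0.4, 0.1))

  ## ---- raters ------------------------------------------------------------
  set.seed(derive_seed(cfg$seed, 3L))
  raters <- matrix("", n, cfg$n_raters,
                   dimnames = list(sample_ids,
                                   sprintf("rater%d", seq_len(cfg$n_raters))))
  other <- c("SVZM+" = "SVZM-", "SVZM-" = "SVZM+")
  for (r in seq_len(cfg$n_raters)) {
    flip <- stats::runif(n) < cfg$rater_error
    raters[, r] <- ifelse(flip, other[truth_labels], truth_labels)
  }
  # sample-sheet MRI label: majority vote across raters (ties -> rater 1)
  mri_label <- apply(raters, 1L, function(v) {
    tb <- table(v)
    if (length(tb) > 1L && tb[1] == tb[2]) v[1] else names(which.max(tb))
  })
  samples <- data.frame(sample_id = sample_ids, mri_label = mri_label,
                        cohort = "synthetic", time_months = round(time, 3),
                        event = event, age = age, kps80 = kps80, tmz = tmz,
                        mgmt = mgmt, dose60 = dose60, surgery = surgery,
                        stringsAsFactors = FALSE)

  ## ---- expression coupled to planted CpGs --------------------------------
  set.seed(derive_seed(cfg$seed, 4L))
  gene_ids <- sprintf("EXP%04d", seq_len(cfg$n_genes))
  n_coupled <- min(cfg$n_genes, cfg$n_dmp)
  map <- data.frame(gene = character(0), cpg = character(0),
                    stringsAsFactors = FALSE)
  mlog <- matrix(stats::rnorm(cfg$n_genes * n, 0, 1), cfg$n_genes, n)
  if (n_coupled > 0) {
    cpg_for_gene <- dmp_ids[seq_len(n_coupled)]
    map <- data.frame(gene = gene_ids[seq_len(n_coupled)],
                      cpg = cpg_for_gene, stringsAsFactors = FALSE)
    mz <- t(scale(t(beta_to_m(beta[cpg_for_gene, , drop = FALSE]))))
    mz[!is.finite(mz)] <- 0
    rho <- cfg$coupling_rho
    mlog[seq_len(n_coupled), ] <- rho * mz +
      sqrt(max(0, 1 - rho^2)) * mlog[seq_len(n_coupled), , drop = FALSE]
  }
  base_mean <- exp(stats::rnorm(cfg$n_genes, log(200), 0.8))
  libfac <- exp(stats::rnorm(n, 0, 0.2))
  mu_e <- base_mean * exp(1.0 * mlog) %*% diag(libfac)
  counts <- matrix(stats::rnbinom(cfg$n_genes * n, mu = c(mu_e),
                                  size = cfg$nb_size),
                   cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))

  ## ---- CNV probe track ---------------------------------------------------
  set.seed(derive_seed(cfg$seed, 5L))
  cnv_chroms <- paste0("chr", 1:22)
  per_chrom <- 100L
  cnv_pos <- data.frame(
    chrom = rep(cnv_chroms, each = per_chrom),
    pos = as.integer(rep((seq_len(per_chrom) - 1L) * 1e6, 22L)),
    stringsAsFactors = FALSE)
  np <- nrow(cnv_pos)
  shift <- matrix(0, np, n)
  event_carriers <- list()
  for (ev in cfg$cnv_events) {
    elig <- switch(ev$group, pos = which(pos), neg = which(!pos),
                   all = seq_len(n))
    carriers <- elig[stats::runif(length(elig)) < ev$penetrance]
    rows <- cnv_pos$chrom == ev$chrom
    amp <- if (ev$state == "loss") -0.5 else 0.4
    shift[rows, carriers] <- shift[rows, carriers] + amp
    event_carriers[[paste(ev$chrom, ev$state, sep = "_")]] <-
      sample_ids[carriers]
  }
  cnv <- shift + matrix(stats::rnorm(np * n, 0, 0.15), np, n)
  colnames(cnv) <- sample_ids
  cnv_input <- cbind(cnv_pos, as.data.frame(cnv, check.names = FALSE))
  ref <- matrix(stats::rnorm(np * cfg$n_cnv_ref, 0, 0.15), np, cfg$n_cnv_ref,
                dimnames = list(NULL, sprintf("N%03d", seq_len(cfg$n_cnv_ref))))
  cnv_reference <- cbind(cnv_pos, as.data.frame(ref, check.names = FALSE))

  ## ---- mutations through noisy pipelines ---------------------------------
  set.seed(derive_seed(cfg$seed, 6L))
  mr <- cfg$mutation_rates
  classes <- c("missense", "nonsense", "frameshift_ins", "frameshift_del",
               "inframe_del", "splice_region", "splice_site", "other")
  cls_prob <- c(0.50, 0.10, 0.08, 0.08, 0.05, 0.07, 0.07, 0.05)
  recs <- list()
  truth_mut <- matrix(FALSE, n, nrow(mr),
                      dimnames = list(sample_ids, mr$gene))
  for (g in seq_len(nrow(mr))) {
    rate <- ifelse(pos, mr$rate_pos[g], mr$rate_neg[g])
    mut <- stats::runif(n) < rate
    vclass <- ifelse(stats::runif(n) < cfg$silent_frac, "silent",
                     sample(classes, n, replace = TRUE, prob = cls_prob))
    truth_mut[, g] <- mut & vclass != "silent"
    for (p in seq_len(cfg$n_pipelines)) {
      det <- mut & (stats::runif(n) < cfg$pipeline_sensitivity)
      fp <- !mut & (stats::runif(n) < cfg$pipeline_false_rate)
      idx <- which(det | fp)
      if (!length(idx)) next
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = sample_ids[idx], gene = mr$gene[g],
        pipeline_id = sprintf("P%d", p),
        variant_class = ifelse(det[idx], vclass[idx],
                               sample(classes, length(idx), replace = TRUE,
                                      prob = cls_prob)),
        stringsAsFactors = FALSE)
    }
  }
  mutations <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sample_id = character(0), gene = character(0),
               pipeline_id = character(0), variant_class = character(0),
               stringsAsFactors = FALSE)
  mutations$silent <- mutations$variant_class == "silent"
  rownames(mutations) <- NULL

  bundle <- list(methylation = methylation, samples = samples,
                 expression = list(counts = counts, gene_cpg_map = map),
                 cnv_input = cnv_input, cnv_reference = cnv_reference,
                 mutations = mutations,
                 raters = data.frame(sample_id = sample_ids, raters,
                                     stringsAsFactors = FALSE),
                 truth = list(labels = truth_labels, dmp_ids = dmp_ids,
                              dmp_hypo_in_pos = stats::setNames(hypo, dmp_ids),
                              meth_internals = list(
                                base_beta = stats::setNames(base_beta,
                                                            probe_ids)),
                              coupled_genes = map$gene,
                              cnv_carriers = event_carriers,
                              mutated = truth_mut,
                              config = unclass(cfg)))
  class(bundle) <- "CohortBundle"
  bundle
}

#' @export
print.CohortBundle <- function(x, ...) {
  cat(sprintf(paste0("CohortBundle: %d samples (%d SVZM+ / %d SVZM-), ",
                     "%d CpGs (%d planted DMPs), %d genes\n"),
              nrow(x$samples), sum(x$truth$labels == "SVZM+"),
              sum(x$truth$labels == "SVZM-"), nrow(x$methylation$beta),
              length(x$truth$dmp_ids), nrow(x$expression$counts)))
  invisible(x)
}

#' Write a cohort bundle to a directory of TSV files plus a truth JSON
#'
#' @param bundle a `CohortBundle`.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "CohortBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_methylation_tsv(bundle$methylation, p("methylation.tsv"),
                        p("probe_annotation.tsv"))
  utils::write.table(bundle$samples, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ec <- data.frame(gene_id = rownames(bundle$expression$counts),
                   bundle$expression$counts, check.names = FALSE)
  utils::write.table(ec, p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$expression$gene_cpg_map, p("gene_cpg_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$cnv_input, p("cnv_probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$cnv_reference, p("cnv_reference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$mutations, p("mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$raters, p("raters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$mutated <- NULL         # matrix; carried in-memory only
  truth$meth_internals <- NULL  # generator internals, in-memory only
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
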