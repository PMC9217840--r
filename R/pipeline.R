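#' Pipeline configuration
#'
#' Collects the stage parameters of the two-cohort workflow (simulate or
#' load a training cohort, derive the signature, classify a validation
#' cohort, characterize both) together with the output directory and the
#' seeds of every stochastic stage. Defaults carry the published
#' thresholds: DMP p < 0.001, 15-CpG signature, 30,000 MAD probes, 500
#' SAM permutations, FDR 0.05, pipeline consensus 3 of 4, panel FDR 0.10.
#'
#' @param out_dir output directory.
#' @param alpha_dmp DMP p-value threshold.
#' @param k_signature signature size.
#' @param mad_top MAD preselection count (NULL disables; selections larger
#'   than the probe universe are a no-op).
#' @param n_perm SAM permutations.
#' @param fdr SAM / DE FDR level.
#' @param min_pipelines mutation-consensus threshold.
#' @param panel_fdr FDR level for panel mutation enrichment.
#' @param n_trees random-forest trees.
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param sim_train,sim_valid `SimulationConfig`s for the simulate stage
#'   (validation defaults to a larger, independently seeded cohort).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir = tempfile("svzm_run_"),
                            alpha_dmp = 0.001, k_signature = 15L,
                            mad_top = 30000L, n_perm = 500L, fdr = 0.05,
                            min_pipelines = 3L, panel_fdr = 0.10,
                            n_trees = 500L, seed = 1L,
                            sim_train = NULL, sim_valid = NULL) {
  if (alpha_dmp <= 0 || alpha_dmp > 1) stop("alpha_dmp must be in (0, 1]")
  if (fdr <= 0 || fdr > 1) stop("fdr must be in (0, 1]")
  if (panel_fdr <= 0 || panel_fdr > 1) stop("panel_fdr must be in (0, 1]")
  if (k_signature < 1) stop("k_signature must be >= 1")
  if (is.null(sim_train))
    sim_train <- sim_config(seed = derive_seed(seed, 11L))
  if (is.null(sim_valid))
    sim_valid <- sim_config(n_pos = 60L, n_neg = 72L,
                            seed = derive_seed(seed, 12L))
  structure(list(out_dir = out_dir, alpha_dmp = alpha_dmp,
                 k_signature = as.integer(k_signature),
                 mad_top = mad_top, n_perm = as.integer(n_perm), fdr = fdr,
                 min_pipelines = as.integer(min_pipelines),
                 panel_fdr = panel_fdr, n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 sim_train = sim_train, sim_valid = sim_valid),
            class = "PipelineConfig")
}

stage_deps <- list(simulate = character(0),
                   preprocess = "simulate",
                   discover = "preprocess",
                   classify = "discover",
                   survival = "classify",
                   agreement = "classify",
                   cnv = "classify",
                   mutations = "classify",
                   integrate = "classify",
                   report = c("survival", "agreement", "cnv", "mutations",
                              "integrate"))

stage_done <- function(cfg, stage) {
  file.exists(file.path(cfg$out_dir, paste0("manifest_", stage, ".json")))
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  sums <- vapply(inputs[file.exists(inputs)], function(f)
    unname(tools::md5sum(f)), character(1))
  man <- list(stage = stage, seed = cfg$seed,
              parameters = cfg[c("alpha_dmp", "k_signature", "mad_top",
                                 "n_perm", "fdr", "min_pipelines",
                                 "panel_fdr", "n_trees")],
              inputs = as.list(sums), outputs = outputs,
              package_version = as.character(utils::packageVersion("svzmeth")))
  jsonlite::write_json(man, file.path(cfg$out_dir,
                                      paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one stage of the SVZM workflow
#'
#' Stages: `simulate` (write the training and validation cohorts),
#' `preprocess` (probe filtering + MAD selection), `discover` (signature
#' derivation on the training cohort), `classify` (SVZM assignment of
#' both cohorts), `survival`, `agreement`, `cnv`, `mutations`,
#' `integrate`, `report`, or `all`. Each stage writes its result tables
#' plus a JSON manifest (input checksums, parameters, seed, package
#' version) into the configured output directory; a stage refuses to run
#' before its dependencies.
#'
#' @param stage stage name.
#' @param cfg a `PipelineConfig`.
#' @return invisibly, a named list of the stage's in-memory results.
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  if (stage == "all") {
    for (s in c("simulate", "preprocess", "discover", "classify",
                "survival", "agreement", "cnv", "mutations", "integrate",
                "report"))
      run_stage(s, cfg)
    return(invisible(NULL))
  }
  if (!stage %in% names(stage_deps)) stop("unknown stage: ", stage)
  for (dep in stage_deps[[stage]])
    if (!stage_done(cfg, dep))
      stop("stage '", stage, "' requires prior stage '", dep, "'")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)
  t0 <- Sys.time()
  message(sprintf("[%s] starting (seed %d)", stage, cfg$seed))
  out <- switch(stage,
    simulate = {
      btrain <- generate_cohort(cfg$sim_train)
      write_cohort(btrain, p("train"))
      write_cohort(generate_cohort(cfg$sim_valid, template = btrain,
                                   sample_prefix = "V"), p("valid"))
      write_manifest(cfg, stage, character(0),
                     c("train/", "valid/"))
      NULL
    },
    preprocess = {
      for (coh in c("train", "valid")) {
        m <- read_methylation_tsv(p(coh, "methylation.tsv"),
                                  p(coh, "probe_annotation.tsv"))
        m <- filter_probes(m)
        if (!is.null(cfg$mad_top) && cfg$mad_top < nrow(m$beta))
          m <- top_mad_probes(m, cfg$mad_top)
        write_methylation_tsv(m, p(coh, "methylation_filtered.tsv"),
                              p(coh, "probe_annotation_filtered.tsv"))
      }
      write_manifest(cfg, stage,
                     p("train", "methylation.tsv"),
                     c("train/methylation_filtered.tsv",
                       "valid/methylation_filtered.tsv"))
      NULL
    },
    discover = {
      m <- read_methylation_tsv(p("train", "methylation_filtered.tsv"),
                                p("train", "probe_annotation_filtered.tsv"))
      sheet <- utils::read.delim(p("train", "samples.tsv"),
                                 stringsAsFactors = FALSE)
      labels <- sheet$mri_label[match(colnames(m$beta), sheet$sample_id)]
      disc <- discover_signature(m, labels, alpha = cfg$alpha_dmp,
                                 k = cfg$k_signature,
                                 n_trees = cfg$n_trees,
                                 seed = derive_seed(cfg$seed, 21L))
      write_signature_json(disc$signature, p("signature.json"))
      utils::write.table(disc$dmp, p("dmp_table.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_manifest(cfg, stage, p("train", "methylation_filtered.tsv"),
                     c("signature.json", "dmp_table.tsv"))
      list(discovery = disc)
    },
    classify = {
      sig <- read_signature_json(p("signature.json"))
      for (coh in c("train", "valid")) {
        m <- read_methylation_tsv(p(coh, "methylation.tsv"),
                                  p(coh, "probe_annotation.tsv"))
        mode <- if (coh == "train") "train_clustering" else
          "validation_clustering"
        lab <- classify_svzm(m, sig, mode)
        utils::write.table(
          data.frame(sample_id = names(lab), svzm_label = lab),
          p(coh, "svzm_labels.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
      write_manifest(cfg, stage, p("signature.json"),
                     c("train/svzm_labels.tsv", "valid/svzm_labels.tsv"))
      NULL
    },
    survival = {
      res <- list()
      for (coh in c("train", "valid")) {
        sheet <- utils::read.delim(p(coh, "samples.tsv"),
                                   stringsAsFactors = FALSE)
        lab <- utils::read.delim(p(coh, "svzm_labels.tsv"),
                                 stringsAsFactors = FALSE)
        sheet$svzm <- as.integer(
          lab$svzm_label[match(sheet$sample_id, lab$sample_id)] == "SVZM+")
        sheet$mri <- as.integer(sheet$mri_label == "SVZM+")
        screen <- univariable_screen(
          sheet, c("svzm", "mri", "age", "kps80", "tmz", "mgmt", "dose60"))
        utils::write.table(screen, p(coh, "univariable_screen.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        wb <- weibull_fit(sheet, "svzm")
        res[[coh]] <- list(screen = screen, weibull = wb)
      }
      write_manifest(cfg, stage, p("train", "svzm_labels.tsv"),
                     c("train/univariable_screen.tsv",
                       "valid/univariable_screen.tsv"))
      res
    },
    agreement = {
      res <- list()
      for (coh in c("train", "valid")) {
        raters <- utils::read.delim(p(coh, "raters.tsv"),
                                    stringsAsFactors = FALSE)
        rmat <- as.matrix(raters[, -1, drop = FALSE])
        rownames(rmat) <- raters$sample_id
        cons <- consensus_rating(rmat)
        icc_res <- icc(matrix(as.numeric(rmat == "SVZM+"), nrow(rmat)))
        utils::write.table(
          data.frame(sample_id = rownames(rmat),
                     consensus = cons$consensus),
          p(coh, "consensus_rating.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
        res[[coh]] <- list(consensus = cons, icc = icc_res)
      }
      write_manifest(cfg, stage, p("train", "raters.tsv"),
                     c("train/consensus_rating.tsv",
                       "valid/consensus_rating.tsv"))
      res
    },
    cnv = {
      res <- list()
      for (coh in c("train", "valid")) {
        track <- utils::read.delim(p(coh, "cnv_probes.tsv"),
                                   check.names = FALSE,
                                   stringsAsFactors = FALSE)
        ref <- utils::read.delim(p(coh, "cnv_reference.tsv"),
                                 check.names = FALSE,
                                 stringsAsFactors = FALSE)
        segs <- segment_track(track, seed = derive_seed(cfg$seed, 31L))
        ref_segs <- segment_track(ref, seed = derive_seed(cfg$seed, 32L))
        thr <- auto_thresholds(ref_segs$mean_log2ratio)
        segs <- call_states(segs, thr)
        lab <- utils::read.delim(p(coh, "svzm_labels.tsv"),
                                 stringsAsFactors = FALSE)
        labels <- stats::setNames(lab$svzm_label, lab$sample_id)
        cmp <- group_cnv_comparison(segs, labels)
        write_segments_tsv(segs, p(coh, "cnv_segments.tsv"))
        utils::write.table(cmp, p(coh, "cnv_group_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res[[coh]] <- list(segments = segs, thresholds = thr,
                           comparison = cmp)
      }
      write_manifest(cfg, stage, p("train", "cnv_probes.tsv"),
                     c("train/cnv_segments.tsv", "valid/cnv_segments.tsv"))
      res
    },
    mutations = {
      res <- list()
      for (coh in c("train", "valid")) {
        calls <- read_mutations_tsv(p(coh, "mutations.tsv"))
        pls <- sort(unique(calls$pipeline_id))
        lab <- utils::read.delim(p(coh, "svzm_labels.tsv"),
                                 stringsAsFactors = FALSE)
        labels <- stats::setNames(lab$svzm_label, lab$sample_id)
        cons <- pipeline_consensus(calls, pls,
                                   min_pipelines = cfg$min_pipelines,
                                   samples = lab$sample_id)
        enr <- per_gene_enrichment(cons, labels)
        burden <- mutation_burden_test(cons, labels)
        inter <- mutation_type_interaction(calls, labels)
        utils::write.table(enr, p(coh, "mutation_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(inter, p(coh, "mutation_type_interaction.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res[[coh]] <- list(enrichment = enr, burden = burden,
                           interaction = inter)
      }
      write_manifest(cfg, stage, p("train", "mutations.tsv"),
                     c("train/mutation_enrichment.tsv",
                       "valid/mutation_enrichment.tsv"))
      res
    },
    integrate = {
      sams <- list()
      for (coh in c("train", "valid")) {
        m <- read_methylation_tsv(p(coh, "methylation_filtered.tsv"),
                                  p(coh, "probe_annotation_filtered.tsv"))
        lab <- utils::read.delim(p(coh, "svzm_labels.tsv"),
                                 stringsAsFactors = FALSE)
        labels <- lab$svzm_label[match(colnames(m$beta), lab$sample_id)]
        sams[[coh]] <- sam_test(m, labels, n_perm = cfg$n_perm,
                                fdr_target = cfg$fdr,
                                seed = derive_seed(cfg$seed, 41L),
                                positive = "SVZM+")
      }
      cons <- consensus_dmp(sams$train, sams$valid)
      ann <- utils::read.delim(p("valid", "probe_annotation.tsv"),
                               stringsAsFactors = FALSE)
      rank_tab <- gene_cpg_rank(cons$probes, ann)
      counts_df <- utils::read.delim(p("valid", "expression.tsv"),
                                     row.names = 1L, check.names = FALSE)
      counts <- as.matrix(counts_df)
      lab <- utils::read.delim(p("valid", "svzm_labels.tsv"),
                               stringsAsFactors = FALSE)
      labels <- lab$svzm_label[match(colnames(counts), lab$sample_id)]
      de <- differential_expression(counts, labels, fdr = cfg$fdr,
                                    positive = "SVZM+")
      utils::write.table(rank_tab, p("gene_cpg_rank.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(de, p("differential_expression.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(n_consensus = length(cons$probes), n_hypo = cons$n_hypo,
             n_hyper = cons$n_hyper, frac_hypo = cons$frac_hypo),
        p("consensus_summary.json"), auto_unbox = TRUE, digits = NA)
      write_manifest(cfg, stage, p("train", "methylation_filtered.tsv"),
                     c("gene_cpg_rank.tsv", "differential_expression.tsv",
                       "consensus_summary.json"))
      list(sam = sams, consensus = cons, de = de, gene_rank = rank_tab)
    },
    report = {
      manifests <- list.files(cfg$out_dir, "^manifest_.*json$")
      jsonlite::write_json(list(stages = manifests, seed = cfg$seed),
                           p("report.json"), auto_unbox = TRUE, digits = NA)
      write_manifest(cfg, stage, character(0), "report.json")
      NULL
    })
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(out)
}

#' Run the whole pipeline
#'
#' @param cfg a `PipelineConfig`.
#' @return invisibly, NULL; results are on disk under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) run_stage("all", cfg)
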