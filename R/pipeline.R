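# Configuration-driven orchestration of the full synthetic end-to-end
# study: simulate two cohorts -> per-cohort DE + cross-cohort intersection
# -> differential-correlation network -> pathway ORA -> classifier
# training -> evaluation -> qPCR validation statistics. Stages communicate
# through files in the output directory, so each is independently
# replaceable, and a manifest of content hashes makes reruns checkable.

#' Default pipeline configuration
#'
#' A nested list mirroring the stage structure. All randomness derives
#' from the single `seed` argument of [run_pipeline()] through named
#' per-stage substreams.
#'
#' @param sim simulation settings: samples per group, matrix sizes, DE
#'   fraction and fold change, planted-pair count and latent correlations,
#'   decoy-edge count.
#' @param de DE thresholds (alpha on the Mann-Whitney p, abundance and
#'   stability-filter settings).
#' @param diffcor differential-correlation selection rule.
#' @param ora ORA settings.
#' @param train predictor-table sizes/effects and the FCNN specification.
#' @param qpcr CT generation settings.
#' @param stages character vector of enabled stages, in dependency order.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(
    sim = list(n_samples_per_group = 30, n_mirna = 120, n_mrna = 240,
               frac_de = 0.1, de_fc = 3, n_planted_pairs = 20,
               rho_bcr = 0.8, rho_brf = -0.2, n_decoy_edges = 200,
               n_ppi = 10, n_tf = 10, n_lnc = 5),
    de = list(alpha = 0.05, min_abundance = 0,
              min_median_log2cpm = 1.0, min_detection_rate = 0.8),
    diffcor = list(alpha = 0.05, min_abs_delta = 0, variance = 1,
                   selection = "fdr"),
    ora = list(alpha = 0.05, adjust = FALSE, n_sets = 20),
    train = list(n_train_per_group = 100, n_test_per_group = 100,
                 gene_effect = 1.5, mirna_effect = 1.0,
                 isup_effect = 0.8, pt_effect = 0.6,
                 hidden_sizes = c(150, 120, 90, 60, 40, 30, 20),
                 activation = "relu", learning_rate = 0.003,
                 epochs = 60, batch_size = 8),
    qpcr = list(n_assays = 4, ct_intercept = 25, ct_slope = 1,
                ct_noise_sd = 0.15),
    stages = c("simulate", "de", "diffcor", "ora", "train", "evaluate",
               "qpcr")) {
  structure(list(sim = sim, de = de, diffcor = diffcor, ora = ora,
                 train = train, qpcr = qpcr, stages = stages),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_pipeline_config`, a `pipeline_config`; for
#'   `write_pipeline_config`, the path invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  for (sec in names(raw)) {
    if (sec == "stages") defaults$stages <- unlist(raw$stages)
    else for (k in names(raw[[sec]])) defaults[[sec]][[k]] <- raw[[sec]][[k]]
  }
  defaults
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_path <- function(outdir, ...) file.path(outdir, paste0(...))

require_upstream <- function(outdir, files, stage) {
  missing <- files[!file.exists(file.path(outdir, files))]
  if (length(missing)) {
    stop("stage '", stage, "' requires upstream output(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order, with all intermediate
#' and final artifacts written under `outdir`, and returns (and writes) a
#' manifest of produced files with MD5 content hashes, the configuration
#' snapshot and the seed. Identical config + seed reproduce identical
#' hashes.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param seed global integer seed; per-stage seeds are derived from it by
#'   a fixed hash of the stage name.
#' @param quiet suppress progress messages (default TRUE).
#' @return the manifest, invisibly: list with `seed`, `config`, `files`
#'   (data.frame `file`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, seed = 1L,
                         quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stages <- config$stages

  if ("simulate" %in% stages) {
    say("stage: simulate")
    pp <- default_planted_pairs(config$sim$n_planted_pairs,
                                config$sim$n_mirna, config$sim$n_mrna,
                                config$sim$rho_bcr, config$sim$rho_brf)
    for (co in c("A", "B")) {
      cfg <- sim_config(
        n_samples_per_group = config$sim$n_samples_per_group,
        n_mirna = config$sim$n_mirna, n_mrna = config$sim$n_mrna,
        frac_de = config$sim$frac_de, de_fc = config$sim$de_fc,
        planted_pairs = pp,
        seed = derive_seed(seed, paste0("simulate-", co)))
      write_cohort(generate_cohort(cfg), outdir, paste0("cohort", co))
    }
    truth <- read_truth(stage_path(outdir, "cohortA_truth.json"))
    catalog <- generate_interaction_catalog(
      truth, n_decoy_edges = config$sim$n_decoy_edges,
      n_ppi = config$sim$n_ppi, n_tf = config$sim$n_tf,
      n_lnc = config$sim$n_lnc, seed = derive_seed(seed, "catalog"))
    write_tsv(catalog[, c("source", "target", "edge_type", "evidence",
                          "source_db")],
              stage_path(outdir, "catalog.tsv"))
    gs <- generate_gene_sets(truth, n_sets = config$ora$n_sets,
                             seed = derive_seed(seed, "genesets"))
    write_gmt(gs$collection, stage_path(outdir, "genesets.gmt"))
    write_tsv(gs$mirna_annotation, stage_path(outdir, "mirna_annotation.tsv"))
  }

  if ("de" %in% stages) {
    say("stage: de")
    require_upstream(outdir, c("cohortA_counts_mirna.tsv",
                               "cohortB_counts_mirna.tsv"), "de")
    res <- list()
    cohorts <- list()
    for (co in c("A", "B")) {
      counts <- read_count_matrix(
        stage_path(outdir, "cohort", co, "_counts_mirna.tsv"))
      meta <- read_tsv(stage_path(outdir, "cohort", co, "_meta.tsv"))
      res[[co]] <- call_de(counts, meta, alpha = config$de$alpha,
                           min_abundance = config$de$min_abundance)
      cohorts[[co]] <- list(counts = counts, meta = meta)
      write_tsv(res[[co]], stage_path(outdir, "de_mirna_cohort", co, ".tsv"))
    }
    cc <- cross_cohort_de(res$A, res$B)
    filtered <- expression_stability_filter(
      cc$shared, cohorts,
      min_median_log2cpm = config$de$min_median_log2cpm,
      min_detection_rate = config$de$min_detection_rate)
    jsonlite::write_json(
      list(up_a = cc$up_a, down_a = cc$down_a, up_b = cc$up_b,
           down_b = cc$down_b, shared_up = cc$shared_up,
           shared_down = cc$shared_down, shared = cc$shared,
           shared_stable = filtered),
      stage_path(outdir, "venn_summary.json"), auto_unbox = FALSE)
  }

  if ("diffcor" %in% stages) {
    say("stage: diffcor")
    require_upstream(outdir, c("cohortA_counts_mirna.tsv", "catalog.tsv"),
                     "diffcor")
    counts_mir <- read_count_matrix(stage_path(outdir, "cohortA_counts_mirna.tsv"))
    counts_mrna <- read_count_matrix(stage_path(outdir, "cohortA_counts_mrna.tsv"))
    meta <- read_tsv(stage_path(outdir, "cohortA_meta.tsv"))
    catalog <- validate_catalog(read_tsv(stage_path(outdir, "catalog.tsv")))
    lcpm_mir <- cpm_matrix(counts_mir, tmm_factors(counts_mir), log = TRUE)
    lcpm_mrna <- cpm_matrix(counts_mrna, tmm_factors(counts_mrna), log = TRUE)
    # PPI/TF edges live inside the mRNA namespace; lncRNA sources have no
    # expression and are annotated NA by the scan's skip path
    expr_all <- rbind(lcpm_mir, lcpm_mrna)
    pc <- pair_correlations(expr_all, lcpm_mrna, meta, catalog)
    dc <- differential_correlation_scan(pc, alpha = config$diffcor$alpha,
                                        min_abs_delta = config$diffcor$min_abs_delta,
                                        variance = config$diffcor$variance,
                                        selection = config$diffcor$selection)
    write_tsv(dc, stage_path(outdir, "diffcor_results.tsv"))
    de_ann <- NULL
    if (file.exists(stage_path(outdir, "de_mirna_cohortA.tsv"))) {
      de_ann <- do.call(rbind, lapply(c("A", "B"), function(co) {
        d <- read_tsv(stage_path(outdir, "de_mirna_cohort", co, ".tsv"))
        data.frame(id = d$feature_id, cohort = co, is_de = d$is_de,
                   direction = d$direction, stringsAsFactors = FALSE)
      }))
    }
    net <- build_network(dc, catalog, de_ann)
    export_network(net, stage_path(outdir, "network.graphml"), "graphml")
    export_network(net, stage_path(outdir, "network.json"), "json")
    export_network(net, stage_path(outdir, "network_edges.tsv"), "tsv")
    write_tsv(network_degree_table(net), stage_path(outdir, "degree_table.tsv"))
  }

  if ("ora" %in% stages) {
    say("stage: ora")
    require_upstream(outdir, c("network.json", "genesets.gmt",
                               "mirna_annotation.tsv"), "ora")
    net <- import_network(stage_path(outdir, "network.json"), "json")
    if (nrow(net$nodes)) {
      collection <- read_gmt(stage_path(outdir, "genesets.gmt"))
      ann <- read_mirna_annotation(stage_path(outdir, "mirna_annotation.tsv"))
      ora <- run_ora(net$nodes$id, collection, ann,
                     alpha = config$ora$alpha, adjust = config$ora$adjust)
      write_tsv(ora, stage_path(outdir, "ora_results.tsv"))
    } else {
      write_tsv(data.frame(), stage_path(outdir, "ora_results.tsv"))
    }
  }

  if ("train" %in% stages) {
    say("stage: train")
    tr <- config$train
    dat_train <- generate_predictor_table(
      tr$n_train_per_group, tr$gene_effect, tr$mirna_effect,
      tr$isup_effect, tr$pt_effect, seed = derive_seed(seed, "train-data"))
    dat_test <- generate_predictor_table(
      tr$n_test_per_group, tr$gene_effect, tr$mirna_effect,
      tr$isup_effect, tr$pt_effect, seed = derive_seed(seed, "test-data"))
    spec <- fcnn_spec(n_inputs = ncol(dat_train$x),
                      hidden_sizes = tr$hidden_sizes,
                      activation = tr$activation,
                      learning_rate = tr$learning_rate,
                      epochs = tr$epochs, batch_size = tr$batch_size,
                      seed = derive_seed(seed, "fcnn"))
    model <- train_model(init_model(spec), dat_train$x, dat_train$y)
    write_fcnn(model, stage_path(outdir, "model.json"))
    write_tsv(data.frame(sample_id = rownames(dat_train$x), dat_train$x,
                         label = dat_train$y, check.names = FALSE),
              stage_path(outdir, "predictors_train.tsv"))
    write_tsv(data.frame(sample_id = rownames(dat_test$x), dat_test$x,
                         label = dat_test$y, check.names = FALSE),
              stage_path(outdir, "predictors_test.tsv"))
    score <- predict_proba(model, dat_test$x)[, "p_BCR"]
    write_tsv(data.frame(sample_id = rownames(dat_test$x), score = score,
                         predicted = predict_class(model, dat_test$x),
                         label = dat_test$y),
              stage_path(outdir, "predictions_test.tsv"))
  }

  if ("evaluate" %in% stages) {
    say("stage: evaluate")
    require_upstream(outdir, c("model.json", "predictors_train.tsv",
                               "predictors_test.tsv"), "evaluate")
    model <- read_fcnn(stage_path(outdir, "model.json"))
    tr <- read_tsv(stage_path(outdir, "predictors_train.tsv"))
    te <- read_tsv(stage_path(outdir, "predictors_test.tsv"))
    xcols <- setdiff(names(tr), c("sample_id", "label"))
    row <- model_metrics_row("six-predictor recurrence model", model,
                             as.matrix(tr[, xcols]), tr$label,
                             as.matrix(te[, xcols]), te$label)
    write_tsv(row, stage_path(outdir, "metrics.tsv"))
    roc <- roc_auc(predict_proba(model, as.matrix(te[, xcols]))[, "p_BCR"],
                   te$label)
    write_tsv(roc$curve, stage_path(outdir, "roc_test.tsv"))
  }

  if ("qpcr" %in% stages) {
    say("stage: qpcr")
    require_upstream(outdir, c("cohortA_counts_mirna.tsv",
                               "cohortA_truth.json"), "qpcr")
    truth <- read_truth(stage_path(outdir, "cohortA_truth.json"))
    counts_mir <- read_count_matrix(stage_path(outdir, "cohortA_counts_mirna.tsv"))
    counts_mrna <- read_count_matrix(stage_path(outdir, "cohortA_counts_mrna.tsv"))
    meta <- read_tsv(stage_path(outdir, "cohortA_meta.tsv"))
    qp <- config$qpcr
    de <- truth$de_features
    gene_assays <- utils::head(de$feature_id[de$matrix_name == "mrna"],
                               qp$n_assays)
    mir_assays <- utils::head(de$feature_id[de$matrix_name == "mirna"], 2)
    cpm_mrna <- cpm_matrix(counts_mrna, tmm_factors(counts_mrna))
    cpm_mir <- cpm_matrix(counts_mir, tmm_factors(counts_mir))
    expr <- cbind(t(cpm_mrna[gene_assays, , drop = FALSE]) + 0.5,
                  t(cpm_mir[mir_assays, , drop = FALSE]) + 0.5,
                  `ref-gene` = 100, `ref-mir` = 100)
    ct <- generate_ct_table(expr, c("ref-gene", "ref-mir"),
                            ct_intercept = qp$ct_intercept,
                            ct_slope = qp$ct_slope,
                            ct_noise_sd = qp$ct_noise_sd,
                            seed = derive_seed(seed, "qpcr"))
    utils::write.csv(ct, stage_path(outdir, "ct_table.csv"),
                     row.names = FALSE)
    assay_types <- c(stats::setNames(rep("gene", length(gene_assays)),
                                     gene_assays),
                     stats::setNames(rep("mirna", length(mir_assays)),
                                     mir_assays),
                     `ref-gene` = "gene", `ref-mir` = "mirna")
    rel <- relative_expression(ct, assay_types,
                               c(gene = "ref-gene", mirna = "ref-mir"))
    write_tsv(rel, stage_path(outdir, "rel_expr.tsv"))
    stats_df <- qpcr_group_stats(rel, meta,
                                 exclude_assays = c("ref-gene", "ref-mir"))
    write_tsv(stats_df, stage_path(outdir, "qpcr_stats.tsv"))
  }

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    seed = seed,
    stages = stages,
    config = unclass(config),
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outdir, files))),
      stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, stage_path(outdir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
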