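#' Default pipeline run configuration
#'
#' A nested, YAML-round-trippable configuration covering every stage:
#' simulation, digitization, clustering, Tanimoto scoring, model training,
#' evaluation and unknown-strain prediction. All stochastic steps derive
#' their seeds from the single global `seed`.
#'
#' @param seed Global seed.
#' @param ... Named overrides merged over the defaults (nested lists merge
#'   recursively).
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    paths = list(spectra_dir = "", strain_table = "", go_table = "",
                 output_dir = "maldigo_run"),
    digitization = list(window_low = 3000, window_high = 20000,
                        bin_width = 10, z_threshold = 52,
                        score_reference = "noise_floor", noise_quantile = 0.5),
    simulation = list(n_genes = 100, n_go_terms = 8, genes_per_go = c(15, 30),
                      baseline_peaks = 300, signature_bins_per_go = 30,
                      signature_penetrance = 0.9, bin_noise_rate = 0.02,
                      replicates_per_strain = 2, unknown_fraction = 0.1),
    clustering = list(n_clusters = 13),
    tanimoto = list(min_positive = 3, alpha = 0.05,
                    overlap_threshold = 0.05),
    balance = list(smote_target_positives = 1000, negative_multiplier = 5,
                   smote_k_neighbors = 5),
    rf = list(n_trees = 500, features_per_tree = 8),
    svm = list(gamma_grid = 2^seq(-15, 3, by = 2),
               c_grid = 2^seq(-5, 15, by = 2), inner_folds = 3,
               tune = "once"),
    training = list(models = c("rf", "svm"), min_positive = 20, k_folds = 10),
    matching = list(max_positive_training_vectors = 400,
                    require_all_replicates = TRUE, n_models_averaged = 10)
  )
  overrides <- list(...)
  if (length(overrides) > 0) cfg <- modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The YAML form round-trips losslessly through [read_run_config()].
#'
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `path` invisibly (write) or a `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(seed = cfg$seed %||% 1L)
  structure(modifyList(unclass(base), cfg), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Print the fully resolved configuration
#' @param x A `run_config`.
#' @param ... Unused.
#' @export
print.run_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, cfg, stage, extra = list()) {
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     config_hash = config_hash(cfg),
                     package_version = as.character(
                       utils::packageVersion("maldigo"))),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_log <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Simulate a knockout library to disk
#'
#' Writes spectra, strain table, annotations and planted truth under
#' `output_dir`, with a manifest recording the seed and config hash so the
#' run can be reproduced bit-identically.
#'
#' @param cfg A [default_run_config()].
#' @param force Overwrite a non-empty output directory.
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(cfg = default_run_config(), force = FALSE) {
  out <- cfg$paths$output_dir
  if (dir.exists(out) && length(list.files(out)) > 0 && !force) {
    stop("output directory ", out, " is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dcfg <- do.call(digitization_config, cfg$digitization)
  sim <- cfg$simulation
  scfg <- sim_config(
    n_genes = sim$n_genes, n_go_terms = sim$n_go_terms,
    genes_per_go = sim$genes_per_go, baseline_peaks = sim$baseline_peaks,
    signature_bins_per_go = sim$signature_bins_per_go,
    signature_penetrance = sim$signature_penetrance,
    bin_noise_rate = sim$bin_noise_rate,
    replicates_per_strain = sim$replicates_per_strain,
    seed = cfg$seed
  )
  lib <- simulate_library(scfg, dcfg)
  if (sim$unknown_fraction > 0) {
    lib <- make_unknown_set(lib, sim$unknown_fraction)
  }
  write_sim_library(lib, out)
  writeLines(lib$unknown_genes, file.path(out, "truth", "unknown_genes.txt"))
  write_run_config(cfg, file.path(out, "config.yaml"))
  write_manifest(out, cfg, "simulate",
                 list(n_spectra = length(lib$spectra),
                      n_genes = scfg$n_genes,
                      n_unknown_genes = length(lib$unknown_genes)))
  pipeline_log("simulate: ", length(lib$spectra), " spectra for ",
               scfg$n_genes, " genes -> ", out)
  invisible(out)
}

path_or <- function(p, default) {
  if (is.null(p) || !nzchar(p)) default else p
}

load_run_inputs <- function(cfg) {
  out <- cfg$paths$output_dir
  spectra_dir <- path_or(cfg$paths$spectra_dir, file.path(out, "spectra"))
  strain_path <- path_or(cfg$paths$strain_table,
                         file.path(out, "strain_table.tsv"))
  go_path <- path_or(cfg$paths$go_table, file.path(out, "go_annotations.tsv"))
  for (p in c(spectra_dir, strain_path, go_path)) {
    if (!file.exists(p)) {
      stop("missing pipeline input: ", p,
           " (run the simulate stage or point paths at your data)",
           call. = FALSE)
    }
  }
  strain <- readr::read_tsv(strain_path, show_col_types = FALSE)
  files <- list.files(spectra_dir, pattern = "\\.(tsv|mzML|mzml)$",
                      full.names = TRUE)
  spectra <- lapply(files, function(f) {
    sid <- sub("\\.[^.]*$", "", basename(f))
    row <- strain[strain$spectrum_id == sid, ]
    if (nrow(row) == 0) {
      stop("spectrum file ", basename(f), " has no strain-table row",
           call. = FALSE)
    }
    read_spectrum(f, spectrum_id = sid, gene_id = row$gene_id[1],
                  replicate = row$replicate[1])
  })
  unknown_file <- file.path(out, "truth", "unknown_genes.txt")
  unknown <- if (file.exists(unknown_file)) readLines(unknown_file)
             else character(0)
  unknown <- unknown[nzchar(unknown)]
  list(spectra = spectra, strain = strain, go = read_go(go_path),
       unknown_genes = unknown)
}

#' Run pipeline stages over a (simulated or real) library on disk
#'
#' Stages run in the order digitize, cluster, tanimoto, train, evaluate,
#' predict; each stage writes its TSV/JSON outputs under the run's output
#' directory and is idempotent for a fixed seed. Downstream stages require
#' the upstream artifacts and fail with the missing file named.
#'
#' @param cfg A [default_run_config()].
#' @param stages Subset of
#'   `c("digitize", "cluster", "tanimoto", "train", "evaluate", "predict")`.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg = default_run_config(),
                         stages = c("digitize", "cluster", "tanimoto",
                                    "train", "evaluate", "predict")) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$paths$output_dir
  dcfg <- do.call(digitization_config, cfg$digitization)
  fp_path <- file.path(out, "fingerprints.tsv")

  if ("digitize" %in% stages) {
    t0 <- Sys.time()
    inputs <- load_run_inputs(cfg)
    fp <- digitize_library(inputs$spectra, dcfg)
    write_fingerprints(fp, fp_path, "wide")
    write_fingerprints(fp, file.path(out, "fingerprints_bits.tsv"), "bits")
    pipeline_log(sprintf("digitize: %d spectra -> %d bins [%.1fs]",
                         nrow(fp$bits), ncol(fp$bits),
                         as.numeric(Sys.time() - t0, units = "secs")))
  }

  need <- function(path) {
    if (!file.exists(path)) {
      stop("missing upstream artifact: ", path, call. = FALSE)
    }
    path
  }

  later <- intersect(stages, c("cluster", "tanimoto", "train", "evaluate",
                               "predict"))
  if (length(later) > 0) {
    fp <- read_fingerprints(need(fp_path), dcfg)
    inputs <- load_run_inputs(cfg)
    go <- inputs$go
    unknown <- inputs$unknown_genes
  }

  if ("cluster" %in% stages) {
    t0 <- Sys.time()
    known_rows <- !fp$meta$gene_id %in% unknown
    sub <- fingerprint_set(fp$bits[known_rows, , drop = FALSE],
                           fp$meta[known_rows, ], dcfg)
    k <- min(cfg$clustering$n_clusters, nrow(sub$bits))
    cl <- ward_cluster(sub, k)
    readr::write_tsv(cl$assignments, file.path(out, "clusters.tsv"))
    enr <- cluster_enrichment(cl, sub, go)
    readr::write_tsv(enr, file.path(out, "enrichment.tsv"))
    if (requireNamespace("ape", quietly = TRUE)) {
      export_dendrogram_newick(cl, file.path(out, "dendrogram.nwk"))
    }
    pipeline_log(sprintf("cluster: %d vectors in %d clusters [%.1fs]",
                         nrow(cl$assignments), k,
                         as.numeric(Sys.time() - t0, units = "secs")))
  }

  if ("tanimoto" %in% stages) {
    t0 <- Sys.time()
    tan <- tanimoto_model(fp, go, min_positive = cfg$tanimoto$min_positive,
                          unknown_genes = unknown,
                          alpha = cfg$tanimoto$alpha,
                          overlap_threshold = cfg$tanimoto$overlap_threshold)
    readr::write_tsv(tan$summary, file.path(out, "tanimoto_go.tsv"))
    readr::write_tsv(tan$scores, file.path(out, "tanimoto_scores.tsv"))
    pipeline_log(sprintf("tanimoto: %d GO accessions scored [%.1fs]",
                         nrow(tan$summary),
                         as.numeric(Sys.time() - t0, units = "secs")))
  }

  bal_cfg <- do.call(balance_config, cfg$balance)
  rf_cfg <- do.call(rf_config, cfg$rf)
  svm_cfg <- svm_config(gamma_grid = cfg$svm$gamma_grid,
                        c_grid = cfg$svm$c_grid,
                        inner_folds = cfg$svm$inner_folds)

  if ("train" %in% stages) {
    dir.create(file.path(out, "models"), showWarnings = FALSE)
    for (kind in cfg$training$models) {
      t0 <- Sys.time()
      set <- fit_go_models(fp, go, kind,
                           min_positive = cfg$training$min_positive,
                           unknown_genes = unknown,
                           k_folds = cfg$training$k_folds,
                           balance_cfg = bal_cfg, rf_cfg = rf_cfg,
                           svm_cfg = svm_cfg, tune = cfg$svm$tune,
                           seed = cfg$seed)
      saveRDS(set, file.path(out, "models", paste0(kind, ".rds")))
      for (acc in names(set$results)) {
        d <- file.path(out, "models", kind, gsub(":", "_", acc))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(
          list(go_accession = acc, model_kind = kind, seed = cfg$seed,
               config_hash = config_hash(cfg),
               metrics = as.list(set$results[[acc]]$metrics)),
          file.path(d, "manifest.json"), auto_unbox = TRUE, digits = NA)
      }
      pipeline_log(sprintf("train %s: %d GO accessions, mean AUC %.3f [%.1fs]",
                           kind, nrow(set$metrics), mean(set$metrics$auc),
                           as.numeric(Sys.time() - t0, units = "secs")))
    }
  }

  if ("evaluate" %in% stages) {
    summaries <- list()
    for (kind in cfg$training$models) {
      set <- readRDS(need(file.path(out, "models", paste0(kind, ".rds"))))
      readr::write_tsv(set$metrics,
                       file.path(out, paste0("metrics_", kind, ".tsv")))
      agg <- summarize_metrics(set$metrics)
      summaries[[kind]] <- c(list(model_kind = kind), as.list(agg$overall))
    }
    jsonlite::write_json(summaries, file.path(out, "metrics_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pipeline_log("evaluate: summaries for ",
                 paste(cfg$training$models, collapse = ", "))
  }

  if ("predict" %in% stages) {
    t0 <- Sys.time()
    kind <- if ("svm" %in% cfg$training$models) "svm"
            else cfg$training$models[1]
    set <- readRDS(need(file.path(out, "models", paste0(kind, ".rds"))))
    if (length(unknown) == 0L) {
      pipeline_log("predict: no unknown genes; skipping")
    } else {
      mcfg <- do.call(unknown_match_config, cfg$matching)
      pm <- predict_unknown(fp, set, unknown, mcfg)
      readr::write_tsv(pm$table, file.path(out, "predictions.tsv"))
      export_heatmap_table(pm, file.path(out, "prediction_matrix.tsv"))
      pipeline_log(sprintf("predict: %d matches over %d genes [%.1fs]",
                           sum(pm$table$match),
                           length(unique(pm$table$gene_id)),
                           as.numeric(Sys.time() - t0, units = "secs")))
    }
  }

  write_manifest(out, cfg, paste(stages, collapse = "+"))
  invisible(out)
}
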