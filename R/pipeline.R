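#' Build a pipeline run configuration
#'
#' Flat key-value configuration for [run_pipeline()], with every default
#' matching the study conditions: pIC50 activity cutoff 7.6, 28 test
#' compounds, 5 k-means clusters (seed 42), feature-importance cutoff
#' 0.120, CSN edge threshold Tc 0.68, and the field-engine defaults of
#' [probe_spec()] (1.0 A spacing, 4.0 A margin).
#'
#' @param input_csv path to a raw activity CSV (molecule_id, smiles,
#'   ic50_nM); when NULL a synthetic table is generated.
#' @param out_dir run directory for stage outputs.
#' @param n_compounds synthetic set size when generating (default 137).
#' @param cutoff pIC50 activity cutoff (default 7.6).
#' @param n_test test-set size (default 28).
#' @param k_clusters k-means clusters (default 5).
#' @param importance_cutoff feature-importance threshold (default 0.120).
#' @param edge_threshold CSN Tanimoto edge threshold (default 0.68).
#' @param n_trials hyperparameter-search trials (default 20).
#' @param n_series congeneric series size for the field stage (default 24).
#' @param n_conformers conformers per molecule (default 5).
#' @param spacing,margin grid geometry in Angstrom.
#' @param truncation field energy cap, kcal/mol (default 30).
#' @param noise_sd planted pIC50 noise (default 0.3).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_csv = NULL, out_dir = tempfile("kmosar_run"),
                       n_compounds = 137, cutoff = 7.6, n_test = 28,
                       k_clusters = 5, importance_cutoff = 0.120,
                       edge_threshold = 0.68, n_trials = 20,
                       n_series = 24, n_conformers = 5, spacing = 1.0,
                       margin = 4.0, truncation = 30, noise_sd = 0.3,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config a `run_config`.
#' @param path JSON path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(cfg$input_csv) == 0) cfg["input_csv"] <- list(NULL)
  structure(cfg, class = "run_config")
}

#' Run the full study pipeline
#'
#' Executes the stages in dependency order — generate (optional), curate,
#' physicochemical profile, split/map, classifier training, applicability
#' domain, chemical space network, congeneric conformer series, field
#' descriptors, PLS — writing each stage's tables under `config$out_dir`
#' and a manifest (seeds, package version, stage status, file hashes).
#' Deterministic stages reproduce identical hashes on rerun with the
#' same configuration.
#'
#' @param config a [run_config()].
#' @return list with the in-memory stage results and the manifest,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("kmosar")),
                   seed = seed, stages = list())
  res <- list()
  stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
    manifest$stages[[name]] <<- "complete"
    out
  }

  res$raw <- stage("generate", function() {
    if (!is.null(config$input_csv)) {
      utils::read.csv(config$input_csv, stringsAsFactors = FALSE)
    } else {
      spec <- planted_sar_spec(n_compounds = config$n_compounds,
                               noise_sd = config$noise_sd, seed = seed)
      tab <- generate_activity_table(spec)
      write_activity_csv(tab, file.path(config$out_dir, "raw.csv"))
      tab
    }
  })

  res$records <- stage("curate", function() {
    rec <- curate(res$raw, cutoff = config$cutoff)
    write_curated(rec, file.path(config$out_dir, "curated.csv"),
                  file.path(config$out_dir, "curation_log.txt"))
    rec
  })

  res$physchem <- stage("physchem", function() {
    ph <- compute_physchem(res$records)
    utils::write.csv(ph, file.path(config$out_dir, "physchem.csv"),
                     row.names = FALSE)
    r <- correlation_matrix(ph, pic50 = res$records$pic50)
    utils::write.csv(correlation_long(r),
                     file.path(config$out_dir, "correlations.csv"),
                     row.names = FALSE)
    ph
  })

  res$split <- stage("split", function() {
    sp <- split_and_map(res$records, n_test = config$n_test,
                        k_clusters = config$k_clusters, seed = 42L)
    utils::write.csv(sp, file.path(config$out_dir, "split.csv"),
                     row.names = FALSE)
    sp
  })

  res$classifier <- stage("classify", function() {
    feats <- pretreat(res$physchem[setdiff(names(res$physchem),
                                           "molecule_id")])
    sel <- tryCatch(
      select_features(feats, res$records$activity_class,
                      importance_cutoff = config$importance_cutoff),
      error = function(e) feats)   # small panels may all fall below cutoff
    tr <- res$split$set == "train"
    fit <- train_classifier(sel[tr, , drop = FALSE],
                            res$records$activity_class[tr],
                            n_trials = config$n_trials, seed = 42L)
    test_pred <- predict(fit$model, sel[!tr, , drop = FALSE],
                         type = "class")
    fit$test_metrics <-
      classification_metrics(test_pred,
                             res$records$activity_class[!tr])
    fit$features <- names(sel)
    fit$feature_matrix <- sel
    jsonlite::write_json(
      list(hyperparameters = fit$report$hyperparameters,
           cv_accuracy = fit$report$cv_accuracy,
           test = fit$test_metrics[c("accuracy", "precision", "recall",
                                     "f1")]),
      file.path(config$out_dir, "classifier_report.json"),
      auto_unbox = TRUE, digits = NA)
    fit
  })

  res$ad <- stage("ad", function() {
    tr <- res$split$set == "train"
    M <- res$classifier$feature_matrix
    lev <- leverage(M[tr, , drop = FALSE], M[!tr, , drop = FALSE])
    write_ad_csv(lev, file.path(config$out_dir, "ad.csv"))
    lev
  })

  res$csn <- stage("csn", function() {
    net <- build_csn(res$records, edge_threshold = config$edge_threshold)
    write_csn(net, file.path(config$out_dir, "csn"))
    net
  })

  res$ensembles <- stage("conformers", function() {
    synthetic_congeneric_ensembles(n_compounds = config$n_series,
                                   n_conformers = config$n_conformers,
                                   seed = seed + 1L)
  })

  res$fields <- stage("fields", function() {
    grid <- build_grid(res$ensembles, spacing = config$spacing,
                       margin = config$margin)
    probe <- probe_spec(truncation = config$truncation)
    fm <- field_matrix(res$ensembles, grid, probe, mode = "4d")
    utils::write.csv(as.data.frame(fm),
                     file.path(config$out_dir, "field_matrix.csv"))
    list(grid = grid, probe = probe, matrix = fm)
  })

  res$pls <- stage("pls", function() {
    planted <- plant_field_response(res$fields$matrix,
                                    noise_sd = config$noise_sd,
                                    seed = seed + 2L)
    pruned <- prune_columns(res$fields$matrix, planted$y)
    sel <- select_variables(pruned, planted$y)
    summ <- pls_summary(pruned[, sel$columns, drop = FALSE], planted$y)
    jsonlite::write_json(
      summ[c("n_lv", "r2", "rmsec", "sec", "f_stat", "press_cv", "q2",
             "rmsecv")],
      file.path(config$out_dir, "pls_summary.json"),
      auto_unbox = TRUE, digits = NA)
    list(planted = planted, summary = summ, selected = sel$columns)
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest$hashes <- as.list(tools::md5sum(files))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest)))
}
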