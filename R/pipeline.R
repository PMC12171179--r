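## End-to-end pipeline orchestration: reproducible multi-stage runs with a
## single base seed, per-stage derived seeds, structured logging and a hash
## manifest of every output file.

PIPELINE_STAGES <- c("simulate", "pulse_features", "screen", "select_features",
                     "baselines", "train", "evaluate", "explain")

#' Assemble a pipeline run configuration
#'
#' @param out_dir run directory (created).
#' @param stages ordered subset of `simulate`, `pulse_features`, `screen`,
#'   `select_features`, `baselines`, `train`, `evaluate`, `explain`.
#' @param seed base seed; each stage derives its own seed from it.
#' @param cohort a [cohort_spec()] (required by the `simulate` stage).
#' @param manifest_path existing manifest CSV (alternative to `simulate`).
#' @param config a [fusion_config()].
#' @param train a [train_spec()].
#' @param n_explain patients rendered by the `explain` stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, stages = PIPELINE_STAGES, seed = 1,
                       cohort = NULL, manifest_path = NULL,
                       config = fusion_config(), train = train_spec(),
                       n_explain = 2) {
  assert_that(all(stages %in% PIPELINE_STAGES),
              "unknown stage(s): ", paste(setdiff(stages, PIPELINE_STAGES),
                                          collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  assert_that("simulate" %in% stages || !is.null(manifest_path),
              "either include the simulate stage or give manifest_path")
  structure(as.list(environment()), class = "run_config")
}

log_line <- function(con, stage, msg, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                stage = stage, msg = msg), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order, writing every output
#' under `cfg$out_dir` together with the resolved configuration
#' (`resolved_config.yaml`), a line-delimited JSON log (`log.jsonl`) and a
#' hash manifest (`hash_manifest.csv`) of all other outputs. Identical
#' configuration + seed reproduce identical hashes; each stage seeds its
#' own RNG stream via [derive_seed()].
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the run directory, the hash manifest and
#'   per-stage outputs.
#' @export
run_pipeline <- function(cfg) {
  assert_that(inherits(cfg, "run_config"), "not a run_config")
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "log.jsonl"), open = "wt")
  on.exit(close(logf))
  resolved <- list(seed = cfg$seed, stages = cfg$stages,
                   cohort = if (!is.null(cfg$cohort)) unclass(cfg$cohort),
                   model = unclass(cfg$config), train = unclass(cfg$train))
  yaml::write_yaml(resolved, file.path(out, "resolved_config.yaml"))
  results <- list()
  manifest <- NULL
  fit <- NULL

  get_manifest <- function() {
    if (!is.null(manifest)) return(manifest)
    assert_that(!is.null(cfg$manifest_path),
                "dependency error: no manifest (run simulate or give manifest_path)")
    read_manifest(cfg$manifest_path)
  }

  for (stage in cfg$stages) {
    seed <- derive_seed(cfg$seed, stage)
    set.seed(seed)
    log_line(logf, stage, "start", seed = seed)
    if (stage == "simulate") {
      assert_that(!is.null(cfg$cohort), "simulate stage needs a cohort spec")
      sp <- cfg$cohort
      sp$seed <- seed
      g <- generate_cohort(sp, file.path(out, "cohort"))
      manifest <- g$manifest
      results$simulate <- file.path(out, "cohort", "manifest.csv")
    } else if (stage == "pulse_features") {
      manifest <- get_manifest()
      pf <- pulse_features_table(manifest)
      data.table::fwrite(pf, file.path(out, "pulse_features.csv"))
      results$pulse_features <- file.path(out, "pulse_features.csv")
    } else if (stage == "screen") {
      manifest <- get_manifest()
      tab <- read_clinical_table(manifest)
      tab <- tab[manifest$records$patient_id, , drop = FALSE]
      sc <- compare_groups(tab, manifest$records$label)
      data.table::fwrite(sc, file.path(out, "screen.csv"))
      results$screen <- file.path(out, "screen.csv")
    } else if (stage == "select_features") {
      manifest <- get_manifest()
      tr <- manifest$records$split == "train"
      tab <- read_clinical_table(manifest)
      tab <- tab[manifest$records$patient_id, , drop = FALSE]
      sel <- select_top_features(tab[tr, , drop = FALSE],
                                 manifest$records$label[tr],
                                 k = cfg$config$n_clinical_in, seed = seed)
      data.table::fwrite(sel$ranking, file.path(out, "feature_ranking.csv"))
      writeLines(sel$selected, file.path(out, "selected_features.txt"))
      results$select_features <- file.path(out, "selected_features.txt")
    } else if (stage == "baselines") {
      manifest <- get_manifest()
      bt <- baseline_feature_table(manifest, cfg$config$image_size,
                                   cfg$config$n_clinical_in, seed = seed)
      bl <- run_baselines(bt$features, bt$labels, bt$splits, seed = seed)
      data.table::fwrite(bl, file.path(out, "baselines.csv"))
      results$baselines <- file.path(out, "baselines.csv")
    } else if (stage == "train") {
      manifest <- get_manifest()
      tsp <- cfg$train
      tsp$seed <- seed
      fit <- cadfuse_fit(manifest, cfg$config, tsp)
      save_cadfuse(fit, file.path(out, "model.rds"))
      data.table::fwrite(fit$log, file.path(out, "training_log.csv"))
      results$train <- file.path(out, "model.rds")
    } else if (stage == "evaluate") {
      assert_that(!is.null(fit), "dependency error: evaluate needs the train stage")
      manifest <- get_manifest()
      ev <- do.call(rbind, lapply(intersect(SPLIT_LEVELS,
                                            unique(manifest$records$split)),
                                  function(sp)
        tryCatch(evaluate_model(fit, manifest, sp), error = function(e) NULL)))
      data.table::fwrite(ev, file.path(out, "evaluation.csv"))
      results$evaluate <- file.path(out, "evaluation.csv")
    } else if (stage == "explain") {
      assert_that(!is.null(fit), "dependency error: explain needs the train stage")
      manifest <- get_manifest()
      ids <- utils::head(manifest$records$patient_id, cfg$n_explain)
      for (id in ids) {
        render_overlays(fit, manifest, id, file.path(out, "explain", id))
      }
      results$explain <- file.path(out, "explain")
    }
    log_line(logf, stage, "done")
  }

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("log.jsonl", "hash_manifest.csv")]
  hm <- data.frame(file = sub(paste0("^", out, "/?"), "", files),
                   md5 = vapply(files, file_md5, character(1)))
  hm <- hm[order(hm$file), ]
  data.table::fwrite(hm, file.path(out, "hash_manifest.csv"))
  log_line(logf, "pipeline", "complete", n_files = nrow(hm))
  invisible(list(out_dir = out, hashes = hm, results = results))
}
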