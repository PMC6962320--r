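#' Pipeline configuration
#'
#' A single declarative configuration that drives the staged pipeline. All
#' defaults follow the tuned hyper-parameters used throughout the package
#' (Adam at 0.001, L2 0.0025, dropout 0.5, batch 128, patience 30; class
#' roster target 600; TPE with 200 trials). One global seed fans out to
#' per-stage seeds by fixed offsets so stages are independently
#' reproducible. The configuration round-trips through JSON.
#'
#' @param out_dir artifact directory.
#' @param models architectures to include (default all seven).
#' @param n_per_class phantom patches per class for the phantom stage.
#' @param target balanced roster size per class.
#' @param epochs max training epochs per model.
#' @param patience early-stopping patience.
#' @param filters,dense_units network widths.
#' @param batch_size minibatch size.
#' @param n_trials ensemble weight-search trials.
#' @param grid_spacing full-scan sampling grid step (voxels).
#' @param certainty_threshold ILA certainty cutoff.
#' @param seed global seed.
#' @return A `run_config` object (a named list).
#' @export
run_config <- function(out_dir = tempfile("lungtex_run_"),
                       models = arch_names(), n_per_class = 40L,
                       target = NULL, epochs = 8L, patience = 30L,
                       filters = c(8L, 8L, 16L), dense_units = 32L,
                       batch_size = 64L, n_trials = 60L, grid_spacing = 5L,
                       certainty_threshold = 0.95, seed = 1L) {
  structure(list(out_dir = out_dir, models = models,
                 n_per_class = as.integer(n_per_class),
                 target = as.integer(target %||% round(0.8 * n_per_class)),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 batch_size = as.integer(batch_size),
                 n_trials = as.integer(n_trials),
                 grid_spacing = as.integer(grid_spacing),
                 certainty_threshold = certainty_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, j)
}

stage_seed <- function(cfg, stage) {
  cfg$seed + 1000L * match(stage, c("phantoms", "split", "train", "optimize",
                                    "evaluate", "classify"))
}

artifact_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(cfg, name, needed_by) {
  p <- artifact_path(cfg, name)
  if (!file.exists(p))
    stop_lungtex(sprintf(
      "stage '%s' requires missing artifact '%s'; run the producing stage first",
      needed_by, name), "lungtex_dependency_error")
  p
}

#' Run one pipeline stage
#'
#' Stages (in dependency order): `phantoms` generates the patch sets;
#' `split` makes the train/validation/test partition; `train` fits the
#' member networks; `optimize` searches the ensemble weights on pooled
#' validation predictions; `evaluate` computes test metrics; `classify`
#' labels a phantom volume and scores ILA. Each stage is deterministic
#' given (config, seed), writes its artifacts under `cfg$out_dir` and logs
#' a JSON record with the config hash and seeds.
#'
#' @param cfg a [run_config].
#' @param stage one of `"phantoms"`, `"split"`, `"train"`, `"optimize"`,
#'   `"evaluate"`, `"classify"`, or `"all"`.
#' @return The stage artifact (invisibly for file-producing stages).
#' @export
run_pipeline <- function(cfg, stage = c("all", "phantoms", "split", "train",
                                        "optimize", "evaluate", "classify")) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("phantoms", "split", "train", "optimize", "evaluate",
                "classify"))
      run_pipeline(cfg, s)
    return(invisible(cfg$out_dir))
  }
  log_stage <- function(artifacts) {
    rec <- list(stage = stage, seed = stage_seed(cfg, stage),
                config_hash = config_hash(cfg), artifacts = artifacts,
                r_version = as.character(getRversion()))
    jsonlite::write_json(rec, artifact_path(cfg, paste0(stage, ".log.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  switch(stage,
    phantoms = {
      ps <- generate_patchset(cfg$n_per_class, mode = "all",
                              seed = stage_seed(cfg, "phantoms"))
      saveRDS(ps, artifact_path(cfg, "patchset.rds"))
      write_annotations(ps$points, artifact_path(cfg, "annotations.csv"))
      log_stage(c("patchset.rds", "annotations.csv"))
      invisible(ps)
    },
    split = {
      ps <- readRDS(require_artifact(cfg, "patchset.rds", "split"))
      n <- length(ps$labels)
      idx <- seq_len(n)
      sp <- with_seed(stage_seed(cfg, "split"), {
        lapply(split(idx, ps$labels), function(rows) {
          rows <- sample(rows)
          n_tr <- min(cfg$target, floor(0.8 * length(rows)))
          n_va <- max(1L, floor(0.25 * n_tr))
          list(val = rows[seq_len(n_va)],
               train = rows[n_va + seq_len(n_tr - n_va)],
               test = rows[-seq_len(n_tr)])
        })
      })
      plan <- list(train = unlist(lapply(sp, `[[`, "train"), use.names = FALSE),
                   val = unlist(lapply(sp, `[[`, "val"), use.names = FALSE),
                   test = unlist(lapply(sp, `[[`, "test"), use.names = FALSE))
      saveRDS(plan, artifact_path(cfg, "split.rds"))
      log_stage("split.rds")
      invisible(plan)
    },
    train = {
      ps <- readRDS(require_artifact(cfg, "patchset.rds", "train"))
      plan <- readRDS(require_artifact(cfg, "split.rds", "train"))
      norm <- fit_normalization(
        c(ps$sample_sets$axial2d[plan$train], ps$sample_sets$axial2d[plan$val]))
      saveRDS(norm, artifact_path(cfg, "norm_stats.rds"))
      models <- list()
      for (m in seq_along(cfg$models)) {
        name <- cfg$models[m]
        spec <- arch_spec(name, filters = cfg$filters,
                          dense_units = cfg$dense_units)
        mode <- spec$input_mode
        prep <- function(rows) {
          ss <- lapply(ps$sample_sets[[mode]][rows], apply_normalization, norm)
          ds <- roi_stack(ss, needs_context = spec$needs_context)
          ds$y <- as.integer(ps$labels[rows])
          ds
        }
        tc <- train_config(batch_size = cfg$batch_size,
                           patience = cfg$patience,
                           max_epochs = cfg$epochs,
                           seed = stage_seed(cfg, "train") + m)
        mod <- build_model(spec, tc)
        mod <- train_cnn(mod, prep(plan$train), prep(plan$val), tc)
        mod$norm_stats <- norm
        save_model(mod, artifact_path(cfg, paste0("model_", name, ".rds")))
        models[[name]] <- mod
      }
      log_stage(paste0("model_", cfg$models, ".rds"))
      invisible(models)
    },
    optimize = {
      ps <- readRDS(require_artifact(cfg, "patchset.rds", "optimize"))
      plan <- readRDS(require_artifact(cfg, "split.rds", "optimize"))
      norm <- readRDS(require_artifact(cfg, "norm_stats.rds", "optimize"))
      P <- lapply(cfg$models, function(name) {
        mod <- load_model(require_artifact(cfg, paste0("model_", name, ".rds"),
                                           "optimize"))
        ss <- lapply(ps$sample_sets[[mod$arch$input_mode]][plan$val],
                     apply_normalization, norm)
        predict_proba(mod, ss)
      })
      names(P) <- cfg$models
      ew <- optimize_weights(P, as.integer(ps$labels[plan$val]),
                             search_config(n_trials = cfg$n_trials,
                                           seed = stage_seed(cfg, "optimize")))
      save_weights(ew, artifact_path(cfg, "weights.json"))
      log_stage("weights.json")
      invisible(ew)
    },
    evaluate = {
      ps <- readRDS(require_artifact(cfg, "patchset.rds", "evaluate"))
      plan <- readRDS(require_artifact(cfg, "split.rds", "evaluate"))
      norm <- readRDS(require_artifact(cfg, "norm_stats.rds", "evaluate"))
      ew <- load_weights(require_artifact(cfg, "weights.json", "evaluate"))
      P <- lapply(cfg$models, function(name) {
        mod <- load_model(artifact_path(cfg, paste0("model_", name, ".rds")))
        ss <- lapply(ps$sample_sets[[mod$arch$input_mode]][plan$test],
                     apply_normalization, norm)
        predict_proba(mod, ss)
      })
      Y <- fuse(P, ew$w)
      pred <- decide(Y)
      truth <- ps$labels[plan$test]
      cm <- confusion(truth, pred)
      met <- metrics_from_confusion(cm,
        classes = rownames(cm)[rowSums(cm) > 0])
      write.csv(met$per_class, artifact_path(cfg, "metrics.csv"),
                row.names = FALSE)
      write.csv(cm, artifact_path(cfg, "confusion.csv"))
      jsonlite::write_json(as.list(met$macro),
                           artifact_path(cfg, "metrics_macro.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage(c("metrics.csv", "confusion.csv", "metrics_macro.json"))
      invisible(met)
    },
    classify = {
      norm <- readRDS(require_artifact(cfg, "norm_stats.rds", "classify"))
      ew <- load_weights(require_artifact(cfg, "weights.json", "classify"))
      models <- lapply(cfg$models, function(name)
        load_model(artifact_path(cfg, paste0("model_", name, ".rds"))))
      ens <- ensemble_classifier(models, ew$w)
      ph <- generate_phantom(phantom_spec(
        class_counts = stats::setNames(rep(1L, 8), tissue_classes()),
        seed = stage_seed(cfg, "classify")))
      map <- classify_scan(ph$volume, ens, grid_spacing = cfg$grid_spacing,
                           norm_stats = norm)
      sc <- ila_score(map, cfg$certainty_threshold)
      write.csv(data.frame(scan_id = "phantom",
                           threshold = sc$threshold, score = sc$score),
                artifact_path(cfg, "ila_scores.csv"), row.names = FALSE)
      log_stage("ila_scores.csv")
      invisible(sc)
    })
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE)
  # small rolling hash; avoids a digest dependency
  sum_val <- 0
  for (ch in utf8ToInt(as.character(s))) sum_val <- (sum_val * 31 + ch) %% 2^31
  sprintf("%08x", sum_val)
}
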