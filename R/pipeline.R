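# configuration schema: allowed keys per block, with defaults and checks

config_schema <- function() {
  list(
    scene = list(n_scenes = 6, preset = "easy", height = 256, width = 256,
                 n_bands = 150),
    pipeline = list(target_size = 256, patch_size = 64, stride = 32,
                    rot_threshold = 0.10, bg_threshold = 0.50,
                    ratio = c(2, 1, 1), augment_eval = TRUE,
                    augment_classes = c("healthy", "soft_rot"),
                    ops = c("mirror", "crop", "shadow"),
                    crop_fraction = 0.85, shadow_alpha = 0.3),
    model = list(variant = "DBSACaps", routing_iters = 3),
    train = list(learning_rate = 5e-6, weight_decay = 1e-6, batch_size = 16,
                 epochs = 100, microbatch = 2, stop_at_val_oa = NULL),
    seed = 1L,
    out = "dbsacaps_run"
  )
}

#' Default run configuration
#'
#' @return The fully resolved default configuration list (class
#'   `run_config`).
#' @export
default_config <- function() {
  structure(config_schema(), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks a YAML file (or list) against the configuration schema: unknown
#' keys are rejected, missing keys filled with defaults, and value
#' constraints (three-way split ratio, positive rates, known variant and
#' preset, geometry bounds) enforced. All problems are collected and
#' reported together.
#'
#' @param config path to a YAML file, or a configuration list.
#' @param stop_on_error if `TRUE` (default) raise one error listing every
#'   problem; if `FALSE` return the character vector of problems.
#' @return A validated, fully resolved `run_config` (invisibly the error
#'   vector when `stop_on_error = FALSE` and problems were found).
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  schema <- config_schema()
  errors <- character(0)
  note <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))

  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top))
    note("unknown top-level key(s): %s", paste(unknown_top, collapse = ", "))
  for (blk in c("scene", "pipeline", "model", "train")) {
    given <- config[[blk]] %||% list()
    unknown <- setdiff(names(given), names(schema[[blk]]))
    if (length(unknown))
      note("unknown key(s) in '%s': %s", blk, paste(unknown, collapse = ", "))
    schema[[blk]] <- modifyList(schema[[blk]], given[setdiff(names(given), unknown)])
  }
  schema$seed <- config$seed %||% schema$seed
  schema$out <- config$out %||% schema$out

  sc <- schema$scene; pl <- schema$pipeline; md <- schema$model; tr <- schema$train
  if (!is_count(sc$n_scenes) || sc$n_scenes < 3)
    note("scene.n_scenes must be an integer >= 3")
  if (!sc$preset %in% c("easy", "hard"))
    note("scene.preset must be 'easy' or 'hard'")
  if (!is_count(sc$n_bands) || sc$n_bands < 35)
    note("scene.n_bands must be an integer >= 35")
  if (length(pl$ratio) != 3 || any(pl$ratio <= 0))
    note("pipeline.ratio must be three positive numbers (got %s)",
         paste(pl$ratio, collapse = ":"))
  if (!is_count(pl$patch_size) || pl$patch_size < 6)
    note("pipeline.patch_size must be an integer >= 6")
  if (!is_count(pl$stride)) note("pipeline.stride must be a positive integer")
  if (pl$rot_threshold < 0 || pl$rot_threshold > 1 ||
        pl$bg_threshold < 0 || pl$bg_threshold > 1)
    note("pipeline thresholds must be in [0, 1]")
  if (!md$variant %in% variant_names())
    note("model.variant '%s' unknown; valid: %s", md$variant,
         paste(variant_names(), collapse = ", "))
  if (!is.numeric(tr$learning_rate) || tr$learning_rate <= 0)
    note("train.learning_rate must be positive")
  if (!is.numeric(tr$weight_decay) || tr$weight_decay < 0)
    note("train.weight_decay must be nonnegative")
  if (!is_count(tr$epochs)) note("train.epochs must be a positive integer")
  if (!is_count(tr$batch_size)) note("train.batch_size must be a positive integer")
  if (!is_count(schema$seed %||% 0)) note("seed must be a positive integer")

  if (length(errors)) {
    if (stop_on_error)
      stopf("invalid configuration:\n%s",
            paste(paste0("  - ", errors), collapse = "\n"))
    return(invisible(errors))
  }
  structure(schema, class = "run_config")
}

#' Run the full simulate -> prepare -> train -> evaluate pipeline
#'
#' Generates synthetic scenes, builds the patch dataset, trains the
#' configured variant and evaluates it on the test split, writing every
#' artifact into a run directory: the patch store, `manifest.csv`,
#' `counts.json`, `checkpoint.rds`, `history.csv`, `metrics.json`, a frozen
#' copy of the resolved configuration, the package version string and a
#' stage log. Rerunning with the same configuration and seed reproduces
#' the manifests and metrics. On failure, partial artifacts are retained
#' alongside a `FAILED` marker and the error is re-raised.
#'
#' @param config a `run_config`, configuration list or YAML path (validated
#'   first).
#' @param out_dir output directory; defaults to the configuration's `out`.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- out_dir %||% cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_resolved.yaml"))
  writeLines(as.character(utils::packageVersion("dbsacaps")),
             file.path(out, "version.txt"))
  tryCatch({
    log_line("[simulate] %d scenes, preset %s", cfg$scene$n_scenes,
             cfg$scene$preset)
    scenes <- lapply(seq_len(cfg$scene$n_scenes), function(i) {
      spec <- random_scene_spec(sub_seed(cfg$seed, i), cfg$scene$preset,
                                height = cfg$scene$height,
                                width = cfg$scene$width,
                                n_bands = cfg$scene$n_bands)
      c(generate_scene(spec), list(id = sprintf("scene_%03d", i)))
    })
    log_line("[prepare] blocking %d x %d at stride %d", cfg$pipeline$patch_size,
             cfg$pipeline$patch_size, cfg$pipeline$stride)
    policy <- augmentation_policy(cfg$pipeline$augment_classes,
                                  cfg$pipeline$ops,
                                  cfg$pipeline$crop_fraction,
                                  cfg$pipeline$shadow_alpha)
    ds <- build_dataset(scenes, policy, cfg$pipeline$ratio,
                        seed = sub_seed(cfg$seed, 1000L),
                        target_size = cfg$pipeline$target_size,
                        patch_size = cfg$pipeline$patch_size,
                        stride = cfg$pipeline$stride,
                        rot_threshold = cfg$pipeline$rot_threshold,
                        bg_threshold = cfg$pipeline$bg_threshold,
                        augment_eval = cfg$pipeline$augment_eval)
    for (w in ds$warnings) log_line("[prepare] warning: %s", w)
    write_patch_store(ds$patches, file.path(out, "dataset"))
    write.csv(ds$manifest, file.path(out, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(attr(ds$manifest, "counts"),
                         file.path(out, "counts.json"), auto_unbox = TRUE)
    tr_cfg <- train_config(learning_rate = cfg$train$learning_rate,
                           weight_decay = cfg$train$weight_decay,
                           batch_size = cfg$train$batch_size,
                           epochs = cfg$train$epochs,
                           routing_iters = cfg$model$routing_iters,
                           seed = sub_seed(cfg$seed, 2000L),
                           microbatch = cfg$train$microbatch,
                           stop_at_val_oa = cfg$train$stop_at_val_oa)
    model <- dbsa_model(cfg$model$variant, bands = cfg$scene$n_bands,
                        input_size = cfg$pipeline$patch_size,
                        routing_iters = cfg$model$routing_iters,
                        seed = sub_seed(cfg$seed, 3000L))
    sel <- function(s) ds$patches[ds$patches$split == s]
    log_line("[train] %s, %d epochs", cfg$model$variant, cfg$train$epochs)
    model <- fit(model, sel("train"), sel("val"), tr_cfg)
    write.csv(model$history, file.path(out, "history.csv"), row.names = FALSE)
    save_model(model, file.path(out, "checkpoint.rds"))
    log_line("[eval] test split")
    rep <- evaluate(model, sel("test"), microbatch = tr_cfg$microbatch)
    jsonlite::write_json(list(oa = rep$oa, aa = rep$aa,
                              per_class = rep$per_class,
                              confusion = as.data.frame(rep$confusion)),
                         file.path(out, "metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    log_line("[done] OA %.4f AA %.4f", rep$oa, rep$aa)
  }, error = function(e) {
    writeLines(conditionMessage(e), file.path(out, "FAILED"))
    log_line("[failed] %s", conditionMessage(e))
    stopf("pipeline failed (artifacts in %s): %s", out, conditionMessage(e))
  })
  invisible(out)
}

#' Write synthetic scenes to disk
#'
#' Generates seeded scenes and writes each as an ENVI cube pair, a
#' multi-band TIFF and a PNG mask.
#'
#' @param n_scenes number of scenes.
#' @param out_dir target directory.
#' @param seed integer seed.
#' @param preset difficulty preset.
#' @param height,width,n_bands scene geometry.
#' @return Data frame listing the written files, invisibly.
#' @export
simulate_scenes <- function(n_scenes, out_dir, seed = 1L,
                            preset = c("easy", "hard"), height = 256,
                            width = 256, n_bands = 150) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_scenes), function(i) {
    spec <- random_scene_spec(sub_seed(seed, i), preset, height = height,
                              width = width, n_bands = n_bands)
    sc <- generate_scene(spec)
    id <- sprintf("scene_%03d", i)
    write_envi(sc$cube, file.path(out_dir, id))
    write_cube_tiff(sc$cube, file.path(out_dir, paste0(id, ".tif")))
    write_mask_png(sc$mask, file.path(out_dir, paste0(id, "_mask.png")))
    data.frame(id = id, envi = paste0(id, ".hdr"),
               tiff = paste0(id, ".tif"), mask = paste0(id, "_mask.png"))
  })
  out <- do.call(rbind, rows)
  write.csv(out, file.path(out_dir, "scenes.csv"), row.names = FALSE)
  invisible(out)
}
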