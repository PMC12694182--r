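#' Default pipeline configuration (reduced desk-scale preset)
#'
#' Nested sections mirror the stage functions: `dataset` feeds
#' [generate_dataset()], `model` feeds [unet_config()], `train` feeds
#' [train_config()], `evaluate` feeds [evaluate_run()]. `seed` drives every
#' stage; each run writes a resolved-config snapshot next to its outputs.
#'
#' @param out_dir output root.
#' @param seed global seed.
#' @return a `run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L) {
  structure(
    list(
      out_dir = out_dir,
      seed = as.integer(seed),
      dataset = list(
        donors = 2L, unseen_donors = 0L, ratios = c(10, 50, 1000),
        crops_per_combo = 20L, crop_size = 128L,
        sensor_side = 512L, cells_per_field = 72L
      ),
      model = list(levels = 4L, base_channels = 16L, input_side = 128L,
                   in_channels = 3L),
      train = list(lr = 1e-3, batch_size = 4L, epochs = 30L, patience = 10L),
      evaluate = list(split = "test", threshold = 0.75, min_area_px = 50)
    ),
    class = "run_config"
  )
}

known_config_keys <- c("out_dir", "seed", "dataset", "model", "train",
                       "evaluate", "log_level")

merge_config <- function(base, override) {
  bad <- setdiff(names(override), known_config_keys)
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  utils::modifyList(base, override)
}

stage_snapshot_path <- function(out_dir, stage) {
  file.path(out_dir, paste0(stage, "_config.json"))
}

stage_up_to_date <- function(out_dir, stage, snapshot, outputs) {
  sp <- stage_snapshot_path(out_dir, stage)
  if (!file.exists(sp) || !all(file.exists(outputs))) return(FALSE)
  old <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                  error = function(e) NULL)
  identical(
    jsonlite::toJSON(old, auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(snapshot, auto_unbox = TRUE, digits = NA)
  )
}

write_snapshot <- function(out_dir, stage, snapshot) {
  jsonlite::write_json(snapshot, stage_snapshot_path(out_dir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

file_hash <- function(path) unname(tools::md5sum(path))

#' Run the full virtual-staining pipeline
#'
#' simulate/reconstruct/preprocess (via [generate_dataset()]), then train,
#' then evaluate, with stage skipping: a stage re-runs only when its
#' resolved configuration or the content hash of its inputs changed since
#' the snapshot written next to its outputs. Stage failures propagate with
#' the stage name.
#'
#' @param config a `run_config` from [pipeline_config()] (or a list of
#'   overrides merged onto it).
#' @param verbose print per-stage progress and timings.
#' @return list with `manifest`, `model`, `history`, `report`, and `paths`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "run_config")) {
    stopifnot(is.list(config), !is.null(config$out_dir))
    config <- merge_config(pipeline_config(config$out_dir), config)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    if (verbose) {
      message(sprintf("[%s] %.1fs", name, as.numeric(Sys.time() - t0,
                                                     units = "secs")))
    }
    r
  }

  # --- dataset (simulate + reconstruct + preprocess) ---
  ds <- config$dataset
  manifest_path <- file.path(out_dir, "manifest.json")
  snap_ds <- list(section = ds, seed = seed)
  manifest <- log_stage("dataset", {
    if (stage_up_to_date(out_dir, "dataset", snap_ds, manifest_path)) {
      if (verbose) message("[dataset] up to date, skipping")
      read_manifest(manifest_path)
    } else {
      cfg <- optical_config(sensor_shape = rep(ds$sensor_side, 2))
      m <- generate_dataset(
        out_dir,
        donors = ds$donors, unseen_donors = ds$unseen_donors,
        ratios = ds$ratios, crops_per_combo = ds$crops_per_combo,
        crop_size = ds$crop_size, cfg = cfg,
        cells_per_field = ds$cells_per_field,
        seed = seed, verbose = verbose
      )
      write_snapshot(out_dir, "dataset", snap_ds)
      m
    }
  })

  # --- train ---
  ckpt_path <- file.path(out_dir, "model.rds")
  hist_path <- file.path(out_dir, "training_log.csv")
  snap_tr <- list(section = config$train, model = config$model, seed = seed,
                  manifest_md5 = file_hash(manifest_path))
  trained <- log_stage("train", {
    if (stage_up_to_date(out_dir, "train", snap_tr, c(ckpt_path, hist_path))) {
      if (verbose) message("[train] up to date, skipping")
      list(model = load_checkpoint(ckpt_path),
           history = tibble::as_tibble(utils::read.csv(hist_path)))
    } else {
      mcfg <- do.call(unet_config, c(config$model, list(seed = seed)))
      model <- build_model(mcfg)
      tcfg <- do.call(train_config, c(config$train,
                                      list(seed = seed, verbose = verbose)))
      tr <- train_unet(model,
                       load_split(manifest, "train"),
                       load_split(manifest, "val"), tcfg)
      save_checkpoint(tr$model, ckpt_path,
                      meta = list(seed = seed,
                                  best_epoch = attr(tr$history, "best_epoch"),
                                  best_val_mae = min(tr$history$val_mae)))
      utils::write.csv(tr$history, hist_path, row.names = FALSE)
      write_snapshot(out_dir, "train", snap_tr)
      tr
    }
  })

  # --- evaluate ---
  ev <- config$evaluate
  metrics_path <- file.path(out_dir, "metrics.json")
  snap_ev <- list(section = ev, seed = seed,
                  checkpoint_md5 = file_hash(ckpt_path))
  report <- log_stage("evaluate", {
    if (stage_up_to_date(out_dir, "evaluate", snap_ev, metrics_path)) {
      if (verbose) message("[evaluate] up to date, skipping")
      j <- jsonlite::read_json(metrics_path, simplifyVector = TRUE)
      structure(
        list(ssim_mean = j$ssim_mean,
             per_image = tibble::as_tibble(utils::read.csv(
               file.path(out_dir, "metrics_per_image.csv"))),
             counts = structure(as.list(j$counts), class = "confusion_counts"),
             metrics = tibble::as_tibble(j$metrics),
             n_images = j$n_images, split = j$split),
        class = "metrics_report"
      )
    } else {
      rep <- evaluate_run(trained$model, manifest, split = ev$split,
                          threshold = ev$threshold,
                          min_area_px = ev$min_area_px)
      write_metrics(rep, out_dir, "metrics")
      write_snapshot(out_dir, "evaluate", snap_ev)
      rep
    }
  })

  list(
    manifest = manifest,
    model = trained$model,
    history = trained$history,
    report = report,
    paths = list(manifest = manifest_path, checkpoint = ckpt_path,
                 metrics = metrics_path)
  )
}
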