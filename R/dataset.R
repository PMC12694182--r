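#' Plan a dataset manifest
#'
#' Lays out the acquisition campaign as a manifest tibble without rendering
#' any pixels: `donors x ratios x crops_per_combo` primary examples plus
#' `unseen_donors x ratios x crops_per_combo` quarantined unseen-donor
#' examples, with 3:1:1 train/val/test splits assigned per (donor, ratio)
#' stratum. [generate_dataset()] renders the files this plan describes.
#'
#' @param donors number of primary donors.
#' @param unseen_donors number of held-out donors (always split `"unseen"`).
#' @param ratios PBMC:tumor mixing ratios.
#' @param crops_per_combo crops per (donor, ratio) combination.
#' @param crop_size crop side in pixels.
#' @param seed split-shuffle seed.
#' @return a manifest tibble with columns `example_id`, `donor_id`,
#'   `ratio`, `crop_index`, `split`.
#' @export
#' @examples
#' m <- plan_dataset(donors = 5, unseen_donors = 2,
#'                   ratios = c(10, 50, 1000), crops_per_combo = 100)
#' table(m$split) # 900 train / 300 val / 300 test / 600 unseen
plan_dataset <- function(donors = 5L, unseen_donors = 2L,
                         ratios = c(10, 50, 1000), crops_per_combo = 100L,
                         crop_size = 512L, seed = 1L) {
  stopifnot(donors >= 1, unseen_donors >= 0, crops_per_combo >= 1)
  all_donors <- c(
    sprintf("donor%d", seq_len(donors)),
    if (unseen_donors > 0) sprintf("unseen%d", seq_len(unseen_donors))
  )
  rows <- expand.grid(
    crop_index = seq_len(crops_per_combo),
    ratio = ratios,
    donor_id = all_donors,
    stringsAsFactors = FALSE
  )
  man <- tibble::tibble(
    example_id = sprintf("%s_r%d_c%03d", rows$donor_id,
                         as.integer(rows$ratio), rows$crop_index),
    donor_id = rows$donor_id,
    ratio = rows$ratio,
    crop_index = rows$crop_index,
    split = ifelse(grepl("^unseen", rows$donor_id), "unseen", NA_character_)
  )
  attr(man, "crop_size") <- as.integer(crop_size)
  attr(man, "seed") <- as.integer(seed)
  split_manifest(man, seed = seed)
}

#' Generate a rendered synthetic dataset
#'
#' Runs the full simulated acquisition for every field of the plan: sample
#' a cell field, synthesize the sample and reference holograms (with a
#' polynomial aberration and sensor noise), reconstruct the
#' aberration-corrected phase, build the 3-channel input stack, render and
#' segment the fluorescence, compose the stain target, and crop
#' co-registered training pairs. All image channels are written as 32-bit
#' float TIFF, masks as 8-bit TIFF, and the manifest (with a generation
#' parameter snapshot) as JSON.
#'
#' @inheritParams plan_dataset
#' @param out_dir output directory.
#' @param cfg an [optical_config()]; its `sensor_shape` is the field size.
#' @param cells_per_field cells per field.
#' @param fields_per_combo fields each (donor, ratio) pool of crops is drawn
#'   from; defaults to one field per 10 crops.
#' @param noise_sigma hologram sensor-noise sd.
#' @param aberration_coefs polynomial aberration coefficients
#'   (see [make_aberration()]).
#' @param spec_args extra arguments for [cell_population_spec()].
#' @param settings a [recon_settings()] for reconstruction.
#' @param verbose print progress.
#' @return the rendered manifest tibble (invisibly written to
#'   `out_dir/manifest.json`), with file-path columns filled in.
#' @export
generate_dataset <- function(out_dir, donors = 5L, unseen_donors = 2L,
                             ratios = c(10, 50, 1000),
                             crops_per_combo = 100L,
                             crop_size = 128L,
                             cfg = optical_config(),
                             cells_per_field = 72L,
                             fields_per_combo = NULL,
                             noise_sigma = 0.02,
                             aberration_coefs = c(tilt_x = 0.4, tilt_y = -0.25,
                                                  defocus = 0.6, astig_0 = 0.2,
                                                  astig_45 = 0.1),
                             spec_args = list(),
                             settings = recon_settings(),
                             seed = 1L, verbose = FALSE) {
  man <- plan_dataset(donors, unseen_donors, ratios, crops_per_combo,
                      crop_size, seed)
  dir.create(file.path(out_dir, "fields"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "crops"), recursive = TRUE, showWarnings = FALSE)
  if (is.null(fields_per_combo)) {
    fields_per_combo <- max(1L, ceiling(crops_per_combo / 10))
  }
  n <- nrow(man)
  man$path_gx <- man$path_gy <- man$path_phase <- NA_character_
  man$path_target <- man$path_mask <- man$path_fluo <- NA_character_
  man$path_cells <- NA_character_
  man$field_id <- NA_character_
  man$crop_row <- man$crop_col <- NA_integer_

  aber <- make_aberration(cfg$sensor_shape, aberration_coefs)
  combos <- unique(man[, c("donor_id", "ratio")])
  combo_seed <- 0L
  for (ci in seq_len(nrow(combos))) {
    d <- combos$donor_id[ci]; rt <- combos$ratio[ci]
    rows <- which(man$donor_id == d & man$ratio == rt)
    spec <- do.call(cell_population_spec, utils::modifyList(
      list(ratio_pbmc_to_tumor = rt, cells_per_field = cells_per_field,
           donor_id = d, seed = seed),
      spec_args
    ))
    # distribute this combo's crops over its fields
    assign_field <- rep(seq_len(fields_per_combo),
                        length.out = length(rows))
    for (fi in seq_len(fields_per_combo)) {
      combo_seed <- combo_seed + 1L
      fseed <- (seed * 10000L + combo_seed * 17L) %% 2147483647L
      frows <- rows[assign_field == fi]
      if (length(frows) == 0) next
      field <- sample_cell_field(spec, cfg, seed = fseed)
      field$field_id <- sprintf("%s_r%d_f%d", d, as.integer(rt), fi)
      if (verbose) message("field ", field$field_id)
      holo <- synthesize_hologram(field, cfg, aberration = aber,
                                  noise_sigma = noise_sigma, seed = fseed + 1L)
      ref <- synthesize_reference_hologram(cfg, aberration = aber,
                                           noise_sigma = noise_sigma,
                                           seed = fseed + 2L)
      pm <- reconstruct_phase(holo, ref, cfg, settings)
      stack <- gradient_channels(pm)
      fluo <- render_fluorescence(field, seed = fseed + 3L)
      mask <- suppressWarnings(fluo_to_mask(fluo))
      target <- compose_target(pm, mask)

      fbase <- file.path(out_dir, "fields", field$field_id)
      writeTIFF32(fluo$image / max(1, max(fluo$image)), paste0(fbase, "_fluo.tif"))
      tiff::writeTIFF(mask * 1, paste0(fbase, "_mask.tif"), bits.per.sample = 8L)
      cells_path <- paste0(fbase, "_cells.json")
      jsonlite::write_json(field$cells, cells_path, digits = NA)

      crops <- crop_pairs(stack, target, size = crop_size,
                          n = length(frows), seed = fseed + 4L)
      for (k in seq_along(frows)) {
        i <- frows[k]
        cr <- crops[[k]]
        base <- file.path(out_dir, "crops", man$example_id[i])
        writeTIFF32(cr$input[, , 1], paste0(base, "_gx.tif"))
        writeTIFF32(cr$input[, , 2], paste0(base, "_gy.tif"))
        writeTIFF32(cr$input[, , 3], paste0(base, "_phase.tif"))
        writeTIFF32(cr$target, paste0(base, "_target.tif"))
        tiff::writeTIFF(cr$mask * 1, paste0(base, "_mask.tif"),
                        bits.per.sample = 8L)
        man$path_gx[i] <- paste0(base, "_gx.tif")
        man$path_gy[i] <- paste0(base, "_gy.tif")
        man$path_phase[i] <- paste0(base, "_phase.tif")
        man$path_target[i] <- paste0(base, "_target.tif")
        man$path_mask[i] <- paste0(base, "_mask.tif")
        man$path_fluo[i] <- paste0(fbase, "_fluo.tif")
        man$path_cells[i] <- cells_path
        man$field_id[i] <- field$field_id
        man$crop_row[i] <- cr$origin["row"]
        man$crop_col[i] <- cr$origin["col"]
      }
    }
  }
  attr(man, "crop_size") <- as.integer(crop_size)
  attr(man, "seed") <- as.integer(seed)
  attr(man, "params") <- list(
    donors = donors, unseen_donors = unseen_donors, ratios = ratios,
    crops_per_combo = crops_per_combo, crop_size = crop_size,
    cells_per_field = cells_per_field, fields_per_combo = fields_per_combo,
    noise_sigma = noise_sigma, sensor_shape = cfg$sensor_shape, seed = seed
  )
  write_manifest(man, file.path(out_dir, "manifest.json"))
  man
}

writeTIFF32 <- function(x, path) {
  x <- pmin(pmax(x, 0), 1)
  ok <- tiff::writeTIFF(x, path, bits.per.sample = 32L)
  if (!ok) stop("failed to write ", path)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' Manifests are JSON files with a schema version, the generation-parameter
#' snapshot and the entry table.
#'
#' @param man manifest tibble.
#' @param path JSON path.
#' @return `read_manifest()` returns the manifest tibble.
#' @export
write_manifest <- function(man, path) {
  jsonlite::write_json(
    list(schema = "holostain-manifest-1",
         crop_size = attr(man, "crop_size"),
         seed = attr(man, "seed"),
         params = attr(man, "params"),
         entries = man),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "holostain-manifest-1")) {
    stop("not a holostain manifest: ", path)
  }
  man <- tibble::as_tibble(j$entries)
  attr(man, "crop_size") <- j$crop_size
  attr(man, "seed") <- j$seed
  attr(man, "params") <- j$params
  man
}

#' Load one training example from a manifest entry
#'
#' Reads the input channels, target and mask, and derives the crop-frame
#' ground-truth cell records (cells whose centroid falls inside the crop,
#' shifted to crop coordinates).
#'
#' @param entry one manifest row (with rendered file paths).
#' @return a `training_example` with an extra `truth_cells` tibble.
#' @export
load_example <- function(entry) {
  stopifnot(nrow(entry) == 1, !is.na(entry$path_gx))
  rd <- function(p) {
    m <- tiff::readTIFF(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  }
  gx <- rd(entry$path_gx); gy <- rd(entry$path_gy); ph <- rd(entry$path_phase)
  input <- array(c(gx, gy, ph), c(dim(gx), 3L))
  target <- rd(entry$path_target)
  mask <- rd(entry$path_mask) > 0.5
  cells <- tibble::as_tibble(jsonlite::read_json(entry$path_cells,
                                                 simplifyVector = TRUE))
  size <- nrow(target)
  r0 <- entry$crop_row; c0 <- entry$crop_col
  inside <- cells$y >= r0 & cells$y < r0 + size &
    cells$x >= c0 & cells$x < c0 + size
  tc <- cells[inside, , drop = FALSE]
  tc$x <- tc$x - c0 + 1
  tc$y <- tc$y - r0 + 1
  structure(
    list(input = input, target = target, mask = mask,
         origin = c(row = r0, col = c0),
         truth_cells = tc, example_id = entry$example_id),
    class = "training_example"
  )
}

#' Load all examples of a split
#'
#' @param manifest rendered manifest tibble.
#' @param split split label.
#' @return list of `training_example`s.
#' @export
load_split <- function(manifest, split) {
  rows <- which(manifest$split == split)
  if (length(rows) == 0) stop("split '", split, "' is empty")
  lapply(rows, function(i) load_example(manifest[i, ]))
}
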