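# shared fixtures: small optical configs and fields keep the suite fast;
# physics scales with the pixel pitch, not the pixel count

small_cfg <- function(side = 256L, ...) {
  optical_config(sensor_shape = c(side, side), ...)
}

small_spec <- function(ratio = 10, cells = 18L, donor = "dT", seed = 2L, ...) {
  cell_population_spec(ratio_pbmc_to_tumor = ratio, cells_per_field = cells,
                       donor_id = donor, seed = seed, ...)
}

# a demodulated field from a freshly simulated hologram
demod_field <- function(field, cfg, aberration = NULL, noise = 0, seed = 1L,
                        settings = recon_settings()) {
  holo <- synthesize_hologram(field, cfg, aberration = aberration,
                              noise_sigma = noise, seed = seed)
  demodulate_offaxis(holo, cfg, settings)
}

# tiny rendered dataset for IO/pipeline tests (built once per test run)
micro_dataset <- function(dir, donors = 1L, ratios = 5, crops = 5L,
                          crop_size = 64L, side = 256L, cells = 12L,
                          seed = 3L) {
  generate_dataset(
    dir, donors = donors, unseen_donors = 0L, ratios = ratios,
    crops_per_combo = crops, crop_size = crop_size,
    cfg = optical_config(sensor_shape = c(side, side)),
    cells_per_field = cells, seed = seed
  )
}
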