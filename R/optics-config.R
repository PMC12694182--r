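#' Optical configuration of the off-axis holographic microscope
#'
#' Bundles the physical parameters shared by the hologram simulator and the
#' reconstruction code: illumination wavelength, objective magnification and
#' numerical aperture, camera geometry and the off-axis carrier frequency of
#' the tilted reference beam. The defaults describe a 532 nm laser, a 20x /
#' 0.50 NA objective and a 5.5 um-pixel sensor, giving an object-plane pixel
#' pitch of 0.275 um.
#'
#' The off-axis carrier must separate the +1 interference order from the DC
#' term and its twin: with `b` the validation band radius (cycles/pixel) the
#' constructor enforces `b < |f|` and `|f| + b < 0.5`. At these optics the
#' NA-limited cutoff (`NA * pitch / wavelength`, about 0.259 cycles/pixel)
#' is too wide for any carrier to satisfy that on this sensor, so the
#' validation/windowing band radius defaults to
#' `min(NA * pitch / wavelength, 0.15)`: the smooth cell phase profiles the
#' simulator emits are band-limited far below the NA cutoff.
#'
#' @param wavelength illumination wavelength in meters.
#' @param magnification objective magnification (dimensionless).
#' @param numerical_aperture objective NA.
#' @param camera_pixel physical sensor pixel size in meters.
#' @param sensor_shape integer vector `c(rows, cols)` of the sensor;
#'   512 x 512 is a convenient desk-scale default, 2048 x 2048 the full
#'   sensor.
#' @param carrier reference-tilt carrier frequency `c(fx, fy)` in
#'   cycles/pixel; `fy` must be positive (the auto carrier search looks in
#'   the upper frequency half-plane).
#' @param defocus_z defocus between object and reconstruction plane, meters
#'   (object-side coordinates).
#' @param bit_depth 0 stores holograms as floats; a positive value quantizes
#'   them to that many bits.
#' @param band_radius validation/demodulation band radius in cycles/pixel,
#'   or `NULL` for the default described above.
#'
#' @return an object of class `optical_config` with derived fields `pitch`
#'   (object-plane meters/pixel) and `band_radius`.
#' @export
#' @examples
#' cfg <- optical_config(sensor_shape = c(256, 256))
#' cfg$pitch # 2.75e-07
optical_config <- function(wavelength = 532e-9,
                           magnification = 20,
                           numerical_aperture = 0.50,
                           camera_pixel = 5.5e-6,
                           sensor_shape = c(512L, 512L),
                           carrier = c(0.23, 0.23),
                           defocus_z = 0,
                           bit_depth = 0L,
                           band_radius = NULL) {
  stopifnot(
    wavelength > 0, magnification > 0, camera_pixel > 0,
    numerical_aperture > 0,
    length(sensor_shape) == 2, all(sensor_shape >= 16),
    length(carrier) == 2, is.finite(defocus_z), bit_depth >= 0
  )
  pitch <- camera_pixel / magnification
  # snap the carrier to the DFT grid of this sensor so simulated fringes are
  # periodic on the frame (no spectral leakage of the +1 order)
  carrier <- round(carrier * rev(sensor_shape)) / rev(sensor_shape)
  na_band <- numerical_aperture * pitch / wavelength
  if (is.null(band_radius)) band_radius <- min(na_band, 0.15)
  stopifnot(band_radius > 0)
  fmag <- sqrt(sum(carrier^2))
  if (!(band_radius < fmag && fmag + band_radius < 0.5)) {
    stop(
      "carrier |f| = ", signif(fmag, 4),
      " does not separate the +1 order: need band_radius < |f| and ",
      "|f| + band_radius < 0.5 with band_radius = ", signif(band_radius, 4)
    )
  }
  if (carrier[2] <= 0) {
    stop("carrier fy must be positive (upper half-plane convention)")
  }
  structure(
    list(
      wavelength = wavelength,
      magnification = magnification,
      numerical_aperture = numerical_aperture,
      camera_pixel = camera_pixel,
      sensor_shape = as.integer(sensor_shape),
      carrier = as.numeric(carrier),
      defocus_z = defocus_z,
      bit_depth = as.integer(bit_depth),
      pitch = pitch,
      na_band_radius = na_band,
      band_radius = band_radius
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat(
    "<optical_config> ", x$sensor_shape[1], "x", x$sensor_shape[2],
    " px, lambda ", x$wavelength * 1e9, " nm, ",
    x$magnification, "x / NA ", x$numerical_aperture,
    ", pitch ", signif(x$pitch * 1e6, 4), " um, carrier (",
    x$carrier[1], ", ", x$carrier[2], ") cyc/px\n",
    sep = ""
  )
  invisible(x)
}

#' Cell population of a simulated liquid-cytology field
#'
#' Describes the mixture of abundant small low-phase PBMC-like cells and
#' rare large high-phase tumor-like (HCT116-like) cells smeared on one
#' field. The PBMC:tumor mixing ratio follows the acquisition campaign
#' (10:1, 50:1 and 1000:1). Cell radii are in micrometers and peak optical
#' phase in radians; the tumor peak phase must stay below pi so that the
#' reconstructed phase never wraps.
#'
#' @param ratio_pbmc_to_tumor PBMC:tumor mixing ratio (>= 1).
#' @param cells_per_field number of cells on the field; 200 matches the
#'   full 2048 px sensor, desk-scale fields use proportionally fewer.
#' @param pbmc_radius,tumor_radius radius ranges `c(min, max)` in um.
#' @param pbmc_peak_phase,tumor_peak_phase peak-phase ranges in radians.
#' @param adhesion_prob probability that a newly placed cell is set tangent
#'   to an existing one, producing adherent clusters.
#' @param donor_id donor label; together with `seed` it fixes the donor's
#'   biological jitter.
#' @param donor_jitter multiplicative log-normal spread applied per donor to
#'   the radius and phase ranges.
#' @param seed integer seed for the per-donor jitter draw.
#' @return an object of class `cell_population_spec`.
#' @export
cell_population_spec <- function(ratio_pbmc_to_tumor = 10,
                                 cells_per_field = 200L,
                                 pbmc_radius = c(3.5, 5.0),
                                 tumor_radius = c(7.0, 12.0),
                                 pbmc_peak_phase = c(0.6, 1.2),
                                 tumor_peak_phase = c(1.8, 2.8),
                                 adhesion_prob = 0.15,
                                 donor_id = "donor1",
                                 donor_jitter = 0.1,
                                 seed = 1L) {
  ordered_pos <- function(r) length(r) == 2 && r[1] > 0 && r[1] <= r[2]
  stopifnot(
    ratio_pbmc_to_tumor >= 1, cells_per_field >= 1,
    ordered_pos(pbmc_radius), ordered_pos(tumor_radius),
    ordered_pos(pbmc_peak_phase), ordered_pos(tumor_peak_phase),
    adhesion_prob >= 0, adhesion_prob <= 1, donor_jitter >= 0
  )
  if (tumor_peak_phase[2] >= pi) {
    stop("tumor peak phase must stay below pi to keep reconstruction wrap-free")
  }
  structure(
    list(
      ratio_pbmc_to_tumor = ratio_pbmc_to_tumor,
      cells_per_field = as.integer(cells_per_field),
      pbmc_radius = pbmc_radius,
      tumor_radius = tumor_radius,
      pbmc_peak_phase = pbmc_peak_phase,
      tumor_peak_phase = tumor_peak_phase,
      adhesion_prob = adhesion_prob,
      donor_id = donor_id,
      donor_jitter = donor_jitter,
      seed = as.integer(seed)
    ),
    class = "cell_population_spec"
  )
}

# deterministic small integer hash of a string (for donor-level seeds)
string_seed <- function(s) {
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
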