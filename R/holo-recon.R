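#' Complex optical field
#'
#' The unit of all propagation and demodulation steps: a 2D complex
#' amplitude with its physical object-plane pixel pitch, wavelength, and the
#' propagation state `z_offset` (meters still to be refocused).
#'
#' @param field complex matrix.
#' @param pitch object-plane pixel pitch in meters.
#' @param wavelength illumination wavelength in meters.
#' @param z_offset current propagation state in meters.
#' @return an object of class `complex_field`.
#' @export
complex_field <- function(field, pitch, wavelength, z_offset = 0) {
  stopifnot(is.matrix(field), pitch > 0, wavelength > 0, is.finite(z_offset))
  if (!is.complex(field)) field <- field + 0i
  if (!all(is.finite(Re(field))) || !all(is.finite(Im(field)))) {
    stop("complex field contains non-finite entries")
  }
  structure(
    list(field = field, pitch = pitch, wavelength = wavelength,
         z_offset = z_offset),
    class = "complex_field"
  )
}

#' Reconstruction settings
#'
#' @param filter_radius demodulation window radius in cycles/pixel; 0 uses
#'   the config's band radius.
#' @param carrier_mode `"auto-peak"` locates the +1 order as the strongest
#'   spectral peak outside the DC-exclusion disk in the upper half-plane;
#'   `"explicit"` uses `carrier` (rounded to the DFT grid).
#' @param carrier explicit carrier `c(fx, fy)` in cycles/pixel (used when
#'   `carrier_mode = "explicit"`).
#' @param z_search autofocus search `list(z_min, z_max, coarse_step,
#'   refinement_levels)` in meters.
#' @param focus_metric one of `"neg_variance_amplitude"` (default: the
#'   specimens are near-pure phase objects, whose amplitude is flattest at
#'   focus, making negative amplitude variance a sharp and exact focus
#'   score), `"tenengrad_phase"` (mean squared gradient magnitude of the
#'   phase), or `"tamura_amplitude"`.
#' @param window `"hard_disk"` or `"gaussian_soft"` order-selection window.
#' @return an object of class `recon_settings`.
#' @export
recon_settings <- function(filter_radius = 0,
                           carrier_mode = c("auto-peak", "explicit"),
                           carrier = NULL,
                           z_search = list(z_min = -100e-6, z_max = 100e-6,
                                           coarse_step = 10e-6,
                                           refinement_levels = 1L),
                           focus_metric = c("neg_variance_amplitude",
                                            "tenengrad_phase",
                                            "tamura_amplitude"),
                           window = c("hard_disk", "gaussian_soft")) {
  carrier_mode <- match.arg(carrier_mode)
  focus_metric <- match.arg(focus_metric)
  window <- match.arg(window)
  stopifnot(
    filter_radius >= 0,
    z_search$z_min < z_search$z_max,
    z_search$coarse_step > 0,
    z_search$refinement_levels >= 0
  )
  if (carrier_mode == "explicit" && is.null(carrier)) {
    stop("explicit carrier_mode needs a carrier")
  }
  structure(
    list(filter_radius = filter_radius, carrier_mode = carrier_mode,
         carrier = carrier, z_search = z_search,
         focus_metric = focus_metric, window = window),
    class = "recon_settings"
  )
}

#' Demodulate an off-axis hologram
#'
#' Computes the hologram spectrum, locates the +1 interference order (auto:
#' strongest peak outside a DC-exclusion disk of radius twice the band
#' radius, in the half-plane `fy > 0`; ties broken by magnitude then
#' lexicographic frequency order), windows it, shifts it to baseband and
#' inverse-transforms, recovering the complex object wave.
#'
#' @param hologram real non-constant matrix.
#' @param cfg an [optical_config()].
#' @param settings a [recon_settings()].
#' @return a [complex_field()] with `z_offset = cfg$defocus_z`.
#' @export
demodulate_offaxis <- function(hologram, cfg, settings = recon_settings()) {
  stopifnot(is.matrix(hologram), is.numeric(hologram))
  if (max(hologram) == min(hologram)) stop("hologram is constant")
  nr <- nrow(hologram); nc <- ncol(hologram)
  S <- fft2(hologram)
  fg <- freq_grids(nr, nc)
  fmag2 <- fg$fx^2 + fg$fy^2

  if (settings$carrier_mode == "explicit") {
    # snap to the DFT grid so explicit and auto agree on clean input
    ic <- round(settings$carrier[1] * nc) %% nc
    ir <- round(settings$carrier[2] * nr) %% nr
    pr <- ir + 1L; pc <- ic + 1L
  } else {
    excl <- 2 * cfg$band_radius
    cand <- (fg$fy > 0) & (sqrt(fmag2) > excl)
    if (!any(cand)) stop("no carrier found: exclusion disk covers half-plane")
    mag <- Mod(S)
    mag[!cand] <- -Inf
    # order: magnitude desc, then fy, then fx (lexicographic tie-break)
    best <- max(mag)
    noise_floor <- stats::median(Mod(S)[cand])
    if (best < 10 * noise_floor) stop("no carrier found above the noise floor")
    hits <- which(mag == best, arr.ind = TRUE)
    if (nrow(hits) > 1) {
      key <- order(fg$fy[hits], fg$fx[hits])
      hits <- hits[key, , drop = FALSE]
    }
    pr <- hits[1, 1]; pc <- hits[1, 2]
  }
  pfx <- fg$fx[pr, pc]; pfy <- fg$fy[pr, pc]

  radius <- if (settings$filter_radius > 0) settings$filter_radius else cfg$band_radius
  # distance from the peak on the frequency torus
  dfx <- wrap_freq(fg$fx - pfx)
  dfy <- wrap_freq(fg$fy - pfy)
  d <- sqrt(dfx^2 + dfy^2)
  clip <- radius + sqrt(pfx^2 + pfy^2) > 0.5
  if (clip) {
    warning("demodulation window clipped by the Nyquist limit")
  }
  W <- if (settings$window == "hard_disk") {
    (d <= radius) * 1
  } else {
    exp(-0.5 * (d / (radius / 2))^2)
  }
  Sw <- S * W
  # shift the +1 order to baseband
  Sb <- roll2(Sw, -(pr - 1L), -(pc - 1L))
  complex_field(ifft2(Sb), pitch = cfg$pitch, wavelength = cfg$wavelength,
                z_offset = cfg$defocus_z)
}

wrap_freq <- function(f) ((f + 0.5) %% 1) - 0.5

#' Angular-spectrum propagation
#'
#' Propagates a complex field by distance `z` (meters):
#' `U(z) = IFT( FT(U) * exp(i 2 pi z sqrt(1/lambda^2 - fx^2 - fy^2)) )`,
#' with evanescent components (spatial frequencies beyond `1/lambda`)
#' zeroed. Exact (non-paraxial) scalar propagation; unitary on the
#' propagating band, so `propagate(z)` then `propagate(-z)` restores the
#' field, and `z = 0` is the identity.
#'
#' @param field a [complex_field()].
#' @param z propagation distance in meters (positive toward the source).
#' @return the propagated [complex_field()], `z_offset` decremented by `z`.
#' @export
angular_spectrum_propagate <- function(field, z) {
  stopifnot(inherits(field, "complex_field"), is.finite(z))
  if (z == 0) return(field)
  nr <- nrow(field$field); nc <- ncol(field$field)
  fg <- freq_grids(nr, nc)
  fm2 <- (fg$fx / field$pitch)^2 + (fg$fy / field$pitch)^2 # cycles^2 / m^2
  arg <- 1 / field$wavelength^2 - fm2
  H <- matrix(0 + 0i, nr, nc)
  prop <- arg >= 0
  H[prop] <- exp(1i * 2 * pi * z * sqrt(arg[prop]))
  complex_field(
    ifft2(fft2(field$field) * H),
    pitch = field$pitch, wavelength = field$wavelength,
    z_offset = field$z_offset - z
  )
}

#' Numerical autofocus
#'
#' Scans propagation distances over a coarse grid, then refines around the
#' argmax (one decade finer per refinement level), and returns the distance
#' maximizing the focus metric. Ties break toward the smallest `|z|`.
#'
#' @param field a [complex_field()] as returned by [demodulate_offaxis()].
#' @param settings a [recon_settings()]; `z_search` sets the grid and
#'   `focus_metric` the sharpness score.
#' @return list with `z_best` (meters), `metric_curve` (tibble of z, score),
#'   and `boundary_warning` (TRUE if the argmax sat on the search boundary).
#' @export
autofocus <- function(field, settings = recon_settings()) {
  zs <- settings$z_search
  grid <- seq(zs$z_min, zs$z_max, by = zs$coarse_step)
  score <- vapply(grid, function(z) focus_score(field, z, settings$focus_metric),
                  numeric(1))
  all_z <- grid; all_s <- score
  pick <- function(z, s) {
    best <- max(s)
    cand <- z[s >= best - 1e-15 * abs(best)]
    cand[which.min(abs(cand))]
  }
  z_best <- pick(grid, score)
  boundary <- abs(z_best - zs$z_min) < zs$coarse_step / 2 ||
    abs(z_best - zs$z_max) < zs$coarse_step / 2
  step <- zs$coarse_step
  if (zs$refinement_levels > 0) {
    for (lev in seq_len(zs$refinement_levels)) {
      fine <- seq(z_best - step, z_best + step, by = step / 10)
      fs <- vapply(fine, function(z) focus_score(field, z, settings$focus_metric),
                   numeric(1))
      all_z <- c(all_z, fine); all_s <- c(all_s, fs)
      z_best <- pick(fine, fs)
      step <- step / 10
    }
  }
  if (boundary) warning("autofocus argmax at search boundary; widen z_search")
  list(
    z_best = z_best,
    metric_curve = tibble::tibble(z = all_z, score = all_s),
    boundary_warning = boundary
  )
}

focus_score <- function(field, z, metric) {
  u <- angular_spectrum_propagate(field, z)$field
  switch(metric,
    tenengrad_phase = {
      ph <- Arg(u)
      gx <- ph[, -1] - ph[, -ncol(ph)]
      gy <- ph[-1, ] - ph[-nrow(ph), ]
      mean(gx^2) + mean(gy^2)
    },
    tamura_amplitude = {
      a <- Mod(u)
      sqrt(stats::sd(a) / mean(a))
    },
    neg_variance_amplitude = {
      a <- Mod(u)
      -stats::var(as.vector(a))
    }
  )
}

#' Reference-based phase aberration correction
#'
#' Subtracts the background phase recorded in a sample-free reference
#' reconstruction. Implemented as the argument of the complex ratio
#' `sample * conj(reference) / max(|reference|, eps)` rather than a literal
#' phase subtraction, which is robust to 2 pi wraps of the difference.
#'
#' @param sample,reference [complex_field()]s demodulated with identical
#'   settings and matching shapes.
#' @return an object of class `phase_map`: list with `phase` (radians, in
#'   `(-pi, pi]`), `pitch`, and `provenance`.
#' @export
correct_aberration <- function(sample, reference) {
  stopifnot(inherits(sample, "complex_field"), inherits(reference, "complex_field"))
  if (!all(dim(sample$field) == dim(reference$field))) {
    stop("sample and reference shapes differ")
  }
  amp <- Mod(reference$field)
  weak <- mean(amp < 1e-6 * max(amp))
  if (weak > 0.01) {
    warning("reference amplitude near zero over ", round(100 * weak, 1),
            "% of pixels")
  }
  ph <- Arg(sample$field * Conj(reference$field) / pmax(amp, 1e-12))
  phase_map(ph, pitch = sample$pitch,
            provenance = list(z_offset = sample$z_offset,
                              aberration_corrected = TRUE))
}

#' Quantitative phase map
#'
#' @param phase phase matrix in radians.
#' @param pitch object-plane pitch in meters/pixel.
#' @param provenance free-form list (source hologram id, z used, flags).
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(phase, pitch = NA_real_, provenance = list()) {
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  structure(list(phase = phase, pitch = pitch, provenance = provenance),
            class = "phase_map")
}

#' Full reconstruction of a sample/reference hologram pair
#'
#' Demodulates both holograms, autofocuses the sample, propagates both to
#' the focal plane and corrects aberration by complex-ratio subtraction.
#'
#' @param hologram,reference sample and sample-free hologram matrices.
#' @param cfg an [optical_config()].
#' @param settings a [recon_settings()].
#' @param refocus if `FALSE`, skip autofocus and use `-cfg$defocus_z`.
#' @return a `phase_map` with `z_used` in its provenance.
#' @export
reconstruct_phase <- function(hologram, reference, cfg,
                              settings = recon_settings(), refocus = TRUE) {
  s <- demodulate_offaxis(hologram, cfg, settings)
  r <- demodulate_offaxis(reference, cfg, settings)
  z <- if (refocus && cfg$defocus_z != 0) {
    autofocus(s, settings)$z_best
  } else if (refocus) 0 else -cfg$defocus_z
  if (z != 0) {
    s <- angular_spectrum_propagate(s, z)
    r <- angular_spectrum_propagate(r, z)
  }
  pm <- correct_aberration(s, r)
  pm$provenance$z_used <- z
  pm
}
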