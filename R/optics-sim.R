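#' Sample a synthetic liquid-cytology field
#'
#' Places `cells_per_field` non-overlapping cells on the field, with
#' `max(1, round(cells_per_field / (ratio + 1)))` of them tumor cells and the
#' rest PBMCs, and renders each as a smooth spherical-cap phase profile
#' `peak_phase * sqrt(max(0, 1 - (d/r)^2))`. Overlapping profiles would sum,
#' but placement keeps footprints disjoint (adherent cells are tangent) so the
#' total phase stays below pi and the downstream reconstruction never wraps.
#' With probability `adhesion_prob` a cell is placed touching an existing one,
#' reproducing the adherent clusters that are the hard case for phase-only
#' staining.
#'
#' Donor-level biology is emulated by a per-donor multiplicative log-normal
#' jitter (sd `donor_jitter`) on the radius and phase ranges, drawn
#' deterministically from `spec$seed` and `spec$donor_id`; field-level
#' randomness comes from `seed` alone, so the same `(spec, cfg, seed)` always
#' reproduces the field bit for bit.
#'
#' @param spec a [cell_population_spec()].
#' @param cfg an [optical_config()]; the field shape is `cfg$sensor_shape`
#'   and cell sizes are converted to pixels with `cfg$pitch`.
#' @param seed integer seed for cell placement.
#' @return an object of class `ground_truth_field`: a list with `cells`
#'   (tibble of kind, x, y, radius_px, peak_phase), `phase` (radians),
#'   `cancer_mask` (logical matrix), `donor_id`, `ratio`, `field_id`.
#' @export
sample_cell_field <- function(spec, cfg, seed = 1L) {
  stopifnot(inherits(spec, "cell_population_spec"), inherits(cfg, "optical_config"))
  nr <- cfg$sensor_shape[1]; nc <- cfg$sensor_shape[2]
  px <- cfg$pitch * 1e6 # um per pixel

  donor_seed <- (string_seed(spec$donor_id) + 7919L * spec$seed) %% 2147483647L
  jit <- with_seed(donor_seed, stats::rnorm(2, 0, spec$donor_jitter))
  r_fac <- exp(jit[1]); p_fac <- exp(jit[2])
  # keep the wrap-free guarantee under jitter
  p_cap <- (pi - 1e-3) / spec$tumor_peak_phase[2]
  p_fac <- min(p_fac, p_cap)

  n_tumor <- max(1L, as.integer(round(spec$cells_per_field /
    (spec$ratio_pbmc_to_tumor + 1))))
  n_pbmc <- spec$cells_per_field - n_tumor
  kinds <- c(rep("TUMOR", n_tumor), rep("PBMC", n_pbmc))

  with_seed(seed, {
    draw <- function(rng, fac) stats::runif(1, rng[1], rng[2]) * fac
    xs <- ys <- rs <- ps <- numeric(0)
    for (k in kinds) {
      r_um <- if (k == "TUMOR") draw(spec$tumor_radius, r_fac) else draw(spec$pbmc_radius, r_fac)
      pk <- if (k == "TUMOR") draw(spec$tumor_peak_phase, p_fac) else draw(spec$pbmc_peak_phase, p_fac)
      r <- r_um / px
      if (2 * r + 2 > min(nr, nc)) {
        stop("could not place a cell of radius ", signif(r, 4),
             " px on a ", nr, "x", nc, " field: field too small")
      }
      placed <- FALSE
      adhere <- length(xs) > 0 && stats::runif(1) < spec$adhesion_prob
      for (try in seq_len(400L)) {
        if (adhere) {
          j <- sample.int(length(xs), 1)
          ang <- stats::runif(1, 0, 2 * pi)
          d <- rs[j] + r
          cx <- xs[j] + d * cos(ang); cy <- ys[j] + d * sin(ang)
          if (cx < 1 + r || cx > nc - r || cy < 1 + r || cy > nr - r) next
        } else {
          cx <- stats::runif(1, 1 + r, nc - r)
          cy <- stats::runif(1, 1 + r, nr - r)
        }
        ok <- TRUE
        if (length(xs) > 0) {
          dd <- sqrt((xs - cx)^2 + (ys - cy)^2)
          lim <- rs + r + if (adhere) -0.5 else 1
          if (adhere) {
            # tangent to cell j is allowed; no interpenetration elsewhere
            ok <- all(dd >= rs + r - 0.5)
          } else {
            ok <- all(dd >= lim)
          }
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        stop(
          "could not place ", length(xs) + 1, " of ", spec$cells_per_field,
          " cells on a ", nr, "x", nc, " field: field too small/dense ",
          "(cell radius ", signif(r, 4), " px)"
        )
      }
      xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r); ps <- c(ps, pk)
    }

    phase <- matrix(0, nr, nc)
    cancer_mask <- matrix(FALSE, nr, nc)
    for (i in seq_along(xs)) {
      prof <- cell_profile(nr, nc, xs[i], ys[i], rs[i], ps[i])
      phase[prof$rows, prof$cols] <- phase[prof$rows, prof$cols] + prof$patch
      if (kinds[i] == "TUMOR") {
        cancer_mask[prof$rows, prof$cols] <-
          cancer_mask[prof$rows, prof$cols] | (prof$patch > 0)
      }
    }

    structure(
      list(
        cells = tibble::tibble(
          kind = kinds, x = xs, y = ys, radius_px = rs, peak_phase = ps
        ),
        phase = phase,
        cancer_mask = cancer_mask,
        donor_id = spec$donor_id,
        ratio = spec$ratio_pbmc_to_tumor,
        field_id = sprintf("%s_r%d_s%d", spec$donor_id,
                           as.integer(spec$ratio_pbmc_to_tumor), as.integer(seed))
      ),
      class = "ground_truth_field"
    )
  })
}

# spherical-cap phase patch of one cell, clipped to the field
cell_profile <- function(nr, nc, cx, cy, r, peak) {
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  cols <- c0:c1; rows <- r0:r1
  dx <- outer(rep(1, length(rows)), cols - cx)
  dy <- outer(rows - cy, rep(1, length(cols)))
  d2 <- (dx^2 + dy^2) / r^2
  patch <- peak * sqrt(pmax(0, 1 - d2))
  list(rows = rows, cols = cols, patch = patch)
}

#' Polynomial background aberration map
#'
#' Sum of low-order 2D polynomials (piston, tilt, defocus, astigmatism) over
#' normalized coordinates in \[-1, 1\], standing in for the system-induced
#' background phase that reference-hologram correction removes.
#'
#' @param shape `c(rows, cols)`.
#' @param coefs named numeric vector with any of `piston`, `tilt_x`,
#'   `tilt_y`, `defocus`, `astig_0`, `astig_45` (radians at the field edge).
#' @return a phase matrix in radians.
#' @export
make_aberration <- function(shape, coefs = c(tilt_x = 0.4, tilt_y = -0.25,
                                             defocus = 0.6, astig_0 = 0.2,
                                             astig_45 = 0.1)) {
  nr <- shape[1]; nc <- shape[2]
  u <- matrix(seq(-1, 1, length.out = nc), nr, nc, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = nr), nr, nc)
  g <- function(name) if (name %in% names(coefs)) coefs[[name]] else 0
  g("piston") + g("tilt_x") * u + g("tilt_y") * v +
    g("defocus") * (u^2 + v^2) + g("astig_0") * (u^2 - v^2) +
    g("astig_45") * u * v
}

#' Synthesize an off-axis hologram of a field
#'
#' Forward model of the recording: the object wave `O = exp(i(phi + ab))` is
#' propagated by `cfg$defocus_z` with the angular-spectrum kernel, interfered
#' with a tilted unit-amplitude plane reference
#' `R = exp(i 2 pi (fx x + fy y))`, and the intensity `|O + R|^2` is recorded
#' with optional additive Gaussian noise and quantization.
#'
#' @param field a `ground_truth_field` (or a bare phase matrix).
#' @param cfg an [optical_config()] whose `sensor_shape` matches the field.
#' @param aberration background phase map in radians, or `NULL`.
#' @param noise_sigma sd of additive Gaussian intensity noise.
#' @param seed seed for the noise draw.
#' @return a numeric hologram matrix (non-negative).
#' @export
synthesize_hologram <- function(field, cfg, aberration = NULL,
                                noise_sigma = 0, seed = 1L) {
  phi <- if (inherits(field, "ground_truth_field")) field$phase else field
  stopifnot(is.matrix(phi), inherits(cfg, "optical_config"))
  if (!all(dim(phi) == cfg$sensor_shape)) {
    stop("field phase shape does not match cfg$sensor_shape")
  }
  if (!is.null(aberration)) {
    stopifnot(all(dim(aberration) == dim(phi)))
    phi <- phi + aberration
  }
  obj <- exp(1i * phi)
  if (cfg$defocus_z != 0) {
    cf <- complex_field(obj, pitch = cfg$pitch, wavelength = cfg$wavelength)
    obj <- angular_spectrum_propagate(cf, cfg$defocus_z)$field
  }
  nr <- nrow(phi); nc <- ncol(phi)
  xg <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yg <- matrix(0:(nr - 1), nr, nc)
  # negative tilt so the order carrying O (not its conjugate) lands at
  # +carrier in the upper frequency half-plane
  ref <- exp(-1i * 2 * pi * (cfg$carrier[1] * xg + cfg$carrier[2] * yg))
  holo <- Mod(obj + ref)^2
  if (noise_sigma > 0) {
    holo <- holo + with_seed(seed, matrix(stats::rnorm(length(holo), 0, noise_sigma), nr, nc))
  }
  holo <- pmax(holo, 0)
  if (cfg$bit_depth > 0) {
    full <- max(holo)
    levels <- 2^cfg$bit_depth - 1
    holo <- round(holo / full * levels) / levels * full
  }
  holo
}

#' Synthesize a sample-free reference hologram
#'
#' Identical to [synthesize_hologram()] with a flat object phase; the same
#' aberration map must be used as for the paired sample hologram so that
#' correction removes it.
#'
#' @inheritParams synthesize_hologram
#' @return a numeric hologram matrix.
#' @export
synthesize_reference_hologram <- function(cfg, aberration = NULL,
                                          noise_sigma = 0, seed = 1L) {
  synthesize_hologram(matrix(0, cfg$sensor_shape[1], cfg$sensor_shape[2]),
                      cfg, aberration, noise_sigma, seed)
}

#' Render a raw fluorescence image of a field
#'
#' Tumor footprints fluoresce at unit intensity; PBMC footprints pick up a
#' fraction `leakage_level` of that from excitation bleed-through. The scene
#' is blurred by a Gaussian PSF, offset by a uniform background and corrupted
#' by Gaussian noise, then clipped at zero - emulating the blurry edges and
#' background of real raw fluorescence.
#'
#' @param field a `ground_truth_field`.
#' @param psf_sigma Gaussian PSF sd in pixels (0 skips blurring).
#' @param background_level uniform background offset.
#' @param leakage_level PBMC bleed-through fraction.
#' @param noise_sigma sd of additive Gaussian noise.
#' @param seed seed for the noise draw.
#' @return an object of class `raw_fluorescence`: list with `image` and the
#'   parameters used.
#' @export
render_fluorescence <- function(field, psf_sigma = 2, background_level = 0.05,
                                leakage_level = 0.15, noise_sigma = 0.02,
                                seed = 1L) {
  stopifnot(
    inherits(field, "ground_truth_field"),
    psf_sigma >= 0, background_level >= 0, leakage_level >= 0, noise_sigma >= 0
  )
  nr <- nrow(field$phase); nc <- ncol(field$phase)
  img <- matrix(0, nr, nc)
  for (i in seq_len(nrow(field$cells))) {
    cl <- field$cells[i, ]
    prof <- cell_profile(nr, nc, cl$x, cl$y, cl$radius_px, 1)
    lvl <- if (cl$kind == "TUMOR") 1.0 else leakage_level
    img[prof$rows, prof$cols] <- pmax(img[prof$rows, prof$cols],
                                      lvl * (prof$patch > 0))
  }
  if (psf_sigma > 0) img <- gaussian_blur(img, psf_sigma)
  img <- img + background_level
  if (noise_sigma > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(nr * nc, 0, noise_sigma), nr, nc))
  }
  structure(
    list(
      image = pmax(img, 0),
      psf_sigma = psf_sigma, background_level = background_level,
      leakage_level = leakage_level, noise_sigma = noise_sigma
    ),
    class = "raw_fluorescence"
  )
}

# Gaussian blur with border-safe normalization (EBImage gblur pads internally)
gaussian_blur <- function(x, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(x), sigma = sigma))
}
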