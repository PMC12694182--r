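band_limited_field <- function(n, pitch, wavelength, seed = 1) {
  # random smooth complex field, strictly inside the propagating band
  withr::with_seed(seed, {
    spec <- matrix(0 + 0i, n, n)
    fg <- holostain:::freq_grids(n, n)
    keep <- sqrt(fg$fx^2 + fg$fy^2) < 0.2
    spec[keep] <- complex(real = rnorm(sum(keep)), imaginary = rnorm(sum(keep)))
    complex_field(holostain:::ifft2(spec), pitch, wavelength)
  })
}

test_that("angular-spectrum propagation is the identity at z = 0", {
  f <- band_limited_field(64, 0.275e-6, 532e-9)
  expect_identical(angular_spectrum_propagate(f, 0), f)
})

test_that("propagation is unitary and invertible on the propagating band", {
  f <- band_limited_field(64, 0.275e-6, 532e-9)
  e0 <- sum(Mod(f$field)^2)
  g <- angular_spectrum_propagate(f, 37e-6)
  expect_lt(abs(sum(Mod(g$field)^2) - e0) / e0, 1e-10)
  back <- angular_spectrum_propagate(g, -37e-6)
  expect_lt(max(Mod(back$field - f$field)), 1e-10)
  expect_equal(back$z_offset, f$z_offset)
})

test_that("propagation satisfies the semigroup property", {
  f <- band_limited_field(64, 0.275e-6, 532e-9, seed = 3)
  two_step <- angular_spectrum_propagate(
    angular_spectrum_propagate(f, 11e-6), 26e-6)
  one_step <- angular_spectrum_propagate(f, 37e-6)
  expect_lt(max(Mod(two_step$field - one_step$field)), 1e-10)
})

test_that("an on-axis plane wave picks up the global phase 2 pi z / lambda", {
  lam <- 532e-9
  f <- complex_field(matrix(1 + 0i, 32, 32), 0.275e-6, lam)
  z <- 20e-6
  g <- angular_spectrum_propagate(f, z)
  expected <- exp(1i * 2 * pi * z / lam)
  expect_lt(max(Mod(g$field - expected)), 1e-12)
})

test_that("propagated Gaussian aperture matches direct Fresnel quadrature", {
  n <- 48; pitch <- 1e-6; lam <- 532e-9; z <- 150e-6
  xs <- (0:(n - 1)) - (n - 1) / 2
  r2 <- outer(xs^2, xs^2, "+")
  U0 <- exp(-r2 / (2 * 3^2)) # sigma 3 px aperture
  prop <- angular_spectrum_propagate(complex_field(U0, pitch, lam), z)

  # independent oracle: direct quadrature of the Fresnel diffraction integral
  k <- 2 * pi / lam
  xm <- xs * pitch
  out <- matrix(0 + 0i, n, n)
  for (i in 1:n) {
    dy2 <- (xm[i] - xm)^2
    for (j in 1:n) {
      dx2 <- (xm[j] - xm)^2
      ker <- exp(1i * k / (2 * z) * outer(dy2, dx2, "+"))
      out[i, j] <- sum(U0 * ker)
    }
  }
  out <- out * exp(1i * k * z) / (1i * lam * z) * pitch^2
  expect_gt(stats::cor(as.vector(Mod(prop$field)^2), as.vector(Mod(out)^2)),
            0.999)
})

test_that("a pure carrier hologram demodulates to a flat unit field", {
  cfg <- small_cfg(128L)
  holo <- synthesize_hologram(matrix(0, 128, 128), cfg)
  f <- demodulate_offaxis(holo, cfg)
  interior <- f$field[11:118, 11:118]
  expect_lt(sqrt(mean(Arg(interior)^2)), 1e-6)
  expect_lt(max(abs(Mod(interior) - 1)), 1e-6)
})

test_that("demodulation recovers the object phase within the band limit", {
  cfg <- small_cfg(512L)
  fld <- sample_cell_field(small_spec(cells = 24L), cfg, seed = 11)
  f <- demod_field(fld, cfg)
  # compare against the band-limited rendering of the true phase
  fg <- holostain:::freq_grids(512, 512)
  W <- (sqrt(fg$fx^2 + fg$fy^2) <= cfg$band_radius) * 1
  phi_bl <- Re(holostain:::ifft2(holostain:::fft2(fld$phase) * W))
  expect_lt(sqrt(mean((Arg(f$field) - phi_bl)^2)), 0.01)
})

test_that("explicit carrier demodulation equals the auto-peak result", {
  cfg <- small_cfg(256L)
  fld <- sample_cell_field(small_spec(cells = 8L), cfg, seed = 2)
  holo <- synthesize_hologram(fld, cfg)
  auto <- demodulate_offaxis(holo, cfg, recon_settings())
  expl <- demodulate_offaxis(holo, cfg,
                             recon_settings(carrier_mode = "explicit",
                                            carrier = cfg$carrier))
  expect_identical(auto$field, expl$field)
})

test_that("demodulation refuses carrier-free input", {
  cfg <- small_cfg(128L)
  expect_error(demodulate_offaxis(matrix(1, 128, 128), cfg), "constant")
  withr::with_seed(1, {
    noise <- matrix(abs(rnorm(128 * 128, 1, 0.01)), 128, 128)
  })
  expect_error(demodulate_offaxis(noise, cfg), "no carrier")
})

test_that("autofocus recovers a known defocus to the refinement step", {
  cfg <- optical_config(sensor_shape = c(256, 256), defocus_z = 50e-6)
  fld <- sample_cell_field(small_spec(cells = 12L), cfg, seed = 2)
  dm <- demod_field(fld, cfg, noise = 0.01, seed = 7)
  st <- recon_settings(z_search = list(z_min = -200e-6, z_max = 200e-6,
                                       coarse_step = 10e-6,
                                       refinement_levels = 1L))
  af <- autofocus(dm, st)
  expect_lt(abs(af$z_best - (-50e-6)), 1e-6)
  expect_false(af$boundary_warning)
  # curve bookkeeping: coarse grid plus one refinement sweep
  expect_equal(nrow(af$metric_curve), 41L + 21L)

  # already-focused field: |z_best| within one coarse step
  cfg0 <- optical_config(sensor_shape = c(256, 256), defocus_z = 0)
  dm0 <- demod_field(sample_cell_field(small_spec(cells = 12L), cfg0, seed = 3),
                     cfg0)
  af0 <- autofocus(dm0, st)
  expect_lte(abs(af0$z_best), 10e-6)
})

test_that("autofocus recovers random defocus over many trials", {
  st <- recon_settings(z_search = list(z_min = -160e-6, z_max = 160e-6,
                                       coarse_step = 10e-6,
                                       refinement_levels = 1L))
  errs <- withr::with_seed(21, {
    zs <- runif(20, -150e-6, 150e-6)
    vapply(seq_along(zs), function(i) {
      cfg <- optical_config(sensor_shape = c(256, 256), defocus_z = zs[i])
      fld <- sample_cell_field(small_spec(cells = 5L), cfg, seed = i)
      af <- suppressWarnings(autofocus(demod_field(fld, cfg, seed = i), st))
      abs(af$z_best + zs[i])
    }, numeric(1))
  })
  expect_lte(stats::median(errs), 1e-6) # refinement step: 1 um
})

test_that("aberration correction removes the reference phase exactly", {
  cfg <- small_cfg(128L)
  f <- band_limited_field(128, cfg$pitch, cfg$wavelength, seed = 5)
  self <- correct_aberration(f, f)
  expect_lt(max(abs(self$phase)), 1e-12)
  expect_error(
    correct_aberration(f, band_limited_field(64, cfg$pitch, cfg$wavelength)),
    "shape"
  )
})

test_that("an aberration-only pair corrects to a flat phase", {
  cfg <- small_cfg(256L)
  ab <- make_aberration(c(256, 256))
  holo <- synthesize_hologram(matrix(0, 256, 256), cfg, aberration = ab)
  ref <- synthesize_reference_hologram(cfg, aberration = ab)
  pm <- correct_aberration(demodulate_offaxis(holo, cfg),
                           demodulate_offaxis(ref, cfg))
  expect_lt(stats::sd(pm$phase), 0.01)
})

test_that("reference demodulation recovers the aberration map", {
  cfg <- small_cfg(256L)
  ab <- make_aberration(c(256, 256), c(tilt_x = 0.3, defocus = 0.4))
  ref <- synthesize_reference_hologram(cfg, aberration = ab)
  f <- demodulate_offaxis(ref, cfg)
  interior <- 21:236
  expect_lt(sqrt(mean((Arg(f$field)[interior, interior] -
                         ab[interior, interior])^2)), 0.01)
})

test_that("simulate-reconstruct round trip matches ground truth", {
  # at the acquisition-campaign density the full chain (aberration + noise +
  # autofocus-free reconstruction) recovers the phase to a few hundredths rad
  cfg <- small_cfg(512L)
  fld <- sample_cell_field(small_spec(cells = 13L), cfg, seed = 8)
  ab <- make_aberration(c(512, 512))
  holo <- synthesize_hologram(fld, cfg, aberration = ab)
  ref <- synthesize_reference_hologram(cfg, aberration = ab)
  pm <- reconstruct_phase(holo, ref, cfg)
  expect_lt(sqrt(mean((pm$phase - fld$phase)^2)), 0.02)
  expect_true(all(pm$phase > -pi & pm$phase <= pi))
})
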