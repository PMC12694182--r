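test_that("gradient channels equal the brute-force shift-subtract oracle", {
  withr::with_seed(14, {
    phi <- matrix(rnorm(40 * 32), 40, 32)
  })
  st <- gradient_channels(phi)
  # independent oracle: explicit pixel loops
  gx <- matrix(0, 40, 32); gy <- matrix(0, 40, 32)
  for (i in 1:40) for (j in 1:32) {
    if (j > 1) gx[i, j] <- phi[i, j] - phi[i, j - 1]
    if (i > 1) gy[i, j] <- phi[i, j] - phi[i - 1, j]
  }
  denorm <- function(k) {
    st$channels[, , k] * st$norm[[k]]$scale + st$norm[[k]]$offset
  }
  expect_equal(denorm(1), gx, tolerance = 1e-12)
  expect_equal(denorm(2), gy, tolerance = 1e-12)
  expect_equal(denorm(3), phi, tolerance = 1e-12)
  expect_true(all(st$channels >= 0 & st$channels <= 1))
})

test_that("gradient channels of constants and ramps are exact", {
  const <- gradient_channels(matrix(2.5, 16, 16))
  expect_equal(const$norm[[1]]$scale, 1) # degenerate range guard
  expect_true(all(const$channels[, , 1] == 0))
  expect_true(all(const$channels[, , 2] == 0))

  xg <- matrix(0:15, 16, 16, byrow = TRUE)
  yg <- matrix(0:15, 16, 16)
  ramp <- gradient_channels(0.3 * xg + 0.7 * yg)
  gx <- ramp$channels[, , 1] * ramp$norm[[1]]$scale + ramp$norm[[1]]$offset
  gy <- ramp$channels[, , 2] * ramp$norm[[2]]$scale + ramp$norm[[2]]$offset
  expect_true(all(abs(gx[, 2:16] - 0.3) < 1e-12))
  expect_true(all(abs(gy[2:16, ] - 0.7) < 1e-12))
  expect_true(all(gx[, 1] == 0))
  expect_true(all(gy[1, ] == 0))
})

test_that("two clean disks segment into two components", {
  img <- matrix(0, 128, 128)
  for (ctr in list(c(40, 40), c(90, 95))) {
    d2 <- outer((1:128 - ctr[1])^2, (1:128 - ctr[2])^2, "+")
    img[d2 <= 15^2] <- 1
  }
  mask <- fluo_to_mask(img, blur_sigma = 1, min_area_px = 50)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(max(as.matrix(lab)), 2L)
  expect_warning(fluo_to_mask(matrix(0, 64, 64), min_area_px = 10), "empty")
})

test_that("mask pipeline recovers tumor counts on simulated fluorescence", {
  cfg <- small_cfg(512L)
  # isolated cells: exact count; adherent clusters may merge (within 1)
  for (s in 1:10) {
    fld <- sample_cell_field(small_spec(ratio = 5, cells = 12L,
                                        adhesion_prob = 0),
                             cfg, seed = 300 + s)
    msk <- suppressWarnings(fluo_to_mask(render_fluorescence(fld, seed = s)))
    ncomp <- max(as.matrix(EBImage::bwlabel(EBImage::Image(msk * 1))))
    expect_equal(ncomp, sum(fld$cells$kind == "TUMOR"))
  }
  errs <- vapply(1:10, function(s) {
    fld <- sample_cell_field(small_spec(ratio = 5, cells = 12L), cfg,
                             seed = 400 + s)
    msk <- suppressWarnings(fluo_to_mask(render_fluorescence(fld, seed = s)))
    ncomp <- max(as.matrix(EBImage::bwlabel(EBImage::Image(msk * 1))))
    ncomp - sum(fld$cells$kind == "TUMOR")
  }, numeric(1))
  expect_true(all(abs(errs) <= 1))
})

test_that("Otsu segmentation keeps excitation leakage out of the mask", {
  cfg <- small_cfg(512L)
  bad <- 0L
  for (s in 1:10) {
    fld <- sample_cell_field(small_spec(ratio = 5, cells = 12L,
                                        adhesion_prob = 0),
                             cfg, seed = 500 + s)
    fl <- render_fluorescence(fld, leakage_level = 0.15, seed = s)
    msk <- suppressWarnings(fluo_to_mask(fl))
    pb <- fld$cells[fld$cells$kind == "PBMC", ]
    px <- which(msk, arr.ind = TRUE)
    for (j in seq_len(nrow(pb))) {
      bad <- bad + sum((px[, 2] - pb$x[j])^2 + (px[, 1] - pb$y[j])^2 <=
                         pb$radius_px[j]^2)
    }
  }
  expect_equal(bad, 0L)
})

test_that("target composition follows the documented overlay rule", {
  withr::with_seed(3, phi <- matrix(runif(64 * 64, 0, 2.5), 64, 64))
  mask <- matrix(FALSE, 64, 64); mask[10:20, 30:40] <- TRUE
  tg <- compose_target(phi, mask)
  np <- (phi - tg$norm$offset) / tg$norm$scale
  expect_equal(tg$image[!mask], 0.5 * np[!mask], tolerance = 1e-12)
  expect_true(all(tg$image[mask] == 1))
  # the rule is invertible: thresholding at 0.75 recovers the mask exactly
  expect_identical(tg$image >= 0.75, mask)
  # degenerate cases
  empty <- compose_target(phi, matrix(FALSE, 64, 64))
  expect_true(all(empty$image <= 0.5))
  full <- compose_target(phi, matrix(TRUE, 64, 64))
  expect_true(all(full$image == 1))
  expect_error(compose_target(phi, matrix(FALSE, 32, 32)), "shape")
})

test_that("centroid registration recovers a pure shift exactly", {
  withr::with_seed(8, {
    a <- data.frame(x = runif(20, 10, 200), y = runif(20, 10, 200))
  })
  b <- data.frame(x = a$x + 17, y = a$y - 4)
  r <- register_by_centroids(a, b, max_match_dist = 5)
  expect_equal(r$translation, c(17, -4), tolerance = 1e-12)
  expect_equal(r$residual, 0)
  expect_equal(nrow(r$matches), 20L)
})

test_that("centroid registration tolerates jitter and spurious points", {
  errs <- t(vapply(1:50, function(s) {
    withr::with_seed(s, {
      a <- data.frame(x = runif(50, 10, 400), y = runif(50, 10, 400))
      b <- data.frame(x = a$x + 17 + rnorm(50, 0, 0.5),
                      y = a$y - 4 + rnorm(50, 0, 0.5))
    })
    abs(register_by_centroids(a, b, 5)$translation - c(17, -4))
  }, numeric(2)))
  expect_lt(stats::median(errs[, 1]), 0.2)
  expect_lt(stats::median(errs[, 2]), 0.2)

  errs2 <- t(vapply(1:20, function(s) {
    withr::with_seed(s, {
      a <- data.frame(x = runif(50, 10, 400), y = runif(50, 10, 400))
      b <- data.frame(x = a$x + 17 + rnorm(50, 0, 0.5),
                      y = a$y - 4 + rnorm(50, 0, 0.5))
      b <- rbind(b, data.frame(x = runif(15, 10, 400), y = runif(15, 10, 400)))
    })
    abs(register_by_centroids(a, b, 5)$translation - c(17, -4))
  }, numeric(2)))
  expect_lt(max(errs2), 0.5)
  expect_error(register_by_centroids(data.frame(x = 1:2, y = 1:2),
                                     data.frame(x = 1:3, y = 1:3)), NULL)
})

test_that("crop pairs are deterministic and respect capacity", {
  withr::with_seed(2, phi <- matrix(runif(128 * 128), 128, 128))
  st <- gradient_channels(phi)
  tg <- compose_target(phi, matrix(FALSE, 128, 128))
  one <- crop_pairs(st, tg, size = 128, n = 1)
  expect_equal(one[[1]]$origin, c(row = 1L, col = 1L))
  expect_equal(one[[1]]$target, tg$image)
  a <- crop_pairs(st, tg, size = 32, n = 5, seed = 4)
  b <- crop_pairs(st, tg, size = 32, n = 5, seed = 4)
  expect_identical(lapply(a, `[[`, "origin"), lapply(b, `[[`, "origin"))
  expect_error(crop_pairs(st, tg, size = 64, n = 100), "origins")
  # crops are pixelwise co-registered between input and target
  cr <- a[[1]]
  rr <- cr$origin["row"]:(cr$origin["row"] + 31)
  cc <- cr$origin["col"]:(cr$origin["col"] + 31)
  expect_identical(cr$input[, , 3], st$channels[rr, cc, 3])
  expect_identical(cr$target, tg$image[rr, cc])
})

test_that("3:1:1 splits are stratified, disjoint, exhaustive, reproducible", {
  man <- plan_dataset(donors = 5, unseen_donors = 2,
                      ratios = c(10, 50, 1000), crops_per_combo = 100,
                      seed = 11)
  tab <- table(man$split)
  expect_equal(as.vector(tab[c("train", "val", "test", "unseen")]),
               c(900L, 300L, 300L, 600L))
  expect_equal(nrow(man), 2100L)
  expect_equal(sum(tab[c("train", "val")]), 1200L)
  # stratification: every (donor, ratio) cell splits 60/20/20
  primary <- man[man$split != "unseen", ]
  by_stratum <- table(primary$donor_id, primary$ratio, primary$split)
  expect_true(all(by_stratum[, , "train"] == 60L))
  expect_true(all(by_stratum[, , "val"] == 20L))
  expect_true(all(by_stratum[, , "test"] == 20L))
  # unseen donors never leak into the primary splits
  expect_true(all(man$split[grepl("^unseen", man$donor_id)] == "unseen"))
  expect_false(any(grepl("^unseen", primary$donor_id)))
  # reproducibility and id uniqueness
  man2 <- plan_dataset(donors = 5, unseen_donors = 2,
                       ratios = c(10, 50, 1000), crops_per_combo = 100,
                       seed = 11)
  expect_identical(man$split, man2$split)
  expect_false(any(duplicated(man$example_id)))
})

test_that("a five-example stratum splits 3/1/1 and tiny strata warn", {
  man <- plan_dataset(donors = 1, unseen_donors = 0, ratios = 10,
                      crops_per_combo = 5)
  expect_equal(as.vector(table(man$split)[c("train", "val", "test")]),
               c(3L, 1L, 1L))
  w <- capture_warnings(plan_dataset(donors = 1, unseen_donors = 0,
                                     ratios = 10, crops_per_combo = 3))
  expect_true(any(grepl("fallback", w)))
})
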