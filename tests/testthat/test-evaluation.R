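test_that("ssim is 1 on identical images and symmetric", {
  withr::with_seed(5, x <- matrix(runif(40 * 40), 40, 40))
  expect_equal(ssim(x, x), 1.0, tolerance = 1e-12)
  withr::with_seed(6, y <- matrix(runif(40 * 40), 40, 40))
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_error(ssim(x, matrix(0, 20, 20)), "shape")
})

test_that("ssim of a checkerboard against its inverse is negative", {
  cb <- matrix(rep(c(0, 1), length.out = 32 * 32), 32, 32)
  cb <- (cb + matrix(rep(c(0, 1), each = 32, length.out = 32 * 32),
                     32, 32)) %% 2
  expect_lt(ssim(cb, 1 - cb), 0)
})

test_that("ssim agrees with the reference implementation on random pairs", {
  # frozen oracle: scikit-image structural_similarity with an 11x11
  # Gaussian window (sigma 1.5), K1=0.01, K2=0.03, data_range=1, no sample
  # covariance correction, computed on the pairs regenerated below
  expected <- c(
    0.8377780407, 0.8104321941, 0.8176878598, 0.8370967598, 0.8365862188,
    0.8158609723, 0.7961434434, 0.8205291505, 0.8228167177, 0.8185458056
  )
  set.seed(99)
  got <- vapply(1:10, function(i) {
    n <- sample(24:48, 1)
    a <- matrix(runif(n * n), n, n)
    b <- pmin(pmax(a + matrix(rnorm(n * n, 0, 0.2), n, n), 0), 1)
    ssim(a, b)
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-6)
})

disk_stain <- function(centers, radius = 10, n = 128, level = 1) {
  img <- matrix(0, n, n)
  for (ctr in centers) {
    d2 <- outer((1:n - ctr[2])^2, (1:n - ctr[1])^2, "+")
    img[d2 <= radius^2] <- level
  }
  img
}

test_that("predicted-cell extraction finds components above threshold", {
  stain <- disk_stain(list(c(40, 40), c(90, 100)))
  cells <- extract_predicted_cells(stain, threshold = 0.75, min_area_px = 50)
  expect_equal(nrow(cells), 2L)
  expect_equal(sort(round(cells$x)), c(40, 90))
  expect_equal(sort(round(cells$y)), c(40, 100))
  blank <- extract_predicted_cells(matrix(0, 64, 64))
  expect_equal(nrow(blank), 0L)
  # sub-threshold and sub-area structures are ignored
  weak <- disk_stain(list(c(30, 30)), level = 0.5)
  expect_equal(nrow(extract_predicted_cells(weak)), 0L)
  tiny <- disk_stain(list(c(30, 30)), radius = 3)
  expect_equal(nrow(extract_predicted_cells(tiny, min_area_px = 50)), 0L)
})

test_that("two adherent cells merge into one documented component", {
  stain <- disk_stain(list(c(60, 60), c(75, 60)), radius = 10)
  cells <- extract_predicted_cells(stain)
  expect_equal(nrow(cells), 1L)
})

truth_fixture <- function() {
  tibble::tibble(
    kind = c(rep("TUMOR", 3), rep("PBMC", 5)),
    x = c(30, 70, 110, 20, 50, 90, 120, 60),
    y = c(30, 40, 90, 100, 100, 15, 40, 70),
    radius_px = c(12, 12, 12, 6, 6, 6, 6, 6)
  )
}

test_that("confusion counting matches hand-enumerated fixtures", {
  truth <- truth_fixture()
  # perfect prediction: a component on every tumor cell
  perfect <- disk_stain(list(c(30, 30), c(70, 40), c(110, 90)))
  cc <- count_confusion(extract_predicted_cells(perfect), truth)
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 3L, FN = 0L, TN = 5L, FP = 0L))
  # empty prediction: all tumor cells missed, all PBMCs clean
  cc0 <- count_confusion(extract_predicted_cells(matrix(0, 128, 128)), truth)
  expect_equal(unclass(cc0)[c("TP", "FN", "TN", "FP")],
               list(TP = 0L, FN = 3L, TN = 5L, FP = 0L))
  # one tumor missed, one false alarm on the PBMC at (50, 100)
  partial <- disk_stain(list(c(30, 30), c(70, 40), c(50, 100)))
  cc1 <- count_confusion(extract_predicted_cells(partial), truth)
  expect_equal(unclass(cc1)[c("TP", "FN", "TN", "FP")],
               list(TP = 2L, FN = 1L, TN = 4L, FP = 1L))
})

test_that("confusion counts preserve the cell totals", {
  truth <- truth_fixture()
  stains <- list(
    disk_stain(list(c(30, 30))),
    disk_stain(list(c(30, 30), c(50, 100), c(90, 15))),
    matrix(0, 128, 128)
  )
  for (s in stains) {
    cc <- count_confusion(extract_predicted_cells(s), truth)
    expect_equal(cc$TP + cc$FN, 3L)
    expect_equal(cc$TN + cc$FP, 5L)
  }
})

test_that("precision, recall, F1 and accuracy follow their definitions", {
  m <- prf_accuracy(list(TP = 9, FP = 1, FN = 0, TN = 90))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 1.0)
  expect_equal(m$f1, 18 / 19)
  expect_equal(m$accuracy, 0.99)
  # division guards return the explicit undefined flag, never silent zero
  expect_true(is.na(prf_accuracy(list(TP = 0, FP = 0, FN = 2, TN = 5))$precision))
  expect_true(is.na(prf_accuracy(list(TP = 0, FP = 1, FN = 0, TN = 5))$recall))
  expect_true(is.na(prf_accuracy(list(TP = 0, FP = 0, FN = 0, TN = 0))$accuracy))
  # precision = recall = p implies F1 = p
  m2 <- prf_accuracy(list(TP = 3, FP = 1, FN = 1, TN = 10))
  expect_equal(m2$f1, m2$precision)
})

test_that("F1 is the harmonic mean and bounded by max(precision, recall)", {
  withr::with_seed(17, {
    for (i in 1:25) {
      cc <- list(TP = sample(0:20, 1), FP = sample(0:20, 1),
                 FN = sample(0:20, 1), TN = sample(0:20, 1))
      m <- prf_accuracy(cc)
      if (!is.na(m$f1)) {
        expect_equal(m$f1,
                     2 * m$precision * m$recall / (m$precision + m$recall),
                     tolerance = 1e-12)
        expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
      }
      if (!is.na(m$accuracy)) {
        expect_gte(m$accuracy, 0); expect_lte(m$accuracy, 1)
      }
    }
  })
})

test_that("an oracle stainer scores perfectly on simulated targets", {
  # staining the composed target itself: SSIM 1 and perfect per-cell counts
  cfg <- small_cfg(256L)
  pooled <- list(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
  for (s in 1:3) {
    fld <- sample_cell_field(small_spec(ratio = 4, cells = 10L,
                                        adhesion_prob = 0),
                             cfg, seed = 40 + s)
    tg <- compose_target(fld$phase, fld$cancer_mask)
    expect_equal(ssim(tg$image, tg$image), 1.0)
    cells <- extract_predicted_cells(tg$image, 0.75, min_area_px = 50)
    cc <- count_confusion(cells, fld$cells)
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
  }
  m <- prf_accuracy(pooled)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
})
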