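#' Build the 3-channel network input from a phase map
#'
#' The two orthogonal phase-differential channels are computed by shifting
#' the phase map one pixel in x and y and subtracting from the original:
#' `gx[i, j] = phi[i, j] - phi[i, j - 1]`, `gy[i, j] = phi[i, j] - phi[i - 1, j]`,
#' with the first column/row set to 0 (replicate padding). Channels are
#' ordered (gradient_x, gradient_y, phase) and each is min-max normalized to
#' \[0, 1\] with the affine parameters recorded so the mapping is invertible.
#'
#' @param phase a [phase_map()] or a bare phase matrix (radians).
#' @return an object of class `input_stack`: list with `channels`
#'   (H x W x 3 array), `norm` (per-channel list of `offset`, `scale` such
#'   that raw = normalized * scale + offset), `provenance`.
#' @export
gradient_channels <- function(phase) {
  prov <- list()
  if (inherits(phase, "phase_map")) {
    prov <- phase$provenance
    phase <- phase$phase
  }
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  nr <- nrow(phase); nc <- ncol(phase)
  gx <- matrix(0, nr, nc)
  gx[, 2:nc] <- phase[, 2:nc] - phase[, 1:(nc - 1)]
  gy <- matrix(0, nr, nc)
  gy[2:nr, ] <- phase[2:nr, ] - phase[1:(nr - 1), ]
  raw <- list(gradient_x = gx, gradient_y = gy, phase = phase)
  norm <- lapply(raw, function(ch) {
    lo <- min(ch); hi <- max(ch)
    # degenerate (near-constant) channel: unit scale, don't amplify noise
    scale <- if (hi - lo < 1e-9) 1 else hi - lo
    list(offset = lo, scale = scale)
  })
  channels <- array(0, dim = c(nr, nc, 3L),
                    dimnames = list(NULL, NULL, names(raw)))
  for (k in 1:3) {
    channels[, , k] <- (raw[[k]] - norm[[k]]$offset) / norm[[k]]$scale
  }
  structure(list(channels = channels, norm = norm, provenance = prov),
            class = "input_stack")
}

#' Segment cancer cells from a raw fluorescence image
#'
#' Gaussian denoise, global threshold (Otsu by default), morphological
#' opening, small-component removal and optional hole filling: turns the
#' blurry, noisy raw fluorescence into a clean binary cancer mask aligned
#' with the phase map. An empty mask (legitimate for 1000:1 crops with no
#' tumor cell in view) is returned with a warning.
#'
#' @param fluo a `raw_fluorescence` object or a non-negative image matrix.
#' @param blur_sigma Gaussian denoise sd in pixels.
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (on the \[0, 1\]-scaled image) when
#'   `threshold_mode = "fixed"`.
#' @param min_area_px drop connected components smaller than this; the
#'   default is a quarter of the smallest tumor footprint at the default
#'   optics (7 um radius at 0.275 um/pixel).
#' @param opening_radius_px radius of the morphological opening brush.
#' @param fill_holes fill interior holes of surviving components.
#' @return a logical mask matrix.
#' @export
fluo_to_mask <- function(fluo, blur_sigma = 2,
                         threshold_mode = c("otsu", "fixed"),
                         threshold = 0.5,
                         min_area_px = NULL,
                         opening_radius_px = 2,
                         fill_holes = TRUE) {
  threshold_mode <- match.arg(threshold_mode)
  img <- if (inherits(fluo, "raw_fluorescence")) fluo$image else fluo
  stopifnot(is.matrix(img), all(img >= 0))
  if (is.null(min_area_px)) {
    min_area_px <- round(0.25 * pi * (7 / 0.275)^2)
  }
  if (blur_sigma > 0) img <- gaussian_blur(img, blur_sigma)
  rng <- max(img) - min(img)
  scaled <- if (rng > 0) (img - min(img)) / rng else img * 0
  thr <- if (threshold_mode == "otsu") {
    EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  } else {
    threshold
  }
  bin <- scaled > thr
  if (opening_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * opening_radius_px + 1, shape = "disc")
    bin <- as.matrix(EBImage::opening(EBImage::Image(bin * 1), brush)) > 0.5
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  labm <- as.matrix(lab)
  if (max(labm) > 0) {
    areas <- tabulate(labm[labm > 0], nbins = max(labm))
    keep <- which(areas >= min_area_px)
    bin <- matrix(labm %in% keep, nrow(labm), ncol(labm))
  }
  if (fill_holes && any(bin)) {
    bin <- as.matrix(EBImage::fillHull(EBImage::Image(bin * 1))) > 0.5
  }
  if (!any(bin)) warning("fluorescence mask is empty")
  bin
}

#' Compose the virtual-stain training target
#'
#' The single-channel target combines the segmentation map with the phase
#' map: outside the cancer mask the target is half the min-max-normalized
#' phase (cellular context at half dynamic range), inside the mask it is
#' saturated at 1.0. Thresholding the target at 0.75 therefore recovers the
#' mask exactly, and the target is recomputable from its parts.
#'
#' @param phase a [phase_map()] or phase matrix.
#' @param mask logical cancer mask of the same shape.
#' @return an object of class `stain_target`: list with `image` (in
#'   \[0, 1\]), `mask`, `norm` (phase normalization used).
#' @export
compose_target <- function(phase, mask) {
  if (inherits(phase, "phase_map")) phase <- phase$phase
  stopifnot(is.matrix(phase), is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (!all(dim(phase) == dim(mask))) stop("phase and mask shapes differ")
  lo <- min(phase); rng <- max(phase) - lo
  scale <- if (rng < 1e-9) 1 else rng
  img <- 0.5 * (phase - lo) / scale
  img[mask] <- 1.0
  structure(list(image = img, mask = mask,
                 norm = list(offset = lo, scale = scale)),
            class = "stain_target")
}

#' Estimate a translation from matched cell centroids
#'
#' Coarse alignment from the mode of the pairwise-offset histogram (4 px
#' bins), mutual-nearest-neighbour matching under that alignment, then a
#' robust translation as the component-wise median of matched offsets.
#' Matches whose residual exceeds `max_match_dist` are dropped and the
#' translation re-estimated once.
#'
#' @param a,b data frames / tibbles with columns `x`, `y` (pixel coords);
#'   `b` is the moved set, so `translation` maps a onto b (`b ~ a + t`).
#' @param max_match_dist residual gate in pixels.
#' @return list with `translation = c(dx, dy)`, `matches` (tibble of index
#'   pairs), `residual` (median absolute residual, pixels).
#' @export
register_by_centroids <- function(a, b, max_match_dist = 5) {
  stopifnot(nrow(a) >= 3, nrow(b) >= 3)
  ox <- outer(b$x, a$x, "-"); oy <- outer(b$y, a$y, "-")
  bins <- paste(floor(ox / 4), floor(oy / 4))
  tb <- sort(table(bins), decreasing = TRUE)
  if (length(tb) > 1 && tb[2] >= 0.9 * tb[1] &&
      names(tb)[2] != names(tb)[1]) {
    # genuinely ambiguous only if the runner-up is not an adjacent bin
    b1 <- as.numeric(strsplit(names(tb)[1], " ")[[1]])
    b2 <- as.numeric(strsplit(names(tb)[2], " ")[[1]])
    if (max(abs(b1 - b2)) > 1) {
      stop("ambiguous offset histogram: candidate bins (",
           names(tb)[1], ") and (", names(tb)[2], ")")
    }
  }
  sel <- bins == names(tb)[1]
  coarse <- c(mean(ox[sel]), mean(oy[sel]))

  match_once <- function(coarse) {
    ax <- a$x + coarse[1]; ay <- a$y + coarse[2]
    d2 <- outer(b$x, ax, "-")^2 + outer(b$y, ay, "-")^2
    nb <- apply(d2, 1, which.min) # for each b, nearest a
    na_ <- apply(d2, 2, which.min) # for each a, nearest b
    mutual <- which(na_[nb] == seq_len(nrow(b)))
    tibble::tibble(ia = nb[mutual], ib = mutual)
  }
  m <- match_once(coarse)
  if (nrow(m) < 3) stop("registration failed: fewer than 3 mutual matches")
  est <- function(m) {
    dx <- b$x[m$ib] - a$x[m$ia]; dy <- b$y[m$ib] - a$y[m$ia]
    tr <- c(stats::median(dx), stats::median(dy))
    res <- sqrt((dx - tr[1])^2 + (dy - tr[2])^2)
    list(tr = tr, res = res)
  }
  e <- est(m)
  keep <- e$res <= max_match_dist
  if (any(!keep)) {
    m <- m[keep, , drop = FALSE]
    if (nrow(m) < 3) stop("registration failed: fewer than 3 surviving matches")
    e <- est(m)
  }
  list(translation = e$tr, matches = m, residual = stats::median(e$res))
}

#' Crop co-registered training pairs
#'
#' Draws `n` crop origins uniformly without replacement from a grid with
#' stride `size / 4` (so crops never near-duplicate each other) and applies
#' the identical origins to the input channels and the target.
#'
#' @param stack an [gradient_channels()] `input_stack`.
#' @param target a [compose_target()] `stain_target`.
#' @param size crop side length in pixels.
#' @param n number of crops.
#' @param seed seed for origin sampling.
#' @return list of `training_example`s, each with `input` (size x size x 3),
#'   `target` (size x size), `mask`, and `origin = c(row, col)` (1-based).
#' @export
crop_pairs <- function(stack, target, size, n, seed = 1L) {
  stopifnot(inherits(stack, "input_stack"), inherits(target, "stain_target"))
  d <- dim(stack$channels)
  stopifnot(size <= d[1], size <= d[2], n >= 1)
  stride <- max(1L, as.integer(size / 4))
  or <- seq(1L, d[1] - size + 1L, by = stride)
  oc <- seq(1L, d[2] - size + 1L, by = stride)
  grid <- expand.grid(row = or, col = oc)
  if (n > nrow(grid)) {
    stop("requested ", n, " crops but only ", nrow(grid),
         " origins available on the stride-", stride, " grid")
  }
  idx <- with_seed(seed, sample.int(nrow(grid), n))
  lapply(idx, function(i) {
    r0 <- grid$row[i]; c0 <- grid$col[i]
    rr <- r0:(r0 + size - 1L); cc <- c0:(c0 + size - 1L)
    structure(
      list(
        input = stack$channels[rr, cc, , drop = FALSE],
        target = target$image[rr, cc],
        mask = target$mask[rr, cc],
        origin = c(row = r0, col = c0)
      ),
      class = "training_example"
    )
  })
}

#' Assign train/validation/test splits in a 3:1:1 ratio
#'
#' Within each (donor, ratio) stratum of the primary pool, examples are
#' shuffled with the given seed and assigned 3:1:1 (validation and test get
#' `floor(n/5)` each, remainders go to train). Unseen-donor entries keep the
#' label `"unseen"` and are never mixed into the primary splits.
#'
#' @param manifest a dataset manifest tibble (see [plan_dataset()]) with
#'   columns `example_id`, `donor_id`, `ratio`, `split` where primary rows
#'   have `split = NA` or a previous assignment and unseen rows are
#'   `"unseen"`.
#' @param seed shuffle seed.
#' @return the manifest with `split` filled in (`train`/`val`/`test`/
#'   `unseen`).
#' @export
split_manifest <- function(manifest, seed = 1L) {
  stopifnot(all(c("example_id", "donor_id", "ratio", "split") %in% names(manifest)))
  primary <- which(is.na(manifest$split) | manifest$split != "unseen")
  if (length(primary) < 5) {
    warning("primary pool smaller than 5; proportional fallback")
  }
  strata <- split(primary,
                  paste(manifest$donor_id[primary], manifest$ratio[primary]))
  with_seed(seed, {
    for (nm in sort(names(strata))) {
      rows <- strata[[nm]]
      n <- length(rows)
      if (n < 5) warning("stratum ", nm, " smaller than 5; proportional fallback")
      n_val <- n %/% 5L
      n_test <- n %/% 5L
      rows <- rows[sample.int(n)]
      lab <- c(rep("train", n - n_val - n_test),
               rep("val", n_val), rep("test", n_test))
      manifest$split[rows] <- lab
    }
  })
  manifest
}
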