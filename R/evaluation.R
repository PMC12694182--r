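#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the standard parameterization: 11 x 11 Gaussian
#' window (sigma 1.5), K1 = 0.01, K2 = 0.03, and no sample-covariance
#' correction. Local statistics within half a window of the border are
#' excluded from the mean (they would depend on padding, not data), so the
#' result agrees with the common reference implementations.
#'
#' @param a,b numeric matrices of identical shape.
#' @param window_sigma Gaussian window sd in pixels.
#' @param window_size window side (odd).
#' @param K1,K2 stabilization constants.
#' @param data_range dynamic range of the images.
#' @return scalar SSIM in \[-1, 1\]; 1 iff `a == b`.
#' @export
ssim <- function(a, b, window_sigma = 1.5, window_size = 11L,
                 K1 = 0.01, K2 = 0.03, data_range = 1.0) {
  stopifnot(is.matrix(a), is.matrix(b), data_range > 0,
            window_size %% 2 == 1)
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  rad <- (window_size - 1L) %/% 2L
  k1 <- seq(-rad, rad)
  g <- exp(-0.5 * (k1 / window_sigma)^2)
  K <- outer(g, g)
  K <- K / sum(K)
  f <- function(x) as.matrix(EBImage::filter2(EBImage::Image(x), K))
  mu_a <- f(a); mu_b <- f(b)
  s_aa <- f(a * a) - mu_a^2
  s_bb <- f(b * b) - mu_b^2
  s_ab <- f(a * b) - mu_a * mu_b
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  S <- ((2 * mu_a * mu_b + C1) * (2 * s_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2))
  nr <- nrow(S); nc <- ncol(S)
  if (nr <= 2 * rad || nc <= 2 * rad) stop("image smaller than the SSIM window")
  mean(S[(rad + 1):(nr - rad), (rad + 1):(nc - rad)])
}

#' Extract predicted cells from a stain map
#'
#' Thresholds the stain at the target's saturation level (0.75 by default,
#' locked to the [compose_target()] rule that the mask sits at 1.0 and
#' context below 0.5) and returns the 8-connected components above the
#' minimum area, with intensity-weighted centroids.
#'
#' @param stain matrix in \[0, 1\].
#' @param threshold detection threshold.
#' @param min_area_px drop components smaller than this (pixels).
#' @return tibble with columns `id`, `x`, `y` (centroid), `area`; the pixel
#'   sets are kept in the `label` attribute (a labeled matrix).
#' @export
extract_predicted_cells <- function(stain, threshold = 0.75,
                                    min_area_px = 50) {
  stopifnot(is.matrix(stain), min(stain) >= 0, max(stain) <= 1)
  bin <- stain >= threshold
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(bin * 1)))
  out <- tibble::tibble(id = integer(0), x = numeric(0), y = numeric(0),
                        area = integer(0))
  if (max(lab) > 0) {
    keep <- integer(0)
    rows <- list()
    relab <- matrix(0L, nrow(lab), ncol(lab))
    nid <- 0L
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      if (length(px) < min_area_px) next
      nid <- nid + 1L
      r <- (px - 1L) %% nrow(lab) + 1L
      c <- (px - 1L) %/% nrow(lab) + 1L
      w <- stain[px]
      rows[[nid]] <- tibble::tibble(
        id = nid, x = sum(c * w) / sum(w), y = sum(r * w) / sum(w),
        area = length(px)
      )
      relab[px] <- nid
    }
    if (nid > 0) out <- do.call(rbind, rows)
    lab <- relab
  }
  attr(out, "label") <- lab
  out
}

#' Cell-level confusion counts
#'
#' Matches predicted stain components to ground-truth tumor cells greedily
#' by ascending centroid distance; a match is accepted if the distance is
#' within the cell's radius. Matched tumor cells are true positives,
#' unmatched ones false negatives. Each surplus predicted component charges
#' one false positive to the nearest PBMC whose footprint it overlaps;
#' remaining PBMCs are true negatives. Counts are cells, not pixels.
#'
#' @param pred tibble from [extract_predicted_cells()].
#' @param truth_cells tibble with columns `kind` (PBMC/TUMOR), `x`, `y`,
#'   `radius_px`, in the same (crop) frame as `pred`.
#' @return an object of class `confusion_counts`: list with integers `TP`,
#'   `FN`, `TN`, `FP`.
#' @export
count_confusion <- function(pred, truth_cells) {
  tum <- truth_cells[truth_cells$kind == "TUMOR", , drop = FALSE]
  pbm <- truth_cells[truth_cells$kind == "PBMC", , drop = FALSE]
  n_pred <- nrow(pred)
  matched_pred <- rep(FALSE, n_pred)
  matched_tum <- rep(FALSE, nrow(tum))
  if (n_pred > 0 && nrow(tum) > 0) {
    d <- outer(pred$x, tum$x, "-")^2 + outer(pred$y, tum$y, "-")^2
    cand <- which(sqrt(d) <= matrix(tum$radius_px, n_pred, nrow(tum),
                                    byrow = TRUE), arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand])
      for (i in ord) {
        p <- cand[i, 1]; t <- cand[i, 2]
        if (!matched_pred[p] && !matched_tum[t]) {
          matched_pred[p] <- TRUE
          matched_tum[t] <- TRUE
        }
      }
    }
  }
  TP <- sum(matched_tum)
  FN <- nrow(tum) - TP
  fp_pbmc <- rep(FALSE, nrow(pbm))
  if (any(!matched_pred) && nrow(pbm) > 0) {
    lab <- attr(pred, "label")
    for (p in which(!matched_pred)) {
      # PBMCs whose footprint overlaps this surplus component
      if (!is.null(lab)) {
        px <- which(lab == pred$id[p])
        r <- (px - 1L) %% nrow(lab) + 1L
        c <- (px - 1L) %/% nrow(lab) + 1L
        overl <- vapply(seq_len(nrow(pbm)), function(j) {
          any((c - pbm$x[j])^2 + (r - pbm$y[j])^2 <= pbm$radius_px[j]^2)
        }, logical(1))
      } else {
        overl <- sqrt((pbm$x - pred$x[p])^2 + (pbm$y - pred$y[p])^2) <=
          pbm$radius_px
      }
      hit <- which(overl & !fp_pbmc)
      if (length(hit) > 0) {
        dd <- (pbm$x[hit] - pred$x[p])^2 + (pbm$y[hit] - pred$y[p])^2
        fp_pbmc[hit[which.min(dd)]] <- TRUE
      }
    }
  }
  FP <- sum(fp_pbmc)
  TN <- nrow(pbm) - FP
  structure(list(TP = as.integer(TP), FN = as.integer(FN),
                 TN = as.integer(TN), FP = as.integer(FP)),
            class = "confusion_counts")
}

#' Precision, recall, F1 and accuracy from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(FN+TP)`,
#' `F1 = 2 * precision * recall / (precision + recall)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. Division-by-zero cases yield `NA`
#' (an explicit undefined flag, never silently 0).
#'
#' @param c a `confusion_counts` or list with `TP`, `FN`, `TN`, `FP`.
#' @return tibble with columns `precision`, `recall`, `f1`, `accuracy`.
#' @export
prf_accuracy <- function(c) {
  stopifnot(c$TP >= 0, c$FN >= 0, c$TN >= 0, c$FP >= 0)
  precision <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  recall <- if (c$FN + c$TP > 0) c$TP / (c$FN + c$TP) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tot <- c$TP + c$TN + c$FP + c$FN
  accuracy <- if (tot > 0) (c$TP + c$TN) / tot else NA_real_
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy)
}

#' Evaluate a trained model on a manifest split
#'
#' For every example of the split: predict the stain, compute SSIM against
#' the stored target, extract predicted cells and count cell-level
#' confusion against the crop's ground truth. Confusion counts are pooled
#' (micro-averaged) over all images before computing precision, recall, F1
#' and accuracy.
#'
#' @param model a `unet_model` or a checkpoint path.
#' @param manifest dataset manifest tibble (see [generate_dataset()]) whose
#'   rows carry file paths and per-crop ground truth.
#' @param split one of `"train"`, `"val"`, `"test"`, `"unseen"`.
#' @param threshold stain detection threshold (locked to the target rule).
#' @param min_area_px minimum predicted-component area.
#' @return an object of class `metrics_report`: list with `ssim_mean`,
#'   `per_image` (tibble), `counts` (`confusion_counts`), `metrics`
#'   (tibble), `n_images`, `split`.
#' @export
evaluate_run <- function(model, manifest, split = "test", threshold = 0.75,
                         min_area_px = 50) {
  if (is.character(model)) model <- load_checkpoint(model)
  rows <- which(manifest$split == split)
  if (length(rows) == 0) stop("split '", split, "' is empty")
  per <- vector("list", length(rows))
  pooled <- list(TP = 0L, FN = 0L, TN = 0L, FP = 0L)
  for (i in seq_along(rows)) {
    entry <- manifest[rows[i], ]
    ex <- load_example(entry)
    pr <- predict_stain(model, ex)
    s <- ssim(pr, ex$target)
    cells <- extract_predicted_cells(pr, threshold, min_area_px)
    cc <- count_confusion(cells, ex$truth_cells)
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    per[[i]] <- tibble::tibble(
      example_id = entry$example_id, ssim = s,
      TP = cc$TP, FN = cc$FN, TN = cc$TN, FP = cc$FP
    )
  }
  per <- do.call(rbind, per)
  counts <- structure(pooled, class = "confusion_counts")
  structure(
    list(
      ssim_mean = mean(per$ssim),
      per_image = per,
      counts = counts,
      metrics = prf_accuracy(counts),
      n_images = nrow(per),
      split = split
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> split '", x$split, "', ", x$n_images, " images\n",
      "  SSIM mean: ", signif(x$ssim_mean, 6), "\n",
      "  counts: TP ", x$counts$TP, " FN ", x$counts$FN,
      " TN ", x$counts$TN, " FP ", x$counts$FP, "\n",
      "  precision ", signif(x$metrics$precision, 4),
      "  recall ", signif(x$metrics$recall, 4),
      "  F1 ", signif(x$metrics$f1, 4),
      "  accuracy ", signif(x$metrics$accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Broom-style tidiers for metrics reports
#'
#' `tidy_metrics()` returns the per-image table; `glance_metrics()` the
#' one-row summary.
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy_metrics <- function(x, ...) x$per_image

#' @rdname tidy_metrics
#' @export
glance_metrics <- function(x, ...) {
  tibble::tibble(
    split = x$split, n_images = x$n_images, ssim_mean = x$ssim_mean,
    TP = x$counts$TP, FN = x$counts$FN, TN = x$counts$TN, FP = x$counts$FP,
    precision = x$metrics$precision, recall = x$metrics$recall,
    f1 = x$metrics$f1, accuracy = x$metrics$accuracy
  )
}

#' Serialize a metrics report
#'
#' Writes the summary as JSON and the per-image table as CSV.
#'
#' @param report a `metrics_report`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return the JSON path, invisibly.
#' @export
write_metrics <- function(report, dir, prefix = "metrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jp <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(
    list(
      split = report$split, n_images = report$n_images,
      ssim_mean = report$ssim_mean,
      counts = unclass(report$counts),
      metrics = as.list(report$metrics)
    ),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.csv(report$per_image,
                   file.path(dir, paste0(prefix, "_per_image.csv")),
                   row.names = FALSE)
  invisible(jp)
}
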