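#' U-net configuration
#'
#' The virtual-staining network geometry: a symmetric encoder/decoder, four
#' blocks per path. Encoder blocks are (3x3 conv, ReLU) x 2 with channel
#' schedule C, 2C, 4C, 8C joined by stride-2 average pooling; decoder blocks
#' are joined by 2x bilinear upsampling, a learned 1x1 projection to the
#' skip's channel count, concatenation with the same-level encoder features
#' (doubling the channels) and (3x3 conv, ReLU) x 2 mapping the concatenated
#' 2k channels to k/2 (the per-block "reduced by a factor of four"). A final
#' 1x1 convolution maps to the single-channel stain.
#'
#' @param levels encoder/decoder depth (blocks per path).
#' @param base_channels first encoder block width C; 64 reproduces the
#'   full-scale geometry, 16 is the reduced desk-scale preset.
#' @param input_side input image side; must be divisible by `2^levels`.
#' @param in_channels 3 for (gradient_x, gradient_y, phase), 1 for the
#'   phase-only ablation control.
#' @param seed weight-initialization seed.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(levels = 4L, base_channels = 64L, input_side = 512L,
                        in_channels = 3L, seed = 1L) {
  stopifnot(levels >= 1, base_channels >= 2, base_channels %% 2 == 0,
            in_channels %in% c(1L, 3L))
  if (input_side %% 2^levels != 0) {
    stop("input_side must be divisible by 2^levels = ", 2^levels)
  }
  structure(
    list(levels = as.integer(levels),
         base_channels = as.integer(base_channels),
         input_side = as.integer(input_side),
         in_channels = as.integer(in_channels),
         out_channels = 1L,
         seed = as.integer(seed)),
    class = "unet_config"
  )
}

#' Reduced desk-scale preset of [unet_config()]
#' @param ... overrides passed to [unet_config()].
#' @export
unet_config_reduced <- function(...) {
  args <- utils::modifyList(
    list(levels = 4L, base_channels = 16L, input_side = 128L),
    list(...)
  )
  do.call(unet_config, args)
}

#' Rectified linear unit
#'
#' `ReLU(x) = max(x, 0)`, elementwise.
#' @param x numeric scalar, vector, matrix or array.
#' @return same shape as `x`.
#' @export
relu <- function(x) {
  stopifnot(all(is.finite(x)))
  pmax(x, 0)
}

#' Mean absolute error
#'
#' `(1/m) * sum(|y - f(x)|)` over all elements of the batch.
#' @param pred,truth numeric arrays of identical shape.
#' @return scalar MAE.
#' @export
mae_loss <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth)) {
    stop("pred and truth shapes differ")
  }
  mean(abs(truth - pred))
}

# channel schedule helpers
unet_channels <- function(cfg) {
  L <- cfg$levels
  enc <- cfg$base_channels * 2^(0:(L - 1)) # encoder block widths
  list(enc = enc, skip = enc, dec_out = enc / 2) # dec level l outputs S_l/2
}

#' Build the virtual-staining U-net
#'
#' Allocates and seeds the weights (He initialization for the 3x3 ReLU
#' convolutions, smaller uniform-variance init for the linear 1x1 layers).
#'
#' @param cfg a [unet_config()].
#' @return an object of class `unet_model`: list with `params` (named list
#'   of weight matrices) and `cfg`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  ch <- unet_channels(cfg)
  L <- cfg$levels
  with_seed(cfg$seed, {
    p <- list()
    he <- function(nout, nin) {
      matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
    }
    lin <- function(nout, nin) {
      matrix(stats::rnorm(nout * nin, 0, sqrt(1 / nin)), nout, nin)
    }
    for (l in seq_len(L)) {
      cin <- if (l == 1) cfg$in_channels else ch$enc[l - 1]
      cl <- ch$enc[l]
      p[[paste0("enc", l, "_aW")]] <- he(cl, 9 * cin)
      p[[paste0("enc", l, "_ab")]] <- numeric(cl)
      p[[paste0("enc", l, "_bW")]] <- he(cl, 9 * cl)
      p[[paste0("enc", l, "_bb")]] <- numeric(cl)
    }
    for (l in seq_len(L)) {
      s <- ch$skip[l]
      din <- if (l == L) ch$enc[L] else ch$dec_out[l + 1] # always equals s
      p[[paste0("dec", l, "_pW")]] <- lin(s, din)
      p[[paste0("dec", l, "_pb")]] <- numeric(s)
      p[[paste0("dec", l, "_aW")]] <- he(ch$dec_out[l], 9 * 2 * s)
      p[[paste0("dec", l, "_ab")]] <- numeric(ch$dec_out[l])
      p[[paste0("dec", l, "_bW")]] <- he(ch$dec_out[l], 9 * ch$dec_out[l])
      p[[paste0("dec", l, "_bb")]] <- numeric(ch$dec_out[l])
    }
    p[["finW"]] <- lin(1, ch$dec_out[1])
    p[["finb"]] <- numeric(1)
    structure(list(params = p, cfg = cfg), class = "unet_model")
  })
}

# input coercion: training_example input array or plain H x W x C array
as_input_array <- function(x, cfg) {
  if (inherits(x, "training_example")) x <- x$input
  if (inherits(x, "input_stack")) x <- x$channels
  d <- dim(x)
  if (is.null(d) || length(d) != 3) stop("input must be an H x W x C array")
  if (cfg$in_channels == 1L && d[3] == 3L) {
    x <- x[, , 3, drop = FALSE] # phase-only ablation uses the phase channel
  }
  d <- dim(x)
  if (d[3] != cfg$in_channels) {
    stop("input has ", d[3], " channels, model expects ", cfg$in_channels)
  }
  if (d[1] != cfg$input_side || d[2] != cfg$input_side) {
    stop("input side ", d[1], "x", d[2], " does not match model side ",
         cfg$input_side)
  }
  x
}

#' Predict a stain map
#'
#' Runs the network forward and clips the output to \[0, 1\] for export.
#' Deterministic given the checkpointed weights.
#'
#' @param model a `unet_model`.
#' @param input a `training_example`, `input_stack` or H x W x C array; or
#'   a list of them for batched inference.
#' @param clip clip the output to \[0, 1\] (default TRUE).
#' @return a stain matrix in \[0, 1\], or a list of them.
#' @export
predict_stain <- function(model, input, clip = TRUE) {
  stopifnot(inherits(model, "unet_model"))
  if (is.list(input) && !inherits(input, c("training_example", "input_stack")) &&
      is.null(dim(input))) {
    return(lapply(input, predict_stain, model = model, clip = clip))
  }
  x <- as_input_array(input, model$cfg)
  out <- unet_forward_cpp(model$params, as.numeric(x),
                          dim(x)[1], dim(x)[2],
                          model$cfg$levels, model$cfg$in_channels)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Training configuration
#'
#' All optimizer hyperparameters are configurable; the defaults are the
#' package's own choices (Adam, learning rate 1e-3, betas (0.9, 0.999)).
#'
#' @param lr Adam learning rate.
#' @param betas Adam `c(beta1, beta2)`.
#' @param epsilon Adam epsilon.
#' @param batch_size examples per optimizer step.
#' @param epochs maximum epochs.
#' @param lr_decay multiplicative per-epoch learning-rate decay (1 = constant).
#' @param patience early-stop patience on validation MAE (epochs without
#'   improvement); `Inf` disables early stopping.
#' @param seed shuffle seed.
#' @param verbose print per-epoch progress.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, betas = c(0.9, 0.999), epsilon = 1e-8,
                         batch_size = 8L, epochs = 100L, patience = 10L,
                         lr_decay = 1.0, seed = 1L, verbose = FALSE) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, patience >= 1,
            lr_decay > 0, lr_decay <= 1)
  structure(
    list(lr = lr, betas = betas, epsilon = epsilon,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         patience = patience, lr_decay = lr_decay,
         seed = as.integer(seed), verbose = verbose),
    class = "train_config"
  )
}

# loss and gradients for one example
example_grad <- function(model, ex) {
  x <- as_input_array(ex, model$cfg)
  y <- if (inherits(ex, "training_example")) ex$target else ex$y
  unet_grad_cpp(model$params, as.numeric(x), as.numeric(y),
                dim(x)[1], dim(x)[2], model$cfg$levels, model$cfg$in_channels)
}

#' Train the virtual-staining U-net
#'
#' Minimizes the mean-absolute-error loss with Adam, logging train and
#' validation MAE per epoch; returns the weights of the best validation
#' epoch. Reproducible for a fixed seed on a fixed platform (BLAS-level
#' determinism, not bit-portable across platforms).
#'
#' @param model a `unet_model` from [build_model()].
#' @param train_set,val_set disjoint lists of `training_example`s.
#' @param tcfg a [train_config()].
#' @return list with `model` (best-epoch weights) and `history` (tibble of
#'   epoch, train_mae, val_mae) with attribute `best_epoch`.
#' @export
train_unet <- function(model, train_set, val_set, tcfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), length(train_set) >= 1,
            length(val_set) >= 1)
  p <- model$params
  mstate <- lapply(p, function(w) w * 0)
  vstate <- mstate
  tstep <- 0
  b1 <- tcfg$betas[1]; b2 <- tcfg$betas[2]
  hist <- list()
  best_val <- Inf; best_p <- p; best_epoch <- 0L; stall <- 0L

  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$epochs)) {
      lr_ep <- tcfg$lr * tcfg$lr_decay^(epoch - 1)
      ord <- sample.int(length(train_set))
      ep_loss <- 0
      for (start in seq(1, length(ord), by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1, length(ord))]
        gsum <- NULL
        bloss <- 0
        for (i in idx) {
          model$params <- p
          r <- example_grad(model, train_set[[i]])
          if (!is.finite(r$loss)) {
            stop("non-finite loss at epoch ", epoch, ", example ", i,
                 " (lr = ", tcfg$lr, ")")
          }
          bloss <- bloss + r$loss
          gsum <- if (is.null(gsum)) r$grads else Map(`+`, gsum, r$grads)
        }
        nb <- length(idx)
        ep_loss <- ep_loss + bloss
        tstep <- tstep + 1
        for (nm in names(p)) {
          g <- gsum[[nm]] / nb
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g^2
          mhat <- mstate[[nm]] / (1 - b1^tstep)
          vhat <- vstate[[nm]] / (1 - b2^tstep)
          p[[nm]] <- p[[nm]] - lr_ep * mhat / (sqrt(vhat) + tcfg$epsilon)
        }
      }
      model$params <- p
      val_mae <- mean(vapply(val_set, function(ex) {
        pr <- predict_stain(model, ex, clip = FALSE)
        y <- if (inherits(ex, "training_example")) ex$target else ex$y
        mae_loss(pr, y)
      }, numeric(1)))
      train_mae <- ep_loss / length(train_set)
      hist[[epoch]] <- c(epoch = epoch, train_mae = train_mae, val_mae = val_mae)
      if (tcfg$verbose) {
        message(sprintf("epoch %3d  train MAE %.5f  val MAE %.5f",
                        epoch, train_mae, val_mae))
      }
      if (val_mae < best_val) {
        best_val <- val_mae; best_p <- p; best_epoch <- epoch; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= tcfg$patience) break
      }
    }
  })
  model$params <- best_p
  history <- tibble::as_tibble(do.call(rbind, hist))
  attr(history, "best_epoch") <- best_epoch
  list(model = model, history = history)
}

#' Save / load a model checkpoint
#'
#' The weights go into an RDS file; a JSON sidecar records the
#' configuration, seed, best epoch and final metrics so a checkpoint is
#' self-describing. Reloading reproduces predictions bit for bit.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (`.rds`).
#' @param meta extra metadata stored in the JSON sidecar.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  side <- c(list(config = unclass(model$cfg)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<unet_model> ", x$cfg$levels, " levels, base ", x$cfg$base_channels,
      ", side ", x$cfg$input_side, ", in ", x$cfg$in_channels,
      " ch, ", format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Tidy a training history
#'
#' @param x the `history` tibble returned by [train_unet()] (already tidy);
#'   provided for pipe-friendly symmetry.
#' @param ... unused.
#' @export
glance_history <- function(x, ...) {
  tibble::tibble(
    epochs_run = nrow(x),
    best_epoch = attr(x, "best_epoch"),
    best_val_mae = min(x$val_mae),
    final_train_mae = x$train_mae[nrow(x)]
  )
}
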