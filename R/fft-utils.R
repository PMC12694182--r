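# Internal FFT helpers. Frequencies are in cycles/pixel, standard DFT order
# (0, 1/N, ..., -1/N); images are matrices with rows = y, cols = x.

fft_freq <- function(n) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - floor(n / 2) - 1L)
  k / n
}

# row/col frequency grids for an nr x nc image
freq_grids <- function(nr, nc) {
  list(
    fx = matrix(fft_freq(nc), nrow = nr, ncol = nc, byrow = TRUE),
    fy = matrix(fft_freq(nr), nrow = nr, ncol = nc)
  )
}

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# circularly roll a matrix by (dr, dc); positive shifts move content down/right
roll2 <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  dr <- ((dr %% nr) + nr) %% nr
  dc <- ((dc %% nc) + nc) %% nc
  ri <- c(seq.int(nr - dr + 1L, length.out = dr), seq_len(nr - dr))
  ci <- c(seq.int(nc - dc + 1L, length.out = dc), seq_len(nc - dc))
  x[ri, ci, drop = FALSE]
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
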