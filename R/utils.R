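# Small shared numerics: matrix shifts with replicate borders, separable
# Gaussian smoothing, FFT-based correlation for large stencils, disc
# structuring elements.

shift_mat <- function(m, dr, dc) {
  # replicate-padded shift: out(r, c) = m(r + dr, c + dc)
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_smooth <- function(m, sigma) {
  k <- gauss_kernel_1d(sigma)
  a <- conv_bank_cpp(m, list(matrix(k, nrow = 1)))
  a <- matrix(a, nrow(m), ncol(m))
  b <- conv_bank_cpp(a, list(matrix(k, ncol = 1)))
  matrix(b, nrow(m), ncol(m))
}

disc_brush <- function(radius) {
  # strict Euclidean ball: offsets with dr^2 + dc^2 <= radius^2
  r <- floor(radius)
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  (d <= radius^2) * 1
}

dilate_disc <- function(mask, radius) {
  if (radius <= 0) return(mask)
  st <- storage.mode(mask)
  out <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(t(mask * 1)), disc_brush(radius)))
  t(out) > 0
}

# Per-pixel maximum (and arg-max) over the third dimension of an array.
max_over_layers <- function(arr) {
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  idx <- max.col(m, ties.method = "first")
  list(max = matrix(m[cbind(seq_len(nrow(m)), idx)], d[1], d[2]),
       which = matrix(idx, d[1], d[2]))
}

# Correlation of `img` with possibly complex kernels via FFT, replicate
# padding. Returns a list of complex matrices, one per kernel. Used for the
# large elongated Gabor stencils where direct correlation is wasteful.
fft_correlate <- function(img, kernels) {
  rad <- vapply(kernels, function(k) (max(dim(k)) - 1) / 2, numeric(1))
  R <- max(rad)
  nr <- nrow(img); nc <- ncol(img)
  pr <- stats::nextn(nr + 2 * R); pc <- stats::nextn(nc + 2 * R)
  ri <- pmin(pmax(seq_len(pr) - R, 1L), nr)
  ci <- pmin(pmax(seq_len(pc) - R, 1L), nc)
  pad <- img[ri, ci]
  Fimg <- stats::fft(pad)
  lapply(kernels, function(k) {
    kr <- nrow(k); kc <- ncol(k)
    rk <- (kr - 1) / 2; ck <- (kc - 1) / 2
    # embed the 180-degree rotated kernel with its center at (1, 1) so the
    # circular convolution theorem yields a correlation
    krev <- k[kr:1, kc:1, drop = FALSE]
    emb <- matrix(0 + 0i, pr, pc)
    rows <- ((-rk:rk) %% pr) + 1
    cols <- ((-ck:ck) %% pc) + 1
    emb[rows, cols] <- krev
    full <- stats::fft(Fimg * stats::fft(emb), inverse = TRUE) / (pr * pc)
    full[R + seq_len(nr), R + seq_len(nc)]
  })
}

restore_rng <- function() {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}
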