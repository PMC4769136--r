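#' Min-max normalize a response over the field of view
#'
#' Rescales a raw filter response so that its FOV minimum maps to 0 and its
#' FOV maximum to 1; pixels outside the FOV are set to 0. Monotone, so the
#' intensity ordering (all that rank-based fusion uses) is preserved.
#'
#' @param raw Numeric matrix of finite values.
#' @param fov Logical FOV matrix.
#' @param source Filter tag attached to the result (default `"IN"`).
#' @return An [enhanced_image()].
#' @export
normalize_response <- function(raw, fov, source = "IN") {
  if (!identical(dim(raw), dim(fov)))
    stop("`raw` and `fov` dimensions differ")
  if (any(!is.finite(raw))) stop("`raw` contains non-finite values")
  v <- raw[fov]
  lo <- min(v); hi <- max(v)
  if (hi <= lo)
    stop("degenerate input: constant response inside the FOV")
  out <- (raw - lo) / (hi - lo)
  out <- pmin(pmax(out, 0), 1)
  out[!fov] <- 0
  enhanced_image(out, fov, source)
}

#' Oriented matched filter
#'
#' Correlates the inverted intensity image (vessels bright) with a bank of
#' zero-mean oriented Gaussian ridge templates and keeps, at every pixel,
#' the maximum response over orientations. The classical operating point is
#' sigma = 2 px, delta = 9 px, 12 orientations at 15-degree steps.
#'
#' @param img A contrast-stretched [gray_image()] (vessels dark).
#' @param bank An oriented kernel bank built with `zero_mean = TRUE`.
#' @return An [enhanced_image()] tagged `"MF"`, normalized over the FOV.
#'   The attribute `"orientation"` holds the per-pixel arg-max bank index
#'   (first orientation wins ties).
#' @export
matched_filter <- function(img, bank = build_kernel_bank(2, 9, 15, TRUE)) {
  stopifnot(inherits(img, "gray_image"),
            inherits(bank, "oriented_kernel_bank"))
  if (!bank$zero_mean) stop("matched filtering needs a zero-mean bank")
  ksz <- nrow(bank$kernels[[1]])
  if (ksz > nrow(img$pixels) || ksz > ncol(img$pixels))
    stop("kernel larger than image")
  arr <- conv_bank_cpp(1 - img$pixels, bank$kernels)
  m <- max_over_layers(array(arr, c(dim(img$pixels), length(bank$kernels))))
  out <- normalize_response(m$max, img$fov, source = "MF")
  attr(out, "orientation") <- m$which
  out
}

#' Hessian-eigenvalue vesselness
#'
#' Multiscale tubularity measure from the eigenvalues of the
#' Gaussian-smoothed image Hessian. With `|lambda1| <= |lambda2|`, the
#' score at one scale is
#' `V = exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#' where `Rb = lambda1 / lambda2` suppresses blobs, `S` is the Frobenius
#' norm of the Hessian and the structure sign is restricted to dark ridges
#' (`lambda2 > 0`, vessels darker than background). Scale-normalized
#' second derivatives (factor `s^2`) make responses comparable across
#' scales; the per-pixel maximum over scales is kept.
#'
#' @param img A [gray_image()] with dark vessels.
#' @param scales Gaussian scales in pixels (default 1 to 3 by 0.5).
#' @param beta Blob-suppression sensitivity (default 0.5).
#' @param c Structure-ness sensitivity; `NULL` (default) uses half the
#'   maximum Hessian norm over the image and scale range.
#' @return An [enhanced_image()] tagged `"FR"`, normalized over the FOV.
#'   The attribute `"scale"` maps each pixel to the scale that won the
#'   per-pixel maximum.
#' @export
frangi_vesselness <- function(img, scales = c(1, 1.5, 2, 2.5, 3),
                              beta = 0.5, c = NULL) {
  stopifnot(inherits(img, "gray_image"))
  if (length(scales) == 0) stop("`scales` must be non-empty")
  if (any(scales <= 0)) stop("all scales must be positive")
  p <- img$pixels
  per_scale <- lapply(scales, function(s) {
    sm <- gaussian_smooth(p, s)
    hrr <- (shift_mat(sm, 1, 0) - 2 * sm + shift_mat(sm, -1, 0)) * s^2
    hcc <- (shift_mat(sm, 0, 1) - 2 * sm + shift_mat(sm, 0, -1)) * s^2
    hrc <- (shift_mat(sm, 1, 1) - shift_mat(sm, 1, -1) -
              shift_mat(sm, -1, 1) + shift_mat(sm, -1, -1)) / 4 * s^2
    mid <- (hrr + hcc) / 2
    disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    e_lo <- mid - disc
    e_hi <- mid + disc
    # order by magnitude
    swap <- abs(e_lo) > abs(e_hi)
    l1 <- ifelse(swap, e_hi, e_lo)
    l2 <- ifelse(swap, e_lo, e_hi)
    list(l1 = l1, l2 = l2, s2 = hrr^2 + 2 * hrc^2 + hcc^2)
  })
  if (is.null(c)) {
    smax <- max(vapply(per_scale, function(z) sqrt(max(z$s2)), numeric(1)))
    c <- smax / 2
    if (c <= 0) c <- 1  # flat image: response will be zero anyway
  }
  vmaps <- lapply(per_scale, function(z) {
    rb2 <- ifelse(z$l2 != 0, (z$l1 / z$l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-z$s2 / (2 * c^2)))
    v[z$l2 <= 0] <- 0  # keep dark-tubular sign only
    v
  })
  vmax <- vmaps[[1]]
  smap <- matrix(1L, nrow(p), ncol(p))
  for (i in seq_along(vmaps)[-1]) {
    better <- vmaps[[i]] > vmax
    vmax[better] <- vmaps[[i]][better]
    smap[better] <- i
  }
  if (max(vmax[img$fov]) <= min(vmax[img$fov])) {
    # constant (e.g. flat) image: zero response by convention
    return(enhanced_image(matrix(0, nrow(p), ncol(p)), img$fov, "FR"))
  }
  out <- normalize_response(vmax, img$fov, source = "FR")
  attr(out, "scale") <- matrix(scales[smap], nrow(p), ncol(p))
  out
}

gabor_kernels <- function(scales, elongation, step_deg, freq = 3) {
  n <- ceiling(180 / step_deg)
  angles <- (seq_len(n) - 1) * step_deg
  out <- list()
  for (a in scales) {
    R <- ceiling(3 * elongation * a)
    off <- -R:R
    x <- matrix(off, 2 * R + 1, 2 * R + 1, byrow = TRUE)
    y <- matrix(off, 2 * R + 1, 2 * R + 1)
    for (th in angles) {
      ang <- th * pi / 180
      u <- x * cos(ang) + y * sin(ang)
      v <- -x * sin(ang) + y * cos(ang)
      env <- exp(-(u^2 / a^2 + v^2 / (elongation * a)^2) / 2)
      k <- env * exp(1i * freq * u / a)
      k <- k - mean(k)  # exact zero mean: constant images give 0 response
      out[[length(out) + 1]] <- k / a
    }
  }
  out
}

#' Gabor wavelet transform response
#'
#' Modulus of the 2-D continuous wavelet transform with an elongated
#' complex Gabor (Morlet-type) mother wavelet: a Gaussian envelope
#' stretched along the vessel axis and modulated across it. The response
#' keeps the per-pixel maximum of the modulus over orientations (sampled
#' over half a turn) and scales. The wavelet is corrected to exact zero
#' mean, so the response is invariant to adding a constant to the image.
#'
#' @param img A [gray_image()].
#' @param scales Wavelet scales in pixels (default 2 to 5).
#' @param elongation Envelope axis ratio (>= 1, default 4).
#' @param step_deg Orientation step in degrees (default 10).
#' @return An [enhanced_image()] tagged `"GW"`, normalized over the FOV.
#' @export
gabor_wavelet <- function(img, scales = 2:5, elongation = 4, step_deg = 10) {
  stopifnot(inherits(img, "gray_image"))
  if (length(scales) == 0) stop("`scales` must be non-empty")
  if (elongation < 1) stop("`elongation` must be >= 1")
  kerns <- gabor_kernels(scales, elongation, step_deg)
  resp <- fft_correlate(img$pixels, kerns)
  mods <- lapply(resp, Mod)
  mmax <- Reduce(pmax, mods)
  if (max(mmax[img$fov]) <= min(mmax[img$fov]) + 1e-14) {
    return(enhanced_image(matrix(0, nrow(mmax), ncol(mmax)), img$fov, "GW"))
  }
  normalize_response(mmax, img$fov, source = "GW")
}

#' Compute a set of enhancement responses
#'
#' Convenience driver producing the normalized responses for a subset of
#' the four fusion inputs: `"MF"` (matched filter), `"FR"` (vesselness),
#' `"GW"` (Gabor wavelet) and `"IN"` (the inverted contrast-stretched
#' intensity image itself, so that all inputs carry vessels bright).
#'
#' @param img A contrast-stretched [gray_image()].
#' @param tags Character vector of tags to compute.
#' @param params Optional named list of per-filter parameter overrides,
#'   e.g. `list(MF = list(sigma = 2, delta = 9), GW = list(scales = 2:5))`.
#' @return Named list of [enhanced_image()] objects, one per tag.
#' @export
enhance <- function(img, tags = c("MF", "FR", "GW"), params = list()) {
  stopifnot(inherits(img, "gray_image"))
  bad <- setdiff(tags, c("MF", "FR", "GW", "IN"))
  if (length(bad)) stop("unknown filter tag(s): ", paste(bad, collapse = ", "))
  out <- lapply(setNames(tags, tags), function(tag) {
    pr <- params[[tag]]
    switch(tag,
      MF = matched_filter(img, do.call(build_kernel_bank, c(
        list(sigma = pr$sigma %||% 2, delta = pr$delta %||% 9,
             step_deg = pr$step_deg %||% 15, zero_mean = TRUE)))),
      FR = frangi_vesselness(img,
        scales = pr$scales %||% c(1, 1.5, 2, 2.5, 3),
        beta = pr$beta %||% 0.5, c = pr$c),
      GW = gabor_wavelet(img, scales = pr$scales %||% 2:5,
        elongation = pr$elongation %||% 4,
        step_deg = pr$step_deg %||% 10),
      IN = normalize_response(1 - img$pixels, img$fov, source = "IN"))
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
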