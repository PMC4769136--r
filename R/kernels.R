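#' Build a bank of oriented Gaussian-profile kernels
#'
#' Each kernel is an anisotropic Gaussian ridge template: across the vessel
#' the profile is `exp(-u^2 / (2 sigma^2))`, along the vessel it is flat
#' over a length `delta`, with support restricted to the rotated
#' neighborhood `|u| <= 3 sigma`, `|v| <= delta / 2`. Orientations cover
#' half a turn at `step_deg` spacing (the template has 180-degree
#' symmetry), so a 15-degree step yields 12 kernels.
#'
#' Two conventions share this constructor: the matched-filter variant
#' subtracts the in-support mean (zero DC response, vessels pop against any
#' constant background), and the region-fitting variant normalizes the
#' in-support mass to one so that correlations are proper local weighted
#' averages.
#'
#' @param sigma Cross-profile scale in pixels (> 0).
#' @param delta Template length in pixels (>= 1).
#' @param step_deg Orientation step in degrees (0 < step <= 90).
#' @param zero_mean If `TRUE`, subtract the in-support mean (matched-filter
#'   convention); otherwise normalize the kernel mass to 1.
#' @return An `oriented_kernel_bank`: list with `kernels` (square numeric
#'   stencils), `angles` (degrees), `sigma`, `delta`, `zero_mean`.
#' @export
build_kernel_bank <- function(sigma, delta, step_deg = 15, zero_mean = TRUE) {
  if (sigma <= 0) stop("`sigma` must be positive")
  if (delta < 1) stop("`delta` must be >= 1")
  if (step_deg <= 0 || step_deg > 90) stop("`step_deg` must be in (0, 90]")
  n <- ceiling(180 / step_deg)
  angles <- (seq_len(n) - 1) * step_deg
  R <- ceiling(max(3 * sigma, delta / 2))
  off <- -R:R
  x <- matrix(off, 2 * R + 1, 2 * R + 1, byrow = TRUE)  # column offset
  y <- matrix(off, 2 * R + 1, 2 * R + 1)                # row offset
  kernels <- lapply(angles, function(th) {
    u <- x * cospi(th / 180) + y * sinpi(th / 180)
    v <- -x * sinpi(th / 180) + y * cospi(th / 180)
    sup <- abs(u) <= 3 * sigma & abs(v) <= delta / 2
    k <- exp(-u^2 / (2 * sigma^2)) * sup
    if (zero_mean) {
      k[sup] <- k[sup] - mean(k[sup])
      k * sup
    } else {
      k / sum(k)
    }
  })
  structure(list(kernels = kernels, angles = angles, sigma = sigma,
                 delta = delta, zero_mean = zero_mean),
            class = "oriented_kernel_bank")
}

#' @export
print.oriented_kernel_bank <- function(x, ...) {
  cat(sprintf(
    "<oriented_kernel_bank> %d kernels (%s), sigma=%.2g delta=%.2g, %s\n",
    length(x$kernels), paste0(x$angles[1], ":", x$angles[2] - x$angles[1],
                              ":", tail(x$angles, 1), " deg"),
    x$sigma, x$delta,
    if (x$zero_mean) "zero-mean" else "unit-mass"))
  invisible(x)
}
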