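#' Specification of a synthetic fundus phantom
#'
#' Describes a fundus-like test image: a circular field of view, a bright
#' background with mild radial shading (brighter center, emulating the
#' illumination nonuniformity that contrast stretching mitigates), and
#' dark curvilinear vessels of varying width with a Gaussian
#' cross-sectional intensity profile. Ground truth is exact (half-maximum
#' support of the noise-free ridge).
#'
#' Defaults model a DRIVE-like acquisition scaled to a 300 x 300 frame:
#' six vessels of width 2-6 px, vessel-to-background contrast 0.5,
#' additive Gaussian noise of 0.05, and a FOV filling 96 percent of the
#' frame height.
#'
#' @param size Integer `(rows, cols)`.
#' @param n_vessels Number of vessels (0 allowed: empty-truth phantom).
#' @param width_range Vessel width range `(min, max)` in pixels (>= 1).
#' @param contrast Vessel-to-background intensity drop in (0, 1\].
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param curvature Standard deviation of the heading change per unit step
#'   of the vessel random walk (radians).
#' @param fov_radius_frac FOV radius as a fraction of the smaller image
#'   dimension, in (0, 0.5\].
#' @param rng_seed Integer seed; generation is bit-reproducible from it.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size = c(300, 300), n_vessels = 6,
                         width_range = c(2, 6), contrast = 0.5,
                         noise_sigma = 0.05, curvature = 0.05,
                         fov_radius_frac = 0.48, rng_seed = 1) {
  stopifnot(length(size) == 2, all(size >= 16),
            n_vessels >= 0,
            length(width_range) == 2, width_range[1] >= 1,
            width_range[2] >= width_range[1],
            contrast > 0, contrast <= 1,
            noise_sigma >= 0, curvature >= 0,
            fov_radius_frac > 0, fov_radius_frac <= 0.5)
  structure(list(size = as.integer(size), n_vessels = as.integer(n_vessels),
                 width_range = width_range, contrast = contrast,
                 noise_sigma = noise_sigma, curvature = curvature,
                 fov_radius_frac = fov_radius_frac,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

disc_fov <- function(size, radius_frac) {
  r0 <- (size[1] + 1) / 2
  c0 <- (size[2] + 1) / 2
  R <- radius_frac * min(size)
  d2 <- outer((seq_len(size[1]) - r0)^2, (seq_len(size[2]) - c0)^2, "+")
  d2 <= R^2
}

# Stamp a Gaussian ridge profile around one centerline point; `ridge` is
# updated by pointwise maximum so overlapping stamps form a smooth tube.
stamp_point <- function(ridge, r, c, s) {
  nr <- nrow(ridge); nc <- ncol(ridge)
  wr <- ceiling(3 * s)
  rs <- max(1, round(r) - wr):min(nr, round(r) + wr)
  cs <- max(1, round(c) - wr):min(nc, round(c) + wr)
  d2 <- outer((rs - r)^2, (cs - c)^2, "+")
  ridge[rs, cs] <- pmax(ridge[rs, cs], exp(-d2 / (2 * s^2)))
  ridge
}

render_phantom <- function(size, fov, centerlines, widths, contrast,
                           noise_sigma, shading_amp = 0.1, base = 0.7) {
  ridge <- matrix(0, size[1], size[2])
  for (i in seq_along(centerlines)) {
    pts <- centerlines[[i]]
    s <- (widths[i] / 2) / sqrt(2 * log(2))  # half-maximum at width/2
    for (j in seq_len(nrow(pts)))
      ridge <- stamp_point(ridge, pts[j, 1], pts[j, 2], s)
  }
  r0 <- (size[1] + 1) / 2; c0 <- (size[2] + 1) / 2
  R <- max(1, 0.5 * min(size))
  d2 <- outer((seq_len(size[1]) - r0)^2, (seq_len(size[2]) - c0)^2, "+")
  bg <- base + shading_amp * pmax(0, 1 - d2 / R^2)
  clean <- bg - contrast * ridge
  noise <- if (noise_sigma > 0)
    matrix(rnorm(prod(size), sd = noise_sigma), size[1], size[2])
  else matrix(0, size[1], size[2])
  green <- pmin(pmax(clean + noise, 0), 1)
  green[!fov] <- 0
  red <- pmin(pmax(0.95 * bg - 0.25 * contrast * ridge +
                     noise * 1.3, 0), 1)
  blue <- pmin(pmax(0.25 * bg + noise * 1.5, 0), 1)
  red[!fov] <- 0; blue[!fov] <- 0
  color <- array(c(red, green, blue), c(size, 3))
  truth <- ridge >= 0.5 & fov
  list(color = color, truth = truth, ridge = ridge)
}

#' Generate a synthetic fundus phantom
#'
#' Vessels start near the FOV center and grow outward as smooth random
#' walks (unit steps, Gaussian heading increments), each rendered as a
#' dark Gaussian-profile ridge of its sampled width on the shaded
#' background; vessel structure is carried in the green channel, as in
#' real fundus photographs. Ground truth is the half-maximum support of
#' the noise-free ridge field, restricted to the FOV.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom`: list with `color` (rows x cols x 3 array), `truth`
#'   ([binary_segmentation()]), `fov`, `centerlines` (list of n x 2
#'   (row, col) matrices), and `spec`. If `n_vessels` is 0 the attribute
#'   `"empty_truth"` is `TRUE` and a warning is issued.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  restore <- restore_rng()
  on.exit(restore())
  set.seed(spec$rng_seed)
  size <- spec$size
  fov <- disc_fov(size, spec$fov_radius_frac)
  r0 <- (size[1] + 1) / 2; c0 <- (size[2] + 1) / 2
  R <- spec$fov_radius_frac * min(size)
  centerlines <- list()
  widths <- numeric(0)
  n <- spec$n_vessels
  if (n > 0) {
    for (i in seq_len(n)) {
      ang0 <- runif(1, 0, 2 * pi)
      rad0 <- runif(1, 0, 0.25 * R)
      pos <- c(r0 + rad0 * sin(ang0), c0 + rad0 * cos(ang0))
      heading <- runif(1, 0, 2 * pi)
      pts <- matrix(pos, 1, 2)
      for (step in seq_len(ceiling(3 * R))) {
        heading <- heading + rnorm(1, sd = spec$curvature)
        pos <- pos + c(sin(heading), cos(heading))
        if ((pos[1] - r0)^2 + (pos[2] - c0)^2 > (R - 1)^2) break
        pts <- rbind(pts, pos)
      }
      centerlines[[i]] <- pts
      widths[i] <- runif(1, spec$width_range[1], spec$width_range[2])
    }
  }
  rend <- render_phantom(size, fov, centerlines, widths, spec$contrast,
                         spec$noise_sigma)
  out <- structure(list(color = rend$color,
                        truth = binary_segmentation(rend$truth, fov),
                        fov = fov, centerlines = centerlines,
                        widths = widths, spec = spec),
                   class = "phantom")
  if (n == 0) {
    attr(out, "empty_truth") <- TRUE
    warning("phantom generated with an empty ground truth (n_vessels = 0)")
  }
  out
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d, %d vessel(s), %d truth px, seed %d\n",
              nrow(x$fov), ncol(x$fov), length(x$centerlines),
              sum(x$truth$labels), x$spec$rng_seed))
  invisible(x)
}

#' Straight-bar phantom
#'
#' A single straight vessel through the image center at a given angle,
#' with analytic ground truth (perpendicular distance at most half the
#' width). Angle 0 runs along image rows (vertical); the angle-90 phantom
#' is the transpose of the angle-0 one. Intended as an oracle for oriented
#' filters: the response arg-max orientation on the bar must match the
#' bank angle nearest `angle_deg`.
#'
#' @param size Integer `(rows, cols)`.
#' @param angle_deg Bar orientation in degrees.
#' @param width Bar width in pixels (>= 1).
#' @param contrast Vessel-to-background drop (default 1).
#' @return A `phantom` with a full-frame FOV and no noise.
#' @export
straight_bar <- function(size = c(64, 64), angle_deg = 0, width = 3,
                         contrast = 1) {
  stopifnot(width >= 1)
  size <- as.integer(size)
  r0 <- (size[1] + 1) / 2; c0 <- (size[2] + 1) / 2
  x <- matrix(seq_len(size[2]) - c0, size[1], size[2], byrow = TRUE)
  y <- matrix(seq_len(size[1]) - r0, size[1], size[2])
  # cospi/sinpi are exact at the axis angles, keeping 0/90 transposable
  u <- x * cospi(angle_deg / 180) + y * sinpi(angle_deg / 180)
  s <- (width / 2) / sqrt(2 * log(2))
  ridge <- exp(-u^2 / (2 * s^2))
  fov <- matrix(TRUE, size[1], size[2])
  bg <- 0.8
  green <- pmin(pmax(bg - contrast * ridge, 0), 1)
  color <- array(c(pmin(bg * 1.1, 1) - 0.2 * contrast * ridge, green,
                   rep(0.25, prod(size))), c(size, 3))
  truth <- abs(u) <= width / 2
  structure(list(color = color,
                 truth = binary_segmentation(truth, fov),
                 fov = fov,
                 centerlines = list(), widths = width,
                 spec = NULL, angle_deg = angle_deg),
            class = "phantom")
}
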