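#' Grayscale image with a field-of-view mask
#'
#' The basic carrier of intensity data: a numeric matrix with values in
#' \[0, 1\] plus a logical matrix of the same shape marking the circular
#' field of view (FOV) of the fundus photograph. All pixel statistics,
#' thresholds and metrics downstream are restricted to the FOV.
#'
#' @param pixels Numeric matrix, intensities in \[0, 1\].
#' @param fov Logical matrix of the same dimensions (`TRUE` = inside the
#'   field of view). Defaults to an all-`TRUE` mask.
#' @return An object of class `gray_image` with elements `pixels` and `fov`.
#' @export
gray_image <- function(pixels, fov = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(pixels), ncol(pixels))
  storage.mode(fov) <- "logical"
  if (!identical(dim(pixels), dim(fov)))
    stop("`pixels` and `fov` dimensions differ")
  if (any(!is.finite(pixels)))
    stop("`pixels` contains non-finite values")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("`pixels` must lie in [0, 1]")
  structure(list(pixels = pmin(pmax(pixels, 0), 1), fov = fov),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d FOV pixels, range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$fov),
              min(x$pixels[x$fov]), max(x$pixels[x$fov])))
  invisible(x)
}

#' Vessel-enhancement response
#'
#' A filter or fusion response over the same grid as its source image,
#' min-max normalized so the FOV spans \[0, 1\] (weighted-mean fusions are
#' kept on the convex \[0, 1\] scale of their defining formula instead).
#' The `source` tag records which operator produced the response and fixes
#' the vessel polarity convention: `"fused-wm"` responses carry vessels
#' dark, every other tag carries vessels bright.
#'
#' @param response Numeric matrix in \[0, 1\].
#' @param fov Logical FOV matrix.
#' @param source Tag: one of `"MF"`, `"FR"`, `"GW"`, `"IN"`, `"fused-wm"`,
#'   `"fused-mr"`.
#' @return An `enhanced_image` object.
#' @export
enhanced_image <- function(response, fov, source) {
  if (!identical(dim(response), dim(fov)))
    stop("`response` and `fov` dimensions differ")
  if (any(!is.finite(response)))
    stop("`response` contains non-finite values")
  storage.mode(fov) <- "logical"
  stopifnot(is.character(source), length(source) == 1)
  structure(list(response = response, fov = fov, source = source),
            class = "enhanced_image")
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image:%s> %d x %d, FOV range [%.3f, %.3f]\n",
              x$source, nrow(x$response), ncol(x$response),
              min(x$response[x$fov]), max(x$response[x$fov])))
  invisible(x)
}

#' Does this response carry vessels dark?
#' @param resp An `enhanced_image`.
#' @return `TRUE` for weighted-mean fusions (vessels dark), else `FALSE`.
#' @export
vessels_dark <- function(resp) identical(resp$source, "fused-wm")

#' Binary vessel segmentation
#'
#' A logical label field (`TRUE` = vessel) restricted to the FOV: the
#' constructor clears any label outside the mask so the invariant holds by
#' construction.
#'
#' @param labels Logical matrix.
#' @param fov Logical FOV matrix of the same dimensions.
#' @return A `binary_segmentation` object.
#' @export
binary_segmentation <- function(labels, fov) {
  if (!identical(dim(labels), dim(fov)))
    stop("`labels` and `fov` dimensions differ")
  storage.mode(labels) <- "logical"
  storage.mode(fov) <- "logical"
  labels <- labels & fov
  structure(list(labels = labels, fov = fov), class = "binary_segmentation")
}

#' @export
print.binary_segmentation <- function(x, ...) {
  cat(sprintf("<binary_segmentation> %d x %d, %d vessel px / %d FOV px\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels), sum(x$fov)))
  invisible(x)
}

#' Contrast-stretch output limits
#'
#' @param alpha1,alpha2 Lower and upper output bounds (defaults 0 and 1).
#' @return A `stretch_limits` object.
#' @export
stretch_limits <- function(alpha1 = 0, alpha2 = 1) {
  if (!(alpha1 < alpha2)) stop("`alpha1` must be < `alpha2`")
  structure(list(alpha1 = alpha1, alpha2 = alpha2), class = "stretch_limits")
}

#' Fusion weight vector on the probability simplex
#'
#' Non-negative weights over a set of filter tags, summing to one: the
#' convexity constraint that keeps the weighted-mean fusion inside \[0, 1\].
#'
#' @param weights Named numeric vector, names are filter tags.
#' @return A `weight_vector` object.
#' @export
weight_vector <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by filter tag")
  if (any(weights < -1e-12)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (within 1e-9)")
  structure(pmax(weights, 0), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector>",
      paste(sprintf("%s=%.4f", names(x), unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' Per-pixel rank map of a response
#'
#' Pixels inside the FOV are ranked by intensity, highest intensity getting
#' rank `top` (= FOV pixel count); ties share the mean of the positions
#' they cover. Pixels outside the FOV carry rank 0.
#'
#' @param ranks Numeric matrix of ranks.
#' @param fov Logical FOV matrix.
#' @param top Total number of FOV pixels.
#' @return A `rank_image` object.
#' @export
rank_image <- function(ranks, fov, top) {
  if (!identical(dim(ranks), dim(fov)))
    stop("`ranks` and `fov` dimensions differ")
  structure(list(ranks = ranks, fov = fov, top = as.integer(top)),
            class = "rank_image")
}

#' Genetic-algorithm settings
#'
#' Defaults are sized for the small search spaces this package optimizes
#' over (at most four fusion weights, or one scalar threshold): population
#' 50, tournament selection of size 3, blend crossover, Gaussian mutation.
#' The search stops after `patience` consecutive generations without
#' improvement of the incumbent.
#'
#' @param population_size Number of chromosomes per generation.
#' @param crossover_rate Probability a child is produced by blend crossover.
#' @param mutation_rate Per-gene probability of Gaussian perturbation.
#' @param mutation_sd Standard deviation of the mutation perturbation.
#' @param patience Generations without improvement before stopping.
#' @param max_generations Hard cap on generations.
#' @param rng_seed Integer seed; the whole search is reproducible from it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 50, crossover_rate = 0.9,
                      mutation_rate = 0.1, mutation_sd = 0.1,
                      patience = 50, max_generations = 500, rng_seed = 1) {
  stopifnot(population_size >= 2,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            patience >= 1, max_generations >= 1)
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd,
                 patience = as.integer(patience),
                 max_generations = as.integer(max_generations),
                 rng_seed = as.integer(rng_seed)),
            class = "ga_config")
}

#' Fuzzy C-means settings
#'
#' `n_clusters` groups are fitted to the 1-D FOV intensity distribution;
#' one cluster captures vessels and the remaining `n_clusters - 1` absorb
#' the heterogeneous background. Two clusters suffice on both DRIVE-like
#' and STARE-like material.
#'
#' @param n_clusters Number of clusters c (>= 2).
#' @param fuzziness Membership exponent m (> 1).
#' @param tol Convergence tolerance on the maximum membership change.
#' @param max_iter Iteration cap.
#' @param rng_seed Kept for interface symmetry; the quantile-based
#'   initialization is deterministic.
#' @return A `fcm_config` object.
#' @export
fcm_config <- function(n_clusters = 2, fuzziness = 2, tol = 1e-5,
                       max_iter = 200, rng_seed = 1) {
  stopifnot(n_clusters >= 2, fuzziness > 1, tol > 0, max_iter >= 1)
  structure(list(n_clusters = as.integer(n_clusters), fuzziness = fuzziness,
                 tol = tol, max_iter = as.integer(max_iter),
                 rng_seed = as.integer(rng_seed)),
            class = "fcm_config")
}

#' Oriented region-scalable-fitting level-set settings
#'
#' `lambda1`/`lambda2` weight the outside/inside local fitting terms and
#' `nu` the contour-length penalty; the published operating points are
#' lambda = 3 (DRIVE-like material) or 2 (STARE-like) with nu = 130 on the
#' 0..255 intensity scale the evolution uses internally. `sigma` and
#' `delta` set the cross-profile scale and length of the oriented local
#' averaging windows (12 orientations at the default 15 degree step).
#'
#' @param lambda1,lambda2 Positive region-fitting weights.
#' @param nu Contour-length weight (>= 0).
#' @param sigma Kernel cross-profile scale in pixels.
#' @param delta Kernel length in pixels.
#' @param step_deg Orientation step in degrees.
#' @param time_step Explicit evolution step.
#' @param max_iter Iteration cap.
#' @param convergence_tol Stop when the fraction of pixels whose level-set
#'   sign changed in one iteration falls below this.
#' @param epsilon Width of the regularized Heaviside/Dirac.
#' @param mu Distance-regularization weight on the level-set field.
#' @param isotropic If `TRUE`, replace the oriented bank by the single
#'   isotropic Gaussian window of the classical region-scalable-fitting
#'   model (radius 3 sigma, unit mass); the evolution then reduces to RSF.
#' @return An `orsf_config` object.
#' @export
orsf_config <- function(lambda1 = 3, lambda2 = 3, nu = 130, sigma = 3,
                        delta = 9, step_deg = 15, time_step = 0.1,
                        max_iter = 300, convergence_tol = 1e-4,
                        epsilon = 1.5, mu = 1, isotropic = FALSE) {
  stopifnot(lambda1 > 0, lambda2 > 0, nu >= 0, sigma > 0, delta >= 1,
            step_deg > 0, step_deg <= 90, time_step > 0, max_iter >= 1,
            convergence_tol >= 0, epsilon > 0, mu >= 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, nu = nu,
                 sigma = sigma, delta = delta, step_deg = step_deg,
                 time_step = time_step, max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol, epsilon = epsilon,
                 mu = mu, isotropic = isotropic),
            class = "orsf_config")
}
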