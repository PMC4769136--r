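#' Fixed global threshold
#'
#' Labels vessel wherever a (vessels-bright) normalized response reaches
#' the threshold, restricted to the FOV. Monotone in `t`: raising the
#' threshold can only shrink the vessel set.
#'
#' @param resp A normalized [enhanced_image()], vessels bright.
#' @param t Threshold in \[0, 1\].
#' @return A [binary_segmentation()].
#' @export
fixed_threshold <- function(resp, t) {
  stopifnot(inherits(resp, "enhanced_image"))
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1)
    stop("`t` must be a scalar in [0, 1]")
  binary_segmentation(resp$response >= t, resp$fov)
}

#' Learn a global threshold by a genetic algorithm
#'
#' Searches \[0, 1\] for the scalar threshold maximizing mean segmentation
#' accuracy over a training set of (vessels-bright) responses and ground
#' truths; fitness is `1 - mean(ACC)`, minimized, reproducible from the
#' seed in `cfg`.
#'
#' @param train List of normalized [enhanced_image()] objects.
#' @param truths List of matching [binary_segmentation()] ground truths.
#' @param cfg A [ga_config()].
#' @return The learned threshold (scalar); attribute `"fitness"` holds the
#'   achieved objective value.
#' @export
optimize_threshold <- function(train, truths, cfg = ga_config()) {
  if (length(train) < 1) stop("configuration error: empty training set")
  if (length(train) != length(truths))
    stop("training responses and truths differ in number")
  stacks <- lapply(seq_along(train), function(i) {
    fov <- train[[i]]$fov
    list(v = train[[i]]$response[fov], truth = truths[[i]]$labels[fov])
  })
  fitness <- function(t) {
    1 - mean(vapply(stacks, function(s) mean((s$v >= t) == s$truth),
                    numeric(1)))
  }
  res <- ga_minimize(function(x) fitness(x[1]), 1,
                     function(x) pmin(pmax(x, 0), 1), cfg, init = 0.5)
  t <- res$par[1]
  attr(t, "fitness") <- res$value
  t
}

#' Fuzzy C-means segmentation
#'
#' Standard fuzzy C-means on the one-dimensional FOV intensity feature:
#' memberships `u_ij` proportional to `(1 / d_ij^2)^(1 / (m - 1))` and
#' centroids as membership-weighted means alternate until the maximum
#' membership change drops below `tol`. The cluster whose centroid is most
#' vessel-like (darkest for weighted-mean fusions, brightest otherwise) is
#' labeled vessel; the remaining `c - 1` clusters absorb the background.
#' Pixels are defuzzified by maximal membership. Centroids start at the
#' FOV intensity quantiles `k / (c + 1)`, a deterministic initialization.
#'
#' @param resp An [enhanced_image()] with non-constant FOV intensities.
#' @param cfg A [fcm_config()].
#' @return A [binary_segmentation()]. Attribute `"trace"` holds the
#'   objective value per iteration and `"centroids"` the final centroids.
#' @export
fcm_segment <- function(resp, cfg = fcm_config()) {
  stopifnot(inherits(resp, "enhanced_image"), inherits(cfg, "fcm_config"))
  v <- resp$response[resp$fov]
  cc <- cfg$n_clusters
  if (length(unique(v)) < cc)
    stop("degenerate input: fewer distinct intensities than clusters")
  m <- cfg$fuzziness
  cen <- quantile(v, probs = seq_len(cc) / (cc + 1), names = FALSE)
  u_prev <- NULL
  trace <- numeric(0)
  for (iter in seq_len(cfg$max_iter)) {
    d2 <- outer(v, cen, function(a, b) (a - b)^2)
    d2 <- pmax(d2, 1e-12)
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    trace[iter] <- sum(um * d2)
    cen <- colSums(um * v) / colSums(um)
    if (!is.null(u_prev) && max(abs(u - u_prev)) < cfg$tol) {
      u_prev <- u
      break
    }
    u_prev <- u
  }
  vessel_cluster <- if (vessels_dark(resp)) which.min(cen) else which.max(cen)
  hard <- max.col(u_prev, ties.method = "first")
  labels <- matrix(FALSE, nrow(resp$response), ncol(resp$response))
  labels[resp$fov] <- hard == vessel_cluster
  out <- binary_segmentation(labels, resp$fov)
  attr(out, "trace") <- trace
  attr(out, "centroids") <- cen
  out
}

#' Initialize a level-set contour from a vessel estimate
#'
#' Seeds the evolution with a binary-step level-set field: +c0 on the
#' 1-px-dilated skeleton of the Otsu segmentation of the response (a
#' deterministic, centerline-like initial estimate) and -c0 elsewhere
#' (c0 = 2). If skeletonization leaves nothing, the Otsu mask itself is
#' used as fallback.
#'
#' @param resp A normalized [enhanced_image()].
#' @return A `level_set_state`: list with `phi` (signed field, interior
#'   positive), `f1`, `f2` (set by the evolution).
#' @export
init_contour <- function(resp) {
  stopifnot(inherits(resp, "enhanced_image"))
  seg <- otsu_threshold(resp)
  if (!any(seg$labels))
    stop("initialization error: Otsu produced an all-background estimate")
  sk <- skeletonize(seg$labels)
  est <- if (any(sk)) dilate_disc(sk, 1) & resp$fov else seg$labels
  phi <- matrix(-2, nrow(resp$response), ncol(resp$response))
  phi[est] <- 2
  structure(list(phi = phi, f1 = NULL, f2 = NULL), class = "level_set_state")
}

orsf_curvature <- function(phi) {
  px <- (shift_mat(phi, 0, 1) - shift_mat(phi, 0, -1)) / 2
  py <- (shift_mat(phi, 1, 0) - shift_mat(phi, -1, 0)) / 2
  mag <- sqrt(px^2 + py^2) + 1e-10
  nx <- px / mag
  ny <- py / mag
  (shift_mat(nx, 0, 1) - shift_mat(nx, 0, -1)) / 2 +
    (shift_mat(ny, 1, 0) - shift_mat(ny, -1, 0)) / 2
}

orsf_laplacian <- function(phi) {
  shift_mat(phi, 0, 1) + shift_mat(phi, 0, -1) +
    shift_mat(phi, 1, 0) + shift_mat(phi, -1, 0) - 4 * phi
}

#' Oriented region-scalable-fitting level-set evolution
#'
#' Minimizes the region-scalable fitting energy
#' `sum_i lambda_i int ( int_{Omega_i} K(x - y) |I(y) - f_i(x)|^2 dy ) dx
#'  + nu |C|`
#' by explicit gradient descent on a level-set field, with the isotropic
#' Gaussian window replaced by a bank of rotated anisotropic windows (12
#' orientations at the default 15-degree step). Each pixel uses the
#' orientation whose unit-mass kernel gives the maximal smoothing response
#' on the vessel-bright input — the per-pixel "maximum response" rule —
#' so the local fits `f1` (outside) and `f2` (inside) follow the vessel
#' direction. The Heaviside/Dirac pair is regularized with width
#' `epsilon`, the field carries a distance-regularization term, and the
#' evolution stops when the fraction of sign changes per iteration falls
#' below `convergence_tol` (or at `max_iter`). Intensities are mapped to
#' the 0..255 scale internally, the scale on which the published
#' `lambda`/`nu` operating points are meaningful.
#'
#' @param img An [enhanced_image()] (typically a weighted-mean fusion,
#'   vessels dark; the inside region of the initial contour should cover
#'   the vessel estimate, as [init_contour()] arranges).
#' @param state A `level_set_state` from [init_contour()].
#' @param cfg An [orsf_config()].
#' @param record_energy If `TRUE`, evaluate the fitting energy at every
#'   iteration and return it as attribute `"energy"` (costs one extra pass,
#'   intended for diagnostics on small images).
#' @return A [binary_segmentation()] of the `phi > 0` region. Attributes:
#'   `"state"` (final `phi`, `f1`, `f2`), `"iterations"`, and optionally
#'   `"energy"`.
#' @export
orsf_evolve <- function(img, state, cfg = orsf_config(),
                        record_energy = FALSE) {
  stopifnot(inherits(img, "enhanced_image"),
            inherits(state, "level_set_state"),
            inherits(cfg, "orsf_config"))
  I <- img$response * 255
  phi <- state$phi
  if (!identical(dim(phi), dim(I)))
    stop("level-set field and image dimensions differ")
  bank <- if (isTRUE(cfg$isotropic)) {
    R <- ceiling(3 * cfg$sigma)
    d2 <- outer((-R:R)^2, (-R:R)^2, "+")
    k <- exp(-d2 / (2 * cfg$sigma^2)) * (d2 <= (3 * cfg$sigma)^2)
    list(kernels = list(k / sum(k)), angles = 0)
  } else {
    build_kernel_bank(cfg$sigma, cfg$delta, cfg$step_deg, zero_mean = FALSE)
  }
  nk <- length(bank$kernels)
  bright <- if (vessels_dark(img)) 1 - img$response else img$response
  omap <- if (nk == 1) {
    matrix(1L, nrow(I), ncol(I))
  } else {
    arr <- conv_bank_cpp(bright, bank$kernels)
    max_over_layers(array(arr, c(dim(I), nk)))$which
  }
  storage.mode(omap) <- "integer"
  csel <- function(m) conv_select_cpp(m, bank$kernels, omap)
  KI <- csel(I)
  eps <- cfg$epsilon
  dt <- cfg$time_step
  nfov <- sum(img$fov)
  energy <- numeric(0)
  iterations <- 0L
  for (iter in seq_len(cfg$max_iter)) {
    iterations <- iter
    H <- 0.5 * (1 + (2 / pi) * atan(phi / eps))
    dirac <- (eps / pi) / (eps^2 + phi^2)
    KH <- csel(H)
    KHI <- csel(H * I)
    f2 <- KHI / pmax(KH, 1e-8)                 # inside (phi > 0) fit
    f1 <- (KI - KHI) / pmax(1 - KH, 1e-8)      # outside fit
    e1 <- I^2 - 2 * I * csel(f1) + csel(f1^2)
    e2 <- I^2 - 2 * I * csel(f2) + csel(f2^2)
    kappa <- orsf_curvature(phi)
    if (record_energy) {
      gHr <- (shift_mat(H, 1, 0) - shift_mat(H, -1, 0)) / 2
      gHc <- (shift_mat(H, 0, 1) - shift_mat(H, 0, -1)) / 2
      energy[iter] <- sum(cfg$lambda1 * (1 - H) * e1 +
                            cfg$lambda2 * H * e2) +
        cfg$nu * sum(sqrt(gHr^2 + gHc^2))
    }
    force <- dirac * (cfg$lambda1 * e1 - cfg$lambda2 * e2 +
                        cfg$nu * kappa) +
      cfg$mu * (orsf_laplacian(phi) - kappa)
    phi_new <- phi + dt * force
    if (any(!is.finite(phi_new)))
      stop("numerical failure: level-set field diverged at iteration ", iter)
    flipped <- sum((phi_new > 0) != (phi > 0) & img$fov) / nfov
    phi <- phi_new
    if (iter > 5 && flipped < cfg$convergence_tol) break
  }
  out <- binary_segmentation(phi > 0, img$fov)
  attr(out, "state") <- structure(list(phi = phi, f1 = f1, f2 = f2),
                                  class = "level_set_state")
  attr(out, "iterations") <- iterations
  if (record_energy) attr(out, "energy") <- energy
  out
}

#' Segment an enhanced image
#'
#' Dispatch over the three segmentation back-ends: a fixed global
#' threshold (median-ranking pipelines), fuzzy C-means, or the oriented
#' region-scalable-fitting level set (weighted-mean pipelines).
#'
#' @param resp An [enhanced_image()].
#' @param method One of `"threshold"`, `"fcm"`, `"orsf"`.
#' @param params Method parameters: a scalar `t` for `"threshold"`, an
#'   [fcm_config()] for `"fcm"`, an [orsf_config()] for `"orsf"`.
#' @return A [binary_segmentation()] restricted to the FOV.
#' @export
segment_image <- function(resp, method, params = NULL) {
  stopifnot(inherits(resp, "enhanced_image"))
  switch(method,
    threshold = {
      if (is.null(params)) stop("configuration error: threshold missing")
      fixed_threshold(resp, as.numeric(params))
    },
    fcm = fcm_segment(resp, if (is.null(params)) fcm_config() else params),
    orsf = orsf_evolve(resp, init_contour(resp),
                       if (is.null(params)) orsf_config() else params),
    stop("configuration error: unknown segmentation method '", method, "'"))
}
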