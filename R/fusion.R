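#' Weighted-mean fusion of enhancement responses
#'
#' Convex per-pixel combination of normalized responses, inverted so that
#' vessels come out dark: `F = 1 - sum_k g_k w_k`. Because every `g_k`
#' lies in \[0, 1\] and the weights live on the simplex, `F` stays in
#' \[0, 1\] without renormalization.
#'
#' @param responses Named list of [enhanced_image()] objects sharing shape
#'   and FOV; names are filter tags.
#' @param w A [weight_vector()] covering exactly the response tags.
#' @return An [enhanced_image()] tagged `"fused-wm"` (vessels dark).
#' @export
weighted_mean <- function(responses, w) {
  stopifnot(inherits(w, "weight_vector"))
  tags <- names(responses)
  if (is.null(tags)) tags <- vapply(responses, function(r) r$source, "")
  if (!setequal(tags, names(w)) || length(tags) != length(w))
    stop("configuration error: response tags and weight tags differ")
  fov <- responses[[1]]$fov
  dims <- dim(responses[[1]]$response)
  acc <- matrix(0, dims[1], dims[2])
  for (tag in tags) {
    r <- responses[[tag]]
    if (!identical(dim(r$response), dims) || !identical(r$fov, fov))
      stop("responses must share shape and FOV")
    acc <- acc + r$response * unclass(w)[[tag]]
  }
  f <- pmin(pmax(1 - acc, 0), 1)
  f[!fov] <- 0
  enhanced_image(f, fov, "fused-wm")
}

#' Rank transform of a response
#'
#' Orders the FOV pixels by intensity and assigns ranks 1..top with the
#' highest intensity getting rank `top` (the FOV pixel count). Ties share
#' the mean of the positions they cover. Pixels outside the FOV get rank 0.
#'
#' @param resp A normalized [enhanced_image()].
#' @return A [rank_image()].
#' @export
rank_transform <- function(resp) {
  stopifnot(inherits(resp, "enhanced_image"))
  v <- resp$response[resp$fov]
  if (length(v) == 0) stop("empty FOV")
  if (max(v) <= min(v))
    stop("degenerate input: constant response cannot be ranked")
  ranks <- matrix(0, nrow(resp$response), ncol(resp$response))
  ranks[resp$fov] <- rank(v, ties.method = "average")
  rank_image(ranks, resp$fov, length(v))
}

#' Median-ranking fusion
#'
#' Per-pixel median of the rank positions the individual filters assign to
#' each pixel (mean of the two middle values for an even number of
#' filters), min-max normalized over the FOV. A score-free fusion: only
#' orderings enter, so incompatible response scales cannot bias it.
#'
#' @param rank_images List of at least two [rank_image()] objects sharing
#'   shape and FOV.
#' @return An [enhanced_image()] tagged `"fused-mr"` (vessels bright).
#' @export
median_ranking <- function(rank_images) {
  if (length(rank_images) < 2)
    stop("median ranking needs at least two rank images")
  fov <- rank_images[[1]]$fov
  dims <- dim(rank_images[[1]]$ranks)
  for (ri in rank_images)
    if (!identical(dim(ri$ranks), dims) || !identical(ri$fov, fov))
      stop("rank images must share shape and FOV")
  m <- vapply(rank_images, function(ri) ri$ranks[fov],
              numeric(sum(fov)))
  med <- apply(m, 1, median)
  out <- matrix(0, dims[1], dims[2])
  out[fov] <- med
  normalize_response(out, fov, source = "fused-mr")
}

otsu_cut <- function(v, bins = 256) {
  # between-class variance maximization over uniform bins on [0, 1];
  # returns the cut value (upper edge of the background bin)
  h <- tabulate(pmin(pmax(floor(v * bins), 0), bins - 1) + 1L, nbins = bins)
  n <- sum(h)
  mids <- (seq_len(bins) - 0.5) / bins
  w0 <- cumsum(h)[-bins]
  w1 <- n - w0
  s0 <- cumsum(h * mids)[-bins]
  mu <- sum(h * mids) / n
  valid <- w0 > 0 & w1 > 0
  if (!any(valid))
    stop("degenerate input: constant intensity, no Otsu threshold exists")
  bcv <- rep(-Inf, bins - 1)
  bcv[valid] <- (mu * w0[valid] - s0[valid])^2 / (w0[valid] * w1[valid])
  # ties (empty histogram gap between modes): take the middle cut
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  top[ceiling(length(top) / 2)] / bins
}

#' Otsu thresholding of an enhanced image
#'
#' Picks the 256-bin histogram cut maximizing the between-class variance of
#' the FOV intensities, then labels the vessel-polarity class: below the
#' cut for weighted-mean fusions (vessels dark), above it otherwise.
#'
#' @param img An [enhanced_image()] with non-constant FOV intensities.
#' @return A [binary_segmentation()]. The attribute `"threshold"` holds the
#'   cut value.
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "enhanced_image"))
  t <- otsu_cut(img$response[img$fov])
  labels <- if (vessels_dark(img)) img$response <= t else img$response > t
  out <- binary_segmentation(labels, img$fov)
  attr(out, "threshold") <- t
  out
}

#' Pairwise Pearson correlation of responses
#'
#' Diagnostic of filter complementarity: the correlation matrix of the FOV
#' intensity vectors of a set of enhanced images. Low off-diagonal values
#' indicate incompatible scores, the regime where rank-based fusion is the
#' appropriate combiner.
#'
#' @param responses Named list of at least two [enhanced_image()] objects
#'   sharing a FOV.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(responses) {
  if (length(responses) < 2) stop("need at least two responses")
  fov <- responses[[1]]$fov
  m <- vapply(responses, function(r) {
    if (!identical(r$fov, fov)) stop("responses must share the FOV")
    r$response[fov]
  }, numeric(sum(fov)))
  if (any(apply(m, 2, sd) == 0))
    stop("undefined correlation: a response is constant inside the FOV")
  tags <- names(responses)
  if (is.null(tags)) tags <- vapply(responses, function(r) r$source, "")
  cm <- cor(m)
  dimnames(cm) <- list(tags, tags)
  cm
}

#' Learn fusion weights by a genetic algorithm
#'
#' Searches the weight simplex for the combination whose weighted-mean
#' fusion, segmented by Otsu's threshold, maximizes mean accuracy over a
#' training set (fitness `f = 1 - mean(ACC)`, minimized). Enhancement
#' responses are computed once per training image; each candidate only
#' re-mixes them, thresholds, and scores inside the FOV.
#'
#' @param train_images List of contrast-stretched [gray_image()] objects.
#' @param truths List of matching ground-truth [binary_segmentation()]s.
#' @param subset Character vector of filter tags to combine.
#' @param cfg A [ga_config()].
#' @param params Optional per-filter parameter overrides (see [enhance()]).
#' @param responses Optional precomputed list (one element per training
#'   image) of named response lists, bypassing [enhance()].
#' @return A [weight_vector()] over `subset`; attribute `"fitness"` holds
#'   the achieved objective value.
#' @export
optimize_weights <- function(train_images, truths, subset, cfg = ga_config(),
                             params = list(), responses = NULL) {
  if (length(subset) == 0) stop("configuration error: empty filter subset")
  if (length(train_images) < 1) stop("configuration error: no training pairs")
  if (length(train_images) != length(truths))
    stop("training images and truths differ in number")
  for (i in seq_along(train_images))
    if (!identical(dim(train_images[[i]]$pixels), dim(truths[[i]]$labels)))
      stop("image/truth shape mismatch at training pair ", i)
  if (length(subset) == 1) {
    w <- weight_vector(setNames(1, subset))
    attr(w, "fitness") <- NA_real_
    return(w)
  }
  if (is.null(responses))
    responses <- lapply(train_images, enhance, tags = subset, params = params)
  stacks <- lapply(seq_along(responses), function(i) {
    fov <- train_images[[i]]$fov
    list(g = vapply(responses[[i]][subset], function(r) r$response[fov],
                    numeric(sum(fov))),
         truth = truths[[i]]$labels[fov])
  })
  fitness <- function(w) {
    accs <- vapply(stacks, function(s) {
      f <- 1 - as.vector(s$g %*% w)
      t <- otsu_cut(pmin(pmax(f, 0), 1))
      mean((f <= t) == s$truth)
    }, numeric(1))
    1 - mean(accs)
  }
  res <- ga_minimize(fitness, length(subset), project_simplex, cfg,
                     init = rep(1 / length(subset), length(subset)))
  w <- weight_vector(setNames(project_simplex(res$par), subset))
  attr(w, "fitness") <- res$value
  w
}
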