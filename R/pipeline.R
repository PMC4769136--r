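VARIANTS <- c(mr = "median_ranking", `wm-fcm` = "weighted_mean_fcm",
              `wm-orsf` = "weighted_mean_orsf")

#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the pipeline variant, the
#' filter subset to fuse, the learned parameters (fusion weights for
#' weighted-mean variants, a global threshold for median ranking),
#' per-stage configurations and the seed. The elongation threshold of the
#' post-filter defaults to the published operating point of the variant:
#' 3 after ORSF, 2 otherwise.
#'
#' @param variant `"median_ranking"`, `"weighted_mean_fcm"` or
#'   `"weighted_mean_orsf"` (short forms `"mr"`, `"wm-fcm"`, `"wm-orsf"`).
#' @param filters Character vector of fusion input tags.
#' @param weights Optional [weight_vector()] (or named numeric) for
#'   weighted-mean variants.
#' @param threshold Optional scalar threshold for median ranking.
#' @param fcm An [fcm_config()].
#' @param orsf An [orsf_config()].
#' @param elongation_l Elongation threshold of the post-filter; `NULL`
#'   picks the variant default.
#' @param filter_params Per-filter overrides (see [enhance()]).
#' @param ga A [ga_config()] used when training.
#' @param rng_seed Integer seed propagated to training.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(variant, filters = c("MF", "FR", "GW"),
                            weights = NULL, threshold = NULL,
                            fcm = fcm_config(), orsf = orsf_config(),
                            elongation_l = NULL, filter_params = list(),
                            ga = NULL, rng_seed = 1) {
  if (variant %in% names(VARIANTS)) variant <- VARIANTS[[variant]]
  if (!variant %in% VARIANTS)
    stop("configuration error: unknown variant '", variant, "'")
  if (length(filters) == 0)
    stop("configuration error: empty filter subset")
  if (!is.null(weights) && !inherits(weights, "weight_vector"))
    weights <- weight_vector(weights)
  if (is.null(elongation_l))
    elongation_l <- if (variant == "weighted_mean_orsf") 3 else 2
  if (is.null(ga)) ga <- ga_config(rng_seed = rng_seed)
  structure(list(variant = variant, filters = filters, weights = weights,
                 threshold = threshold, fcm = fcm, orsf = orsf,
                 elongation_l = elongation_l,
                 filter_params = filter_params, ga = ga,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %s over {%s}, post l=%g\n", x$variant,
              paste(x$filters, collapse = ","), x$elongation_l))
  if (!is.null(x$weights)) print(x$weights)
  if (!is.null(x$threshold)) cat(sprintf("  threshold = %.4f\n", x$threshold))
  invisible(x)
}

#' Preprocess a fundus image
#'
#' Green-channel extraction followed by FOV-restricted contrast
#' stretching to \[0, 1\].
#'
#' @param image A rows x cols x 3 array, a file path, or a `phantom`.
#' @param fov Logical matrix or mask file path (ignored for phantoms).
#' @return A contrast-stretched [gray_image()].
#' @export
preprocess_fundus <- function(image, fov = NULL) {
  if (inherits(image, "phantom")) {
    fov <- image$fov
    image <- image$color
  }
  if (is.character(image)) image <- read_fundus(image)
  if (is.character(fov)) fov <- read_mask(fov)
  if (is.null(fov)) fov <- matrix(TRUE, dim(image)[1], dim(image)[2])
  contrast_stretch(green_channel(image, fov))
}

bright_view <- function(fused) {
  if (!vessels_dark(fused)) return(fused)
  v <- pmin(pmax(1 - fused$response, 0), 1)
  v[!fused$fov] <- 0
  enhanced_image(v, fused$fov, "fused-wm-inverted")
}

#' Run one segmentation pipeline end to end
#'
#' Executes preprocess, enhancement of the configured filter subset,
#' fusion (weighted mean or median ranking), segmentation (trained
#' threshold, fuzzy C-means or ORSF level set) and the elongation
#' post-filter; if ground truth is available the full metrics report is
#' attached. Configuration completeness is validated before any
#' computation starts.
#'
#' @param image Fundus image: file path, rows x cols x 3 array, or a
#'   `phantom` (which also supplies FOV and truth).
#' @param fov FOV mask: file path or logical matrix (ignored for
#'   phantoms).
#' @param cfg A [pipeline_config()].
#' @param truth Optional ground truth: file path, logical matrix, or
#'   [binary_segmentation()].
#' @param verbose Log stage progress and timings via `message()`.
#' @return A `pipeline_result`: list with `segmentation` (post-filtered),
#'   `raw_segmentation`, `fused`, `responses`, `gray`, `metrics` (or
#'   `NULL`), `config`.
#' @export
run_pipeline <- function(image, fov = NULL, cfg, truth = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$variant == "median_ranking" && is.null(cfg$threshold))
    stop("configuration error: median-ranking variant needs `threshold` ",
         "(train it first)")
  if (cfg$variant != "median_ranking" && is.null(cfg$weights))
    stop("configuration error: weighted-mean variants need `weights` ",
         "(train them first)")
  if (cfg$variant == "median_ranking" && length(cfg$filters) < 2)
    stop("configuration error: median ranking needs at least two filters")
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    say("stage %-12s %6.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  if (inherits(image, "phantom")) {
    if (is.null(truth)) truth <- image$truth
    fov <- image$fov
    image <- image$color
  }
  gray <- stage("preprocess", preprocess_fundus(image, fov))
  responses <- stage("enhance",
                     enhance(gray, cfg$filters, cfg$filter_params))
  if (cfg$variant == "median_ranking") {
    fused <- stage("fuse-mr",
                   median_ranking(lapply(responses, rank_transform)))
    seg0 <- stage("segment", fixed_threshold(fused, cfg$threshold))
  } else {
    fused <- stage("fuse-wm", weighted_mean(responses, cfg$weights))
    seg0 <- if (cfg$variant == "weighted_mean_fcm") {
      stage("segment", fcm_segment(fused, cfg$fcm))
    } else {
      stage("segment", orsf_evolve(fused, init_contour(fused), cfg$orsf))
    }
  }
  seg <- stage("postprocess", elongation_filter(seg0, cfg$elongation_l))
  metrics <- NULL
  if (!is.null(truth)) {
    if (is.character(truth)) truth <- read_mask(truth)
    if (is.matrix(truth)) truth <- binary_segmentation(truth, gray$fov)
    metrics <- stage("evaluate",
                     evaluate_segmentation(seg, truth, bright_view(fused)))
    say("ACC %.4f  MCC %.4f  CAL %.4f", metrics$acc, metrics$mcc,
        metrics$cal)
  }
  structure(list(segmentation = seg, raw_segmentation = seg0,
                 fused = fused, responses = responses, gray = gray,
                 metrics = metrics, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s: %d vessel px\n", x$config$variant,
              sum(x$segmentation$labels)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Train the learned parameters of a pipeline
#'
#' Dispatches to the genetic-algorithm weight search (weighted-mean
#' variants: fusion weights on the simplex, Otsu + accuracy in the loop)
#' or threshold search (median ranking: scalar cut on the fused rank
#' response) over a set of training triples, and returns the completed
#' configuration. Reproducible from the seed carried by `cfg`.
#'
#' @param images List of fundus images (paths, arrays or phantoms).
#' @param fovs List of FOV masks (ignored for phantoms).
#' @param truths List of ground truths (paths, matrices or
#'   [binary_segmentation()]; ignored for phantoms).
#' @param cfg A [pipeline_config()].
#' @return The `pipeline_config` with `weights` or `threshold` filled in;
#'   attribute `"fitness"` holds the achieved training objective.
#' @export
train_pipeline <- function(images, fovs = NULL, truths = NULL, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(images) < 1)
    stop("configuration error: empty training set")
  grays <- vector("list", length(images))
  gts <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (inherits(im, "phantom")) {
      grays[[i]] <- preprocess_fundus(im)
      gts[[i]] <- im$truth
    } else {
      grays[[i]] <- preprocess_fundus(im, fovs[[i]])
      tr <- truths[[i]]
      if (is.character(tr)) tr <- read_mask(tr)
      if (is.matrix(tr)) tr <- binary_segmentation(tr, grays[[i]]$fov)
      gts[[i]] <- tr
    }
  }
  fitness <- NA_real_
  if (cfg$variant == "median_ranking") {
    fused <- lapply(grays, function(g) {
      median_ranking(lapply(enhance(g, cfg$filters, cfg$filter_params),
                            rank_transform))
    })
    t <- optimize_threshold(fused, gts, cfg$ga)
    fitness <- attr(t, "fitness")
    cfg$threshold <- as.numeric(t)
  } else {
    w <- optimize_weights(grays, gts, cfg$filters, cfg$ga,
                          params = cfg$filter_params)
    fitness <- attr(w, "fitness")
    cfg$weights <- w
  }
  attr(cfg, "fitness") <- fitness
  cfg
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- list(
    variant = cfg$variant,
    filters = as.list(cfg$filters),
    weights = if (is.null(cfg$weights)) NULL else
      as.list(setNames(as.numeric(cfg$weights), names(cfg$weights))),
    threshold = cfg$threshold,
    elongation_l = cfg$elongation_l,
    fcm = unclass(cfg$fcm),
    orsf = unclass(cfg$orsf),
    ga = unclass(cfg$ga),
    rng_seed = cfg$rng_seed)
  yaml::write_yaml(lst[!vapply(lst, is.null, TRUE)], path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pipeline_config(
    variant = lst$variant,
    filters = unlist(lst$filters),
    weights = if (!is.null(lst$weights)) unlist(lst$weights),
    threshold = lst$threshold,
    fcm = do.call(fcm_config, lst$fcm %||% list()),
    orsf = do.call(orsf_config, lst$orsf %||% list()),
    elongation_l = lst$elongation_l,
    ga = do.call(ga_config, lst$ga %||% list()),
    rng_seed = lst$rng_seed %||% 1)
}
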