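label_components <- function(mask) {
  storage.mode(mask) <- "logical"
  label_components_cpp(mask)
}

crack_perimeter <- function(lab) {
  # boundary-crack length per label: count of pixel edges exposed to a
  # different label or to the image border
  n <- max(lab)
  if (n == 0) return(numeric(0))
  per <- numeric(n)
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_mat(lab, sh[1], sh[2])
    # replicate padding makes border neighbors equal; mark true borders
    nr <- nrow(lab); nc <- ncol(lab)
    if (sh[1] == 1) nb[nr, ] <- 0
    if (sh[1] == -1) nb[1, ] <- 0
    if (sh[2] == 1) nb[, nc] <- 0
    if (sh[2] == -1) nb[, 1] <- 0
    exposed <- lab > 0 & nb != lab
    per <- per + tabulate(lab[exposed], nbins = n)
  }
  per
}

#' Per-blob shape statistics
#'
#' Identifies the 8-connected components of a binary segmentation and
#' reports, per blob, its pixel area `a`, its boundary-crack perimeter `P`
#' (count of exposed pixel edges), and the isoperimetric elongation
#' `E = P^2 / (4 pi a)` — near 1 for a disc, large for thin elongated
#' structures. 8-connectivity is used because vessels are thin diagonal
#' structures that 4-connectivity would fragment.
#'
#' @param seg A [binary_segmentation()].
#' @return A data frame with columns `label`, `area`, `perimeter`,
#'   `elongation` (empty for an empty segmentation).
#' @export
blob_stats <- function(seg) {
  stopifnot(inherits(seg, "binary_segmentation"))
  lab <- label_components(seg$labels)
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(0), area = integer(0),
                      perimeter = numeric(0), elongation = numeric(0)))
  area <- tabulate(lab[lab > 0], nbins = n)
  per <- crack_perimeter(lab)
  data.frame(label = seq_len(n), area = area, perimeter = per,
             elongation = per^2 / (4 * pi * area))
}

#' Remove non-elongated blobs
#'
#' Drops every 8-connected component whose elongation `E = P^2 / (4 pi a)`
#' falls below the threshold `l`; elongated (vessel-like) blobs are kept
#' verbatim. The operation only removes pixels, is idempotent, and is
#' anti-monotone in `l`. Default `l = 2` suits threshold/FCM pipelines;
#' `l = 3` is the published operating point for ORSF output.
#'
#' @param seg A [binary_segmentation()].
#' @param l Positive elongation threshold (default 2).
#' @return The filtered [binary_segmentation()].
#' @export
elongation_filter <- function(seg, l = 2) {
  stopifnot(inherits(seg, "binary_segmentation"))
  if (!is.numeric(l) || length(l) != 1 || l <= 0)
    stop("`l` must be a positive scalar")
  st <- blob_stats(seg)
  if (nrow(st) == 0) return(seg)
  keep <- st$label[st$elongation >= l]
  lab <- label_components(seg$labels)
  binary_segmentation(matrix(lab %in% keep, nrow(lab), ncol(lab)), seg$fov)
}
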