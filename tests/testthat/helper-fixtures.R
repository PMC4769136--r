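# Shared in-code fixtures: small deterministic images and segmentations.

rand_gray <- function(nr = 32, nc = 32, seed = 1, fov = NULL) {
  set.seed(seed)
  gray_image(matrix(runif(nr * nc), nr, nc), fov)
}

rand_response <- function(nr = 32, nc = 32, seed = 1, source = "MF",
                          fov = NULL) {
  set.seed(seed)
  if (is.null(fov)) fov <- matrix(TRUE, nr, nc)
  normalize_response(matrix(runif(nr * nc), nr, nc), fov, source = source)
}

seg_from <- function(mask, fov = NULL) {
  if (is.null(fov)) fov <- matrix(TRUE, nrow(mask), ncol(mask))
  binary_segmentation(mask, fov)
}

# a filled disc mask of radius r centred in an n x n grid
disc_mask <- function(n, r, centre = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, "+")
  d2 <= r^2
}

# horizontal bar mask: rows r1..r2, cols c1..c2 in an n x n grid
bar_mask <- function(n, r1, r2, c1, c2) {
  m <- matrix(FALSE, n, n)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# independent 8-connected component count (breadth-first search)
count_components_oracle <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p] > 0) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- (q - 1) %% n + 1; cc <- (q - 1) %/% n + 1
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > n || c2 < 1 || c2 > m) next
        q2 <- (c2 - 1) * n + r2
        if (mask[q2] && lab[q2] == 0) {
          lab[q2] <- cur
          queue <- c(queue, q2)
        }
      }
    }
  }
  cur
}

# independent raster read (EBImage directly), (row, col) orientation
read_raster_for_test <- function(path) {
  t(EBImage::imageData(EBImage::readImage(path)))
}

# brute-force Euclidean disc dilation, independent of the package's
# EBImage-backed implementation
dilate_oracle <- function(mask, radius) {
  if (radius <= 0) return(mask)
  r <- floor(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -r:r) for (dc in -r:r) {
    if (dr^2 + dc^2 > radius^2) next
    nr <- nrow(mask); nc <- ncol(mask)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- out[rs - dr, cs - dc] | mask[rs, cs]
  }
  out
}
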