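zshift <- function(m, dr, dc) {
  # zero-padded shift: out(r, c) = m(r + dr, c + dc), 0 outside
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Morphological skeleton by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels that do not break connectivity until
#' a one-pixel-wide skeleton remains. The algorithm choice is pinned by a
#' golden-fixture test because the length-coincidence factor of the
#' segmentation quality score depends on which skeletonization is used.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @return Logical matrix of the skeleton.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- (mask != 0) * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- zshift(m, -1, 0); p3 <- zshift(m, -1, 1)
      p4 <- zshift(m, 0, 1);  p5 <- zshift(m, 1, 1)
      p6 <- zshift(m, 1, 0);  p7 <- zshift(m, 1, -1)
      p8 <- zshift(m, 0, -1); p9 <- zshift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
        (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
        (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1
}
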