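#' @title Raster input/output for fundus images, masks and segmentations
#' @name imaging-io
#' @description Readers and writers for the rasters the pipeline touches:
#'   color fundus photographs, binary FOV masks and ground-truth vessel
#'   maps, and binary segmentations. PNG and TIFF are decoded by EBImage;
#'   PPM/PGM (the STARE dialect) by a built-in parser. Images are stored as
#'   standard R matrices in (row, col) order with intensities in \[0, 1\].
NULL

format_of <- function(path) {
  tolower(sub(".*\\.", "", path))
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected end of PPM file: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  w <- as.integer(token()); h <- as.integer(token())
  maxval <- as.integer(token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxval > 255) stop("16-bit PNM not supported: ", path)
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PNM file: ", path)
  # PNM is row-major, channel-interleaved
  if (nch == 3L) {
    arr <- array(NA_real_, c(h, w, 3))
    for (ch in 1:3)
      arr[, , ch] <- matrix(vals[seq(ch, n, by = 3)] / maxval,
                            nrow = h, ncol = w, byrow = TRUE)
    arr
  } else {
    matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
  }
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster, no such file: ", path)
  fmt <- format_of(path)
  if (fmt %in% c("ppm", "pgm", "pnm")) return(read_ppm(path))
  if (fmt == "gif")
    stop("GIF decoding is not supported; convert '", path,
         "' to PNG, TIFF or PPM")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode raster '", path,
                                           "': ", conditionMessage(e)))
  dat <- EBImage::imageData(img)
  # EBImage stores (x = col, y = row); transpose to (row, col)
  if (length(dim(dat)) == 2) t(dat)
  else aperm(dat[, , seq_len(min(3, dim(dat)[3])), drop = FALSE], c(2, 1, 3))
}

#' Read a color fundus photograph
#'
#' @param path Path to an 8-bit PNG, TIFF or PPM raster with three
#'   channels.
#' @return A rows x cols x 3 numeric array with channel values in \[0, 1\].
#' @export
read_fundus <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) != 3 || dim(arr)[3] != 3)
    stop("fundus image '", path, "' is not a 3-channel raster")
  arr
}

#' Read a binary mask raster (FOV or ground truth)
#'
#' Any nonzero pixel is treated as `TRUE`; multi-channel rasters use their
#' first channel.
#'
#' @param path Path to the mask raster.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr != 0
}

#' Read a grayscale raster as an intensity matrix
#'
#' Multi-channel rasters use their first channel.
#'
#' @param path Path to the raster.
#' @return A numeric matrix with values in \[0, 1\].
#' @export
read_gray <- function(path) {
  arr <- read_raster(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr
}

#' Extract the green channel
#'
#' The green channel offers the best vessel/background contrast in fundus
#' photographs; red and blue are discarded.
#'
#' @param color A rows x cols x 3 array as returned by [read_fundus()].
#' @param fov Logical FOV matrix with matching rows x cols.
#' @return A [gray_image()] whose pixels are the green plane.
#' @export
green_channel <- function(color, fov) {
  if (length(dim(color)) != 3 || dim(color)[3] != 3)
    stop("`color` must be a rows x cols x 3 array")
  if (!identical(dim(color)[1:2], dim(fov)))
    stop("`color` and `fov` dimensions differ")
  gray_image(color[, , 2], fov)
}

#' Contrast stretching
#'
#' Affine rescaling of intensities so that the darkest FOV pixel maps to
#' `alpha1` and the brightest to `alpha2`:
#' `p_out = (p - beta1) * (alpha2 - alpha1) / (beta2 - beta1) + alpha1`,
#' where `beta1`/`beta2` are the minimum/maximum intensity inside the FOV.
#' The input range is measured inside the FOV only, so the black border of
#' a fundus frame cannot dominate it; pixels outside the FOV are set to 0.
#'
#' @param img A [gray_image()] (needs at least two distinct FOV values).
#' @param limits A [stretch_limits()] object; defaults to \[0, 1\].
#' @return The stretched [gray_image()], clipped to the output limits.
#' @export
contrast_stretch <- function(img, limits = stretch_limits()) {
  stopifnot(inherits(img, "gray_image"), inherits(limits, "stretch_limits"))
  v <- img$pixels[img$fov]
  b1 <- min(v); b2 <- max(v)
  if (b2 <= b1)
    stop("degenerate input: constant intensity inside the FOV")
  out <- (img$pixels - b1) * (limits$alpha2 - limits$alpha1) / (b2 - b1) +
    limits$alpha1
  out <- pmin(pmax(out, limits$alpha1), limits$alpha2)
  out[!img$fov] <- 0
  gray_image(out, img$fov)
}

#' Write a binary segmentation as an 8-bit PNG
#'
#' Vessel pixels are stored as 255 and background as 0; the round trip
#' through [read_mask()] is lossless.
#'
#' @param seg A [binary_segmentation()].
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "binary_segmentation"))
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(t(seg$labels * 1)), path, type = "png")
    TRUE
  }, error = function(e) stop("cannot write segmentation to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a grayscale response as a 16-bit PNG
#'
#' @param mat Numeric matrix in \[0, 1\].
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_gray <- function(mat, path) {
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(mat, 0), 1))), path,
                      type = "png", bits.per.sample = 16L)
  invisible(path)
}

#' Write a color image as an 8-bit PNG
#'
#' @param arr rows x cols x 3 numeric array in \[0, 1\].
#' @param path Output path (PNG).
#' @return Invisibly, `path`.
#' @export
write_color <- function(arr, path) {
  EBImage::writeImage(
    EBImage::Image(aperm(pmin(pmax(arr, 0), 1), c(2, 1, 3)),
                   colormode = "Color"),
    path, type = "png")
  invisible(path)
}
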