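#' Frame objects and color-space conversions
#'
#' A `vframe` is the unit every pipeline stage consumes: an RGB raster with
#' channel values in \[0, 1\] plus an optional aligned depth plane in \[0, 1\].
#' Pixel coordinates are 0-based `(x, y)`, x rightward, y downward; all
#' rectangles are half-open `[x, x + w) x [y, y + h)`.
#'
#' @param rgb numeric `H x W x 3` array with values in \[0, 1\].
#' @param depth optional numeric `H x W` matrix with values in \[0, 1\].
#' @param index 0-based frame ordinal.
#' @param fps frame rate used to derive the timestamp (seconds = index / fps).
#' @return An object of class `vframe` with fields `rgb`, `depth`, `index`,
#'   `timestamp`.
#' @export
vframe <- function(rgb, depth = NULL, index = 0L, fps = 30) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("'rgb' must be an H x W x 3 array")
  if (min(rgb) < -1e-9 || max(rgb) > 1 + 1e-9)
    stop("'rgb' channel values must lie in [0, 1]")
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(rgb)[1:2]))
      stop("depth plane dimensions must match the rgb raster")
  }
  structure(
    list(rgb = rgb, depth = depth, index = as.integer(index),
         timestamp = as.integer(index) / fps),
    class = "vframe")
}

#' @export
print.vframe <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<vframe #%d: %d x %d RGB%s, t = %.3f s>\n",
              x$index, d[2L], d[1L],
              if (is.null(x$depth)) "" else " + depth", x$timestamp))
  invisible(x)
}

frame_dim <- function(frame) dim(frame$rgb)[1:2]

#' Load a numbered image sequence as frames
#'
#' Reads a directory of numbered RGB images (8-bit PNG) and, optionally, a
#' directory of aligned depth images (16-bit grayscale PNG or TIFF), pairing
#' RGB and depth by shared numeric stem. Values are rescaled to \[0, 1\]
#' (8-bit by 255, 16-bit by 65535, as done by the readers).
#'
#' @param path directory containing the RGB frames.
#' @param depth_path optional directory containing depth frames.
#' @param fps frame rate recorded on the frames.
#' @param prefix,depth_prefix optional file-name prefixes selecting the RGB /
#'   depth files when a directory mixes several image roles (as the
#'   [write_sequence()] layout does).
#' @return List of [vframe] objects sorted by numeric index.
#' @export
load_frame_sequence <- function(path, depth_path = NULL, fps = 30,
                                prefix = NULL, depth_prefix = NULL) {
  files <- list_numbered_images(path, prefix)
  if (length(files) == 0L)
    stop("no numbered image files found in ", path)
  depth_files <- NULL
  if (!is.null(depth_path)) {
    depth_files <- list_numbered_images(depth_path, depth_prefix)
    if (length(depth_files) != length(files))
      stop("depth sequence length (", length(depth_files),
           ") does not match RGB sequence length (", length(files), ")")
  }
  ref_dim <- NULL
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    rgb <- read_rgb_image(files[i])
    if (is.null(ref_dim)) ref_dim <- dim(rgb)[1:2]
    if (!all(dim(rgb)[1:2] == ref_dim))
      stop("frame dimension mismatch in file ", basename(files[i]))
    depth <- NULL
    if (!is.null(depth_files)) {
      depth <- read_gray_image(depth_files[i])
      if (!all(dim(depth) == ref_dim))
        stop("depth dimension mismatch in file ", basename(depth_files[i]))
    }
    frames[[i]] <- vframe(rgb, depth, index = i - 1L, fps = fps)
  }
  frames
}

list_numbered_images <- function(path, prefix = NULL) {
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!is.null(prefix)) files <- files[startsWith(basename(files), prefix)]
  stems <- sub("\\.[^.]*$", "", basename(files))
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", stems)))
  files <- files[!is.na(num)]
  num <- num[!is.na(num)]
  files[order(num)]
}

read_rgb_image <- function(file) {
  x <- if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
       else tiff::readTIFF(file)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3L] > 3L) x <- x[, , 1:3, drop = FALSE]
  x
}

read_gray_image <- function(file) {
  x <- if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
       else tiff::readTIFF(file)
  if (!is.matrix(x)) x <- x[, , 1L]
  x
}

#' Convert an RGB frame to HSV planes
#'
#' Hue is stored on \[0, 1) so that hue differences can be taken on the
#' circle (`min(|dh|, 1 - |dh|)`, see [hue_distance()]); achromatic pixels
#' (max = min) get h = 0, s = 0 by convention.
#'
#' @param frame a [vframe] or an `H x W x 3` array in \[0, 1\].
#' @return List with matrices `h` (in \[0, 1)), `s`, `v` (in \[0, 1\]).
#' @export
rgb_to_hsv <- function(frame) {
  rgb <- if (inherits(frame, "vframe")) frame$rgb else frame
  d <- dim(rgb)[1:2]
  m <- rbind(as.vector(rgb[, , 1L]), as.vector(rgb[, , 2L]),
             as.vector(rgb[, , 3L]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  h <- matrix(hsv[1L, ], d[1L], d[2L])
  h[h >= 1] <- 0  # keep hue on [0, 1)
  list(h = h,
       s = matrix(hsv[2L, ], d[1L], d[2L]),
       v = matrix(hsv[3L, ], d[1L], d[2L]))
}

#' Circular hue distance
#'
#' @param h1,h2 hue values on \[0, 1).
#' @return Elementwise `min(|h1 - h2|, 1 - |h1 - h2|)`.
#' @export
hue_distance <- function(h1, h2) {
  d <- abs(h1 - h2)
  pmin(d, 1 - d)
}

#' Normalized rg chromaticity
#'
#' Computes the illumination-invariant chromaticity coordinates
#' r = R / (R + G + B) and g = G / (R + G + B). Pixels with R + G + B = 0
#' get r = g = 1/3 (neutral chromaticity) so that downstream chromaticity
#' differences stay well defined on black pixels.
#'
#' @param frame a [vframe] or an `H x W x 3` array in \[0, 1\].
#' @return List with matrices `r` and `g`, each in \[0, 1\].
#' @export
normalized_rg <- function(frame) {
  rgb <- if (inherits(frame, "vframe")) frame$rgb else frame
  s <- rgb[, , 1L] + rgb[, , 2L] + rgb[, , 3L]
  zero <- s == 0
  s[zero] <- 1
  r <- rgb[, , 1L] / s
  g <- rgb[, , 2L] / s
  r[zero] <- 1 / 3
  g[zero] <- 1 / 3
  list(r = r, g = g)
}
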