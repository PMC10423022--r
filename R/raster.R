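#' Binary segmentation masks and membrane probability maps
#'
#' `binary_mask()` wraps an H x W matrix over \{0, 1\} (foreground = membrane
#' pixels); `prob_map()` wraps an H x W matrix of per-pixel membrane
#' probabilities in \[0, 1\]. Both are stored row-major with origin at the
#' top-left, 1-based (row, col) indexing, the convention shared by every
#' function in the package.
#'
#' @param x numeric or integer matrix.
#' @return An object of class `binary_mask` or `prob_map` (a plain matrix with
#'   a class attribute).
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' p <- prob_map(matrix(0.5, 4, 4))
#' @export
binary_mask <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("mask must be at least 1 x 1")
  if (!all(x == 0 | x == 1)) stop("binary_mask values must be in {0, 1}")
  storage.mode(x) <- "integer"
  structure(x, class = c("binary_mask", "matrix", "array"))
}

#' @rdname binary_mask
#' @export
prob_map <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("probability map must be at least 1 x 1")
  storage.mode(x) <- "double"
  if (anyNA(x) || any(x < 0 | x > 1)) stop("prob_map values must be in [0, 1]")
  structure(x, class = c("prob_map", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map %d x %d, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")
is_prob_map <- function(x) inherits(x, "prob_map")

as_matrix_plain <- function(x) {
  attr(x, "class") <- NULL
  x
}

#' Read a single-channel raster as a mask or probability map
#'
#' Reads a PNG or TIFF file. Rasters holding exactly two distinct values are
#' interpreted as a [binary_mask()] (the larger value maps to foreground 1),
#' as are constant all-0 / all-1 rasters; anything else is returned as a
#' [prob_map()] on the reader's native \[0, 1\] scale (values outside that
#' range are min-max rescaled). PNG/TIFF readers return intensities already
#' scaled to \[0, 1\]; the two-valued test is applied on that scale.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return A `binary_mask` or `prob_map`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) {
      img <- img[, , 1L]
    } else {
      stop("multi-channel rasters are not supported: ", path)
    }
  }
  vals <- sort(unique(as.vector(img)))
  if (length(vals) == 2L) {
    # exactly two levels -> binary, larger level = foreground
    return(binary_mask((img == vals[2L]) * 1L))
  }
  if (length(vals) == 1L && vals %in% c(0, 1)) {
    # constant all-background / all-foreground mask; other constants are
    # probability maps (a constant 0.5 map must round-trip as one)
    return(binary_mask(img))
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) img <- (img - rng[1]) / (rng[2] - rng[1])
  prob_map(img)
}

#' Write a mask or probability map to PNG or TIFF
#'
#' Binary masks are written with foreground 1 mapped to full intensity, so a
#' read/write round-trip is bit-exact. Probability maps written as 8-bit PNG
#' round-trip to within 1/255 per pixel; TIFF output is 32-bit float and
#' round-trips exactly.
#'
#' @param x a `binary_mask` or `prob_map`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(x, path) {
  stopifnot(is_binary_mask(x) || is_prob_map(x))
  img <- as_matrix_plain(x)
  storage.mode(img) <- "double"
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png = {
      png::writePNG(img, target = path)
      TRUE
    },
    tif = ,
    tiff = {
      tiff::writeTIFF(img, where = path, bits.per.sample = 32L)
      TRUE
    },
    stop("unsupported raster format: .", ext)
  )
  if (!isTRUE(ok) && !is.integer(ok)) stop("failed to write raster: ", path)
  invisible(path)
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability strictly exceeds `threshold`
#' (ties go to background), so `binarize` is idempotent on its own output.
#'
#' @param p a [prob_map()] (a `binary_mask` is accepted and converted).
#' @param threshold scalar in \[0, 1\]; default 0.5.
#' @return A [binary_mask()].
#' @export
binarize <- function(p, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a scalar in [0, 1]")
  }
  binary_mask((as_matrix_plain(p) > threshold) * 1L)
}

#' Invert mask polarity
#'
#' Membrane datasets sometimes ship with background = 1; this flips the
#' labels so that foreground 1 = membrane, the polarity every metric assumes.
#'
#' @param mask a [binary_mask()].
#' @return A [binary_mask()] with 0/1 swapped.
#' @export
invert_mask <- function(mask) {
  stopifnot(is_binary_mask(mask))
  binary_mask(1L - as_matrix_plain(mask))
}
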