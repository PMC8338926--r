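#' Normalized grayscale image
#'
#' Container for a single-channel 2-D image with intensities in \[0, 1\] and
#' optional pixel-pitch metadata. All filtering and geometry functions in the
#' package operate on this class. Pixels are stored row-major (a base R
#' matrix, rows = image rows top to bottom); angles reported anywhere in the
#' package use the display convention (counter-clockwise from the rightward
#' +x axis, y pointing up).
#'
#' @param pixels numeric matrix with finite values in \[0, 1\], at least
#'   16 x 16.
#' @param px_per_mm optional scalar > 0, pixel pitch. A Spectralis-style
#'   6 mm / 512 px en face acquisition corresponds to `512/6` (about 85.3).
#' @return an object of class `scalar_image`: a list with elements `pixels`,
#'   `height`, `width`, `px_per_mm`.
#' @examples
#' img <- scalar_image(matrix(runif(32 * 32), 32, 32), px_per_mm = 512 / 6)
#' dim(img$pixels)
#' @export
scalar_image <- function(pixels, px_per_mm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16 x 16 pixels", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("all intensities must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (!is.null(px_per_mm)) {
    if (!is.numeric(px_per_mm) || length(px_per_mm) != 1L || px_per_mm <= 0)
      stop("`px_per_mm` must be a positive scalar", call. = FALSE)
  }
  structure(
    list(pixels = unname(pixels), height = nrow(pixels),
         width = ncol(pixels), px_per_mm = px_per_mm),
    class = "scalar_image"
  )
}

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("<scalar_image> %d x %d px", x$height, x$width))
  if (!is.null(x$px_per_mm))
    cat(sprintf(", %.2f px/mm", x$px_per_mm))
  cat(sprintf(", intensity range [%.3f, %.3f]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Coerce matrices / scalar_image transparently (internal).
as_scalar_image <- function(x, px_per_mm = NULL) {
  if (inherits(x, "scalar_image")) return(x)
  scalar_image(as.matrix(x), px_per_mm = px_per_mm)
}

#' Read a grayscale PNG or TIFF image
#'
#' Reads an 8- or 16-bit single-channel image and scales intensities to
#' \[0, 1\] by the bit-depth maximum (the underlying readers already return
#' values on that scale). Multi-channel (RGB/RGBA) input is rejected with an
#' instruction to convert, since an angiogram is a scalar flow-signal map.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param px_per_mm optional pixel pitch to attach to the result.
#' @return a [scalar_image].
#' @export
load_image <- function(path, px_per_mm = NULL) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] == 1L) {
      arr <- arr[, , 1L]
    } else {
      stop(sprintf(
        "'%s' has %d channels; convert to single-channel grayscale first",
        path, dim(arr)[3L]), call. = FALSE)
    }
  }
  arr <- pmin(pmax(arr, 0), 1)  # guard against float TIFF rounding
  scalar_image(arr, px_per_mm = px_per_mm)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param image a [scalar_image] or numeric matrix in \[0, 1\].
#' @param path output path; format chosen by extension (`.png`, `.tif`).
#' @param bits bit depth for PNG/TIFF quantization (8 or 16).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path, bits = 16L) {
  img <- as_scalar_image(image)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img$pixels, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img$pixels, where = path,
                    bits.per.sample = as.integer(bits))
  } else {
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  }
  invisible(path)
}
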