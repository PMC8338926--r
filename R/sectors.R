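#' Macular disk mask
#'
#' Builds the circular region of interest centered at the macula. A pixel is
#' included iff its center lies within `diameter_mm * px_per_mm / 2` of the
#' given center. The standard analysis region is a 5-mm disk inside a
#' 6 x 6 mm scan, which trims edge artifacts.
#'
#' @param center numeric `(row, col)` of the macula center, in pixels.
#' @param diameter_mm disk diameter in millimetres (default 5).
#' @param px_per_mm pixel pitch.
#' @param image_shape integer `(height, width)`.
#' @return list with logical matrix `pixels` and scalar `radius_px`.
#' @export
disk_mask <- function(center, diameter_mm = 5, px_per_mm,
                      image_shape) {
  if (length(center) != 2L || any(!is.finite(center)))
    stop("`center` must be finite (row, col)", call. = FALSE)
  if (diameter_mm <= 0 || px_per_mm <= 0)
    stop("`diameter_mm` and `px_per_mm` must be positive", call. = FALSE)
  h <- image_shape[1L]; w <- image_shape[2L]
  radius <- diameter_mm * px_per_mm / 2
  if (center[1L] - radius < 0.5 || center[1L] + radius > h + 0.5 ||
      center[2L] - radius < 0.5 || center[2L] + radius > w + 0.5)
    stop("disk of radius ", round(radius, 1),
         " px does not fit inside the image at the given center",
         call. = FALSE)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  px <- (rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2
  list(pixels = px, radius_px = radius)
}

# sector labels in counter-clockwise order starting at the nasal axis
# (N nasal, S superior, T temporal, I inferior)
.sector_labels <- c("NS", "SN", "ST", "TS", "TI", "IT", "IN", "NI")

#' Eight anatomical 45-degree sectors of the macular disk
#'
#' Splits the disk into eight equal-area 45-degree wedges labelled by the
#' nasal/superior/temporal/inferior axes: NS, SN, ST, TS, TI, IT, IN, NI.
#' For a right eye (OD) the nasal axis points to the image right and wedges
#' proceed counter-clockwise from it (NS spans \[0, 45) degrees, SN
#' \[45, 90), ... in display coordinates, y up); for a left eye (OS) the
#' geometry is the exact left-right mirror, so nasal points left and wedges
#' proceed clockwise from it. With this construction, mirroring an OD image
#' horizontally and relabelling as OS swaps N and T in every label while S
#' and I are unchanged, pixel for pixel.
#'
#' Wedges are half-open so boundary pixels are assigned exactly once; a
#' pixel is assigned by the polar angle of its center about the disk center.
#'
#' @param center numeric `(row, col)` macula center in pixels.
#' @param diameter_mm disk diameter in millimetres.
#' @param px_per_mm pixel pitch.
#' @param image_shape integer `(height, width)`.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @return an object of class `sector_roi`: list with `center`, `radius_px`,
#'   `eye`, `disk` (logical matrix), `sector_id` (integer matrix, 0 outside
#'   the disk, 1..8 per sector), `labels` (id -> label), and
#'   `angular_ranges` (per-label display-angle interval, degrees CCW
#'   from +x).
#' @examples
#' roi <- sector_roi(c(64, 64), diameter_mm = 5, px_per_mm = 20,
#'                   image_shape = c(128, 128), eye = "OD")
#' table(roi$sector_id[roi$disk])
#' @export
sector_roi <- function(center, diameter_mm = 5, px_per_mm, image_shape,
                       eye = c("OD", "OS")) {
  eye <- match.arg(eye)
  dk <- disk_mask(center, diameter_mm, px_per_mm, image_shape)
  h <- image_shape[1L]; w <- image_shape[2L]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  # display coordinates: x right, y up
  x <- cols - center[2L]
  y <- center[1L] - rows
  alpha <- (atan2(y, x) * 180 / pi) %% 360
  if (eye == "OD") {
    k <- floor(alpha / 45) %% 8
  } else {
    # mirrored frame: angle measured clockwise from the leftward nasal axis;
    # intervals half-open on the opposite side so the mirror of an OD
    # boundary pixel lands in the mirrored sector
    beta <- (180 - alpha) %% 360
    k <- (ceiling(beta / 45) - 1) %% 8
  }
  sector_id <- matrix(0L, h, w)
  sector_id[dk$pixels] <- as.integer(k[dk$pixels]) + 1L
  ranges <- lapply(seq_len(8L), function(i) {
    if (eye == "OD") c(from = (i - 1) * 45, to = i * 45)
    else c(from = (180 - i * 45) %% 360, to = (180 - (i - 1) * 45) %% 360)
  })
  names(ranges) <- .sector_labels
  structure(
    list(center = center, radius_px = dk$radius_px, eye = eye,
         disk = dk$pixels, sector_id = sector_id,
         labels = .sector_labels, angular_ranges = ranges),
    class = "sector_roi"
  )
}

#' Logical mask of one sector
#'
#' @param roi a `sector_roi`.
#' @param label one of `"NS"`, `"SN"`, `"ST"`, `"TS"`, `"TI"`, `"IT"`,
#'   `"IN"`, `"NI"`.
#' @return logical matrix.
#' @export
sector_mask <- function(roi, label) {
  i <- match(label, roi$labels)
  if (is.na(i)) stop("unknown sector label '", label, "'", call. = FALSE)
  roi$sector_id == i
}

#' @export
print.sector_roi <- function(x, ...) {
  cat(sprintf(
    "<sector_roi> eye %s, center (%.1f, %.1f) px, radius %.1f px\n",
    x$eye, x$center[1L], x$center[2L], x$radius_px))
  n <- tabulate(x$sector_id[x$disk], 8L)
  cat("  sector pixel counts:",
      paste(sprintf("%s=%d", x$labels, n), collapse = " "), "\n")
  invisible(x)
}

#' Export sector labels as an 8-bit PNG plus a JSON legend
#'
#' Writes the sector-id matrix (0 outside the disk, 1-8 per sector, scaled
#' into gray levels) and a JSON file mapping gray levels to anatomical
#' labels and angular ranges.
#'
#' @param roi a `sector_roi`.
#' @param path output `.png` path; the legend is written alongside with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
save_sector_map <- function(roi, path) {
  png::writePNG(roi$sector_id / 8, target = path)
  legend <- list(
    eye = roi$eye,
    center_row_col = roi$center,
    radius_px = roi$radius_px,
    sectors = lapply(seq_len(8L), function(i) {
      list(id = i, label = roi$labels[i], gray_level = i / 8,
           angular_range_deg = as.list(roi$angular_ranges[[roi$labels[i]]]))
    })
  )
  jsonlite::write_json(legend, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
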