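#' Axial orientation histogram of a region
#'
#' Accumulates the per-pixel vessel orientations of the masked pixels inside
#' a region into an angular histogram over \[0, 360) degrees. Orientation is
#' axial (head-tail equivalent), so each contributing pixel with orientation
#' `theta` in \[0, 180) increments both the bin at `theta` and the bin at
#' `theta + 180`; the histogram is therefore exactly symmetric under a
#' 180-degree shift and its total mass is twice the number of contributing
#' pixels. Pixels with undefined orientation (`NA`) are skipped.
#'
#' @param theta matrix of axial orientations in degrees (\[0, 180), `NA`
#'   undefined), e.g. `theta0` from [multiscale_vesselness()].
#' @param mask a `binary_mask` or logical matrix selecting vessel pixels.
#' @param region logical matrix selecting the region of interest (e.g. one
#'   sector); `NULL` means the whole image.
#' @param bin_width bin width in degrees; must divide 180.
#' @return an object of class `orientation_distribution`: list with `counts`
#'   (length `360 / bin_width`, bin k covering
#'   \[k * bin_width, (k+1) * bin_width)), `bin_width`, `n_pixels`, and
#'   logical `empty` flagging a histogram with no contributing pixels.
#' @export
orientation_histogram <- function(theta, mask, region = NULL,
                                  bin_width = 1) {
  if (inherits(mask, "binary_mask")) mask <- mask$pixels
  if (is.null(region)) region <- matrix(TRUE, nrow(theta), ncol(theta))
  if (!all(dim(theta) == dim(mask)) || !all(dim(theta) == dim(region)))
    stop("theta, mask and region shapes disagree", call. = FALSE)
  if (bin_width <= 0 || (180 / bin_width) %% 1 != 0)
    stop("`bin_width` must divide 180", call. = FALSE)
  nb <- as.integer(360 / bin_width)
  use <- mask & region & !is.na(theta)
  th <- theta[use] %% 180
  counts <- numeric(nb)
  if (length(th)) {
    k <- floor(th / bin_width)
    half <- tabulate(as.integer(k) + 1L, nbins = nb %/% 2L)
    counts <- c(half, half)
  } else {
    warning("empty mask-by-region intersection: all-zero distribution",
            call. = FALSE)
  }
  structure(
    list(counts = counts, bin_width = bin_width, n_pixels = length(th),
         empty = length(th) == 0L),
    class = "orientation_distribution"
  )
}

# shoelace machinery: polygon from a polar curve r(theta_k), theta_k = bin
# left edge in degrees
polar_polygon <- function(counts, bin_width) {
  ang <- (seq_along(counts) - 1) * bin_width * pi / 180
  cbind(x = counts * cos(ang), y = counts * sin(ang))
}

# signed area and second central moments of a simple closed polygon
# (Green's theorem; vertices in order, implicitly closed)
polygon_moments <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (A == 0)
    return(list(area = 0, cx = NA_real_, cy = NA_real_,
                mxx = NA_real_, mxy = NA_real_, myy = NA_real_))
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  sxx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  syy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  list(area = A, cx = cx, cy = cy,
       mxx = sxx / A - cx^2, mxy = sxy / A - cx * cy, myy = syy / A - cy^2)
}

#' Pattern metrics of an orientation distribution
#'
#' Treats the angular histogram as a closed polar curve (radius = count per
#' bin, one vertex per bin at the bin's nominal angle) and summarises its
#' shape by three numbers:
#' \describe{
#'   \item{vessel area}{the area enclosed by the curve, by the shoelace
#'     formula on the 360-vertex polygon (units: pixel^2, since the radius
#'     is a pixel count per 1-degree bin).}
#'   \item{preferred orientation}{the major-axis angle of the
#'     moment-equivalent ellipse of the filled polygon (second central
#'     moments), folded into \[0, 180) degrees.}
#'   \item{anisotropy}{the major/minor axis-length ratio of that ellipse,
#'     >= 1; 1 for an isotropic (circular) distribution.}
#' }
#' For a degenerate distribution whose polygon has zero area (counts
#' confined to a single axial direction) the moment ellipse collapses:
#' preferred orientation falls back to the axial circular mean of the
#' distribution and anisotropy is reported as `Inf`.
#'
#' @param dist an `orientation_distribution` (or a bare numeric vector of
#'   counts over \[0, 360) with `bin_width` taken as `360 / length`).
#' @return an object of class `pattern_metrics`: list with
#'   `preferred_orientation` (degrees), `anisotropy`, `vessel_area`
#'   (pixel^2), plus diagnostic `axis_lengths`.
#' @examples
#' d <- structure(list(counts = rep(10, 360), bin_width = 1,
#'                     n_pixels = 1800, empty = FALSE),
#'                class = "orientation_distribution")
#' pattern_metrics(d)$anisotropy  # ~1
#' @export
pattern_metrics <- function(dist) {
  if (inherits(dist, "orientation_distribution")) {
    counts <- dist$counts; bw <- dist$bin_width
  } else {
    counts <- as.numeric(dist); bw <- 360 / length(counts)
  }
  if (all(counts == 0))
    stop("all-zero orientation distribution: metrics undefined",
         call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  xy <- polar_polygon(counts, bw)
  mom <- polygon_moments(xy)
  area <- abs(mom$area)
  if (area <= .Machine$double.eps * max(counts)^2) {
    # degenerate spike: orientation from the axial circular mean of mass
    a2 <- 2 * (((seq_along(counts) - 1) * bw) %% 180) * pi / 180
    po <- (atan2(sum(counts * sin(a2)), sum(counts * cos(a2))) /
             2 * 180 / pi) %% 180
    return(structure(
      list(preferred_orientation = po, anisotropy = Inf,
           vessel_area = 0, axis_lengths = c(major = NA_real_,
                                             minor = NA_real_)),
      class = "pattern_metrics"))
  }
  covm <- matrix(c(mom$mxx, mom$mxy, mom$mxy, mom$myy), 2L, 2L)
  ev <- eigen(covm, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  # moment-equivalent ellipse: eigenvalue = (semi-axis)^2 / 4
  axes <- 4 * sqrt(lam)
  aniso <- if (lam[2L] <= 0) Inf else sqrt(lam[1L] / lam[2L])
  po <- (atan2(ev$vectors[2L, 1L], ev$vectors[1L, 1L]) * 180 / pi) %% 180
  if (isTRUE(all.equal(lam[1L], lam[2L], tolerance = 1e-12)))
    po <- NA_real_                       # exactly isotropic: no major axis
  structure(
    list(preferred_orientation = po, anisotropy = aniso,
         vessel_area = area,
         axis_lengths = c(major = axes[1L], minor = axes[2L])),
    class = "pattern_metrics"
  )
}

#' @export
print.pattern_metrics <- function(x, ...) {
  cat(sprintf(
    "<pattern_metrics> preferred orientation %.1f deg, anisotropy %.2f, vessel area %.0f px^2\n",
    x$preferred_orientation, x$anisotropy, x$vessel_area))
  invisible(x)
}

#' Vessel density of a region
#'
#' Fraction of region pixels classified as vessel in the binary mask.
#'
#' @param mask a `binary_mask` or logical matrix.
#' @param region logical matrix (e.g. one sector mask).
#' @return fraction in \[0, 1\].
#' @export
vessel_density <- function(mask, region) {
  if (inherits(mask, "binary_mask")) mask <- mask$pixels
  if (!all(dim(mask) == dim(region)))
    stop("mask and region shapes disagree", call. = FALSE)
  n <- sum(region)
  if (n == 0L) stop("empty region", call. = FALSE)
  sum(mask & region) / n
}
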