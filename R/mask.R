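#' Global Otsu threshold
#'
#' Chooses the histogram bin edge that minimizes the intensity variance
#' within the two classes it induces (equivalently, maximizes the
#' between-class variance). The histogram spans the observed intensity range
#' with `n_bins` equal-width bins; class statistics use the exact per-bin
#' intensity sums, so the selected edge coincides with an exhaustive search
#' over all candidate edges on the raw pixel values. Ties are broken toward
#' the lower threshold.
#'
#' @param image a [scalar_image] or numeric matrix.
#' @param n_bins number of histogram bins (default 256, matching the 8-bit
#'   provenance of exported OCTA en face images).
#' @return the threshold intensity (a bin edge strictly inside the observed
#'   range). Pixels with intensity `>= threshold` form the bright class.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  img <- if (inherits(image, "scalar_image")) image$pixels else as.matrix(image)
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("cannot threshold a constant image", call. = FALSE)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  # left-closed bins [b_k, b_{k+1}); top value goes in the last bin
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(bin, nbins = n_bins)
  vs <- numeric(n_bins)
  agg <- rowsum(v, bin)                  # per-bin intensity sums
  vs[as.integer(rownames(agg))] <- agg
  # cumulative class-0 statistics at each candidate edge k (classes split
  # between bins k and k+1, i.e. threshold = breaks[k + 1])
  c0 <- cumsum(cnt)[-n_bins]
  s0 <- cumsum(vs)[-n_bins]
  n <- length(v); stot <- sum(v)
  c1 <- n - c0
  s1 <- stot - s0
  valid <- c0 > 0 & c1 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (s0[valid] / c0[valid] - s1[valid] / c1[valid])^2 *
    c0[valid] * c1[valid] / n^2
  k <- which.max(bcv)                    # first max = lowest threshold
  breaks[k + 1L]
}

#' Binary vessel mask
#'
#' Builds the binary vessel map used for vessel density and for gating the
#' orientation histogram. Three modes are available: Otsu on the raw
#' angiogram intensities (`"intensity"`), Otsu on the vesselness response
#' (`"vesselness"`), or — the default — the conjunction of both (`"and"`), a
#' pixel counting as vessel only if it passes both gates.
#'
#' @param image a [scalar_image] or numeric matrix.
#' @param vesselness a `vesselness_result` from [multiscale_vesselness()];
#'   may be `NULL` for mode `"intensity"`.
#' @param mode `"and"` (default), `"intensity"` or `"vesselness"`.
#' @param n_bins histogram bins for the Otsu search.
#' @return an object of class `binary_mask`: list with logical matrix
#'   `pixels`, `mode`, and the threshold(s) used (`threshold_intensity`,
#'   `threshold_vesselness`; `NA` when not applicable).
#' @export
make_vessel_mask <- function(image, vesselness = NULL,
                             mode = c("and", "intensity", "vesselness"),
                             n_bins = 256L) {
  mode <- match.arg(mode)
  img <- as_scalar_image(image)
  thr_i <- NA_real_; thr_v <- NA_real_
  m_i <- m_v <- NULL
  if (mode %in% c("and", "intensity")) {
    thr_i <- otsu_threshold(img, n_bins)
    m_i <- img$pixels >= thr_i
  }
  if (mode %in% c("and", "vesselness")) {
    if (is.null(vesselness))
      stop("`vesselness` is required for mode \"", mode, "\"", call. = FALSE)
    if (!all(dim(vesselness$rho) == dim(img$pixels)))
      stop("vesselness and image shapes disagree", call. = FALSE)
    thr_v <- otsu_threshold(vesselness$rho, n_bins)
    m_v <- vesselness$rho >= thr_v
  }
  px <- switch(mode,
    intensity = m_i,
    vesselness = m_v,
    "and" = m_i & m_v
  )
  structure(
    list(pixels = px, mode = mode, threshold_intensity = thr_i,
         threshold_vesselness = thr_v),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, mode \"%s\", %.1f%% vessel",
              nrow(x$pixels), ncol(x$pixels), x$mode,
              100 * mean(x$pixels)))
  if (!is.na(x$threshold_intensity))
    cat(sprintf(", intensity thr %.4f", x$threshold_intensity))
  if (!is.na(x$threshold_vesselness))
    cat(sprintf(", vesselness thr %.4f", x$threshold_vesselness))
  cat("\n")
  invisible(x)
}

#' Export a binary mask as a PNG image
#'
#' @param mask a `binary_mask`.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  png::writePNG(mask$pixels * 1, target = path)
  invisible(path)
}
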