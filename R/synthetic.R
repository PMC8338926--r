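#' Synthetic vessel (tube) descriptor
#'
#' A straight tube with a Gaussian cross-section: intensity
#' `amplitude * exp(-d^2 / (2 s^2))` as a function of perpendicular distance
#' `d` to the centerline. The centerline passes at signed perpendicular
#' offset `offset` (pixels) from the canvas center, at axial angle `angle`
#' (degrees CCW from +x, display convention, y up).
#'
#' By default the centerline is an infinite line spanning the whole canvas.
#' A finite `length` instead renders a segment of that length centred at
#' `center_xy` (display coordinates relative to the canvas center), with
#' rounded Gaussian end caps; short segments are the building block for
#' locally isotropic capillary-like ensembles, where full-span chords would
#' couple orientation to region geometry.
#'
#' @param angle axial angle in degrees; folded into \[0, 180).
#' @param s Gaussian profile standard deviation in pixels (> 0); the
#'   half-width of the rendered vessel.
#' @param amplitude peak intensity contribution, in (0, 1\].
#' @param offset signed perpendicular offset from canvas center, pixels
#'   (infinite-line case).
#' @param center_xy segment midpoint `(x, y)` relative to the canvas
#'   center, display coordinates (finite-length case).
#' @param length centerline length in pixels, or `Inf` for a full-span
#'   line.
#' @return an object of class `synthetic_tube`.
#' @export
tube <- function(angle, s = 1.5, amplitude = 0.8, offset = 0,
                 center_xy = c(0, 0), length = Inf) {
  if (s <= 0) stop("`s` must be positive", call. = FALSE)
  if (amplitude <= 0 || amplitude > 1)
    stop("`amplitude` must be in (0, 1]", call. = FALSE)
  if (length <= 0) stop("`length` must be positive", call. = FALSE)
  structure(list(type = "straight", angle = angle %% 180, s = s,
                 amplitude = amplitude, offset = offset,
                 center_xy = center_xy, length = length),
            class = "synthetic_tube")
}

#' Circular-arc synthetic vessel
#'
#' Like [tube()] but with a circular-arc centerline of radius `radius`
#' around a center given in display coordinates relative to the canvas
#' center. The local ground-truth orientation is the arc tangent.
#'
#' @param center_xy numeric `(x, y)` of the arc center relative to the
#'   canvas center, display coordinates in pixels.
#' @param radius arc radius in pixels (> 0).
#' @param from_deg,to_deg angular span of the arc (degrees CCW from +x about
#'   the arc center); the full circle by default.
#' @inheritParams tube
#' @export
arc_tube <- function(center_xy, radius, from_deg = 0, to_deg = 360,
                     s = 1.5, amplitude = 0.8) {
  if (radius <= 0) stop("`radius` must be positive", call. = FALSE)
  if (s <= 0) stop("`s` must be positive", call. = FALSE)
  if (amplitude <= 0 || amplitude > 1)
    stop("`amplitude` must be in (0, 1]", call. = FALSE)
  structure(list(type = "arc", center_xy = center_xy, radius = radius,
                 from_deg = from_deg, to_deg = to_deg, s = s,
                 amplitude = amplitude),
            class = "synthetic_tube")
}

#' Synthetic OCTA-like scene specification
#'
#' Describes a reproducible synthetic angiogram: bright Gaussian-profile
#' tubes on a darker noisy background, emulating the geometry of an en face
#' OCTA acquisition (the default 427-px canvas corresponds to the 5-mm
#' analysis disk at the 6 mm / 512 px pitch of a macular scan). The spec
#' fixes the scene exactly: rendering the same spec twice gives bit-identical
#' images.
#'
#' @param size canvas side in pixels (square canvas).
#' @param px_per_mm pixel pitch (default 512/6).
#' @param tubes list of [tube()] / [arc_tube()] objects.
#' @param background background intensity level in \[0, 1).
#' @param noise_sd standard deviation of additive Gaussian noise (applied
#'   after tube compositing; the image is then clipped to \[0, 1\]).
#' @param seed integer seed fixing the noise realisation.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(size = 427L, px_per_mm = 512 / 6, tubes = list(),
                       background = 0.1, noise_sd = 0, seed = 1L) {
  if (size < 16L) stop("canvas must be at least 16 px", call. = FALSE)
  if (background < 0 || background >= 1)
    stop("`background` must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  for (tb in tubes) {
    if (!inherits(tb, "synthetic_tube"))
      stop("`tubes` must be a list of synthetic_tube objects", call. = FALSE)
    if (tb$amplitude <= background)
      stop("tube amplitude must exceed the background level", call. = FALSE)
  }
  structure(
    list(size = as.integer(size), px_per_mm = px_per_mm, tubes = tubes,
         background = background, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

#' Random scene with a controlled orientation model
#'
#' Draws `n_tubes` straight vessel segments whose axial angles follow one of
#' three models: `"fixed"` (all at `angle`), `"uniform"` (axially uniform on
#' \[0, 180); drawn by stratified sampling — one jittered angle per
#' equal-width stratum, randomly permuted — so that even moderate tube
#' counts give isotropic ensembles), or `"vonmises"` (axial von Mises:
#' doubled angles follow a von Mises with mean `2 * mu` and concentration
#' `kappa`). Segment midpoints are uniform over the central disk of radius
#' `offset_frac * size / 2` and segment lengths uniform in `length_frac *
#' size`; finite segments keep every subregion of the canvas locally
#' isotropic under the uniform model, which full-span chords would not
#' (their in-region length depends on orientation). Widths and amplitudes
#' are drawn uniformly from the given ranges. All draws are fixed by
#' `seed`.
#'
#' @param n_tubes number of tubes.
#' @param orientation `"uniform"`, `"fixed"` or `"vonmises"`.
#' @param angle fixed axial angle (degrees) for `orientation = "fixed"`.
#' @param mu,kappa axial von Mises parameters for `orientation = "vonmises"`.
#' @param s_range,amplitude_range uniform ranges for tube width (px) and
#'   peak amplitude.
#' @param offset_frac segment midpoints fall within this fraction of the
#'   canvas half-width from the center.
#' @param length_frac range of segment lengths as fractions of the canvas
#'   side.
#' @param vessel_shape `"loop"` (default) renders each vessel as a closed
#'   ring of capillary-lobule scale (curvature radius uniform in
#'   `radius_frac * size`); a ring's tangent covers every axial angle
#'   uniformly, so a loop ensemble is isotropic in every subregion by
#'   construction — the canonical isotropic fixture. `"arc"` renders an
#'   open arc whose midpoint tangent is the drawn angle (tangents sweep a
#'   band of angles, as tortuous vessels do); `"segment"` a straight
#'   segment at exactly the drawn angle.
#' @param radius_frac range of curvature radii as fractions of the canvas
#'   side; defaults to `c(0.016, 0.038)` for loops (roughly 80-190 um at
#'   the standard pitch) and `c(0.25, 0.7)` for arcs.
#' @inheritParams scene_spec
#' @return a `scene_spec`.
#' @export
random_scene_spec <- function(n_tubes, size = 427L, px_per_mm = 512 / 6,
                              orientation = c("uniform", "fixed",
                                              "vonmises"),
                              angle = 0, mu = 90, kappa = 4,
                              s_range = NULL,
                              amplitude_range = NULL,
                              offset_frac = 0.85,
                              length_frac = c(0.2, 0.35),
                              vessel_shape = c("loop", "arc", "segment"),
                              radius_frac = NULL,
                              background = 0.1, noise_sd = 0, seed = 1L) {
  orientation <- match.arg(orientation)
  vessel_shape <- match.arg(vessel_shape)
  if (n_tubes < 1L) stop("need at least one tube", call. = FALSE)
  # capillary loops are small and of uniform calibre; open arcs/segments
  # model larger vessels
  if (is.null(s_range))
    s_range <- if (vessel_shape == "loop") c(1, 1.8) else c(1, 3)
  if (is.null(amplitude_range))
    amplitude_range <- if (vessel_shape == "loop") c(0.7, 0.85)
                       else c(0.55, 0.9)
  if (is.null(radius_frac))
    radius_frac <- if (vessel_shape == "loop") c(0.016, 0.038)
                   else c(0.25, 0.7)
  angles <- with_seed(seed, {
    switch(orientation,
      fixed = rep(angle %% 180, n_tubes),
      uniform = sample((seq_len(n_tubes) - stats::runif(n_tubes)) *
                         180 / n_tubes),
      vonmises = (rvonmises_axial(n_tubes, mu, kappa)) %% 180
    )
  })
  draws <- with_seed(seed + 1L, {
    rad <- offset_frac * size / 2 * sqrt(stats::runif(n_tubes))
    phi <- stats::runif(n_tubes, 0, 2 * pi)
    list(
      s = stats::runif(n_tubes, s_range[1L], s_range[2L]),
      amp = stats::runif(n_tubes, amplitude_range[1L], amplitude_range[2L]),
      cx = rad * cos(phi), cy = rad * sin(phi),
      len = stats::runif(n_tubes, length_frac[1L] * size,
                         length_frac[2L] * size),
      arc_r = stats::runif(n_tubes, radius_frac[1L] * size,
                           radius_frac[2L] * size),
      side = sample(c(-1, 1), n_tubes, replace = TRUE)
    )
  })
  tubes <- lapply(seq_len(n_tubes), function(i) {
    if (vessel_shape == "segment") {
      tube(angles[i], s = draws$s[i], amplitude = draws$amp[i],
           center_xy = c(draws$cx[i], draws$cy[i]), length = draws$len[i])
    } else if (vessel_shape == "loop") {
      arc_tube(c(draws$cx[i], draws$cy[i]), draws$arc_r[i], 0, 360,
               s = draws$s[i], amplitude = draws$amp[i])
    } else {
      # arc through (cx, cy) with midpoint tangent = drawn angle: curvature
      # center sits one radius along the normal; the arc spans len/R rad
      a <- angles[i] * pi / 180
      nx <- -sin(a) * draws$side[i]
      ny <- cos(a) * draws$side[i]
      ctr <- c(draws$cx[i] + draws$arc_r[i] * nx,
               draws$cy[i] + draws$arc_r[i] * ny)
      phi_mid <- atan2(-ny, -nx) * 180 / pi
      half_span <- draws$len[i] / draws$arc_r[i] * 180 / pi / 2
      arc_tube(ctr, draws$arc_r[i],
               from_deg = phi_mid - half_span, to_deg = phi_mid + half_span,
               s = draws$s[i], amplitude = draws$amp[i])
    }
  })
  scene_spec(size = size, px_per_mm = px_per_mm, tubes = tubes,
             background = background, noise_sd = noise_sd, seed = seed)
}

# run expr under a temporary RNG state (restores .Random.seed afterwards)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# axial von Mises sampler: draws 2*theta ~ vM(2*mu, kappa) by the
# Best-Fisher (1979) rejection method, returns theta in degrees
rvonmises_axial <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 180))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + rr * z) / (rr + z)
    ccf <- kappa * (rr - f)
    if (ccf * (2 - ccf) - u[2L] > 0 || log(ccf / u[2L]) + 1 - ccf >= 0) {
      ang2 <- sign(u[3L] - 0.5) * acos(f) + 2 * mu * pi / 180
      out[i] <- (ang2 / 2 * 180 / pi) %% 180
      i <- i + 1L
    }
  }
  out
}

#' Render a synthetic scene with ground truth
#'
#' Rasterises the tubes of a [scene_spec()] onto the canvas. Each tube
#' contributes its Gaussian profile of the perpendicular distance to its
#' centerline; overlapping contributions combine by per-pixel maximum (a
#' crossing is no brighter than its brightest vessel), the result is floored
#' at the background level, Gaussian noise is added, and intensities are
#' clipped to \[0, 1\].
#'
#' Ground truth is defined on the half-maximum footprint of each tube
#' (contribution >= amplitude / 2): the orientation map holds the local
#' centerline tangent (axial degrees; from the tube winning the per-pixel
#' maximum where footprints overlap), the width map the profile `s`, and
#' `crossing` flags pixels within 2 px of two or more centerlines, where
#' orientation is multi-valued and should be excluded from scoring.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `synthetic_scene`: list with `image` (a
#'   [scalar_image]), `orientation` (degrees, `NA` off-footprint),
#'   `footprint`, `crossing` (logical matrices), `width` (px, `NA`
#'   off-footprint) and the `spec`.
#' @export
render_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    stop("`spec` must be a scene_spec", call. = FALSE)
  n <- spec$size
  cx <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  x <- cols - cx
  y <- cx - rows                         # display coords, y up
  half_diag <- sqrt(2) * n / 2
  best <- matrix(0, n, n)
  orient <- width <- matrix(NA_real_, n, n)
  footprint <- matrix(FALSE, n, n)
  near_cl <- matrix(0L, n, n)
  for (tb in spec$tubes) {
    if (tb$type == "straight") {
      a <- tb$angle * pi / 180
      if (is.finite(tb$length)) {
        # segment centred at center_xy: perpendicular + clamped axial excess
        ux <- x - tb$center_xy[1L]
        uy <- y - tb$center_xy[2L]
        if (sqrt(sum(tb$center_xy^2)) > half_diag + tb$length / 2)
          stop("tube centerline lies outside the canvas", call. = FALSE)
        dperp <- -sin(a) * ux + cos(a) * uy
        dpar <- pmax(abs(cos(a) * ux + sin(a) * uy) - tb$length / 2, 0)
        d <- sqrt(dperp^2 + dpar^2)
      } else {
        if (abs(tb$offset) > half_diag)
          stop("tube centerline lies outside the canvas", call. = FALSE)
        d <- abs(-sin(a) * x + cos(a) * y - tb$offset)
      }
      th <- matrix(tb$angle, n, n)
    } else {
      rx <- x - tb$center_xy[1L]
      ry <- y - tb$center_xy[2L]
      rr <- sqrt(rx^2 + ry^2)
      d <- abs(rr - tb$radius)
      phi <- (atan2(ry, rx) * 180 / pi) %% 360
      sweep <- (tb$to_deg - tb$from_deg) %% 360
      if (sweep == 0) sweep <- 360       # full circle
      span <- ((phi - tb$from_deg) %% 360) <= sweep
      d[!span] <- Inf
      th <- (phi + 90) %% 180            # tangent is normal to the radius
      if (!any(is.finite(d) & d < 3 * tb$s))
        stop("arc tube lies outside the canvas", call. = FALSE)
    }
    contrib <- tb$amplitude * exp(-d^2 / (2 * tb$s^2))
    fp <- contrib >= tb$amplitude / 2    # half-maximum footprint
    win <- contrib > best
    best[win] <- contrib[win]
    sel <- fp & win
    orient[sel] <- th[sel]
    width[sel] <- tb$s
    footprint <- footprint | fp
    near_cl <- near_cl + (d <= 2)
  }
  orient[!footprint] <- NA_real_
  width[!footprint] <- NA_real_
  img <- pmax(best, spec$background)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n))
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), 1)
  structure(
    list(image = scalar_image(img, px_per_mm = spec$px_per_mm),
         orientation = orient, footprint = footprint,
         crossing = near_cl >= 2L, width = width, spec = spec),
    class = "synthetic_scene"
  )
}

#' Axial distance between two angles
#'
#' Distance between axial (head-tail) orientations:
#' `min(|a - b| mod 180, 180 - |a - b| mod 180)`, bounded by 90 degrees and
#' invariant to 180-degree shifts of either argument.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return distance in degrees, in \[0, 90\].
#' @export
axial_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Score an estimated orientation map against ground truth
#'
#' Compares a per-pixel axial orientation estimate with the rendered ground
#' truth on the tube footprint. Pixels flagged as crossings (orientation
#' multi-valued), pixels within `border_px` of the image border (where the
#' filter's reflect padding biases estimates) and pixels where the estimate
#' is undefined are excluded.
#'
#' @param estimate matrix of estimated axial orientations in degrees (e.g.
#'   `theta0` of a `vesselness_result`).
#' @param truth a `synthetic_scene` from [render_scene()].
#' @param border_px width of the excluded image border band.
#' @return list with `mean`, `median` (axial error in degrees),
#'   `frac_within_5` (fraction of scored pixels within 5 degrees) and `n`
#'   (scored pixels).
#' @export
orientation_error <- function(estimate, truth, border_px = 2L) {
  if (!inherits(truth, "synthetic_scene"))
    stop("`truth` must be a synthetic_scene", call. = FALSE)
  if (!all(dim(estimate) == dim(truth$orientation)))
    stop("estimate and truth shapes disagree", call. = FALSE)
  n <- nrow(estimate); p <- ncol(estimate)
  interior <- matrix(FALSE, n, p)
  ib <- border_px
  interior[(ib + 1):(n - ib), (ib + 1):(p - ib)] <- TRUE
  valid <- truth$footprint & !truth$crossing & interior &
    !is.na(truth$orientation) & !is.na(estimate)
  if (!any(valid)) stop("no scorable footprint pixels", call. = FALSE)
  err <- axial_distance(estimate[valid], truth$orientation[valid])
  list(mean = mean(err), median = stats::median(err),
       frac_within_5 = mean(err <= 5), n = sum(valid))
}
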