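#' Vesselness filter parameters
#'
#' Bundles the tunable parameters of the multiscale Hessian vesselness
#' filter. The scale grid `sigma_min, sigma_min + sigma_step, ..., <=
#' sigma_max` (pixels) should bracket the vessel half-widths present in the
#' image; `beta` controls how sharply blob-like structure (large eigenvalue
#' ratio) is suppressed and `gamma` how much low-contrast structure is
#' suppressed. `gamma = "auto"` sets it to half the maximum Hessian
#' Frobenius norm observed over all scales of the image being filtered,
#' which adapts the contrast gate to each scan.
#'
#' `scale_power` is the exponent p of the sigma^p normalization applied to
#' the second derivatives before the cross-scale maximum. The default 1.5
#' is the classical ridge-detection choice for Gaussian-profile lines: it
#' makes the strongest response occur at sigma equal to the profile standard
#' deviation, so the argmax scale reads out the vessel half-width directly.
#' (The value 2 — full second-order normalization — shifts the selected
#' scale to sqrt(2) times the profile width; 0 disables normalization and
#' the smallest scale always wins.)
#'
#' @param sigma_min,sigma_max,sigma_step scale grid in pixels; all > 0,
#'   `sigma_min <= sigma_max`, `sigma_min >= 0.5` (below that the sampled
#'   derivative kernels alias).
#' @param beta blob-suppression index, > 0.
#' @param gamma contrast-suppression index, > 0, or `"auto"`.
#' @param polarity `"bright"` for bright vessels on a dark background (the
#'   OCTA case; requires the larger-magnitude eigenvalue to be negative) or
#'   `"dark"` for the opposite contrast.
#' @param scale_power exponent of the scale normalization (see Details).
#' @param truncate kernel truncation radius in units of sigma.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(sigma_min = 1, sigma_max = 4, sigma_step = 0.5,
                          beta = 0.5, gamma = "auto",
                          polarity = c("bright", "dark"),
                          scale_power = 1.5, truncate = 3) {
  polarity <- match.arg(polarity)
  if (sigma_min <= 0 || sigma_max <= 0 || sigma_step <= 0)
    stop("scale grid parameters must be positive", call. = FALSE)
  if (sigma_min < 0.5)
    stop("`sigma_min` must be >= 0.5 px", call. = FALSE)
  if (sigma_min > sigma_max)
    stop("`sigma_min` must not exceed `sigma_max`", call. = FALSE)
  if (beta <= 0) stop("`beta` must be positive", call. = FALSE)
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0))
    stop("`gamma` must be positive or \"auto\"", call. = FALSE)
  sigmas <- seq(sigma_min, sigma_max, by = sigma_step)
  if (length(sigmas) == 0L) stop("empty scale grid", call. = FALSE)
  structure(
    list(sigma_min = sigma_min, sigma_max = sigma_max,
         sigma_step = sigma_step, sigmas = sigmas, beta = beta,
         gamma = gamma, polarity = polarity, scale_power = scale_power,
         truncate = truncate),
    class = "filter_params"
  )
}

#' Scale-normalized Hessian of an image at one scale
#'
#' Computes the three second derivatives `Ixx`, `Ixy`, `Iyy` of the image in
#' Gaussian scale space by convolution with analytic second-derivative-of-
#' Gaussian kernels (separable, reflect-padded boundaries), then multiplies
#' each by `sigma^scale_power` so responses are comparable across scales.
#'
#' Derivatives are reported in the display coordinate frame (x rightward,
#' y upward); since image rows run downward in storage, the mixed derivative
#' computed on the stored matrix is negated.
#'
#' @param image a [scalar_image] or numeric matrix in \[0, 1\].
#' @param sigma scale in pixels, >= 0.5.
#' @param scale_power normalization exponent (see [filter_params()]).
#' @param truncate kernel truncation radius in units of sigma.
#' @return an object of class `hessian_field`: list with matrices `Ixx`,
#'   `Ixy`, `Iyy` and the scalar `sigma`.
#' @export
hessian_at_scale <- function(image, sigma, scale_power = 1.5, truncate = 3) {
  img <- as_scalar_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0.5)
    stop("`sigma` must be a scalar >= 0.5 px", call. = FALSE)
  k <- gauss_kernels_1d(sigma, truncate)
  m <- img$pixels
  s <- sigma^scale_power
  # display y = -storage row  =>  Ixy flips sign, Ixx/Iyy unchanged
  Ixx <- s * conv_sep(m, kx = k$g2, ky = k$g)
  Iyy <- s * conv_sep(m, kx = k$g, ky = k$g2)
  Ixy <- -s * conv_sep(m, kx = k$g1, ky = k$g1)
  structure(list(Ixx = Ixx, Ixy = Ixy, Iyy = Iyy, sigma = sigma),
            class = "hessian_field")
}

#' Pointwise eigen-analysis of a 2-D Hessian field
#'
#' Closed-form eigen-decomposition of the symmetric 2x2 Hessian at every
#' pixel. Eigenvalues are ordered by magnitude (`|lambda1| <= |lambda2|`);
#' `theta` is the angle of the eigenvector of `lambda1` — the direction of
#' least intensity curvature, i.e. the local vessel axis — measured
#' counter-clockwise from +x and folded into \[0, 180) degrees. At isotropic
#' points (`|lambda1| == |lambda2|` with distinct eigenvalues, or a zero
#' Hessian) the orientation is undefined and reported as `NA`; such pixels
#' are excluded from orientation histograms downstream.
#'
#' @param h a `hessian_field` from [hessian_at_scale()], or a list with
#'   matrices `Ixx`, `Ixy`, `Iyy` (display convention).
#' @return an object of class `eigen_field`: list with matrices `lambda1`,
#'   `lambda2`, `theta` (degrees, `NA` where undefined) and `sigma`.
#' @export
eigen_field <- function(h) {
  a <- h$Ixx; b <- h$Ixy; c <- h$Iyy
  m <- (a + c) / 2
  d <- (a - c) / 2
  disc <- sqrt(d^2 + b^2)
  eA <- m + disc                      # algebraically larger
  eB <- m - disc
  swap <- abs(eB) > abs(eA)           # eB is the dominant eigenvalue
  lambda2 <- ifelse(swap, eB, eA)
  lambda1 <- ifelse(swap, eA, eB)
  # eigenvector of lambda1: (b, lambda1 - a), fallback (lambda1 - c, b)
  v1x <- b
  v1y <- lambda1 - a
  alt <- abs(v1x) + abs(v1y) == 0
  v1x[alt] <- (lambda1 - c)[alt]
  v1y[alt] <- b[alt]
  theta <- (atan2(v1y, v1x) * 180 / pi) %% 180
  # undefined orientation: isotropic tie (|l1| == |l2|, l1 != l2, e.g.
  # c*Identity) or an exactly zero Hessian
  tie <- (abs(lambda1) == abs(lambda2)) & (disc == 0 | lambda1 != lambda2)
  zero <- disc == 0 & m == 0
  theta[tie | zero] <- NA_real_
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(c)
  lambda1[bad] <- NA_real_; lambda2[bad] <- NA_real_; theta[bad] <- NA_real_
  structure(list(lambda1 = lambda1, lambda2 = lambda2, theta = theta,
                 sigma = h$sigma),
            class = "eigen_field")
}

#' Single-scale vesselness response
#'
#' Combines the eigenvalue ratio `R = |lambda1| / |lambda2|` (tubularity;
#' near 0 on a line, near 1 on a blob) and the structure-ness
#' `S = sqrt(lambda1^2 + lambda2^2)` (contrast; near 0 on background) into
#' the filter response
#' \deqn{\rho = \exp(-R^2 / 2\beta^2)\,(1 - \exp(-S^2 / 2\gamma^2)).}
#' The response is forced to zero where the sign of `lambda2` contradicts
#' the requested polarity (a bright vessel has negative curvature across its
#' axis, so `lambda2 < 0` is required for `polarity = "bright"`).
#'
#' @param e an `eigen_field` from [eigen_field()].
#' @param beta,gamma suppression indices, > 0.
#' @param polarity `"bright"` or `"dark"`.
#' @return list with matrices `rho` (in \[0, 1\]), `R`, `S`.
#' @export
vesselness_at_scale <- function(e, beta = 0.5, gamma,
                                polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(beta) || beta <= 0)
    stop("`beta` must be positive", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("`gamma` must be positive", call. = FALSE)
  l1 <- e$lambda1; l2 <- e$lambda2
  R <- ifelse(l2 == 0, 0, abs(l1) / abs(l2))
  S <- sqrt(l1^2 + l2^2)
  rho <- exp(-R^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * gamma^2)))
  wrong_sign <- if (polarity == "bright") l2 > 0 else l2 < 0
  rho[wrong_sign] <- 0
  rho[!is.finite(rho)] <- 0
  list(rho = rho, R = R, S = S)
}

#' Multiscale vesselness with width and orientation read-out
#'
#' Runs the vesselness filter over the scale grid and keeps, per pixel, the
#' maximum response `rho`, the scale `sigma0` at which it occurred (the
#' vessel half-width estimate) and the orientation `theta0` of the
#' least-curvature eigenvector at that scale (the local vessel axis, axial
#' degrees in \[0, 180)). Ties across scales resolve to the smallest scale.
#'
#' With `gamma = "auto"` a single contrast gate — half the maximum Hessian
#' Frobenius norm over all pixels and scales — is used for every scale, so
#' that the cross-scale argmax is driven by the scale-normalized structure
#' strength rather than by per-scale renormalization.
#'
#' @param image a [scalar_image] or numeric matrix in \[0, 1\].
#' @param params a [filter_params()] object.
#' @return an object of class `vesselness_result`: list with matrices `rho`
#'   (max response, \[0, 1\]), `sigma0` (pixels), `theta0` (degrees, `NA`
#'   where orientation is undefined), `R0`, `S0` (diagnostics at the argmax
#'   scale), plus `sigmas`, `gamma_used` and `border_px` (width of the
#'   boundary band, `ceiling(3 * sigma_max)`, where reflect padding makes
#'   values less reliable).
#' @examples
#' sc <- render_scene(scene_spec(size = 64, tubes = list(tube(30, s = 2))))
#' v <- multiscale_vesselness(sc$image, filter_params(1, 3, 0.5))
#' range(v$rho)
#' @export
multiscale_vesselness <- function(image, params = filter_params()) {
  img <- as_scalar_image(image)
  if (!inherits(params, "filter_params"))
    stop("`params` must be a `filter_params` object", call. = FALSE)
  sigmas <- params$sigmas
  eigens <- vector("list", length(sigmas))
  smax <- 0
  for (i in seq_along(sigmas)) {
    h <- hessian_at_scale(img, sigmas[i],
                          scale_power = params$scale_power,
                          truncate = params$truncate)
    eigens[[i]] <- eigen_field(h)
    fro <- sqrt(eigens[[i]]$lambda1^2 + eigens[[i]]$lambda2^2)
    smax <- max(smax, max(fro, na.rm = TRUE))
  }
  if (smax < 1e-8) {
    # featureless image: no structure anywhere, response identically zero
    z <- matrix(0, img$height, img$width)
    return(structure(
      list(rho = z, sigma0 = matrix(sigmas[1L], img$height, img$width),
           theta0 = z + NA_real_, R0 = z + NA_real_, S0 = z,
           sigmas = sigmas, gamma_used = NA_real_,
           border_px = as.integer(ceiling(3 * params$sigma_max))),
      class = "vesselness_result"))
  }
  gamma <- if (identical(params$gamma, "auto")) smax / 2 else params$gamma
  rho <- matrix(-1, img$height, img$width)
  sigma0 <- matrix(sigmas[1L], img$height, img$width)
  theta0 <- R0 <- S0 <- matrix(NA_real_, img$height, img$width)
  for (i in seq_along(sigmas)) {
    v <- vesselness_at_scale(eigens[[i]], beta = params$beta, gamma = gamma,
                             polarity = params$polarity)
    better <- v$rho > rho               # strict: ties keep smaller sigma
    rho[better] <- v$rho[better]
    sigma0[better] <- sigmas[i]
    theta0[better] <- eigens[[i]]$theta[better]
    R0[better] <- v$R[better]
    S0[better] <- v$S[better]
  }
  rho[rho < 0] <- 0
  structure(
    list(rho = rho, sigma0 = sigma0, theta0 = theta0, R0 = R0, S0 = S0,
         sigmas = sigmas, gamma_used = gamma,
         border_px = as.integer(ceiling(3 * params$sigma_max))),
    class = "vesselness_result"
  )
}

#' @export
print.vesselness_result <- function(x, ...) {
  cat(sprintf(
    "<vesselness_result> %d x %d px, scales %s, gamma = %.4g\n",
    nrow(x$rho), ncol(x$rho),
    paste(format(x$sigmas), collapse = ", "), x$gamma_used))
  cat(sprintf("  response range [%.3f, %.3f], %.1f%% pixels with defined orientation\n",
              min(x$rho), max(x$rho), 100 * mean(!is.na(x$theta0))))
  invisible(x)
}
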