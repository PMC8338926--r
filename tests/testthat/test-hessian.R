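test_that("Gaussian kernel matches the analytic density and normalizes", {
  k <- make_gaussian_kernel(1, normalize = FALSE)
  r <- (nrow(k) - 1) / 2
  expect_equal(k[r + 1, r + 1], 1 / (2 * pi), tolerance = 1e-12)
  for (s in c(0.7, 1, 2.3)) {
    expect_equal(sum(make_gaussian_kernel(s)), 1, tolerance = 1e-12)
  }
  # self-similarity: the sigma = 2 kernel is the sigma = 1 profile sampled
  # at half spacing (up to normalization)
  k1 <- make_gaussian_kernel(1, truncate_radius = 6, normalize = FALSE)
  k2 <- make_gaussian_kernel(2, truncate_radius = 12, normalize = FALSE)
  x1 <- seq(-6, 6)
  x2 <- seq(-12, 12)
  # value at offset 2t for sigma 2 vs offset t for sigma 1: ratio constant
  ratio <- k2[13 + 2 * x1, 13] / k1[7 + x1, 7]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  expect_error(make_gaussian_kernel(-1), "positive")
  expect_error(make_gaussian_kernel(1, truncate_radius = 2), "3")
})

test_that("Hessian of a constant image vanishes; ridge structure matches the ideal tube", {
  h <- hessian_at_scale(matrix(0.4, 32, 32), sigma = 1)
  expect_equal(max(abs(h$Ixx)), 0, tolerance = 1e-14)
  expect_equal(max(abs(h$Ixy)), 0, tolerance = 1e-14)
  expect_equal(max(abs(h$Iyy)), 0, tolerance = 1e-14)

  # vertical tube (90 deg): at the centerline, curvature is across the tube
  # only: Ixx < 0, Iyy ~ 0, Ixy ~ 0
  sc <- one_tube_scene(90, s = 1, size = 33, background = 0)
  h <- hessian_at_scale(sc$image, sigma = 1)
  mid <- 17
  expect_lt(h$Ixx[mid, mid], 0)
  expect_lt(abs(h$Iyy[mid, mid]), 0.05 * abs(h$Ixx[mid, mid]))
  expect_lt(abs(h$Ixy[mid, mid]), 0.05 * abs(h$Ixx[mid, mid]))

  # rotating the scene by 90 degrees swaps Ixx and Iyy at the center
  sch <- one_tube_scene(0, s = 1, size = 33, background = 0)
  hh <- hessian_at_scale(sch$image, sigma = 1)
  expect_equal(hh$Iyy[mid, mid], h$Ixx[mid, mid], tolerance = 1e-10)
  expect_equal(hh$Ixx[mid, mid], h$Iyy[mid, mid], tolerance = 1e-10)
  expect_error(hessian_at_scale(sc$image, sigma = 0.3), ">= 0.5")
})

test_that("closed-form 2x2 eigen-decomposition matches a characteristic-polynomial solver", {
  set.seed(42)
  n <- 1000L
  a <- stats::rnorm(n); b <- stats::rnorm(n); c <- stats::rnorm(n)
  ef <- eigen_field(list(Ixx = matrix(a, 1), Ixy = matrix(b, 1),
                         Iyy = matrix(c, 1), sigma = 1))
  for (i in seq_len(n)) {
    ev <- eig2_brute(a[i], b[i], c[i])
    expect_equal(ef$lambda1[1, i], ev[1L], tolerance = 1e-10)
    expect_equal(ef$lambda2[1, i], ev[2L], tolerance = 1e-10)
  }
  expect_true(all(abs(ef$lambda1) <= abs(ef$lambda2) + 1e-12))
  # eigenvector check: H v1 = lambda1 v1
  th <- ef$theta[1, ] * pi / 180
  resid <- abs((a - ef$lambda1[1, ]) * cos(th) + b * sin(th)) +
    abs(b * cos(th) + (c - ef$lambda1[1, ]) * sin(th))
  expect_lt(max(resid), 1e-8)
})

test_that("ideal-tube ridge pixel has lambda1 = 0 and orientation along the tube", {
  i0 <- 1 / (2 * pi)   # peak of the unit-width Gaussian tube profile
  ef <- eigen_field(list(Ixx = matrix(-i0), Ixy = matrix(0),
                         Iyy = matrix(0), sigma = 1))
  expect_identical(ef$lambda1[1, 1], 0)
  expect_equal(ef$theta[1, 1], 90)
  # isotropic pixel: orientation undefined
  ef2 <- eigen_field(list(Ixx = matrix(2), Ixy = matrix(0),
                          Iyy = matrix(2), sigma = 1))
  expect_true(is.na(ef2$theta[1, 1]))
  expect_equal(abs(ef2$lambda1[1, 1]), abs(ef2$lambda2[1, 1]))
})

test_that("vesselness response follows the R/S suppression form", {
  mk <- function(l1, l2) list(lambda1 = matrix(l1), lambda2 = matrix(l2))
  v <- vesselness_at_scale(mk(0, -10), beta = 0.5, gamma = 5)
  expect_equal(v$R[1, 1], 0)
  expect_equal(v$S[1, 1], 10)
  expect_equal(v$rho[1, 1], 1 - exp(-2), tolerance = 1e-12)
  # background: no structure, no response
  v0 <- vesselness_at_scale(mk(0, 0), beta = 0.5, gamma = 5)
  expect_equal(v0$rho[1, 1], 0)
  # 3-4-5 arithmetic
  v345 <- vesselness_at_scale(mk(3, -4), beta = 0.5, gamma = 5)
  expect_equal(v345$R[1, 1], 0.75)
  expect_equal(v345$S[1, 1], 5)
  # polarity gate: bright vessels need lambda2 < 0
  vpos <- vesselness_at_scale(mk(0, 10), beta = 0.5, gamma = 5,
                              polarity = "bright")
  expect_equal(vpos$rho[1, 1], 0)
  expect_error(vesselness_at_scale(mk(0, -1), beta = -1, gamma = 1),
               "beta")
})

test_that("multiscale response is bounded, zero on constants, and reduces to single scale", {
  sc <- one_tube_scene(30, s = 2)
  p1 <- filter_params(2, 2, 0.5)
  v1 <- multiscale_vesselness(sc$image, p1)
  expect_true(all(v1$sigma0 == 2))
  h <- hessian_at_scale(sc$image, 2)
  e <- eigen_field(h)
  vs <- vesselness_at_scale(e, beta = p1$beta, gamma = v1$gamma_used)
  expect_equal(v1$rho, vs$rho, tolerance = 1e-12)

  v <- multiscale_vesselness(sc$image, filter_params(1, 4, 0.5))
  expect_true(all(v$rho >= 0 & v$rho <= 1))
  expect_true(all(v$sigma0 >= 1 & v$sigma0 <= 4))
  vc <- multiscale_vesselness(matrix(0.5, 32, 32), filter_params(1, 2, 0.5))
  expect_equal(max(vc$rho), 0)
})

test_that("scale selection reads out tube width and orientation at the argmax scale", {
  sc <- one_tube_scene(90, s = 2, size = 128, background = 0.05)
  v <- multiscale_vesselness(sc$image, filter_params(0.5, 6, 0.5))
  mid <- 64:65
  s0 <- v$sigma0[20:108, mid]
  expect_true(all(s0 >= 1.5 & s0 <= 2.5))
  sc30 <- one_tube_scene(30, s = 2, size = 128)
  v30 <- multiscale_vesselness(sc30$image, filter_params())
  err <- orientation_error(v30$theta0, sc30, border_px = 12)
  expect_lt(err$mean, 3)
})

test_that("rotating a scene by 90 degrees rotates recovered orientations by 90", {
  sc <- render_scene(scene_spec(size = 96, tubes = list(
    tube(25, s = 2, amplitude = 0.8, offset = -10),
    tube(115, s = 1.5, amplitude = 0.7, offset = 15))))
  p <- filter_params()
  v <- multiscale_vesselness(sc$image, p)
  # rotate image 90 deg CCW in display coords
  rot <- t(sc$image$pixels)[nrow(sc$image$pixels):1, ]
  vr <- multiscale_vesselness(scalar_image(rot), p)
  thr <- t(vr$theta0[nrow(vr$theta0):1, , drop = FALSE])
  # undo rotation of the grid; compare on vessel pixels away from borders
  use <- sc$footprint
  use[c(1:16, 81:96), ] <- FALSE
  use[, c(1:16, 81:96)] <- FALSE
  dd <- axial_distance(v$theta0[use] + 90, thr[use])
  expect_lt(mean(dd, na.rm = TRUE), 2)
})
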