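test_that("a vertical tube renders with peak on the centerline and 90-degree truth", {
  sc <- one_tube_scene(90, s = 1.5, size = 33, background = 0)
  mid <- 17
  expect_equal(which.max(sc$image$pixels[5, ]), mid)
  expect_true(all(sc$orientation[sc$footprint] == 90))
  expect_true(all(is.na(sc$orientation[!sc$footprint])))
  expect_equal(unique(sc$width[sc$footprint]), 1.5)
  # footprint is the half-maximum band
  halfw <- 1.5 * sqrt(2 * log(2))
  expect_true(all(abs(which(sc$footprint[5, ]) - mid) <= halfw + 0.5))
})

test_that("rendering is deterministic and noise respects the seed", {
  sp <- scene_spec(size = 48, tubes = list(tube(30, s = 2)), noise_sd = 0.1,
                   seed = 99)
  s1 <- render_scene(sp); s2 <- render_scene(sp)
  expect_identical(s1$image$pixels, s2$image$pixels)
  sp2 <- scene_spec(size = 48, tubes = list(tube(30, s = 2)),
                    noise_sd = 0.1, seed = 100)
  expect_false(identical(render_scene(sp2)$image$pixels, s1$image$pixels))
  # rendering does not disturb the caller's RNG stream
  set.seed(5); before <- stats::runif(1)
  set.seed(5); invisible(render_scene(sp)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("tube crossings are flagged and combined by maximum", {
  sp <- scene_spec(size = 64, tubes = list(tube(0, s = 2, amplitude = 0.6),
                                           tube(90, s = 2, amplitude = 0.8)))
  sc <- render_scene(sp)
  mid <- 32:33
  expect_true(any(sc$crossing[mid, mid]))
  expect_lte(max(sc$image$pixels), 0.8)  # max, not sum
  # away from the crossing each tube keeps its own orientation
  expect_true(all(sc$orientation[32, 55:60] == 0))
  expect_true(all(sc$orientation[55:60, 32] == 90))
  expect_error(render_scene(scene_spec(size = 48,
    tubes = list(tube(0, offset = 300)))), "outside")
})

test_that("uniform-axial ensembles have near-flat footprint orientation histograms", {
  sp <- random_scene_spec(200, size = 256, px_per_mm = 42,
                          vessel_shape = "arc", seed = 31)
  sc <- render_scene(sp)
  gt <- sc$orientation[sc$footprint & !is.na(sc$orientation)]
  h <- tabulate(floor(gt / 10) + 1, 18)
  expect_lte(max(h) / min(h), 2)
})

test_that("axial error metric is symmetric, bounded, wrap-invariant", {
  expect_equal(axial_distance(179, 1), 2)
  expect_equal(axial_distance(0, 90), 90)
  set.seed(33)
  a <- stats::runif(50, 0, 180); b <- stats::runif(50, 0, 180)
  expect_equal(axial_distance(a, b), axial_distance(b, a))
  expect_true(all(axial_distance(a, b) <= 90))
  expect_equal(axial_distance(a + 180, b), axial_distance(a, b),
               tolerance = 1e-9)
})

test_that("orientation_error scores footprints and excludes borders and crossings", {
  sc <- one_tube_scene(45, s = 2, size = 64)
  est <- sc$orientation
  expect_equal(orientation_error(est, sc)$mean, 0)
  expect_equal(orientation_error((est + 90) %% 180, sc)$mean, 90)
  e2 <- orientation_error((est + 2) %% 180, sc)
  expect_equal(e2$mean, 2, tolerance = 1e-9)
  expect_equal(e2$frac_within_5, 1)
  expect_error(orientation_error(est, one_tube_scene(45, size = 48)),
               "shapes")
})

test_that("noiseless straight tubes are recovered within 5 degrees end to end", {
  errs <- sapply(c(10, 75, 150), function(ang) {
    sc <- one_tube_scene(ang, s = 2, size = 96)
    v <- multiscale_vesselness(sc$image, filter_params())
    orientation_error(v$theta0, sc, border_px = 12)$mean
  })
  expect_true(all(errs <= 5))
})

test_that("von Mises axial angles concentrate around mu", {
  sp <- random_scene_spec(150, size = 96, orientation = "vonmises",
                          mu = 45, kappa = 12, vessel_shape = "segment",
                          seed = 35)
  ang <- vapply(sp$tubes, function(t) t$angle, 0)
  expect_lt(axial_distance(axial_mean(ang), 45), 6)
  expect_lt(axial_sd(ang), 20)
})
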