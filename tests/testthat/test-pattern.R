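make_dist <- function(counts, bw = 1) {
  structure(list(counts = counts, bin_width = bw,
                 n_pixels = sum(counts) / 2, empty = all(counts == 0)),
            class = "orientation_distribution")
}

test_that("orientation histogram duplicates axially and conserves mass", {
  th <- matrix(NA_real_, 20, 20)
  th[5, 1:10] <- 90
  mask <- !is.na(th)
  d <- orientation_histogram(th, mask, bin_width = 1)
  expect_equal(d$counts[91], 10)          # bin 90 (1-based index 91)
  expect_equal(d$counts[271], 10)         # bin 270
  expect_equal(sum(d$counts), 2 * 10)
  expect_equal(sum(d$counts != 0), 2)

  # conservation and exact axial symmetry on arbitrary orientation fields
  set.seed(11)
  th2 <- matrix(stats::runif(400, 0, 180), 20, 20)
  m2 <- matrix(stats::runif(400) < 0.6, 20, 20)
  th2[1, 1] <- NA                         # undefined orientation is skipped
  d2 <- orientation_histogram(th2, m2, bin_width = 5)
  expect_equal(sum(d2$counts), 2 * sum(m2 & !is.na(th2)))
  nb <- length(d2$counts)
  expect_identical(d2$counts[1:(nb / 2)], d2$counts[(nb / 2 + 1):nb])

  expect_warning(d0 <- orientation_histogram(th, matrix(FALSE, 20, 20)),
                 "empty")
  expect_true(d0$empty)
  expect_equal(sum(d0$counts), 0)
  expect_error(orientation_histogram(th, mask, bin_width = 7), "180")
})

test_that("metrics of a uniform distribution: unit anisotropy and regular-polygon area", {
  cc <- 10
  pm <- pattern_metrics(make_dist(rep(cc, 360)))
  expect_lt(abs(pm$anisotropy - 1), 0.01)
  expect_equal(pm$vessel_area, 0.5 * 360 * cc^2 * sin(pi / 180),
               tolerance = 1e-12)
  expect_true(is.na(pm$preferred_orientation))  # no major axis when isotropic
})

test_that("axial spike distribution points at its angle", {
  cnt <- numeric(360); cnt[c(31, 211)] <- 7
  pm <- pattern_metrics(make_dist(cnt))
  expect_equal(pm$preferred_orientation, 30)
  expect_equal(pm$vessel_area, 0)
  expect_true(is.infinite(pm$anisotropy))
  expect_error(pattern_metrics(make_dist(numeric(360))), "all-zero")
})

test_that("elliptical rose curve recovers analytic axis ratio and orientation", {
  th <- (0:359) * pi / 180
  for (phi_deg in c(120, 30)) {
    a <- 40; b <- 20; phi <- phi_deg * pi / 180
    r <- a * b / sqrt((b * cos(th - phi))^2 + (a * sin(th - phi))^2)
    pm <- pattern_metrics(make_dist(r))
    expect_lt(abs(pm$anisotropy - 2), 0.05 * 2)
    expect_lt(axial_distance(pm$preferred_orientation, phi_deg), 1)
    expect_lt(abs(pm$vessel_area - pi * a * b) / (pi * a * b), 0.001)
  }
})

test_that("shoelace area matches high-resolution rasterization", {
  th <- (0:359) * pi / 180
  shapes <- list(
    rep(25, 360),
    20 * 15 / sqrt((15 * cos(th - 1))^2 + (20 * sin(th - 1))^2),
    15 + 8 * cos(2 * th) + 3 * cos(4 * th)
  )
  for (cnt in shapes) {
    pm <- pattern_metrics(make_dist(cnt))
    xy <- cbind(cnt * cos(th), cnt * sin(th))
    expect_lt(abs(pm$vessel_area - raster_area(xy)) / pm$vessel_area, 0.02)
  }
})

test_that("pattern metrics transform correctly under rotation, scaling and dilution", {
  set.seed(13)
  half <- 30 + 20 * abs(sin((0:179) * pi / 180 - 0.7)) +
    stats::runif(180, 0, 5)
  base <- c(half, half)
  pm <- pattern_metrics(make_dist(base))
  # rotation by 40 degrees rotates the preferred orientation, nothing else
  rot <- base[((0:359 - 40) %% 360) + 1]
  pmr <- pattern_metrics(make_dist(rot))
  expect_lt(axial_distance(pmr$preferred_orientation,
                           pm$preferred_orientation + 40), 1)
  expect_lt(abs(pmr$anisotropy - pm$anisotropy) / pm$anisotropy, 0.001)
  expect_lt(abs(pmr$vessel_area - pm$vessel_area) / pm$vessel_area, 0.001)
  # scaling counts by k scales area by k^2 only
  pms <- pattern_metrics(make_dist(3 * base))
  expect_equal(pms$vessel_area, 9 * pm$vessel_area, tolerance = 1e-10)
  expect_equal(pms$anisotropy, pm$anisotropy, tolerance = 1e-10)
  expect_equal(pms$preferred_orientation, pm$preferred_orientation,
               tolerance = 1e-8)
  # adding an isotropic floor moves anisotropy toward 1, monotonically
  an <- sapply(c(0, 20, 60, 150), function(k)
    pattern_metrics(make_dist(base + k))$anisotropy)
  expect_true(all(diff(an) < 0))
  expect_true(all(an >= 1))
})

test_that("anisotropy approaches 1 for large iid samples of uniform axial pixels", {
  set.seed(17)
  th <- stats::runif(6000, 0, 180)
  half <- tabulate(floor(th) + 1, 180)
  pm <- pattern_metrics(make_dist(c(half, half)))
  expect_lt(pm$anisotropy, 1.2)
})

test_that("vessel density is the masked fraction of the region", {
  region <- matrix(FALSE, 20, 20); region[1:10, ] <- TRUE
  mask <- matrix(FALSE, 20, 20); mask[1:5, 1:10] <- TRUE
  expect_equal(vessel_density(mask, region), 50 / 200)
  expect_equal(vessel_density(region, region), 1)
  expect_error(vessel_density(mask, matrix(FALSE, 20, 20)), "empty")
})
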