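test_that("axial circular mean handles the head-tail wrap", {
  expect_equal(axial_mean(c(10, 170)), 0, tolerance = 1e-9)
  expect_equal(axial_mean(c(30, 30, 30)), 30, tolerance = 1e-9)
  expect_equal(axial_sd(c(45, 45)), 0, tolerance = 1e-9)
  # invariant to flipping any subset by 180
  set.seed(3)
  th <- stats::runif(20, 0, 180)
  flip <- th + 180 * stats::rbinom(20, 1, 0.5)
  expect_equal(axial_mean(th), axial_mean(flip), tolerance = 1e-9)
})

test_that("sector descriptives produce mean/SD/range and axial summaries", {
  d <- data.frame(sector = rep(c("NS", "SN"), each = 3),
                  po = c(10, 170, 90, 30, 30, 30))
  s <- sector_descriptives(d, "po", angular = TRUE)
  ns <- s[s$sector == "NS", ]
  expect_equal(ns$mean, 90)
  expect_equal(ns$min, 10); expect_equal(ns$max, 170)
  expect_equal(s$axial_mean[s$sector == "SN"], 30, tolerance = 1e-9)
  one <- sector_descriptives(data.frame(sector = "A", v = 5), "v")
  expect_equal(one$mean, 5); expect_equal(one$sd, 0)
  expect_equal(one$min, one$max)
})

test_that("Mann-Whitney U: exact small-sample cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p matches brute-force enumeration, with and without ties", {
  set.seed(21)
  for (i in 1:12) {
    n_a <- sample(2:6, 1); n_b <- sample(2:8, 1)
    a <- sample(1:8, n_a, replace = TRUE)   # replace => ties across groups
    b <- sample(1:8, n_b, replace = TRUE)
    r <- mann_whitney_u(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p, mwu_brute_p(a, b), tolerance = 1e-12)
  }
})

test_that("U statistics of the two groups are complementary and p is rank-invariant", {
  set.seed(22)
  a <- stats::rnorm(6); b <- stats::rnorm(7)
  ra <- mann_whitney_u(a, b); rb <- mann_whitney_u(b, a)
  expect_equal(ra$U + rb$U, length(a) * length(b))
  expect_equal(ra$p, rb$p, tolerance = 1e-12)
  # strictly monotone transform leaves the test untouched
  rt <- mann_whitney_u(exp(a), exp(b))
  expect_equal(ra$U, rt$U)
  expect_equal(ra$p, rt$p, tolerance = 1e-12)
})

test_that("large-sample Mann-Whitney agrees with the normal-approximation reference", {
  set.seed(23)
  a <- stats::rnorm(20); b <- stats::rnorm(15, 0.5)
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal")
  w <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p, w$p.value, tolerance = 1e-10)
})

test_that("Pearson correlation: perfect fits and oracle agreement", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(24)
  u <- stats::rnorm(30); v <- 0.4 * u + stats::rnorm(30)
  r <- pearson_r(u, v)
  r_oracle <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(r$r, r_oracle, tolerance = 1e-12)
  tt <- r_oracle * sqrt(28 / (1 - r_oracle^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tt), 28), tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
})
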