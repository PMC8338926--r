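#' Axial circular mean
#'
#' Mean direction of axial (head-tail) data: angles are doubled, averaged as
#' unit vectors, and the resultant angle halved, so that 0 and 180 degrees
#' describe the same line. Returns `NA` when the doubled resultant vanishes
#' (perfectly balanced axes).
#'
#' @param theta angles in degrees.
#' @param na.rm drop `NA`s first.
#' @return axial mean in \[0, 180) degrees.
#' @examples
#' axial_mean(c(10, 170))  # 0, not 90
#' @export
axial_mean <- function(theta, na.rm = FALSE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  if (length(theta) == 0L) stop("no observations", call. = FALSE)
  a2 <- 2 * theta * pi / 180
  s <- sum(sin(a2)); c <- sum(cos(a2))
  if (abs(s) < 1e-12 && abs(c) < 1e-12) return(NA_real_)
  (atan2(s, c) / 2 * 180 / pi) %% 180
}

#' Axial circular standard deviation
#'
#' Circular standard deviation of the doubled angles, halved back to the
#' axial scale: `0.5 * sqrt(-2 * log(Rbar))` (radians) where `Rbar` is the
#' mean resultant length of the doubled angles.
#'
#' @inheritParams axial_mean
#' @return axial SD in degrees (0 for perfectly aligned axes).
#' @export
axial_sd <- function(theta, na.rm = FALSE) {
  if (na.rm) theta <- theta[!is.na(theta)]
  if (length(theta) == 0L) stop("no observations", call. = FALSE)
  a2 <- 2 * theta * pi / 180
  rbar <- sqrt(mean(sin(a2))^2 + mean(cos(a2))^2)
  rbar <- min(rbar, 1)
  if (rbar <= 0) return(Inf)
  0.5 * sqrt(-2 * log(rbar)) * 180 / pi
}

#' Descriptive statistics per sector
#'
#' Summarises a long table of per-subject, per-sector metric values into the
#' usual descriptive layout: mean, SD, minimum, maximum and n per sector.
#' For orientation metrics (`angular = TRUE`) the axial circular mean and
#' axial circular SD are reported alongside the arithmetic ones — the
#' arithmetic mean of axial angles is kept for comparability with common
#' reporting practice, but it is misleading when values straddle the 0/180
#' wrap, which the axial columns handle correctly.
#'
#' @param data data frame of observations.
#' @param value name of the numeric value column.
#' @param by name of the grouping column (default `"sector"`).
#' @param angular treat values as axial angles in degrees.
#' @return data frame with one row per group: `n`, `mean`, `sd`, `min`,
#'   `max` and, if `angular`, `axial_mean`, `axial_sd`.
#' @export
sector_descriptives <- function(data, value, by = "sector",
                                angular = FALSE) {
  if (!value %in% names(data) || !by %in% names(data))
    stop("`value` and `by` must name columns of `data`", call. = FALSE)
  v <- data[[value]]
  if (any(is.na(v))) stop("NA values in `", value, "`", call. = FALSE)
  groups <- split(v, data[[by]])
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  out <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, function(g) if (length(g) > 1L) stats::sd(g) else 0, 0),
    min = vapply(groups, min, 0),
    max = vapply(groups, max, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  names(out)[1L] <- by
  if (angular) {
    out$axial_mean <- vapply(groups, axial_mean, 0)
    out$axial_sd <- vapply(groups, axial_sd, 0)
  }
  out
}

# exact permutation null of the Mann-Whitney U statistic (midranks), by
# enumeration of all C(n, n_a) group assignments of the pooled sample
mwu_exact_null <- function(pooled_ranks, n_a) {
  idx <- utils::combn(length(pooled_ranks), n_a)
  colSums(matrix(pooled_ranks[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test (Wilcoxon rank sum)
#'
#' Nonparametric two-group comparison. The U statistic is computed from
#' midranks. For small samples (`min(n_a, n_b) <= 8` and `n_a + n_b <= 25`)
#' the p-value is exact, from full enumeration of the permutation null of U
#' (valid under ties as well); for larger samples the normal approximation
#' with tie-corrected variance is used (no continuity correction). The
#' two-sided p-value is the null probability that U deviates from its mean
#' `n_a n_b / 2` by at least the observed amount; the permutation null is
#' symmetric about that mean, so this equals the usual doubled tail.
#'
#' @param a,b numeric vectors of observations.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (location of `a` relative to `b`).
#' @return list with `U` (for group `a`), `p`, `method` (`"exact"` or
#'   `"normal"`), `n_a`, `n_b`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (any(is.na(c(a, b)))) stop("NA observations", call. = FALSE)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))                     # midranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (min(n_a, n_b) <= 8L && n <= 25L) {
    # enumerate over the smaller group; U_a = n_a n_b - U_b in distribution
    null_u <- if (n_a <= n_b) mwu_exact_null(r, n_a)
              else n_a * n_b - mwu_exact_null(r, n_b)
    m <- length(null_u)
    mu <- n_a * n_b / 2
    p <- switch(alternative,
      two.sided = sum(abs(null_u - mu) >= abs(U - mu) - 1e-9) / m,
      less = sum(null_u <= U + 1e-9) / m,
      greater = sum(null_u >= U - 1e-9) / m
    )
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    sig2 <- n_a * n_b / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sig2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE)
    )
    p <- min(p, 1)
    method <- "normal"
  }
  list(U = U, p = p, method = method, n_a = n_a, n_b = n_b)
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; the two-sided p-value comes from the t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, `n >= 3`, each with nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
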