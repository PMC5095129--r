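# Independent oracles and small fixture builders used across the suite.

# Adaptive-quadrature oracles for the paraboloid of revolution of
# z(x) = h (1 - x^2 / r^2): solid volume by slicing, section area, section
# arc length, and lateral surface of revolution. Deliberately written from
# the integral definitions, not the closed forms under test.
quad_volume <- function(h, r) {
  stats::integrate(function(z) pi * r^2 * (1 - z / h), 0, h,
                   rel.tol = 1e-10)$value
}
quad_cross_area <- function(h, r) {
  stats::integrate(function(x) h * (1 - x^2 / r^2), -r, r,
                   rel.tol = 1e-10)$value
}
quad_arc_length <- function(h, r) {
  stats::integrate(function(x) sqrt(1 + (2 * h * x / r^2)^2), -r, r,
                   rel.tol = 1e-10)$value
}
quad_surface <- function(h, r) {
  2 * pi * stats::integrate(function(x) x * sqrt(1 + (2 * h * x / r^2)^2),
                            0, r, rel.tol = 1e-10)$value
}

# Exact parabola contour (no noise) as a contour tibble.
parabola_contour <- function(h, r, n = 201, id = "parabola") {
  x <- seq(-r, r, length.out = n)
  tibble::tibble(contour_id = id, point_index = seq_len(n),
                 x = x, y = h * (1 - x^2 / r^2))
}

# Brute-force Hodges-Lehmann estimate.
hl_brute <- function(x, y) median(as.vector(outer(x, y, `-`)))

# Exact one-sided ("less") Wilcoxon rank-sum p-value by enumerating every
# assignment of ranks to the x-sample (no ties assumed).
wilcox_p_enum <- function(x, y, alternative = "less") {
  n1 <- length(x); n <- n1 + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(n, n1), 2, function(idx) {
    sum(idx) - n1 * (n1 + 1) / 2
  })
  switch(alternative,
         less = mean(all_w <= w_obs),
         greater = mean(all_w >= w_obs),
         two.sided = min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))))
}

# Apply a random rigid motion (+ optional uniform scaling) to a contour table.
random_rigid <- function(contours, scale_range = c(0.5, 2)) {
  th <- stats::runif(1, 0, 2 * pi)
  s <- stats::runif(1, scale_range[1], scale_range[2])
  shift <- stats::rnorm(2, 0, 50)
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(contours[, c("x", "y")]) %*% t(rot) * s
  contours$x <- xy[, 1] + shift[1]
  contours$y <- xy[, 2] + shift[2]
  contours
}

# Standard small cross config used in QTL tests.
test_cross_config <- function(n_lines = 200, qtl = NULL) {
  sim_config(n_lines = n_lines, n_chromosomes = 5,
             markers_per_chromosome = 50, chromosome_length = 100,
             qtl = qtl, n_replicates = 1,
             replicate_offsets = 0)
}

# BC2S3 donor-allele dosage variance implied by the single-locus priors,
# used to size QTL effects for a target variance share.
bc2s3_dosage_var <- function() {
  pr <- c(55, 2, 7) / 64
  m <- sum(pr * 0:2)
  sum(pr * (0:2)^2) - m^2
}

qtl_effect_for_share <- function(share, resid_sd) {
  sqrt(share / (1 - share) * resid_sd^2 / bc2s3_dosage_var())
}
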