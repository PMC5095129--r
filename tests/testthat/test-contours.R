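# Contour normalisation: resampling, orientation, Procrustes alignment.

test_that("resampling a straight segment spaces points uniformly", {
  seg <- data.frame(x = c(0, 10), y = c(0, 0))
  out <- resample_contour(seg, n_points = 5)
  expect_equal(out$x, c(0, 2.5, 5, 7.5, 10))
  expect_equal(out$y, rep(0, 5))
})

test_that("resampling an already-uniform contour is idempotent", {
  # equal segment lengths by construction: a unit-step polyline
  set.seed(1)
  th <- cumsum(rnorm(100, 0, 0.2))
  cont <- data.frame(x = cumsum(c(0, cos(th))), y = cumsum(c(0, sin(th))))
  again <- resample_contour(cont, 101)
  expect_equal(again$x, cont$x, tolerance = 1e-9)
  expect_equal(again$y, cont$y, tolerance = 1e-9)
})

test_that("resampled quarter-circle has equal chord lengths and endpoints kept", {
  th <- seq(0, pi / 2, length.out = 1000)
  qc <- data.frame(x = cos(th), y = sin(th))
  out <- resample_contour(qc, 11)
  chords <- sqrt(diff(out$x)^2 + diff(out$y)^2)
  expect_lt(diff(range(chords)) / mean(chords), 1e-3)
  expect_equal(out$x[1], 1); expect_equal(out$y[11], 1)
})

test_that("resampling preserves total polyline length on smooth curves", {
  for (n in c(100, 400)) {
    th <- seq(0, pi, length.out = 2000)
    curve <- data.frame(x = 80 * cos(th), y = 60 * sin(th))
    len0 <- sum(sqrt(diff(curve$x)^2 + diff(curve$y)^2))
    out <- resample_contour(curve, n)
    len1 <- sum(sqrt(diff(out$x)^2 + diff(out$y)^2))
    expect_lt(abs(len1 - len0) / len0, 0.005)
  }
})

test_that("zero-length contours are a domain error", {
  expect_error(resample_contour(data.frame(x = c(1, 1), y = c(2, 2)), 5),
               "zero length")
})

test_that("orientation: no-op, involution, and reflection definition", {
  set.seed(2)
  cont <- simulate_contour(100, 80, n_points = 50, shear = 0.2)
  expect_equal(orient_contour(cont, "p0_left"), cont)
  flipped <- orient_contour(cont, "p0_right")
  back <- orient_contour(flipped, "p0_left")
  expect_equal(back$x, cont$x, tolerance = 1e-12)
  expect_equal(back$y, cont$y, tolerance = 1e-12)
  # reflection about the vertical axis through the centroid, order reversed
  expect_equal(sort(flipped$x), sort(2 * mean(cont$x) - cont$x))
  expect_equal(flipped$y, rev(cont$y))
  cont$orientation <- NULL
  expect_error(orient_contour(cont, "p0_left"), "orientation")
})

test_that("exactly superimposable shapes align to Procrustes distance zero", {
  set.seed(3)
  base <- resample_contour(simulate_contour(100, 80, 120, noise_sd = 1), 100)
  copy <- random_rigid(base)
  copy$contour_id <- "copy"
  gpa <- procrustes_align(dplyr::bind_rows(base, copy))
  d <- gpa$landmarks[1, , ] - gpa$landmarks[2, , ]
  expect_lt(sqrt(sum(d^2)), 1e-9)
  expect_true(gpa$converged)
})

test_that("aligned shapes are centered with unit centroid size; mean is the average", {
  set.seed(4)
  conts <- purrr::map_dfr(1:6, function(i) {
    simulate_contour(90 + 5 * i, 80, 80, noise_sd = 1,
                     contour_id = sprintf("s%d", i))
  }) |> resample_contour(60)
  gpa <- procrustes_align(conts)
  for (i in 1:6) {
    sh <- gpa$landmarks[i, , ]
    expect_lt(max(abs(colMeans(sh))), 1e-9)
    expect_equal(sqrt(sum(sh^2)), 1, tolerance = 1e-9)
  }
  expect_equal(gpa$mean_shape, apply(gpa$landmarks, c(2, 3), mean))
})

test_that("GPA residual sum of squares is monotone over iterations", {
  set.seed(6)
  conts <- purrr::map_dfr(1:20, function(i) {
    random_rigid(simulate_contour(100, 80, 100, noise_sd = 1,
                                  contour_id = sprintf("s%02d", i)))
  }) |> resample_contour(80)
  gpa <- procrustes_align(conts)
  expect_true(all(diff(gpa$rss) <= 1e-12))
})

test_that("alignment is invariant to rigid motion + scaling of the inputs", {
  set.seed(7)
  conts <- purrr::map_dfr(1:8, function(i) {
    simulate_contour(90 + 3 * i, 75 + 2 * i, 90, noise_sd = 0.5,
                     contour_id = sprintf("s%d", i))
  }) |> resample_contour(70)
  moved <- conts |>
    dplyr::group_by(contour_id) |>
    dplyr::group_modify(~ random_rigid(.x)) |>
    dplyr::ungroup()
  g1 <- procrustes_align(conts)
  g2 <- procrustes_align(moved)
  # superimpose the two mean shapes before comparing (global rotation is free)
  rot <- samorph:::rotation_onto(g2$mean_shape, g1$mean_shape)
  for (i in 1:8) {
    expect_lt(max(abs(g2$landmarks[i, , ] %*% rot - g1$landmarks[i, , ])), 1e-6)
  }
})

test_that("two-shape rotation matches vegan's Procrustes rotation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  x <- as.matrix(resample_contour(simulate_contour(100, 80, 100, noise_sd = 1),
                                  60)[, c("x", "y")])
  th <- 0.7
  y <- x %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) +
    matrix(rnorm(120, 0, 0.5), 60, 2)
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  ours <- samorph:::rotation_onto(yc, xc)
  veg <- vegan::procrustes(xc, yc, scale = FALSE)
  expect_equal(ours, veg$rotation, tolerance = 1e-8)
})

test_that("mismatched point counts are rejected", {
  a <- resample_contour(parabola_contour(50, 50, 60, id = "a"), 50)
  b <- resample_contour(parabola_contour(60, 50, 60, id = "b"), 40)
  expect_error(procrustes_align(dplyr::bind_rows(a, b)), "same number")
})
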