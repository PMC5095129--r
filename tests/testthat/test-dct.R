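# DCT shape descriptors and the PCA morphospace.

make_dct_input <- function(xmat, ymat) {
  # wrap raw landmark matrices as a contour table for dct_transform
  n <- nrow(xmat); np <- ncol(xmat)
  tibble::tibble(
    contour_id = rep(sprintf("s%03d", seq_len(n)), each = np),
    point_index = rep(seq_len(np), times = n),
    x = as.vector(t(xmat)), y = as.vector(t(ymat))
  )
}

test_that("a constant signal has no energy in retained harmonics", {
  d <- make_dct_input(matrix(7, 2, 64), matrix(-3, 2, 64))
  co <- dct_transform(d, n_harmonics = 12)
  expect_equal(max(abs(as.matrix(co[, -1]))), 0, tolerance = 1e-12)
})

test_that("a pure DCT basis function maps to a single harmonic", {
  n <- 64
  i <- 0:(n - 1)
  x <- cos(pi * (2 * i + 1) * 3 / (2 * n))
  d <- make_dct_input(rbind(x, x), matrix(0, 2, n))
  co <- dct_transform(d, n_harmonics = 12)
  cx <- as.numeric(co[1, paste0("x", 1:12)])
  expect_gt(abs(cx[3]), 1)
  expect_lt(max(abs(cx[-3])), 1e-12)
})

test_that("full-harmonic round trip reproduces the centered input", {
  set.seed(21)
  n <- 40
  x <- rnorm(n); y <- rnorm(n)
  d <- make_dct_input(rbind(x, x), rbind(y, y))
  co <- dct_transform(d, n_harmonics = n - 1)
  rec <- inverse_dct(as.numeric(co[1, paste0("x", 1:(n - 1))]),
                     as.numeric(co[1, paste0("y", 1:(n - 1))]), n)
  expect_equal(rec$x, x - mean(x), tolerance = 1e-9)
  expect_equal(rec$y, y - mean(y), tolerance = 1e-9)
})

test_that("Parseval: retained energy is bounded by (and at full order equals) signal energy", {
  set.seed(22)
  n <- 50
  x <- rnorm(n); y <- rnorm(n)
  d <- make_dct_input(rbind(x, x), rbind(y, y))
  energy <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  part <- dct_transform(d, n_harmonics = 10)
  expect_lt(sum(as.matrix(part[1, -1])^2), energy)
  full <- dct_transform(d, n_harmonics = n - 1)
  expect_equal(sum(as.matrix(full[1, -1])^2), energy, tolerance = 1e-9)
})

test_that("zero coefficients reconstruct to the origin; harmonic cap enforced", {
  rec <- inverse_dct(numeric(5), numeric(5), 20)
  expect_equal(max(abs(rec$x)), 0)
  expect_equal(max(abs(rec$y)), 0)
  d <- make_dct_input(matrix(rnorm(20), 1), matrix(rnorm(20), 1))
  expect_error(dct_transform(d, n_harmonics = 20), "smaller")
})

test_that("12 harmonics recapture a smooth parabolic contour to < 1% of height", {
  cont <- resample_contour(parabola_contour(100, 80, 1001), 800)
  co <- dct_transform(cont, n_harmonics = 12)
  rec <- inverse_dct(as.numeric(co[1, paste0("x", 1:12)]),
                     as.numeric(co[1, paste0("y", 1:12)]), 800)
  rmse <- sqrt(mean((rec$x - (cont$x - mean(cont$x)))^2 +
                      (rec$y - (cont$y - mean(cont$y)))^2))
  expect_lt(rmse, 1)   # 1% of the 100 um height
})

test_that("rank-1 coefficient variation loads entirely on PC1", {
  set.seed(23)
  base <- rnorm(24)
  dir <- rnorm(24); dir <- dir / sqrt(sum(dir^2))
  m <- t(sapply(rnorm(10), function(a) base + a * dir))
  colnames(m) <- c(paste0("x", 1:12), paste0("y", 1:12))
  co <- tibble::as_tibble(m)
  co$shape_id <- sprintf("s%d", 1:10)
  p <- shape_pca(co)
  expect_equal(p$explained_fraction[1], 1, tolerance = 1e-9)
})

test_that("PCA invariants: ordering, unit sum, orthonormal loadings, centered uncorrelated scores", {
  set.seed(24)
  conts <- purrr::map_dfr(1:30, function(i) {
    simulate_contour(80 + rnorm(1, 0, 8), 80, 100, noise_sd = 1,
                     shear = rnorm(1, 0, 0.05), contour_id = sprintf("s%02d", i))
  })
  p <- conts |> resample_contour(100) |> procrustes_align() |>
    dct_transform() |> shape_pca()
  ef <- p$explained_fraction
  expect_true(all(diff(ef) <= 1e-12))
  expect_equal(sum(ef), 1, tolerance = 1e-9)
  ll <- p$loadings %*% t(p$loadings)
  expect_equal(ll, diag(nrow(ll)), tolerance = 1e-9, ignore_attr = TRUE)
  sc <- as.matrix(p$scores[, -1])
  expect_lt(max(abs(colMeans(sc))), 1e-9)
  cc <- cor(sc[, 1:10])
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-9)
})

test_that("independent elongation and lean generators are recovered with ~9:1 variance", {
  set.seed(25)
  n <- 200
  elong <- rnorm(n, 0, 3)   # sigma^2 = 9 on the calibrated scale
  lean <- rnorm(n, 0, 1)    # sigma^2 = 1
  # calibrate per-unit coefficient displacement of the two generators so the
  # score-variance ratio is interpretable
  unit_shape <- function(e, s) {
    simulate_contour(100 * exp(0.05 * e), 80, 120, noise_sd = 0,
                     shear = 0.02 * s) |> resample_contour(100)
  }
  coef_of <- function(cont) {
    arr <- samorph:::contours_to_array(cont)
    sh <- arr[1, , ]
    sh <- sweep(sh, 2, colMeans(sh))
    sh <- sh / sqrt(sum(sh^2))
    co <- dct_transform(make_dct_input(t(sh[, 1, drop = FALSE]),
                                       t(sh[, 2, drop = FALSE])), 12)
    as.numeric(co[1, -1])
  }
  c0 <- coef_of(unit_shape(0, 0))
  norm_e <- sqrt(sum((coef_of(unit_shape(1, 0)) - c0)^2))
  norm_s <- sqrt(sum((coef_of(unit_shape(0, 1)) - c0)^2))
  lean <- lean * norm_e / norm_s  # equalise per-unit displacement
  conts <- purrr::map_dfr(seq_len(n), function(i) {
    simulate_contour(100 * exp(0.05 * elong[i]), 80, 120, noise_sd = 0,
                     shear = 0.02 * lean[i], contour_id = sprintf("s%03d", i))
  })
  p <- conts |> resample_contour(100) |> procrustes_align() |>
    dct_transform() |> shape_pca()
  ratio <- p$explained_fraction[1] / p$explained_fraction[2]
  expect_gt(ratio, 4.5)
  expect_lt(ratio, 18)
  # PC1 carries the elongation signal
  expect_gt(abs(cor(p$scores$PC1, elong)), 0.9)
})

test_that("PC reconstructions are linear and mirror about the mean", {
  set.seed(26)
  conts <- purrr::map_dfr(1:20, function(i) {
    simulate_contour(90 + rnorm(1, 0, 10), 80, 80, noise_sd = 0.5,
                     shear = rnorm(1, 0, 0.05), contour_id = sprintf("s%02d", i))
  })
  p <- conts |> resample_contour(80) |> procrustes_align() |>
    dct_transform() |> shape_pca()
  rec <- reconstruct_at_pc(p, 1, c(-2, 0, 2), n_points = 80)
  m0 <- rec[rec$sd_multiple == 0, ]
  k <- 12
  mean_rec <- inverse_dct(p$mean_coeffs[1:k], p$mean_coeffs[k + 1:k], 80)
  expect_equal(m0$x, mean_rec$x)
  expect_equal(m0$y, mean_rec$y)
  plus <- rec[rec$sd_multiple == 2, ]
  minus <- rec[rec$sd_multiple == -2, ]
  expect_equal(plus$x + minus$x, 2 * m0$x, tolerance = 1e-9)
  expect_equal(plus$y + minus$y, 2 * m0$y, tolerance = 1e-9)
})

test_that("lean-PC reconstructions flip the signed area asymmetry", {
  set.seed(27)
  lean <- rnorm(60, 0, 1)
  conts <- purrr::map_dfr(seq_len(60), function(i) {
    simulate_contour(100, 80, 100, noise_sd = 0.2, shear = 0.15 * lean[i],
                     contour_id = sprintf("s%02d", i))
  })
  p <- conts |> resample_contour(100) |> procrustes_align() |>
    dct_transform() |> shape_pca()
  # the lean axis is the PC most correlated with the generator
  pc <- which.max(abs(cor(as.matrix(p$scores[, -1]), lean))[, 1])
  rec <- reconstruct_at_pc(p, pc, c(-2, 2), n_points = 100)
  asym <- vapply(c(-2, 2), function(m) {
    d <- rec[rec$sd_multiple == m, ]
    samorph:::contour_asymmetry(d$x, d$y)
  }, numeric(1))
  expect_lt(asym[1] * asym[2], 0)
})
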