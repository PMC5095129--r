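# Open-outline shape descriptors: orthonormal DCT-II of the x and y
# pseudo-landmark sequences, harmonics k = 1..n_harmonics (k = 0 is the mean
# term and is dropped because aligned shapes are centered), followed by PCA
# of the concatenated [coeff_x, coeff_y] feature vectors.

# Orthonormal DCT-II basis rows for harmonics `k` over N points:
#   C[k, i] = w_k * cos(pi * (2i + 1) * k / (2N)),  i = 0..N-1,
# with w_0 = sqrt(1/N) and w_k = sqrt(2/N) for k >= 1. Rows are orthonormal,
# so the transform is an isometry (Parseval holds exactly).
dct_basis <- function(n_points, k) {
  i <- seq_len(n_points) - 1
  w <- ifelse(k == 0, sqrt(1 / n_points), sqrt(2 / n_points))
  m <- outer(k, i, function(k, i) cos(pi * (2 * i + 1) * k / (2 * n_points)))
  m * w
}

#' Discrete cosine transform of aligned contours
#'
#' Computes, for each aligned shape, the orthonormal DCT-II of its x-coordinate
#' sequence and of its y-coordinate sequence independently, retaining harmonics
#' \eqn{k = 1, \ldots,} `n_harmonics`. Twelve harmonics per axis (the default)
#' suffice to recapture smooth apex-contour variation.
#'
#' @param aligned A `sam_gpa` object from [procrustes_align()], or a data
#'   frame of aligned landmarks (`contour_id`, `point_index`, `x`, `y`).
#' @param n_harmonics Harmonics retained per coordinate axis (default 12);
#'   must be smaller than the landmark count.
#' @return An object of class `sam_dct`: a tibble with one row per shape,
#'   columns `shape_id`, `x1`..`x<k>`, `y1`..`y<k>`, and attributes
#'   `n_harmonics` and `n_points`.
#' @export
dct_transform <- function(aligned, n_harmonics = 12) {
  if (inherits(aligned, "sam_gpa")) {
    ids <- aligned$shape_ids
    xm <- aligned$landmarks[, , 1, drop = FALSE][, , 1]
    ym <- aligned$landmarks[, , 2, drop = FALSE][, , 1]
    if (is.null(dim(xm))) { xm <- matrix(xm, 1); ym <- matrix(ym, 1) }
  } else {
    arr <- contours_to_array(aligned)
    ids <- dimnames(arr)[[1]]
    xm <- arr[, , 1, drop = FALSE][, , 1]
    ym <- arr[, , 2, drop = FALSE][, , 1]
    if (is.null(dim(xm))) { xm <- matrix(xm, 1); ym <- matrix(ym, 1) }
  }
  n_points <- ncol(xm)
  if (n_harmonics >= n_points) {
    abort("`n_harmonics` must be smaller than the number of pseudo-landmarks.")
  }
  basis <- dct_basis(n_points, seq_len(n_harmonics))
  cx <- xm %*% t(basis)
  cy <- ym %*% t(basis)
  colnames(cx) <- paste0("x", seq_len(n_harmonics))
  colnames(cy) <- paste0("y", seq_len(n_harmonics))
  out <- dplyr::bind_cols(tibble(shape_id = ids), as_tibble(cx), as_tibble(cy))
  structure(out, class = c("sam_dct", class(out)),
            n_harmonics = n_harmonics, n_points = n_points)
}

#' Reconstruct a contour from DCT harmonics
#'
#' Inverse orthonormal DCT-II with truncation: rebuilds centered (x, y)
#' pseudo-landmark sequences from retained harmonic amplitudes. Used to render
#' expected shapes, e.g. along principal components.
#'
#' @param coeff_x,coeff_y Numeric vectors of harmonic amplitudes for k = 1..K.
#' @param n_points Number of pseudo-landmarks to reconstruct (>= 2).
#' @return A tibble with columns `point_index`, `x`, `y` (a centered open
#'   contour).
#' @export
inverse_dct <- function(coeff_x, coeff_y, n_points = 800) {
  stopifnot(length(coeff_x) == length(coeff_y), n_points >= 2)
  basis <- dct_basis(n_points, seq_along(coeff_x))
  tibble(
    point_index = seq_len(n_points),
    x = as.vector(crossprod(basis, coeff_x)),
    y = as.vector(crossprod(basis, coeff_y))
  )
}

#' Principal component analysis of DCT shape descriptors
#'
#' PCA (eigen-decomposition of the covariance matrix) of the column-centered,
#' unscaled coefficient matrix `[coeff_x, coeff_y]`. Coefficients share units,
#' so no per-column standardisation is applied — standardising would distort
#' the natural ordering of harmonic energy. The sign of each PC is fixed so
#' that its largest-magnitude loading entry is positive, making score signs
#' reproducible across runs.
#'
#' @param coeffs A `sam_dct` object (or equivalent data frame with `shape_id`
#'   and coefficient columns) for at least 3 shapes.
#' @return An object of class `sam_pca`: a list with `scores` (tibble,
#'   `shape_id` + `PC1..PCk`), `loadings` (PCs in rows, coefficients in
#'   columns, orthonormal), `explained_fraction`, `sdev`, `mean_coeffs`,
#'   `n_points`, `n_harmonics`. `tidy()` returns scores, `glance()` the
#'   variance decomposition.
#' @export
shape_pca <- function(coeffs) {
  stopifnot(is.data.frame(coeffs))
  ids <- coeffs$shape_id %||% as.character(seq_len(nrow(coeffs)))
  m <- as.matrix(coeffs[setdiff(names(coeffs), "shape_id")])
  if (nrow(m) < 3) abort("shape PCA needs at least 3 shapes.")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| entry of each PC is positive
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2, flip, `*`)
  p$x <- sweep(p$x, 2, flip, `*`)
  scores <- dplyr::bind_cols(tibble(shape_id = ids), as_tibble(p$x))
  structure(
    list(
      scores = scores,
      loadings = t(p$rotation),
      explained_fraction = p$sdev^2 / sum(p$sdev^2),
      sdev = p$sdev,
      mean_coeffs = p$center,
      n_points = attr(coeffs, "n_points") %||% 800L,
      n_harmonics = attr(coeffs, "n_harmonics") %||% (ncol(m) / 2)
    ),
    class = "sam_pca"
  )
}

#' @export
print.sam_pca <- function(x, ...) {
  cat("Shape PCA over DCT harmonic coefficients\n")
  cat(sprintf("  shapes: %d, coefficients: %d (%d harmonics per axis)\n",
              nrow(x$scores), ncol(x$loadings), x$n_harmonics))
  ef <- round(100 * x$explained_fraction[seq_len(min(3, length(x$explained_fraction)))], 1)
  cat("  explained (%):", paste(ef, collapse = ", "),
      if (length(x$explained_fraction) > 3) "..." else "", "\n")
  invisible(x)
}

#' @rdname shape_pca
#' @param x,object A `sam_pca` object.
#' @param ... Unused.
#' @export
tidy.sam_pca <- function(x, ...) x$scores

#' @rdname shape_pca
#' @export
glance.sam_pca <- function(x, ...) {
  tibble(
    pc = seq_along(x$explained_fraction),
    sdev = x$sdev,
    explained_fraction = x$explained_fraction,
    cumulative_fraction = cumsum(x$explained_fraction)
  )
}

#' Expected shapes along a principal component
#'
#' Reconstructs the contour expected at chosen multiples of the score standard
#' deviation along one PC: the inverse DCT of
#' `mean_coeffs + m * sd(PC) * loading`. `m = 0` renders the mean shape.
#'
#' @param space A `sam_pca` object.
#' @param pc PC index.
#' @param sd_multiples Numeric vector of standard-deviation multiples
#'   (default `c(-4, -2, 0, 2, 4)`).
#' @param n_points Pseudo-landmarks in each rendering (default the source
#'   landmark count).
#' @return A tibble with columns `pc`, `sd_multiple`, `point_index`, `x`, `y`.
#' @export
reconstruct_at_pc <- function(space, pc = 1, sd_multiples = c(-4, -2, 0, 2, 4),
                              n_points = NULL) {
  stopifnot(inherits(space, "sam_pca"))
  if (pc < 1 || pc > nrow(space$loadings)) abort("`pc` outside retained PCs.")
  n_points <- n_points %||% space$n_points
  k <- length(space$mean_coeffs) / 2
  purrr::map_dfr(sd_multiples, function(m) {
    v <- space$mean_coeffs + m * space$sdev[pc] * space$loadings[pc, ]
    rec <- inverse_dct(v[seq_len(k)], v[k + seq_len(k)], n_points)
    dplyr::bind_cols(tibble(pc = pc, sd_multiple = m), rec)
  })
}

#' @export
autoplot.sam_pca <- function(object, pc = 1,
                             sd_multiples = c(-4, -2, 0, 2, 4), ...) {
  d <- reconstruct_at_pc(object, pc = pc, sd_multiples = sd_multiples)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  colour = factor(.data$sd_multiple),
                                  group = .data$sd_multiple)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "SD multiple", x = "x", y = "y",
                  title = sprintf("Expected SAM shapes along PC%d", pc))
}

# Signed left-right area asymmetry of a centered contour: area of the region
# with x < apex side minus x > apex side, by trapezoidal integration of y over
# x on each half (split at the apex, the point of maximal y).
contour_asymmetry <- function(x, y) {
  i_apex <- which.max(y)
  trapz <- function(x, y) {
    if (length(x) < 2) return(0)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  left <- abs(trapz(x[seq_len(i_apex)], y[seq_len(i_apex)]))
  right <- abs(trapz(x[i_apex:length(x)], y[i_apex:length(x)]))
  left - right
}
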