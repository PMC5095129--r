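# Normalisation of digitized open SAM contours: every trace runs from one
# basal end over the apex to the other basal end, y-up, micrometres.
# Pseudo-landmarks correspond by index across shapes (no sliding).

#' Resample contours to equally spaced pseudo-landmarks
#'
#' Places `n_points` pseudo-landmarks at equal arc-length spacing along each
#' contour polyline, preserving both endpoints exactly. This is the "thinning"
#' step that makes open outlines comparable landmark-by-landmark.
#'
#' @param contours Data frame with columns `contour_id`, `x`, `y` (ordered
#'   points); a single contour without `contour_id` is accepted. An
#'   `orientation` column, if present, is carried through.
#' @param n_points Number of pseudo-landmarks (default 800).
#' @return A tibble with columns `contour_id`, `point_index` (1-based), `x`,
#'   `y` (and `orientation` if supplied).
#' @examples
#' seg <- data.frame(x = c(0, 10), y = c(0, 0))
#' resample_contour(seg, n_points = 5)
#' @export
resample_contour <- function(contours, n_points = 800) {
  stopifnot(is.data.frame(contours), n_points >= 2)
  if (!"contour_id" %in% names(contours)) contours$contour_id <- "contour"
  has_orient <- "orientation" %in% names(contours)
  out <- contours |>
    dplyr::group_by(.data$contour_id) |>
    dplyr::group_modify(function(d, key) {
      p <- resample_xy(d$x, d$y, n_points)
      res <- tibble(point_index = seq_len(n_points), x = p$x, y = p$y)
      if (has_orient) res$orientation <- d$orientation[1]
      res
    }) |>
    dplyr::ungroup()
  out
}

resample_xy <- function(x, y, n_points) {
  keep <- c(TRUE, diff(x)^2 + diff(y)^2 > 0)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) abort("contour has zero length; cannot resample.")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n_points)
  list(
    x = stats::approx(s, x, xout = target, ties = "ordered")$y,
    y = stats::approx(s, y, xout = target, ties = "ordered")$y
  )
}

#' Standardise contour left/right orientation
#'
#' SAM contours are traced with the next leaf primordium to initiate (P0) on a
#' known side; populations are analysed with a common handedness so that
#' left/right asymmetry is a real signal rather than digitization accident.
#' Contours whose recorded `orientation` differs from `target` are mirrored
#' about the vertical axis through their centroid, and their point order is
#' reversed so traversal still runs base-apex-base in the same sense.
#'
#' @param contours Data frame with `contour_id`, `x`, `y` and an `orientation`
#'   column with values `"p0_left"` or `"p0_right"` (`"unknown"` is an error:
#'   orientation cannot be inferred from coordinates alone).
#' @param target Desired orientation, `"p0_left"` (default) or `"p0_right"`.
#' @return A tibble of the same shape with all contours in the target
#'   orientation.
#' @export
orient_contour <- function(contours, target = c("p0_left", "p0_right")) {
  target <- match.arg(target)
  stopifnot(is.data.frame(contours))
  if (!"contour_id" %in% names(contours)) contours$contour_id <- "contour"
  if (!"orientation" %in% names(contours)) {
    abort("`contours` lacks an `orientation` column; set one (p0_left/p0_right) before orienting.")
  }
  bad <- !contours$orientation %in% c("p0_left", "p0_right")
  if (any(bad)) {
    abort("orientation is unknown for some contours; set it to p0_left or p0_right.")
  }
  contours |>
    dplyr::group_by(.data$contour_id) |>
    dplyr::group_modify(function(d, key) {
      if (d$orientation[1] != target) {
        d$x <- 2 * mean(d$x) - d$x
        d <- d[rev(seq_len(nrow(d))), ]
        if ("point_index" %in% names(d)) d$point_index <- rev(d$point_index)
        d$orientation <- target
      }
      d
    }) |>
    dplyr::ungroup()
}

#' Generalized Procrustes alignment of resampled contours
#'
#' Superimposes a set of open contours (all resampled to the same number of
#' pseudo-landmarks, corresponding by index) by iterating: center each shape
#' at the origin, optionally scale to unit centroid size, rotate each onto the
#' current mean by the optimal orthogonal rotation, and update the mean —
#' until the mean shape changes by less than `tol` or `max_iter` is reached.
#' Reflections are never allowed in the rotation step: left/right asymmetry is
#' treated as signal and handled explicitly by [orient_contour()].
#'
#' @param contours Data frame with `contour_id`, `point_index`, `x`, `y`; all
#'   contours must have identical point counts, and at least 2 contours.
#' @param with_scaling Scale each shape to unit centroid size (default `TRUE`,
#'   a shape-only analysis; size is carried by the parabolic estimators).
#' @param tol Convergence tolerance on the root-mean-square change of the mean
#'   shape (default 1e-8).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `sam_gpa`: a list with `landmarks` (array
#'   n_shapes x n_points x 2), `shape_ids`, `centroid_sizes` (micrometres),
#'   `mean_shape`, `converged`, `iterations`, `with_scaling`, and `rss` (the
#'   per-iteration total squared deviation from the mean, non-increasing).
#'   `tidy()` returns the aligned landmarks as a long tibble.
#' @export
procrustes_align <- function(contours, with_scaling = TRUE, tol = 1e-8,
                             max_iter = 100) {
  arr <- contours_to_array(contours)
  n <- dim(arr)[1]
  if (n < 2) abort("need at least 2 contours to align.")
  # center; record centroid sizes
  csize <- numeric(n)
  for (i in seq_len(n)) {
    sh <- arr[i, , ]
    sh <- sweep(sh, 2, colMeans(sh))
    csize[i] <- sqrt(sum(sh^2))
    if (csize[i] == 0) abort("degenerate contour (all points identical).")
    if (with_scaling) sh <- sh / csize[i]
    arr[i, , ] <- sh
  }
  mean_shape <- apply(arr, c(2, 3), mean)
  converged <- FALSE
  iterations <- 0L
  rss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    iterations <- it
    for (i in seq_len(n)) {
      arr[i, , ] <- arr[i, , ] %*% rotation_onto(arr[i, , ], mean_shape)
    }
    new_mean <- apply(arr, c(2, 3), mean)
    rss_trace <- c(rss_trace, sum(sweep(arr, c(2, 3), new_mean)^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(
    list(
      landmarks = arr, shape_ids = dimnames(arr)[[1]],
      centroid_sizes = setNames(csize, dimnames(arr)[[1]]),
      mean_shape = mean_shape, converged = converged,
      iterations = iterations, with_scaling = with_scaling, rss = rss_trace
    ),
    class = "sam_gpa"
  )
}

# Optimal proper rotation (det +1, never a reflection) taking shape X onto
# target Y in the least-squares sense; both centered n_points x 2 matrices.
rotation_onto <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

contours_to_array <- function(contours) {
  stopifnot(is.data.frame(contours))
  if (!"contour_id" %in% names(contours)) contours$contour_id <- "contour"
  if (!"point_index" %in% names(contours)) {
    contours <- contours |>
      dplyr::group_by(.data$contour_id) |>
      dplyr::mutate(point_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  counts <- table(contours$contour_id)
  if (length(unique(as.integer(counts))) != 1) {
    abort("all contours must be resampled to the same number of points.")
  }
  ids <- unique(as.character(contours$contour_id))
  np <- as.integer(counts[1])
  arr <- array(NA_real_, c(length(ids), np, 2),
               dimnames = list(ids, NULL, c("x", "y")))
  ord <- order(match(contours$contour_id, ids), contours$point_index)
  contours <- contours[ord, ]
  arr[, , 1] <- matrix(contours$x, nrow = length(ids), byrow = TRUE)
  arr[, , 2] <- matrix(contours$y, nrow = length(ids), byrow = TRUE)
  arr
}

#' @export
print.sam_gpa <- function(x, ...) {
  cat("Generalized Procrustes alignment\n")
  cat(sprintf("  shapes: %d, pseudo-landmarks: %d, scaling: %s\n",
              dim(x$landmarks)[1], dim(x$landmarks)[2],
              if (x$with_scaling) "unit centroid size" else "off"))
  cat(sprintf("  converged: %s after %d iteration(s)\n",
              x$converged, x$iterations))
  invisible(x)
}

#' @export
tidy.sam_gpa <- function(x, ...) {
  n <- dim(x$landmarks)[1]; np <- dim(x$landmarks)[2]
  tibble(
    contour_id = rep(x$shape_ids, each = np),
    point_index = rep(seq_len(np), times = n),
    x = as.vector(t(x$landmarks[, , 1])),
    y = as.vector(t(x$landmarks[, , 2]))
  )
}

#' @export
autoplot.sam_gpa <- function(object, alpha = 0.25, ...) {
  d <- tidy(object)
  m <- tibble(point_index = seq_len(nrow(object$mean_shape)),
              x = object$mean_shape[, 1], y = object$mean_shape[, 2])
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, group = .data$contour_id)) +
    ggplot2::geom_path(alpha = alpha, colour = "grey40") +
    ggplot2::geom_path(data = m, ggplot2::aes(group = NULL), colour = "firebrick",
                       linewidth = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (aligned)", y = "y (aligned)",
                  title = "Procrustes-aligned SAM contours")
}
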