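# Paraboloid model of the shoot apical meristem.
#
# The SAM median section is modelled as the parabola z(x) = h * (1 - x^2/r^2)
# for x in [-r, r] (apex up, base on the chord z = 0); the solid is its
# surface of revolution about the z axis. All lengths are in micrometres.

#' Eight parabolic estimators of SAM shape and size
#'
#' Derives the full set of paraboloid shape/size estimators from the two
#' primary measures, SAM height and SAM radius. The meristem is modelled as
#' the paraboloid of revolution of \eqn{z(x) = h(1 - x^2/r^2)}:
#'
#' * `h_over_r` — height-to-radius ratio \eqn{h/r} (dimensionless)
#' * `volume` — \eqn{\pi r^2 h / 2} (\eqn{\mu m^3})
#' * `surface_area` — lateral (dome) surface of revolution, no base disk:
#'   \eqn{\frac{\pi}{6 b^2}\left[(1 + 4 b^2 r^2)^{3/2} - 1\right]} with
#'   \eqn{b = h/r^2} (\eqn{\mu m^2})
#' * `arc_length` — length of the parabolic section from base to base:
#'   \eqn{r\sqrt{1 + a^2 r^2} + \frac{1}{a}\,\mathrm{asinh}(a r)} with
#'   \eqn{a = 2h/r^2} (\eqn{\mu m})
#' * `parabolic_coefficient` — curvature \eqn{h/r^2} (\eqn{\mu m^{-1}})
#' * `cross_sectional_area` — area between the parabola and its base chord,
#'   \eqn{4 h r / 3} (\eqn{\mu m^2})
#'
#' @param data A data frame with numeric columns `height` and `radius` in
#'   micrometres (one row per SAM observation); any other columns (for
#'   example `line_id`, `replicate`) are carried through.
#' @return A tibble: the input columns plus `h_over_r`, `volume`,
#'   `surface_area`, `arc_length`, `parabolic_coefficient`,
#'   `cross_sectional_area`.
#' @examples
#' sam_estimators(data.frame(line_id = "l1", height = 100, radius = 100))
#' @seealso [fit_parabola()] for estimating height and radius from a contour.
#' @export
sam_estimators <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("height", "radius") %in% names(data))) {
    abort("`data` must have columns `height` and `radius` (micrometres).")
  }
  h <- data$height
  r <- data$radius
  if (any(!is.finite(h)) || any(h <= 0)) {
    abort("`height` must be finite and strictly positive.")
  }
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("`radius` must be finite and strictly positive.")
  }
  a <- 2 * h / r^2
  b <- h / r^2
  out <- as_tibble(data)
  out$h_over_r <- h / r
  out$volume <- pi * r^2 * h / 2
  # expm1/log1p form of (1 + 4 b^2 r^2)^{3/2} - 1: stays accurate in the
  # flat-dome limit b -> 0, where the naive difference cancels to zero
  out$surface_area <- pi / (6 * b^2) * expm1(1.5 * log1p(4 * b^2 * r^2))
  out$arc_length <- r * sqrt(1 + a^2 * r^2) + asinh(a * r) / a
  out$parabolic_coefficient <- h / r^2
  out$cross_sectional_area <- 4 * h * r / 3
  out
}

# Column names used when writing estimator tables for publication-style output.
estimator_display_names <- c(
  height = "Height", radius = "Radius", h_over_r = "H/R", volume = "Vol.",
  surface_area = "Surf. Area", arc_length = "Arc Len.",
  parabolic_coefficient = "Para. Coeff.", cross_sectional_area = "Area"
)

#' Fit a downward-opening parabola to each SAM contour
#'
#' Least-squares fit of \eqn{y = apex\_y + c\,(x - apex\_x)^2} with \eqn{c < 0}
#' to each open apex contour. The apex abscissa is initialised at the point of
#' maximal `y` and refined by one-dimensional minimisation of the residual sum
#' of squares; given `apex_x` the model is linear in \eqn{(x - apex\_x)^2} and
#' is fitted by ordinary least squares. The fitted radius is half the
#' contour's basal width (half the x-extent), a convention rather than a
#' biological claim; the fitted height is \eqn{|c| \times radius^2} and
#' `baseline_y` is the fitted parabola's value at the basal extremes.
#'
#' @param contours A data frame of contour points with columns `contour_id`,
#'   `x`, `y` (micrometres); points must be ordered within a contour. A single
#'   contour without a `contour_id` column is also accepted.
#' @return A tibble with one row per contour: `contour_id`, `height`,
#'   `radius`, `parabolic_coefficient`, `apex_x`, `baseline_y`, `r_squared`,
#'   and `ok` (`FALSE` when no downward-opening parabola fits, i.e. the
#'   least-squares curvature is non-negative; parameter columns are `NA` in
#'   that case rather than an error).
#' @examples
#' cont <- simulate_contour(height = 120, radius = 80, noise_sd = 0)
#' fit_parabola(cont)
#' @export
fit_parabola <- function(contours) {
  stopifnot(is.data.frame(contours))
  if (!all(c("x", "y") %in% names(contours))) {
    abort("`contours` must have columns `x` and `y`.")
  }
  if (!"contour_id" %in% names(contours)) contours$contour_id <- "contour"
  contours |>
    dplyr::group_by(.data$contour_id) |>
    dplyr::group_modify(~ fit_parabola_one(.x$x, .x$y)) |>
    dplyr::ungroup()
}

fit_parabola_one <- function(x, y) {
  if (length(x) < 5) abort("a contour needs at least 5 points to fit.")
  fail <- tibble(
    height = NA_real_, radius = NA_real_, parabolic_coefficient = NA_real_,
    apex_x = NA_real_, baseline_y = NA_real_, r_squared = NA_real_, ok = FALSE
  )
  rss_at <- function(a) {
    f <- lm.fit(cbind(1, (x - a)^2), y)
    sum(f$residuals^2)
  }
  a0 <- x[which.max(y)]
  span <- diff(range(x))
  opt <- optimize(rss_at, lower = a0 - span / 2, upper = a0 + span / 2,
                  tol = 1e-10)
  apex_x <- opt$minimum
  # optimize() can miss a boundary minimum narrowly; keep the better of the
  # initial guess and the refined value.
  if (rss_at(a0) < opt$objective) apex_x <- a0
  f <- lm.fit(cbind(1, (x - apex_x)^2), y)
  cc <- unname(f$coefficients[2])
  if (!is.finite(cc) || cc >= 0) return(fail)
  ss_res <- sum(f$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  radius <- span / 2
  height <- abs(cc) * radius^2
  tibble(
    height = height, radius = radius, parabolic_coefficient = abs(cc),
    apex_x = apex_x, baseline_y = unname(f$coefficients[1]) - height,
    r_squared = 1 - ss_res / ss_tot, ok = TRUE
  )
}
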