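# Comparative statistics used across the morphospace analyses: rank-based
# group shifts, Fisher-transformed Pearson correlations, the estimator x PC
# correlation matrix, and one-way clade ANOVA.

#' One-sided/two-sided Wilcoxon rank-sum test with a shift estimate
#'
#' Rank-sum test (midranks for ties; exact enumeration when
#' \eqn{n_1 n_2 \le 10000} and there are no ties, otherwise normal
#' approximation with continuity and tie correction) together with the
#' Hodges-Lehmann location-shift estimate — the median of all pairwise
#' differences \eqn{x_i - y_j}. The plain difference of group medians is also
#' reported, but the Hodges-Lehmann value is the primary "estimated shift
#' between medians".
#'
#' @param x,y Numeric samples for the two groups (each non-empty).
#' @param alternative `"two.sided"`, `"less"`, or `"greater"` (of `x`
#'   relative to `y`).
#' @return A one-row tibble: `shift_estimate` (Hodges-Lehmann),
#'   `median_difference`, `statistic` (Mann-Whitney W), `p_value`,
#'   `alternative`, `n1`, `n2`, `exact` (whether the exact distribution was
#'   used).
#' @examples
#' wilcoxon_shift(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_shift <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort("both groups must be non-empty.")
  exact <- length(x) * length(y) <= 10000 && !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  hl <- median(as.vector(outer(x, y, `-`)))
  tibble(
    shift_estimate = hl,
    median_difference = median(x) - median(y),
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    alternative = alternative,
    n1 = length(x), n2 = length(y),
    exact = exact
  )
}

#' Pearson correlation with Fisher-transformation significance
#'
#' Sample Pearson product-moment correlation; significance via the Fisher
#' z-transformation: \eqn{z = \mathrm{atanh}(r)\sqrt{n-3}} referred to the
#' standard normal (two-sided).
#'
#' @param x,y Numeric vectors, jointly non-missing n >= 4, neither constant.
#' @return A one-row tibble: `r`, `z`, `p_value`, `n`.
#' @export
pearson_fisher <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input; correlation undefined.")
  r <- cor(x, y)
  z <- atanh(r) * sqrt(n - 3)
  tibble(r = r, z = z, p_value = 2 * pnorm(-abs(z)), n = n)
}

#' Correlation matrix between parabolic estimators and shape PCs
#'
#' All pairwise Pearson correlations (with Fisher-transformation p-values)
#' between estimator phenotypes and PC scores, joined on `line_id`. No
#' multiple-testing correction is applied; cells with p above `alpha` are
#' flagged non-significant instead.
#'
#' @param estimators Data frame with `line_id` and numeric estimator columns.
#' @param pc_scores Data frame with `line_id` (or `shape_id`) and numeric PC
#'   score columns.
#' @param alpha Significance flag level (default 0.05).
#' @return A tibble with one row per (estimator, pc) pair: `estimator`, `pc`,
#'   `r`, `p_value`, `n`, `significant`.
#' @export
correlation_matrix <- function(estimators, pc_scores, alpha = 0.05) {
  stopifnot(is.data.frame(estimators), is.data.frame(pc_scores))
  if (!"line_id" %in% names(pc_scores) && "shape_id" %in% names(pc_scores)) {
    pc_scores <- dplyr::rename(pc_scores, line_id = "shape_id")
  }
  if (!"line_id" %in% names(estimators) || !"line_id" %in% names(pc_scores)) {
    abort("both tables need a `line_id` column to join on.")
  }
  est_cols <- setdiff(names(estimators), "line_id")
  est_cols <- est_cols[vapply(estimators[est_cols], is.numeric, TRUE)]
  pc_cols <- setdiff(names(pc_scores), "line_id")
  pc_cols <- pc_cols[vapply(pc_scores[pc_cols], is.numeric, TRUE)]
  # prefix value columns so shared names never collide in the join
  est <- estimators[c("line_id", est_cols)]
  names(est) <- c("line_id", paste0("est__", est_cols))
  pcs <- pc_scores[c("line_id", pc_cols)]
  names(pcs) <- c("line_id", paste0("pc__", pc_cols))
  joined <- dplyr::inner_join(est, pcs, by = "line_id")
  if (nrow(joined) < 4) abort("fewer than 4 shared lines between the tables.")
  grid <- tidyr::expand_grid(estimator = est_cols, pc = pc_cols)
  purrr::pmap_dfr(grid, function(estimator, pc) {
    res <- pearson_fisher(joined[[paste0("est__", estimator)]],
                          joined[[paste0("pc__", pc)]])
    tibble(estimator = estimator, pc = pc, r = res$r, p_value = res$p_value,
           n = res$n, significant = res$p_value <= alpha)
  })
}

#' One-way ANOVA across groups (e.g. evolutionary clades)
#'
#' Fixed-effects one-way analysis of variance of a trait (typically the
#' parabolic coefficient) across group labels. An optional second factor may
#' be supplied for a two-way additive model.
#'
#' @param data Data frame with a numeric `value` column and a `group` column;
#'   optionally `factor2` for a two-way additive model.
#' @param value,group,factor2 Column names (strings) to use instead of the
#'   defaults.
#' @return A one-row tibble per model term: `term`, `df`, `statistic` (F),
#'   `p_value`, plus residual df in `df_residual`.
#' @export
clade_anova <- function(data, value = "value", group = "group", factor2 = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c(value, group) %in% names(data))) {
    abort(sprintf("`data` must have columns `%s` and `%s`.", value, group))
  }
  g <- factor(data[[group]])
  v <- data[[value]]
  keep <- !is.na(v) & !is.na(g)
  g <- droplevels(g[keep]); v <- v[keep]
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    abort("need >= 2 groups with >= 2 values each.")
  }
  if (var(v) == 0) abort("trait is constant; F is undefined.")
  d <- data.frame(value = v, group = g)
  form <- value ~ group
  if (!is.null(factor2)) {
    d$factor2 <- factor(data[[factor2]][keep])
    form <- value ~ group + factor2
  }
  a <- anova(lm(form, data = d))
  terms <- rownames(a)
  resid_row <- which(terms == "Residuals")
  tibble(
    term = terms[-resid_row],
    df = a$Df[-resid_row],
    statistic = a$`F value`[-resid_row],
    p_value = a$`Pr(>F)`[-resid_row],
    df_residual = a$Df[resid_row]
  )
}
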