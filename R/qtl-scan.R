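# Single-QTL genome scan by Haley-Knott regression on expected genotype
# dosages, with permutation-based genome-wide significance thresholds and
# Bayes credible intervals for QTL location.

# LOD ceiling: positions where the QTL model is a numerically perfect fit
# (RSS1 < 1e-12 * RSS0) are capped at (n/2) * 12 = (n/2) * log10(1e12).
.lod_rss_ratio_cap <- 1e-12

# LOD scores for one or more phenotype vectors against a centered dosage
# matrix. With a single regressor, LOD = -(n/2) log10(1 - r^2) where r is the
# phenotype-dosage correlation; columns with zero dosage variance score 0.
lod_from_dosage <- function(y_mat, dosage_c, dosage_ss) {
  n <- nrow(y_mat)
  y_c <- sweep(y_mat, 2, colMeans(y_mat))
  y_ss <- colSums(y_c^2)
  num <- crossprod(dosage_c, y_c)               # npos x nperm
  r2 <- sweep(num^2, 1, pmax(dosage_ss, .Machine$double.eps), `/`)
  r2 <- sweep(r2, 2, y_ss, `/`)
  r2[dosage_ss == 0, ] <- 0
  r2 <- pmin(r2, 1 - .lod_rss_ratio_cap)
  -(n / 2) * log10(1 - r2)
}

#' Single-QTL genome scan (Haley-Knott regression)
#'
#' At every marker and pseudomarker, regresses the phenotype on the expected
#' donor-allele dosage from [genotype_probabilities()] and reports
#' \eqn{LOD = (n/2)\,\log_{10}(RSS_0 / RSS_1)}, comparing against the
#' intercept-only model. Individuals with missing phenotype are dropped
#' listwise.
#'
#' @param cross A `sam_cross` object.
#' @param trait Name of a phenotype column in `cross$pheno`.
#' @param step Pseudomarker spacing in cM (default 1).
#' @param error_prob Genotyping error rate for the HMM (default 0.002).
#' @param genoprob Optional precomputed result of [genotype_probabilities()]
#'   (reused across traits and permutations).
#' @return An object of class `sam_scan`: a tibble with columns `chr`, `pos`,
#'   `marker`, `lod`, and attributes `trait`, `n` (individuals used), and
#'   (after [perm_threshold()] is supplied) `threshold`.
#' @export
scan_qtl <- function(cross, trait, step = 1, error_prob = 0.002,
                     genoprob = NULL) {
  stopifnot(inherits(cross, "sam_cross"))
  if (!trait %in% names(cross$pheno)) {
    abort(sprintf("trait `%s` not found in the phenotype table.", trait))
  }
  gp <- genoprob %||% genotype_probabilities(cross, step, error_prob)
  y <- cross$pheno[[trait]]
  keep <- !is.na(y)
  if (sum(keep) < 10) abort("need at least 10 non-missing phenotypes to scan.")
  y <- y[keep]
  d <- gp$dosage[keep, , drop = FALSE]
  if (sd(y) == 0) {
    warn("phenotype is constant; LOD is identically zero.")
    lod <- rep(0, ncol(d))
  } else {
    d_c <- sweep(d, 2, colMeans(d))
    lod <- as.vector(lod_from_dosage(matrix(y, ncol = 1), d_c, colSums(d_c^2)))
  }
  out <- dplyr::bind_cols(gp$positions, tibble(lod = lod))
  structure(out, class = c("sam_scan", class(out)),
            trait = trait, n = sum(keep), step = step)
}

#' Genome-wide LOD significance threshold by phenotype permutation
#'
#' Shuffles the phenotype against the genotypes `n_perm` times, records each
#' genome-wide maximum LOD, and returns the empirical `1 - alpha` quantile
#' (type-7 rule) as the genome-wide significance threshold.
#'
#' @inheritParams scan_qtl
#' @param n_perm Number of permutations (>= 100; the study-scale choice is
#'   10000, smaller counts are used for fast calibration runs).
#' @param alpha Genome-wide type-I error rate(s); default 0.05.
#' @param seed Integer seed for the permutation stream (required for
#'   reproducibility).
#' @return Numeric threshold(s), one per `alpha`, with the permuted maxima in
#'   attribute `maxlods` and `n_perm`/`seed` attributes.
#' @export
perm_threshold <- function(cross, trait, n_perm = 1000, alpha = 0.05,
                           seed = NULL, step = 1, error_prob = 0.002,
                           genoprob = NULL) {
  stopifnot(inherits(cross, "sam_cross"), n_perm >= 100)
  if (any(alpha <= 0 | alpha > 1)) abort("`alpha` must be in (0, 1].")
  if (!is.null(seed)) set.seed(seed)
  gp <- genoprob %||% genotype_probabilities(cross, step, error_prob)
  y <- cross$pheno[[trait]]
  keep <- !is.na(y)
  y <- y[keep]
  d <- gp$dosage[keep, , drop = FALSE]
  d_c <- sweep(d, 2, colMeans(d))
  d_ss <- colSums(d_c^2)
  # permute in blocks to bound memory at ~ npos x 250 doubles
  block <- 250L
  maxlods <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    y_perm <- vapply(seq_len(nb), function(i) sample(y), numeric(length(y)))
    lods <- lod_from_dosage(y_perm, d_c, d_ss)
    maxlods[done + seq_len(nb)] <- apply(lods, 2, max)
    done <- done + nb
  }
  thr <- quantile(maxlods, 1 - alpha, type = 7, names = FALSE)
  structure(setNames(thr, paste0("alpha_", alpha)),
            maxlods = maxlods, n_perm = n_perm, seed = seed)
}

#' Bayes credible interval for QTL location
#'
#' Treats \eqn{10^{LOD}} (normalised over the chromosome's scan grid) as a
#' posterior for QTL location, accumulates grid positions in decreasing
#' posterior order until the target coverage is reached, and expands the
#' resulting span outward to the nearest flanking genotyped markers.
#'
#' @param scan A `sam_scan` object.
#' @param chr Chromosome to summarise.
#' @param prob Coverage probability (default 0.95).
#' @return A tibble with columns `chr`, `lower`, `peak`, `upper` (cM),
#'   `prob`.
#' @export
bayes_interval <- function(scan, chr, prob = 0.95) {
  stopifnot(inherits(scan, "sam_scan"))
  d <- scan[scan$chr == chr, ]
  if (nrow(d) == 0) abort(sprintf("scan does not cover chromosome %s.", chr))
  if (diff(range(d$lod)) < 1e-12) {
    warn("flat LOD profile; interval spans the whole chromosome.")
    return(tibble(chr = chr, lower = min(d$pos), peak = d$pos[which.max(d$lod)],
                  upper = max(d$pos), prob = prob))
  }
  dens <- 10^(d$lod - max(d$lod))
  # trapezoid weights: the scan grid is uneven where markers interleave with
  # pseudomarkers, so each position carries its surrounding interval width
  width <- diff(d$pos)
  delta <- (c(0, width) + c(width, 0)) / 2
  if (all(delta == 0)) delta <- rep(1, length(delta))
  w <- dens * delta
  w <- w / sum(w)
  ord <- order(dens, decreasing = TRUE)  # highest-posterior-density set
  k <- which(cumsum(w[ord]) >= prob)[1]
  sel <- d$pos[ord[seq_len(k)]]
  lower <- min(sel); upper <- max(sel)
  mk_pos <- d$pos[!is.na(d$marker)]
  left <- mk_pos[mk_pos <= lower]
  right <- mk_pos[mk_pos >= upper]
  if (length(left)) lower <- max(left)
  if (length(right)) upper <- min(right)
  tibble(chr = chr, lower = lower, peak = d$pos[which.max(d$lod)],
         upper = upper, prob = prob)
}

#' @export
tidy.sam_scan <- function(x, ...) as_tibble(x)

#' @rdname scan_qtl
#' @param x,object A `sam_scan` object.
#' @param ... Unused.
#' @export
glance.sam_scan <- function(x, ...) {
  peak <- x[which.max(x$lod), ]
  tibble(trait = attr(x, "trait"), n = attr(x, "n"),
         max_lod = peak$lod, peak_chr = peak$chr, peak_pos = peak$pos)
}

#' @export
autoplot.sam_scan <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$pos, .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "map position (cM)", y = "LOD",
                  title = sprintf("Single-QTL scan: %s", attr(object, "trait")))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Summarise replicated phenotypes as BLUP + coefficient
#'
#' Fits, per trait, the mixed model \eqn{y_{ij} = \mu + rep_j + u_i +
#' \epsilon_{ij}} by REML, with replicate as a fixed effect (sum-to-zero
#' contrasts, so \eqn{\mu} is the replicate-averaged intercept) and line as a
#' random effect \eqn{u_i \sim N(0, \sigma_u^2)}. Each line's summarised
#' value is \eqn{\mu + \hat u_i} — the best linear unbiased predictor of the
#' line effect plus the fixed intercept, which shrinks noisy line means
#' toward the population mean.
#'
#' @param data Data frame of raw replicated measures with columns `line_id`,
#'   `replicate`, and the trait column.
#' @param trait Name of the trait column to summarise.
#' @return A tibble with columns `line_id`, `trait`, `blup_plus_coefficient`,
#'   `n_replicates`. If no line has two or more replicates, plain line means
#'   are returned with a warning (shrinkage is undefined).
#' @export
blup_summarize <- function(data, trait) {
  stopifnot(is.data.frame(data))
  need <- c("line_id", "replicate", trait)
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.", paste0("`", need, "`", collapse = ", ")))
  }
  d <- data.frame(
    line_id = factor(data$line_id),
    replicate = factor(data$replicate),
    y = data[[trait]]
  )
  d <- d[!is.na(d$y), ]
  n_rep <- table(d$line_id)
  if (max(n_rep) < 2) {
    warn("no line has >= 2 replicates; returning line means (no shrinkage).")
    means <- tapply(d$y, d$line_id, mean)
    return(tibble(line_id = names(means), trait = trait,
                  blup_plus_coefficient = as.numeric(means),
                  n_replicates = as.integer(n_rep[names(means)])))
  }
  fixed <- if (nlevels(d$replicate) > 1) y ~ replicate else y ~ 1
  fit <- nlme::lme(fixed, random = ~ 1 | line_id, data = d,
                   method = "REML",
                   contrasts = list(replicate = "contr.sum")[nlevels(d$replicate) > 1])
  mu <- as.numeric(nlme::fixef(fit)[1])
  u <- nlme::ranef(fit)
  tibble(line_id = rownames(u), trait = trait,
         blup_plus_coefficient = mu + u[[1]],
         n_replicates = as.integer(n_rep[rownames(u)]))
}
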