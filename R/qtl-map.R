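# Genetic-map utilities and the BC2S3 genotype hidden Markov model.
#
# Genotypes are coded as the count of donor (teosinte, "B") alleles:
# 0 = AA (recurrent maize parent homozygote), 1 = AB, 2 = BB, NA = missing.

#' Kosambi map function
#'
#' Converts between recombination fraction and centimorgan map distance under
#' the Kosambi mapping function: \eqn{d = 25\,\ln((1+2r)/(1-2r))} and its
#' inverse \eqn{r = \tanh(d/50)/2}.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return `kosambi_cm()` returns distances in cM; `kosambi_rf()` returns
#'   recombination fractions.
#' @examples
#' kosambi_cm(0.25)        # 25 * log(3)
#' kosambi_rf(kosambi_cm(0.1))
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0 | r >= 0.5)) abort("recombination fraction must be in [0, 0.5).")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_rf <- function(d) {
  if (any(d < 0)) abort("map distance must be non-negative.")
  0.5 * tanh(d / 50)
}

# ---- BC2S3 pedigree genetics -------------------------------------------
#
# The cross: F1 (maize W22 x teosinte), two backcrosses to the maize parent,
# three generations of selfing. Single-locus genotype priors follow from the
# pedigree: after BC2, P(AB) = 1/4; a selfed het stays het w.p. 1/2 per
# generation and otherwise fixes to AA or BB equally, so after 3 selfings
# P(AB) = 1/4 * 1/8 = 2/64, P(BB) = 1/4 * 7/16 = 7/64, P(AA) = 55/64.

bc2s3_priors <- c(AA = 55, AB = 2, BB = 7) / 64

# Two-locus haplotypes 1..4 = (A,A), (A,B), (B,A), (B,B); an ordered diplotype
# (h1, h2) is state (h1 - 1) * 4 + h2. Meiosis with recombination fraction r:
# each gamete locus comes from one of the two parental haplotypes; the pair of
# source haplotypes is (same, same) w.p. (1-r)/2 each and mixed w.p. r/2 each.
meiosis_matrix <- function(r) {
  al1 <- c(0, 0, 1, 1)  # locus-1 allele of each haplotype (0 = A, 1 = B)
  al2 <- c(0, 1, 0, 1)
  m <- matrix(0, 16, 4)
  for (h1 in 1:4) for (h2 in 1:4) {
    d <- (h1 - 1) * 4 + h2
    for (src1 in 1:2) for (src2 in 1:2) {
      p <- if (src1 == src2) (1 - r) / 2 else r / 2
      a1 <- if (src1 == 1) al1[h1] else al1[h2]
      a2 <- if (src2 == 1) al2[h1] else al2[h2]
      g <- a1 * 2 + a2 + 1  # gamete haplotype index
      m[d, g] <- m[d, g] + p
    }
  }
  m
}

# Exact two-locus joint genotype distribution for BC2S3 at recombination
# fraction r, obtained by propagating the ordered-diplotype distribution
# through the pedigree: F1 -> 2 backcrosses to the AA parent -> 3 selfings.
bc2s3_joint <- function(r) {
  m <- meiosis_matrix(r)
  p <- numeric(16)
  p[(1 - 1) * 4 + 4] <- 1  # F1 = (A,A)/(B,B)
  for (gen in 1:2) {       # backcross: gamete paired with the (A,A) haplotype
    g <- as.vector(crossprod(m, p))
    p <- numeric(16)
    p[(seq_len(4) - 1) * 4 + 1] <- g
  }
  for (gen in 1:3) {       # selfing: two independent gametes from one parent
    nxt <- numeric(16)
    for (d in which(p > 0)) {
      nxt <- nxt + p[d] * as.vector(outer(m[d, ], m[d, ]))
    }
    # outer(g1, g2) vectorizes with g1 varying fastest: state (h2-1)*4+h1 —
    # symmetric under exchange of gametes, so the ordering is immaterial.
    p <- nxt
  }
  al1 <- c(0, 0, 1, 1); al2 <- c(0, 1, 0, 1)
  joint <- matrix(0, 3, 3, dimnames = list(c("AA", "AB", "BB"), c("AA", "AB", "BB")))
  for (h1 in 1:4) for (h2 in 1:4) {
    d <- (h1 - 1) * 4 + h2
    g1 <- al1[h1] + al1[h2] + 1
    g2 <- al2[h1] + al2[h2] + 1
    joint[g1, g2] <- joint[g1, g2] + p[d]
  }
  joint
}

# Conditional transition matrix P(genotype at right locus | left locus),
# memoised on the rounded recombination fraction.
.bc2s3_cache <- new.env(parent = emptyenv())
bc2s3_transition <- function(r) {
  key <- sprintf("%.12f", r)
  hit <- .bc2s3_cache[[key]]
  if (!is.null(hit)) return(hit)
  j <- bc2s3_joint(r)
  t_mat <- j / rowSums(j)
  .bc2s3_cache[[key]] <- t_mat
  t_mat
}

# ---- genotype probabilities by forward-backward ------------------------

# Position grid for one chromosome: markers plus pseudomarkers every `step`
# cM spanning the marker range.
position_grid <- function(marker_pos, step) {
  grid <- seq(min(marker_pos), max(marker_pos), by = step)
  pos <- sort(unique(round(c(marker_pos, grid), 9)))
  marker_idx <- match(round(marker_pos, 9), pos)
  list(pos = pos, marker_idx = marker_idx)
}

#' Expected genotype dosage along the genome for a BC2S3 cross
#'
#' Hidden Markov model over genotype states \{AA, AB, BB\} with the BC2S3
#' stationary priors (55/64, 2/64, 7/64), exact pedigree-derived transition
#' probabilities parameterised by the Kosambi recombination fraction of each
#' cM gap, and an emission model allowing a small genotyping-error rate.
#' Runs forward-backward per chromosome (vectorised over individuals) at all
#' markers and at pseudomarkers every `step` cM, and returns the expected
#' donor-allele dosage scaled to `[0, 1]` (i.e. E[#B alleles]/2).
#'
#' @param cross A `sam_cross` object (see [sam_cross()]).
#' @param step Pseudomarker spacing in cM (default 1). `step = Inf` restricts
#'   the grid to the genotyped markers.
#' @param error_prob Genotyping error rate \eqn{\epsilon} (default 0.002); an
#'   observed genotype is emitted with probability \eqn{1-\epsilon}, each
#'   other genotype with \eqn{\epsilon/2}.
#' @return A list with `positions` (tibble `chr`, `pos`, `marker` — marker
#'   name or `NA` for pseudomarkers) and `dosage` (matrix, individuals x
#'   positions, expected dosage/2).
#' @export
genotype_probabilities <- function(cross, step = 1, error_prob = 0.002) {
  stopifnot(inherits(cross, "sam_cross"))
  map <- cross$map
  n <- nrow(cross$geno)
  pos_list <- list(); dos_list <- list()
  for (ch in unique(map$chr)) {
    mk <- map[map$chr == ch, ]
    if (nrow(mk) == 0) { warn(sprintf("chromosome %s has no markers; skipped", ch)); next }
    g <- if (is.finite(step)) position_grid(mk$pos, step) else
      list(pos = mk$pos, marker_idx = seq_along(mk$pos))
    np <- length(g$pos)
    obs <- matrix(NA_integer_, n, np)
    obs[, g$marker_idx] <- cross$geno[, map$chr == ch, drop = FALSE]
    post <- fb_posteriors(obs, g$pos, error_prob)
    marker <- rep(NA_character_, np)
    marker[g$marker_idx] <- mk$marker
    pos_list[[length(pos_list) + 1]] <- tibble(chr = ch, pos = g$pos, marker = marker)
    dos_list[[length(dos_list) + 1]] <- post
  }
  positions <- dplyr::bind_rows(pos_list)
  dosage <- do.call(cbind, dos_list)
  rownames(dosage) <- rownames(cross$geno)
  list(positions = positions, dosage = dosage)
}

# Forward-backward over one chromosome for all individuals at once.
# obs: n x np matrix of observed genotypes (0/1/2/NA); pos: np grid positions.
# Returns n x np matrix of expected dosage / 2.
fb_posteriors <- function(obs, pos, error_prob) {
  n <- nrow(obs); np <- length(pos)
  trans <- lapply(seq_len(max(np - 1, 0)), function(j) {
    bc2s3_transition(kosambi_rf(pos[j + 1] - pos[j]))
  })
  emit <- function(j) {
    e <- matrix(1, n, 3)
    o <- obs[, j]
    seen <- which(!is.na(o))
    if (length(seen)) {
      e[seen, ] <- error_prob / 2
      e[cbind(seen, o[seen] + 1)] <- 1 - error_prob
    }
    e
  }
  alpha <- array(0, c(n, 3, np))
  a <- matrix(bc2s3_priors, n, 3, byrow = TRUE) * emit(1)
  a <- a / rowSums(a)
  alpha[, , 1] <- a
  for (j in seq_len(np - 1)) {
    a <- (a %*% trans[[j]]) * emit(j + 1)
    a <- a / rowSums(a)
    alpha[, , j + 1] <- a
  }
  post <- matrix(0, n, np)
  b <- matrix(1, n, 3)
  g <- matrix(alpha[, , np], n, 3)
  post[, np] <- (g[, 2] + 2 * g[, 3]) / rowSums(g) / 2
  for (j in rev(seq_len(np - 1))) {
    b <- (b * emit(j + 1)) %*% t(trans[[j]])
    b <- b / rowSums(b)
    g <- matrix(alpha[, , j], n, 3) * b
    post[, j] <- (g[, 2] + 2 * g[, 3]) / rowSums(g) / 2
  }
  post
}

# ---- cross container ----------------------------------------------------

#' Construct a BC2S3 cross population object
#'
#' Bundles a genetic map, a genotype matrix, and per-line phenotypes into the
#' container the scan functions consume.
#'
#' @param map Tibble with columns `marker`, `chr`, `pos` (cM, Kosambi;
#'   non-decreasing within chromosome, unique marker names).
#' @param geno Integer matrix, individuals x markers: 0 = AA (maize
#'   homozygote), 1 = AB, 2 = BB (teosinte homozygote), `NA` missing. Columns
#'   must match `map$marker`.
#' @param pheno Data frame of per-line phenotypes; must contain `line_id`,
#'   one row per individual, rows aligned with `geno`.
#' @param design Breeding design record (default `list(n_backcross = 2,
#'   n_self = 3)`, the BC2S3 this package's genotype model is derived for).
#' @return An object of class `sam_cross`.
#' @export
sam_cross <- function(map, geno, pheno,
                      design = list(n_backcross = 2, n_self = 3)) {
  map <- as_tibble(map)
  stopifnot(all(c("marker", "chr", "pos") %in% names(map)))
  if (anyDuplicated(map$marker)) abort("marker names must be unique.")
  for (ch in unique(map$chr)) {
    if (is.unsorted(map$pos[map$chr == ch])) {
      abort(sprintf("marker positions on chromosome %s are not non-decreasing.", ch))
    }
  }
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map)) abort("genotype columns must match the map.")
  colnames(geno) <- map$marker
  pheno <- as_tibble(pheno)
  if (!"line_id" %in% names(pheno)) abort("`pheno` must have a `line_id` column.")
  if (nrow(pheno) != nrow(geno)) abort("`pheno` rows must match genotype rows.")
  bad <- setdiff(unique(as.vector(geno)), c(0L, 1L, 2L, NA))
  if (length(bad)) abort("genotypes must be coded 0/1/2/NA.")
  rownames(geno) <- pheno$line_id
  structure(list(map = map, geno = geno, pheno = pheno, design = design),
            class = "sam_cross")
}

#' @export
print.sam_cross <- function(x, ...) {
  cat("BC2S3 cross population\n")
  cat(sprintf("  %d individuals, %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  cat("  phenotypes:", paste(setdiff(names(x$pheno), "line_id"), collapse = ", "), "\n")
  invisible(x)
}
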