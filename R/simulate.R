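# Synthetic study generator: BC2S3 crosses with additive QTL on SAM height
# and radius, replicated noisy measures, near-parabolic open contours with
# controllable asymmetry and peakedness, and a diverse-taxa contour panel.
# The generator and the scan HMM deliberately share one genetic model:
# crossovers are drawn interval-wise from inverse-Kosambi recombination
# fractions with no interference.

#' Simulation configuration for a synthetic SAM study
#'
#' Collects every tunable of the synthetic study in one validated list. The
#' defaults describe the standard synthetic population used throughout the
#' package's tests and examples: 400 BC2S3 lines genotyped at 5 chromosomes
#' x 50 markers over 100 cM each, two replicate measurements per line, SAMs
#' around 100 um tall and 80 um in basal radius with 5 um residual spread —
#' the scale of a maize vegetative meristem study.
#'
#' @param n_lines Number of BC2S3 lines (default 400).
#' @param n_chromosomes,markers_per_chromosome,chromosome_length Genome
#'   layout: chromosomes (default 5), evenly spaced markers per chromosome
#'   (default 50), chromosome length in cM (default 100).
#' @param qtl Data frame of QTL with columns `chr`, `pos` (cM),
#'   `height_effect`, `radius_effect` (um added per donor allele). Default:
#'   none.
#' @param base_height,base_radius Population baseline SAM height and radius
#'   in um (defaults 100 and 80).
#' @param residual_sd Named vector, residual SD per trait in um (default
#'   `c(height = 5, radius = 5)`).
#' @param n_replicates Replicate measurements per line (default 2).
#' @param replicate_offsets Systematic offset per replicate block in um
#'   (default `seq(0, by = 2, length.out = n_replicates)`), the fixed effect
#'   [blup_summarize()] estimates.
#' @param contour_points Points per raw simulated contour (default 800).
#' @param contour_noise_sd Isotropic Gaussian displacement SD per contour
#'   point, um (default 1).
#' @param asymmetry_shear Dimensionless left/right shear of the contour
#'   (default 0; positive leans the apex right).
#' @param peakedness_exponent Profile exponent p in
#'   \eqn{y = h(1 - (|x|/r)^p)}; 2 is a parabola, larger is flatter-topped
#'   ("rounded"), smaller more "peaked" (default 2).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 400, n_chromosomes = 5,
                       markers_per_chromosome = 50, chromosome_length = 100,
                       qtl = NULL, base_height = 100, base_radius = 80,
                       residual_sd = c(height = 5, radius = 5),
                       n_replicates = 2, replicate_offsets = NULL,
                       contour_points = 800, contour_noise_sd = 1,
                       asymmetry_shear = 0, peakedness_exponent = 2) {
  qtl <- if (is.null(qtl)) {
    tibble(chr = integer(), pos = numeric(),
           height_effect = numeric(), radius_effect = numeric())
  } else as_tibble(qtl)
  stopifnot(n_lines >= 2, n_chromosomes >= 1, markers_per_chromosome >= 2,
            chromosome_length > 0, peakedness_exponent > 0,
            all(is.finite(c(qtl$height_effect, qtl$radius_effect))))
  if (nrow(qtl) && any(qtl$pos < 0 | qtl$pos > chromosome_length)) {
    abort("QTL position outside the map.")
  }
  replicate_offsets <- replicate_offsets %||%
    seq(0, by = 2, length.out = n_replicates)
  stopifnot(length(replicate_offsets) == n_replicates)
  structure(
    list(n_lines = n_lines, n_chromosomes = n_chromosomes,
         markers_per_chromosome = markers_per_chromosome,
         chromosome_length = chromosome_length, qtl = qtl,
         base_height = base_height, base_radius = base_radius,
         residual_sd = residual_sd, n_replicates = n_replicates,
         replicate_offsets = replicate_offsets,
         contour_points = contour_points,
         contour_noise_sd = contour_noise_sd,
         asymmetry_shear = asymmetry_shear,
         peakedness_exponent = peakedness_exponent),
    class = "sim_config"
  )
}

# One round of meioses for all individuals at once. h1, h2: n x nloci 0/1
# haplotype matrices of the parents; rf: recombination fractions between
# adjacent loci (length nloci - 1). Returns an n x nloci gamete matrix.
meiosis_gametes <- function(h1, h2, rf) {
  n <- nrow(h1); nl <- ncol(h1)
  switches <- matrix(rbinom(n * (nl - 1), 1, rep(rf, each = n)), n, nl - 1)
  cum <- if (ncol(switches) > 1) t(apply(switches, 1, cumsum)) else switches
  src <- (matrix(rbinom(n, 1, 0.5), n, nl) + cbind(0, cum)) %% 2
  ifelse(src == 0, h1, h2)
}

#' Simulate a BC2S3 cross with additive QTL on SAM height and radius
#'
#' Simulates gametes through F1, two backcrosses to the recurrent (maize)
#' parent, and three selfing generations; crossovers are interval-wise
#' Bernoulli draws from the inverse-Kosambi recombination fraction of each
#' marker gap, intervals independent. QTL positions are simulated as extra
#' loci (not reported as markers); line genetic values are
#' \eqn{base + \sum effect \times (donor\ allele\ count)}, and replicated raw
#' measures add the replicate offset and iid Gaussian residual noise.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed (mandatory: every synthetic dataset is
#'   reproducible).
#' @return A `sam_cross` object whose `pheno` holds per-line mean `height`
#'   and `radius` across replicates, with extra elements: `measures` (raw
#'   replicated tibble `line_id`, `replicate`, `height`, `radius`) and
#'   `truth` (per-line genetic values and QTL dosages).
#' @export
simulate_cross <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  n <- config$n_lines
  # per-chromosome locus positions: markers plus any QTL
  chrs <- seq_len(config$n_chromosomes)
  marker_pos <- seq(0, config$chromosome_length,
                    length.out = config$markers_per_chromosome)
  geno_cols <- list(); map_rows <- list()
  qtl_dosage <- matrix(0, n, nrow(config$qtl))
  for (ch in chrs) {
    qp <- config$qtl$pos[config$qtl$chr == ch]
    loci <- sort(unique(c(marker_pos, qp)))
    rf <- kosambi_rf(diff(loci))
    nl <- length(loci)
    # F1 diplotype: one maize (0) and one teosinte (1) haplotype
    h1 <- matrix(0L, n, nl); h2 <- matrix(1L, n, nl)
    for (bc in 1:2) {       # backcross to the maize parent
      g <- meiosis_gametes(h1, h2, rf)
      h1 <- g; h2 <- matrix(0L, n, nl)
    }
    for (s in 1:3) {        # selfing: two independent gametes per parent
      g1 <- meiosis_gametes(h1, h2, rf)
      g2 <- meiosis_gametes(h1, h2, rf)
      h1 <- g1; h2 <- g2
    }
    geno <- h1 + h2
    is_marker <- loci %in% marker_pos
    geno_cols[[ch]] <- geno[, is_marker, drop = FALSE]
    map_rows[[ch]] <- tibble(
      marker = sprintf("c%d_m%02d", ch, seq_len(sum(is_marker))),
      chr = ch, pos = loci[is_marker]
    )
    which_q <- which(config$qtl$chr == ch)
    if (length(which_q)) {
      qtl_dosage[, which_q] <- geno[, match(config$qtl$pos[which_q], loci),
                                    drop = FALSE]
    }
  }
  geno <- do.call(cbind, geno_cols)
  map <- dplyr::bind_rows(map_rows)
  line_id <- sprintf("L%04d", seq_len(n))
  g_height <- config$base_height +
    as.vector(qtl_dosage %*% (config$qtl$height_effect %||% numeric(0)))
  g_radius <- config$base_radius +
    as.vector(qtl_dosage %*% (config$qtl$radius_effect %||% numeric(0)))
  if (!length(g_height)) g_height <- rep(config$base_height, n)
  if (!length(g_radius)) g_radius <- rep(config$base_radius, n)
  reps <- seq_len(config$n_replicates)
  measures <- tidyr::expand_grid(line_id = line_id, replicate = reps) |>
    dplyr::mutate(
      height = rep(g_height, each = length(reps)) +
        config$replicate_offsets[.data$replicate] +
        rnorm(dplyr::n(), 0, config$residual_sd[["height"]]),
      radius = rep(g_radius, each = length(reps)) +
        config$replicate_offsets[.data$replicate] +
        rnorm(dplyr::n(), 0, config$residual_sd[["radius"]])
    )
  pheno <- measures |>
    dplyr::group_by(.data$line_id) |>
    dplyr::summarise(height = mean(.data$height), radius = mean(.data$radius))
  cross <- sam_cross(map, geno, pheno)
  cross$measures <- measures
  cross$truth <- tibble(line_id = line_id, g_height = g_height,
                        g_radius = g_radius)
  if (nrow(config$qtl)) {
    colnames(qtl_dosage) <- sprintf("qtl%d", seq_len(ncol(qtl_dosage)))
    cross$truth <- dplyr::bind_cols(cross$truth, as_tibble(qtl_dosage))
  }
  cross$seed <- seed
  cross
}

#' Simulate one noisy near-parabolic SAM contour
#'
#' Samples the profile \eqn{y = h\,(1 - (|x|/r)^p)} on `n_points` abscissae
#' over \eqn{[-r, r]}, applies the shear \eqn{x \mapsto x + s\,(y/h)\,r}
#' (leaning the apex without moving the base), and adds iid Gaussian
#' displacement noise to both coordinates. The result is an ordered open
#' base-apex-base contour, y-up, in micrometres.
#'
#' @param height,radius Paraboloid height and basal radius in um.
#' @param n_points Points along the contour (default 800).
#' @param noise_sd Gaussian displacement SD in um (default 0).
#' @param shear Dimensionless lean (default 0).
#' @param peakedness Profile exponent p; 2 = parabola (default 2).
#' @param contour_id Identifier for the output tibble.
#' @param orientation Orientation label recorded on the contour (default
#'   `"p0_left"`).
#' @return A contour tibble: `contour_id`, `point_index`, `x`, `y`,
#'   `orientation`.
#' @export
simulate_contour <- function(height, radius, n_points = 800, noise_sd = 0,
                             shear = 0, peakedness = 2,
                             contour_id = "contour", orientation = "p0_left") {
  stopifnot(height > 0, radius > 0, n_points >= 5)
  x0 <- seq(-radius, radius, length.out = n_points)
  y <- height * (1 - (abs(x0) / radius)^peakedness)
  x <- x0 + shear * (y / height) * radius
  if (noise_sd > 0) {
    x <- x + rnorm(n_points, 0, noise_sd)
    y <- y + rnorm(n_points, 0, noise_sd)
  }
  tibble(contour_id = contour_id, point_index = seq_len(n_points),
         x = x, y = y, orientation = orientation)
}

#' Simulate a diverse-taxa panel of apex contours
#'
#' Draws one parabolic coefficient per taxon uniformly from `coeff_range`,
#' holds apex height fixed, and generates a noisy parabolic contour for each
#' — the synthetic counterpart of a survey of shoot apices across distantly
#' related plant lineages, used to exercise the parabolic-fit path.
#'
#' @param n_taxa Number of taxa (default 73).
#' @param coeff_range Range of parabolic coefficients in 1/um (default
#'   `c(0.005, 0.05)`).
#' @param height Fixed apex height in um (default 100).
#' @param noise_sd Contour displacement noise in um (default 2).
#' @param n_points Points per contour (default 400).
#' @param seed Integer seed (mandatory).
#' @return A list with `taxa` (tibble `taxon`, `clade`, `coefficient`,
#'   `height`, `radius`) and `contours` (long contour tibble with
#'   `contour_id` = taxon).
#' @export
simulate_taxa_panel <- function(n_taxa = 73, coeff_range = c(0.005, 0.05),
                                height = 100, noise_sd = 2, n_points = 400,
                                seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(length(coeff_range) == 2, all(coeff_range > 0),
            coeff_range[2] > coeff_range[1])
  set.seed(seed)
  coeff <- runif(n_taxa, coeff_range[1], coeff_range[2])
  radius <- sqrt(height / coeff)
  clades <- paste0("clade_", rep_len(1:4, n_taxa))
  taxa <- tibble(taxon = sprintf("taxon_%03d", seq_len(n_taxa)),
                 clade = sample(clades), coefficient = coeff,
                 height = height, radius = radius)
  contours <- purrr::pmap_dfr(taxa[c("taxon", "height", "radius")],
    function(taxon, height, radius) {
      simulate_contour(height, radius, n_points = n_points,
                       noise_sd = noise_sd, contour_id = taxon)
    })
  list(taxa = taxa, contours = contours)
}

#' Simulate the full synthetic SAM study
#'
#' One call producing every input the pipeline consumes: a BC2S3 cross with
#' QTL on height and radius, replicated measures, and one contour per
#' (line, replicate) generated from that observation's height and radius with
#' line-level lean and peakedness variation.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed (mandatory).
#' @param shear_sd SD of the line-level lean (default `config$asymmetry_shear`
#'   treated as a population SD; lines draw `shear ~ N(0, shear_sd)`).
#' @param contours_per_line Contours generated per line (default 1, from the
#'   replicate-1 measure; the study traced one median section per line).
#' @return A list with `cross`, `measures`, and `contours`.
#' @export
simulate_sam_study <- function(config = sim_config(), seed,
                               shear_sd = config$asymmetry_shear,
                               contours_per_line = 1) {
  if (missing(seed)) abort("`seed` is mandatory.")
  cross <- simulate_cross(config, seed = seed)
  set.seed(seed + 1L)
  n <- config$n_lines
  shear <- if (shear_sd > 0) rnorm(n, 0, shear_sd) else rep(0, n)
  sel <- cross$measures |>
    dplyr::filter(.data$replicate <= contours_per_line)
  idx <- match(sel$line_id, cross$pheno$line_id)
  contours <- purrr::pmap_dfr(
    list(sel$line_id, sel$replicate, pmax(sel$height, 1), pmax(sel$radius, 1),
         shear[idx]),
    function(lid, rep, h, r, sh) {
      simulate_contour(h, r, n_points = config$contour_points,
                       noise_sd = config$contour_noise_sd, shear = sh,
                       peakedness = config$peakedness_exponent,
                       contour_id = if (contours_per_line > 1)
                         paste0(lid, "_r", rep) else lid)
    })
  list(cross = cross, measures = cross$measures, contours = contours)
}
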