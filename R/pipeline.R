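#' Null calibration of the genome-wide permutation threshold
#'
#' Measures the realised genome-wide type-I error of [perm_threshold()]:
#' simulates `n_sims` BC2S3 crosses with no QTL (the phenotype is pure
#' residual noise), computes each cross's alpha-level threshold from `n_perm`
#' phenotype permutations, and records whether the observed genome-wide
#' maximum LOD stays below it. Under a calibrated threshold the non-exceedance
#' fraction matches `1 - alpha` up to binomial error.
#'
#' @param n_sims Number of null crosses (default 200).
#' @param n_perm Permutations per threshold (default 500).
#' @param alpha Nominal genome-wide error rate (default 0.05).
#' @param seed Integer seed governing simulation and permutation streams.
#' @param config Cross configuration; default is the standard synthetic
#'   population (400 lines, 5 chromosomes x 50 markers over 100 cM) with a
#'   single unreplicated measure per line.
#' @param step Scan grid: pseudomarker step in cM, `Inf` for markers only
#'   (default; at ~2 cM marker spacing the genome-wide maximum is already
#'   well resolved).
#' @return The non-exceedance fraction, with the per-simulation logical
#'   record in attribute `below`.
#' @export
calibrate_null_threshold <- function(n_sims = 200, n_perm = 500, alpha = 0.05,
                                     seed = 1, config = NULL, step = Inf) {
  config <- config %||% sim_config(n_replicates = 1, replicate_offsets = 0)
  set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_sims)
  below <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    cr <- simulate_cross(config, seed = sim_seeds[i])
    gp <- genotype_probabilities(cr, step = step)
    sc <- scan_qtl(cr, "height", genoprob = gp)
    thr <- perm_threshold(cr, "height", n_perm = n_perm, alpha = alpha,
                          seed = sim_seeds[n_sims + i], genoprob = gp)
    below[i] <- max(sc$lod) < thr
  }
  structure(mean(below), below = below)
}

# End-to-end synthetic study: simulate -> estimators & contours -> DCT PCs ->
# genome scans for the 8 estimators + 3 shape PCs -> permutation thresholds +
# Bayes intervals -> estimator x PC correlation matrix. One seed governs
# every stage; a JSON manifest records the run.

#' Run the full synthetic SAM morphometrics study
#'
#' Reproduces the package's whole analysis graph on synthetic data: a BC2S3
#' cross with QTL on SAM height and radius is simulated; the eight parabolic
#' estimators are computed per replicate and summarised per line by
#' [blup_summarize()]; contours are resampled, Procrustes aligned, DCT
#' transformed and decomposed into shape PCs; the estimators and the first
#' `n_pcs` PCs are each scanned for QTL with a shared permutation threshold;
#' Bayes 95% intervals are called for chromosomes with significant peaks; and
#' the estimator-by-PC correlation matrix is computed. If `out_dir` is given,
#' all tables plus a run manifest (JSON: seed, configuration, outputs,
#' package version, timestamps) are written there.
#'
#' @param config A [sim_config()] object; defaults include two height/radius
#'   QTL so the scan stage has signal.
#' @param seed Integer seed governing all stages.
#' @param n_perm Permutations for the shared significance threshold (default
#'   1000; the study-scale choice is 10000).
#' @param alpha Genome-wide significance level (default 0.05).
#' @param n_pcs Shape PCs carried into QTL scanning (default 3).
#' @param n_landmarks Pseudo-landmarks after resampling (default 800).
#' @param n_harmonics DCT harmonics per axis (default 12).
#' @param step Pseudomarker step in cM (default 1).
#' @param out_dir Optional output directory.
#' @return A list: `cross`, `estimators` (per-line BLUP+coefficient table),
#'   `pca`, `scores`, `scans` (named list of `sam_scan`), `threshold`,
#'   `intervals`, `correlations`, `manifest`.
#' @export
run_sam_study <- function(config = NULL, seed = 1, n_perm = 1000,
                          alpha = 0.05, n_pcs = 3, n_landmarks = 800,
                          n_harmonics = 12, step = 1, out_dir = NULL) {
  t0 <- Sys.time()
  config <- config %||% sim_config(
    qtl = tibble(chr = c(1, 3), pos = c(30, 65),
                 height_effect = c(6, 0), radius_effect = c(0, 5))
  )
  study <- simulate_sam_study(config, seed = seed, shear_sd = 0.05)
  cross <- study$cross

  # parabolic estimators per replicate, BLUP+coefficient per line
  est_raw <- sam_estimators(study$measures)
  est_traits <- names(estimator_display_names)
  est_blup <- purrr::map(est_traits, function(tr) {
    blup_summarize(est_raw, tr) |>
      dplyr::select("line_id", !!tr := "blup_plus_coefficient")
  }) |> purrr::reduce(dplyr::inner_join, by = "line_id")

  # contour pipeline: orient, resample, align, DCT, PCA
  aligned <- study$contours |>
    orient_contour("p0_left") |>
    resample_contour(n_points = n_landmarks) |>
    procrustes_align()
  pca <- shape_pca(dct_transform(aligned, n_harmonics = n_harmonics))
  scores <- tidy(pca) |>
    dplyr::select("shape_id", dplyr::all_of(paste0("PC", seq_len(n_pcs)))) |>
    dplyr::rename(line_id = "shape_id")

  # scans share one genotype-probability computation and one threshold trait
  cross$pheno <- dplyr::inner_join(
    dplyr::inner_join(cross$pheno["line_id"], est_blup, by = "line_id"),
    scores, by = "line_id")
  gp <- genotype_probabilities(cross, step = step)
  traits <- c(est_traits, paste0("PC", seq_len(n_pcs)))
  scans <- purrr::map(setNames(traits, traits), function(tr) {
    scan_qtl(cross, tr, genoprob = gp)
  })
  thresholds <- purrr::imap(scans, function(sc, tr) {
    perm_threshold(cross, tr, n_perm = n_perm, alpha = alpha,
                   seed = seed + 1000L + match(tr, traits), genoprob = gp)
  })
  intervals <- purrr::imap_dfr(scans, function(sc, tr) {
    thr <- thresholds[[tr]]
    sig <- unique(sc$chr[sc$lod > thr])
    if (!length(sig)) return(tibble())
    purrr::map_dfr(sig, function(ch) bayes_interval(sc, ch)) |>
      dplyr::mutate(trait = tr, .before = 1)
  })
  correlations <- correlation_matrix(est_blup, scores)

  manifest <- list(
    command = "run_sam_study",
    seed = seed,
    config = unclass(config)[c("n_lines", "n_chromosomes",
                               "markers_per_chromosome", "chromosome_length",
                               "base_height", "base_radius", "n_replicates",
                               "contour_points", "contour_noise_sd")],
    qtl = as.data.frame(config$qtl),
    n_perm = n_perm, alpha = alpha, n_pcs = n_pcs,
    n_landmarks = n_landmarks, n_harmonics = n_harmonics, step = step,
    package_version = as.character(utils::packageVersion("samorph")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  result <- list(cross = cross, estimators = est_blup, pca = pca,
                 scores = scores, scans = scans,
                 threshold = purrr::map_dbl(thresholds, unname),
                 intervals = intervals, correlations = correlations,
                 manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cross(cross, file.path(out_dir, "cross.csv"))
    write_estimators(est_blup, file.path(out_dir, "estimators.csv"))
    utils::write.csv(scores, file.path(out_dir, "pc_scores.csv"), row.names = FALSE)
    for (tr in names(scans)) {
      write_scan(scans[[tr]], file.path(out_dir, sprintf("scan_%s.tsv", tr)))
    }
    utils::write.table(as.data.frame(intervals),
                       file.path(out_dir, "intervals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(correlations),
                       file.path(out_dir, "correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$outputs <- list.files(out_dir)
    manifest$thresholds <- as.list(result$threshold)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  invisible(result)
}
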