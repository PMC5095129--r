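# Haley-Knott scan, permutation thresholds, Bayes intervals.

test_that("a noiseless marker phenotype puts the capped peak at that marker", {
  cfg <- test_cross_config(n_lines = 100)
  cr <- simulate_cross(cfg, seed = 41)
  target <- "c3_m25"
  cr$pheno$y <- as.numeric(cr$geno[, target])
  sc <- scan_qtl(cr, "y", step = Inf, error_prob = 1e-8)
  peak <- sc[which.max(sc$lod), ]
  expect_equal(peak$marker, target)
  # LOD hits the numeric cap (n/2) * log10(1/1e-12)
  expect_gt(peak$lod, 0.9 * (attr(sc, "n") / 2) * 12)
})

test_that("LOD is invariant to affine transformation of the phenotype", {
  cfg <- test_cross_config(n_lines = 80)
  cr <- simulate_cross(cfg, seed = 42)
  gp <- genotype_probabilities(cr, step = 5)
  s1 <- scan_qtl(cr, "height", genoprob = gp)
  cr$pheno$height <- 3.7 * cr$pheno$height - 250
  s2 <- scan_qtl(cr, "height", genoprob = gp)
  expect_equal(s2$lod, s1$lod, tolerance = 1e-9)
})

test_that("a constant phenotype scans to all-zero LOD with a warning", {
  cfg <- test_cross_config(n_lines = 50)
  cr <- simulate_cross(cfg, seed = 43)
  cr$pheno$flat <- 5
  expect_warning(sc <- scan_qtl(cr, "flat", step = Inf), "constant")
  expect_true(all(sc$lod == 0))
})

test_that("a simulated additive QTL is localized near its true position", {
  a <- qtl_effect_for_share(0.25, 5)
  hits <- vapply(1:20, function(i) {
    cfg <- test_cross_config(
      n_lines = 200,
      qtl = data.frame(chr = 2, pos = 40, height_effect = a, radius_effect = 0))
    cr <- simulate_cross(cfg, seed = 4300 + i)
    sc <- scan_qtl(cr, "height", step = 2)
    peak <- sc[which.max(sc$lod), ]
    peak$chr == 2 && abs(peak$pos - 40) <= 15
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("permutation thresholds: quantile edge, monotonicity, reproducibility, stability", {
  cfg <- test_cross_config(n_lines = 100)
  cr <- simulate_cross(cfg, seed = 44)
  gp <- genotype_probabilities(cr, step = Inf)
  thr <- perm_threshold(cr, "height", n_perm = 200, alpha = c(1, 0.2, 0.05),
                        seed = 1, genoprob = gp)
  maxl <- attr(thr, "maxlods")
  expect_equal(unname(thr[1]), min(maxl))          # alpha = 1 -> minimum
  expect_true(all(diff(unname(thr)) >= 0))         # monotone in alpha
  thr_b <- perm_threshold(cr, "height", n_perm = 200, alpha = 0.05,
                          seed = 1, genoprob = gp)
  expect_equal(as.numeric(thr_b), as.numeric(thr[3]))  # seeded reproducibility
  expect_equal(as.numeric(thr[3]),
               quantile(maxl, 0.95, type = 7, names = FALSE))
  # doubling the permutation count within one seed family moves the
  # threshold by only a few percent on the standard synthetic cross
  cr_std <- simulate_cross(sim_config(n_replicates = 1, replicate_offsets = 0),
                           seed = 44)
  gp_std <- genotype_probabilities(cr_std, step = Inf)
  t500 <- perm_threshold(cr_std, "height", n_perm = 500, seed = 2,
                         genoprob = gp_std)
  t1000 <- perm_threshold(cr_std, "height", n_perm = 1000, seed = 2,
                          genoprob = gp_std)
  expect_lt(abs(t1000 - t500) / t500, 0.05)
})

test_that("Bayes intervals: spike collapse, symmetry, marker expansion, flat warning", {
  cfg <- sim_config(n_lines = 20, n_chromosomes = 1,
                    markers_per_chromosome = 11, chromosome_length = 100,
                    n_replicates = 1, replicate_offsets = 0)
  cr <- simulate_cross(cfg, seed = 45)
  sc <- scan_qtl(cr, "height", step = 1)
  # craft LOD profiles directly on the scan grid
  spike <- sc
  spike$lod <- ifelse(spike$pos == 47, 20, 0)
  iv <- bayes_interval(spike, 1)
  expect_equal(iv$peak, 47)
  expect_equal(iv$lower, 40)   # flanking genotyped markers at 40 and 50
  expect_equal(iv$upper, 50)
  symm <- sc
  symm$lod <- 5 * exp(-((symm$pos - 50) / 8)^2)
  iv2 <- bayes_interval(symm, 1)
  expect_equal(iv2$peak, 50)
  expect_equal(iv2$upper - 50, 50 - iv2$lower, tolerance = 1e-9)
  flat <- sc
  flat$lod <- rep(1, nrow(flat))
  expect_warning(iv3 <- bayes_interval(flat, 1), "flat")
  expect_equal(c(iv3$lower, iv3$upper), c(0, 100))
  expect_error(bayes_interval(sc, 9), "cover")
})

test_that("95% Bayes intervals cover the simulated QTL position", {
  a <- qtl_effect_for_share(0.25, 5)
  # sanity-level check at 20 repeats; the 50-repeat coverage experiment
  # lives with the end-to-end validations
  covered <- vapply(1:20, function(i) {
    cfg <- test_cross_config(
      n_lines = 200,
      qtl = data.frame(chr = 4, pos = 62, height_effect = a, radius_effect = 0))
    cr <- simulate_cross(cfg, seed = 4600 + i)
    sc <- scan_qtl(cr, "height", step = 2)
    iv <- bayes_interval(sc, 4)
    iv$lower <= 62 && iv$upper >= 62
  }, logical(1))
  expect_gte(mean(covered), 0.75)
})

test_that("BLUP + coefficient equals line means when residual variance is zero", {
  d <- tidyr::expand_grid(line_id = sprintf("l%02d", 1:30), replicate = 1:2)
  set.seed(47)
  vals <- rnorm(30, 100, 10)
  d$y <- rep(vals, each = 2)
  b <- blup_summarize(d, "y")
  expect_equal(b$blup_plus_coefficient, vals, tolerance = 1e-6)
})

test_that("balanced-design BLUP matches the closed-form shrinkage oracle", {
  set.seed(48)
  n <- 80
  u <- rnorm(n, 0, 4)
  d <- tidyr::expand_grid(line_id = sprintf("l%03d", 1:n), replicate = 1:2)
  d$y <- 100 + c(-1.5, 1.5)[d$replicate] + rep(u, each = 2) +
    rnorm(nrow(d), 0, 3)
  b <- blup_summarize(d, "y")
  # oracle: with replicate a sum-to-zero fixed effect and balanced data,
  # u_hat_i = (s_u^2 / (s_u^2 + s_e^2/2)) (ybar_i - ybar), value = ybar + u_hat
  fit <- nlme::lme(y ~ replicate, random = ~ 1 | line_id,
                   data = transform(d, replicate = factor(replicate),
                                    line_id = factor(line_id)),
                   method = "REML",
                   contrasts = list(replicate = "contr.sum"))
  vc <- nlme::VarCorr(fit)
  s_u2 <- as.numeric(vc[1, 1]); s_e2 <- as.numeric(vc[2, 1])
  ybar_i <- tapply(d$y, d$line_id, mean)
  shrink <- s_u2 / (s_u2 + s_e2 / 2)
  oracle <- mean(d$y) + shrink * (ybar_i - mean(d$y))
  expect_equal(b$blup_plus_coefficient, as.numeric(oracle[b$line_id]),
               tolerance = 1e-6)
})

test_that("REML recovers known variance components from simulated data", {
  set.seed(49)
  n <- 500
  s_u <- 5; s_e <- 3
  u <- rnorm(n, 0, s_u)
  d <- tidyr::expand_grid(line_id = sprintf("l%03d", 1:n), replicate = 1:2)
  d$y <- 100 + rep(u, each = 2) + rnorm(nrow(d), 0, s_e)
  fit <- nlme::lme(y ~ replicate, random = ~ 1 | line_id,
                   data = transform(d, replicate = factor(replicate),
                                    line_id = factor(line_id)),
                   method = "REML", contrasts = list(replicate = "contr.sum"))
  vc <- nlme::VarCorr(fit)
  expect_lt(abs(sqrt(as.numeric(vc[1, 1])) - s_u) / s_u, 0.15)
  expect_lt(abs(sqrt(as.numeric(vc[2, 1])) - s_e) / s_e, 0.15)
})

test_that("single-replicate data fall back to means with a warning", {
  d <- data.frame(line_id = c("a", "b"), replicate = 1, y = c(1, 2))
  expect_warning(b <- blup_summarize(d, "y"), "replicates")
  expect_equal(b$blup_plus_coefficient, c(1, 2))
})
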