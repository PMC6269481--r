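test_that("identical seeds reproduce the cohort bit-identically without touching the global RNG", {
  cfg <- simulation_config(n_samples = 30, n_mirna = 80, n_mrna = 60,
                           n_driver_genes = 10, seed = 123)
  set.seed(999)
  before <- .Random.seed
  a <- simulate_cohort(cfg)
  expect_identical(.Random.seed, before)
  b <- simulate_cohort(cfg)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$latent, b$truth$latent)

  c2 <- simulate_cohort(simulation_config(n_samples = 30, n_mirna = 80,
                                          n_mrna = 60, n_driver_genes = 10,
                                          seed = 124))
  expect_false(identical(a$mirna, c2$mirna))
})

test_that("invalid configurations fail before any generation", {
  expect_error(simulation_config(n_up = 300, n_down = 200, n_mirna = 400),
               "n_up \\+ n_down")
  expect_error(simulation_config(n_driver_genes = 50, n_mrna = 10),
               "n_driver_genes")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(effect_size = -1), "effect_size")
  expect_error(simulation_config(n_samples = 0), "positive")
})

test_that("planted members take the packaged signature ids at the default column sizes", {
  cohort <- small_cohort(seed = 3)
  esc <- esc_mirna_signature()
  expect_identical(cohort$truth$mirna_up, esc$up)
  expect_identical(cohort$truth$mirna_down, esc$down)
  expect_true(all(esc$up %in% rownames(cohort$mirna)))
  # non-default sizes fall back to synthetic ids
  alt <- simulate_cohort(simulation_config(n_samples = 10, n_mirna = 30,
                                           n_up = 5, n_down = 5, n_mrna = 20,
                                           n_driver_genes = 4, seed = 3))
  expect_true(all(startsWith(alt$truth$mirna_up, "sim-mir-up")))
})

test_that("a null cohort carries no signal into the score", {
  cohort <- simulate_cohort(simulation_config(
    n_samples = 200, n_mrna = 10, n_driver_genes = 2,
    effect_size = 0, hazard_log_ratio = 0, amp_slope = 0, seed = 8))
  sc <- signature_score(cohort$mirna, esc_mirna_signature())
  expect_lt(abs(cor(sc$score, cohort$truth$latent, method = "spearman")), 0.2)
})

test_that("amplified samples score higher when the label loads on the latent factor", {
  cohort <- small_cohort(seed = 17, n_samples = 200)
  sc <- signature_score(cohort$mirna, esc_mirna_signature())
  amp <- cohort$clinical$mycn_amplified
  expect_gt(mean(sc$score[amp == 1]), mean(sc$score[amp == 0]))
  mw <- two_group_test(unname(sc$score), amp, "mannwhitney")
  expect_lt(mw$p, 0.05)
})

test_that("score-latent correlation is monotone in the effect size", {
  betas <- c(0, 0.5, 1, 2)
  mean_rho <- vapply(betas, function(b) {
    mean(vapply(1:10, function(seed) {
      cohort <- small_cohort(seed = seed, effect_size = b, n_samples = 60)
      sc <- signature_score(cohort$mirna, esc_mirna_signature())
      abs(cor(sc$score, cohort$truth$latent, method = "spearman"))
    }, 0))
  }, 0)
  expect_true(all(diff(mean_rho) > -0.05))  # nondecreasing up to noise
  expect_gt(mean_rho[4], mean_rho[1])
})

test_that("a positive hazard effect pushes the high-score KM curve below the low curve", {
  cohort <- small_cohort(seed = 29, n_samples = 200, hazard_log_ratio = 0.7)
  sc <- signature_score(cohort$mirna, esc_mirna_signature())
  g <- dichotomize_by_median(sc)
  rep <- survival_report(sc, cohort$clinical)
  expect_lt(rep$landmark$high$estimate, rep$landmark$low$estimate)
  expect_lt(rep$logrank$p, 0.05)
})

test_that("truth recovery report computes precision and recall against the planted set", {
  cohort <- simulate_cohort(simulation_config(n_samples = 10, n_mirna = 70,
                                              n_mrna = 40, n_driver_genes = 6,
                                              seed = 2))
  exact <- directional_signature(up = cohort$truth$drivers)
  r1 <- truth_recovery_report(cohort, exact)
  expect_equal(r1$precision, 1)
  expect_equal(r1$recall, 1)

  other <- directional_signature(
    up = setdiff(rownames(cohort$mrna), cohort$truth$drivers)[1:6])
  r0 <- truth_recovery_report(cohort, other)
  expect_equal(r0$precision, 0)
  expect_equal(r0$recall, 0)

  expect_error(truth_recovery_report(cohort, directional_signature(up = "zz")),
               "outside the mRNA feature space")
})

test_that("written cohorts read back equal to the in-memory objects", {
  cohort <- simulate_cohort(simulation_config(n_samples = 8, n_mirna = 20,
                                              n_up = 3, n_down = 3,
                                              n_mrna = 15, n_driver_genes = 4,
                                              seed = 77))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  back <- read_expression_matrix(paths[["mirna"]])
  expect_equal(back, cohort$mirna, tolerance = 1e-12)
  clin <- read_clinical_table(paths[["clinical"]])
  expect_equal(clin$os_time, cohort$clinical$os_time, tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_identical(unlist(truth$drivers), cohort$truth$drivers)
})
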