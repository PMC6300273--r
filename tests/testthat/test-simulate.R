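test_that("identical seed and config reproduce the cohort bit-for-bit", {
  cfg <- sim_config(n_individuals = 300, n_snps = 12, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$scores, b$scores)
})

test_that("generated genotype frequencies follow HWE proportions at p = 0.5", {
  cfg <- sim_config(n_individuals = 10000, n_snps = 4,
                    maf_range = c(0.4999, 0.5001), seed = 15)
  g <- simulate_genotypes(cfg)
  dos <- g$genotypes$rs1
  freqs <- c(mean(dos == 0), mean(dos == 1), mean(dos == 2))
  se <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(freqs[1] - 0.25), se)
  expect_lt(abs(freqs[2] - 0.50), 3 * sqrt(0.5 * 0.5 / 10000))
  expect_lt(abs(freqs[3] - 0.25), se)
})

test_that("generated genotypes pass the HWE filter at close to the nominal rate", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 150, seed = 25)
  g <- simulate_genotypes(cfg)
  out <- filter_hwe(g$genotypes, alpha = 0.05)
  rate <- mean(out$report$excluded)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 0.01)
})

test_that("the generated panel is oriented and typed", {
  cfg <- sim_config(n_individuals = 50, n_snps = 30, seed = 35)
  g <- simulate_genotypes(cfg)
  expect_s3_class(g$panel, "grs_panel")
  expect_true(all(g$panel$beta > 0))
  expect_true(all(g$panel$traits != ""))
  expect_equal(nrow(g$panel), 30)
  expect_equal(geno_variants(g$genotypes), g$panel$rsid)
})

test_that("zero missingness gives a complete matrix; injected variant missingness trips the filter", {
  cfg <- sim_config(n_individuals = 400, n_snps = 10, seed = 45)
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(geno_matrix(g$genotypes)))

  vm <- c(0.06, rep(0, 9))  # only the first variant has 6% missingness
  cfg2 <- sim_config(n_individuals = 2000, n_snps = 10,
                     variant_missingness = vm, seed = 45)
  g2 <- simulate_genotypes(cfg2)
  out <- filter_variant_missingness(g2$genotypes, max_missing = 0.05)
  expect_false("rs1" %in% geno_variants(out$genotypes))
  expect_equal(setdiff(geno_variants(g2$genotypes),
                       geno_variants(out$genotypes)), "rs1")
})

test_that("intercept calibration matches the closed forms under zero effects", {
  cfg <- sim_config(n_individuals = 100, n_snps = 10, seed = 55,
                    ht_prevalence = 0.5, ht_grs_logor = 0,
                    vessel_prevalence = c(0.461, 0.266, 0.139, 0.134),
                    vessel_quartile_logor = matrix(0, 3, 3))
  out <- calibrate_intercepts(cfg)
  expect_equal(out$ht_intercept, 0, tolerance = 1e-6)
  expect_equal(out$vessel_intercepts,
               log(c(0.266, 0.139, 0.134) / 0.461), tolerance = 1e-6)

  cfg2 <- sim_config(n_individuals = 100, n_snps = 10, seed = 55,
                     ht_prevalence = 0.563, ht_grs_logor = 0)
  expect_equal(calibrate_intercepts(cfg2)$ht_intercept, qlogis(0.563),
               tolerance = 1e-6)
})

test_that("calibration under nonzero effects still hits the target marginals", {
  cfg <- sim_config(n_individuals = 100, n_snps = 10, seed = 65)
  out <- calibrate_intercepts(cfg)
  # deterministic integral over the quartile distribution must recover targets
  B <- out$vessel_quartile_logor
  pk <- sapply(1:4, function(qq) {
    eta <- c(0, out$vessel_intercepts + if (qq == 1) 0 else B[, qq - 1])
    exp(eta) / sum(exp(eta))
  })
  expect_equal(rowMeans(pk), c(0.461, 0.266, 0.139, 0.134), tolerance = 1e-4)
})

test_that("raising the GRS effect raises simulated hypertension prevalence at fixed negative intercept", {
  # at intercept 0 the prevalence is pinned at 1/2 by the symmetry of the
  # logistic in a symmetric score; away from 1/2 the effect is monotone
  prevs <- vapply(c(0, 0.6, 1.2), function(g) {
    cfg <- sim_config(n_individuals = 20000, n_snps = 10, seed = 75,
                      ht_grs_logor = g, ht_intercept = -1,
                      vessel_intercepts = c(-1, -2, -2))
    sim <- simulate_genotypes(cfg)
    mean(simulate_phenotypes(sim$genotypes, sim$panel,
                             cfg)$phenotypes$hypertension)
  }, numeric(1))
  expect_true(all(diff(prevs) > 0))
})

test_that("phenotypes carry the outcome structure the models expect", {
  cfg <- sim_config(n_individuals = 600, n_snps = 15, seed = 85)
  cohort <- simulate_cohort(cfg)
  ph <- cohort$phenotypes
  expect_setequal(unique(ph$vessels), 0:3)
  expect_equal(ph$chd, as.integer(ph$vessels >= 1))
  expect_true(all(ph$sex %in% c("male", "female")))
  expect_true(all(ph$bmi > 0))
  # prior AMI is enriched among multi-vessel disease by construction
  expect_gt(mean(ph$prior_ami[ph$vessels >= 2]),
            mean(ph$prior_ami[ph$vessels == 0]) - 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_snps = 3, seed = 1), "at least 4")
  expect_error(sim_config(ht_prevalence = 1.2, seed = 1), "\\(0, 1\\)")
  expect_error(sim_config(vessel_prevalence = c(0.5, 0.5, 0.2, 0.1), seed = 1),
               "summing to 1")
  expect_error(sim_config(maf_range = c(0, 0.5), seed = 1), "inside")
  expect_error(sim_config(n_individuals = 100, n_snps = 10), "seed")
})
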