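oriented_fixture <- function(n, m, seed, miss = 0) {
  set.seed(seed)
  p <- as_panel(make_panel_df(m, beta = runif(m, 0.05, 1.2)))
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[col(matrix(0, n, m))]), n, m)
  if (miss > 0) dos[sample(length(dos), miss)] <- NA
  list(panel = p, geno = make_geno(dos, p), dosage = dos)
}

test_that("unweighted score is the plain dosage sum", {
  fx <- oriented_fixture(1, 3, 1)
  g <- make_geno(matrix(c(0, 1, 2), 1, 3), fx$panel)
  expect_equal(grs_unweighted(g, fx$panel)$score, 3)
  g0 <- make_geno(matrix(0, 1, 3), fx$panel)
  expect_equal(grs_unweighted(g0, fx$panel)$score, 0)
})

test_that("unweighted and weighted scores match the double-loop oracle on random matrices", {
  fx <- oriented_fixture(100, 50, 21)
  expect_equal(grs_unweighted(fx$geno, fx$panel)$score, oracle_ugrs(fx$dosage))
  expect_equal(grs_weighted(fx$geno, fx$panel)$score,
               oracle_wgrs(fx$dosage, fx$panel$beta))
})

test_that("weighted score reduces to the unweighted score under equal weights", {
  set.seed(31)
  p <- as_panel(make_panel_df(12, beta = rep(0.37, 12)))
  g <- make_geno(matrix(rbinom(20 * 12, 2, 0.5), 20, 12), p)
  expect_equal(grs_weighted(g, p)$score, grs_unweighted(g, p)$score)
})

test_that("a single-variant weighted score is the dosage itself", {
  p <- as_panel(make_panel_df(1, beta = 0.83))
  g <- make_geno(matrix(c(0, 0.5, 2), 3, 1), p)
  expect_equal(grs_weighted(g, p)$score, c(0, 0.5, 2))
})

test_that("the two-variant worked example evaluates to 8/3", {
  p <- as_panel(make_panel_df(2, beta = c(0.5, 1.0), traits = c("SBP", "SBP")))
  g <- make_geno(matrix(c(2, 1), 1, 2), p)
  expect_equal(grs_weighted(g, p)$score, 8 / 3)
})

test_that("adding a constant to betas moves wGRS but never uGRS", {
  fx <- oriented_fixture(15, 8, 41)
  p2 <- fx$panel
  p2$beta <- p2$beta + 0.25
  expect_equal(grs_unweighted(fx$geno, p2)$score,
               grs_unweighted(fx$geno, fx$panel)$score)
  expect_false(isTRUE(all.equal(grs_weighted(fx$geno, p2)$score,
                                grs_weighted(fx$geno, fx$panel)$score)))
})

test_that("appending a monomorphic variant leaves uGRS fixed and rescales wGRS as the formula dictates", {
  fx <- oriented_fixture(25, 10, 51)
  extra <- make_panel_df(11, beta = c(runif(10, 0.1, 1), 0.4))[11, ]
  p2 <- as_panel(dplyr::bind_rows(tibble::as_tibble(fx$panel)[, names(extra)], extra))
  dos2 <- cbind(fx$dosage, 0)
  g2 <- make_geno(dos2, p2)
  expect_equal(grs_unweighted(g2, p2)$score,
               grs_unweighted(fx$geno, fx$panel)$score)
  expect_equal(grs_weighted(g2, p2)$score, oracle_wgrs(dos2, p2$beta))
})

test_that("standardization gives mean 0 and sample SD 1 to 1e-10", {
  expect_equal(grs_standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(61)
  x <- rnorm(1000, 50, 7)
  z <- grs_standardize(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_error(grs_standardize(rep(2, 5)), "zero variance")
  expect_error(grs_standardize(3), "at least 2")
})

test_that("quartiles cut ranked scores at the nearest-rank percentiles with ties to the lower interval", {
  expect_equal(grs_quartiles(1:8), rep(1:4, each = 2))
  x <- c(1, 2, 2, 2, 3, 4, 5, 6)   # ties at the first cut share quartile 1
  q <- grs_quartiles(x)
  expect_true(all(q[x == 2] == q[x == 2][1]))
  expect_error(grs_quartiles(c(1, 1, 2, 2, 3)), "4 distinct")
})

test_that("quartile labels are invariant under standardization and monotone maps", {
  set.seed(71)
  x <- rnorm(500)
  expect_equal(grs_quartiles(x), grs_quartiles(grs_standardize(x)))
  expect_equal(grs_quartiles(x), grs_quartiles(exp(x)))
})

test_that("integer-valued scores yield near-equal quartiles up to the ties at each cut", {
  set.seed(81)
  x <- rbinom(4809, 500, 0.5)  # integer-like, heavily tied
  q <- grs_quartiles(x)
  sizes <- as.numeric(table(q))
  cuts <- quantile(x, c(0.25, 0.5, 0.75), type = 1)
  slack <- sum(table(x)[as.character(unique(cuts))])
  expect_true(all(abs(sizes - 4809 / 4) <= slack))
})

test_that("missing-dosage policies behave as declared", {
  p <- as_panel(make_panel_df(2, beta = c(0.5, 0.5)))
  dos <- matrix(c(1, NA, 2, 2), 2, 2)
  g <- make_geno(dos, p)
  # mean imputation: column mean of observed (here 1 for rs1)
  expect_equal(grs_unweighted(g, p, missing = "mean")$score, c(3, 3))
  expect_equal(grs_unweighted(g, p, missing = "zero")$score, c(3, 2))
  drop <- grs_unweighted(g, p, missing = "drop")$score
  expect_equal(drop, c(3, NA))
})

test_that("compute_grs assembles a coherent score set", {
  fx <- oriented_fixture(120, 20, 91)
  s <- compute_grs(fx$geno, fx$panel)
  expect_s3_class(s, "grs_scores")
  expect_equal(attr(s, "panel_n"), 20)
  expect_true(all(s$ugrs_raw >= 0 & s$ugrs_raw <= 2 * 20))
  expect_true(all(s$quartile_u %in% 1:4))
  expect_lt(abs(mean(s$wgrs_std)), 1e-10)
  expect_lt(abs(sd(s$wgrs_std) - 1), 1e-10)
  expect_equal(s$quartile_w, grs_quartiles(s$wgrs_std))
})

test_that("scoring demands an oriented panel and full variant coverage", {
  df <- make_panel_df(2, beta = c(0.5, -0.5), traits = c("SBP", "SBP"))
  p <- as_panel(df)
  g <- make_geno(matrix(1, 2, 2), p)
  expect_error(grs_unweighted(g, p), "orient")
  p_ok <- as_panel(make_panel_df(3, beta = rep(0.2, 3)))
  expect_error(grs_unweighted(g, p_ok), "absent")
})
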