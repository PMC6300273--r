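# design rows for a saturated single-binary-exposure table
toy_binary_design <- function(n11, n10, n01, n00) {
  tibble::tibble(
    grs_q = factor(rep(c("Q4", "Q4", "Q1", "Q1"), c(n11, n10, n01, n00)),
                   levels = paste0("Q", 1:4)),
    y = rep(c(1, 0, 1, 0), c(n11, n10, n01, n00))
  )
}

test_that("the saturated logistic OR equals the contingency cross-product ratio", {
  # exposed: 50 events / 50 non-events; unexposed: 25 / 75 -> OR 3 exactly
  d <- toy_binary_design(50, 50, 25, 75)
  fit <- fit_grs_logistic(d, "y", adjusted = FALSE)
  res <- tidy(fit)
  expect_equal(res$or[res$term == "grs_qQ4"], 3, tolerance = 1e-8)
  expect_equal(glance(fit)$converged, TRUE)
})

test_that("an outcome without variation is rejected", {
  d <- toy_binary_design(50, 0, 25, 0)
  expect_error(fit_grs_logistic(d, "y", adjusted = FALSE), "no variation")
})

test_that("perfect separation is detected rather than reported as a huge OR", {
  d <- toy_binary_design(60, 0, 0, 60)
  expect_error(fit_grs_logistic(d, "y", adjusted = FALSE), "separation")
})

test_that("multinomial level ORs equal the 2x4 table cross-ratios", {
  # rows exposure Q1/Q4; columns vessels 0..3: (40,20,10,10) / (20,20,15,15)
  counts0 <- c(40, 20, 10, 10)
  counts1 <- c(20, 20, 15, 15)
  d <- tibble::tibble(
    grs_q = factor(rep(rep(c("Q1", "Q4"), each = 4), c(counts0, counts1)),
                   levels = paste0("Q", 1:4)),
    vessels = rep(rep(0:3, 2), c(counts0, counts1))
  )
  fit <- fit_grs_multinomial(d, adjusted = FALSE)
  res <- tidy(fit)
  for (k in 1:3) {
    expected <- (counts1[k + 1] * counts0[1]) / (counts0[k + 1] * counts1[1])
    got <- res$or[res$level == k & res$term == "grs_qQ4"]
    expect_equal(got, expected, tolerance = 1e-4)
  }
  # level 3 specifically: (15 * 40) / (10 * 20) = 3
  expect_equal(res$or[res$level == 3 & res$term == "grs_qQ4"], 3,
               tolerance = 1e-4)
})

test_that("two-level multinomial coefficients equal the binary logistic fit", {
  set.seed(13)
  n <- 600
  d <- tibble::tibble(
    grs_q = factor(paste0("Q", sample(1:4, n, replace = TRUE)),
                   levels = paste0("Q", 1:4)),
    vessels = rbinom(n, 1, 0.4)
  )
  mfit <- fit_grs_multinomial(d, adjusted = FALSE)
  bfit <- fit_grs_logistic(d |> dplyr::rename(y = vessels), "y",
                           adjusted = FALSE)
  m <- tidy(mfit); b <- tidy(bfit)
  expect_lt(max(abs(m$estimate - b$estimate)), 1e-6)
  expect_lt(max(abs(m$se - b$se)), 1e-5)
})

test_that("missing outcome levels are an error", {
  d <- tibble::tibble(grs_q = factor(rep("Q1", 5), paste0("Q", 1:4)),
                      vessels = rep(0, 5))
  expect_error(fit_grs_multinomial(d, adjusted = FALSE), "levels")
})

test_that("association results satisfy their structural invariants", {
  set.seed(23)
  n <- 800
  d <- tibble::tibble(
    grs_q = factor(paste0("Q", sample(1:4, n, TRUE)), paste0("Q", 1:4)),
    vessels = sample(0:3, n, TRUE, prob = c(0.45, 0.27, 0.14, 0.14))
  )
  res <- tidy(fit_grs_multinomial(d, adjusted = FALSE))
  expect_true(all(res$ci_low <= res$or & res$or <= res$ci_high))
  expect_equal(res$or, exp(res$estimate))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(nrow(res), 9)  # 3 levels x 3 non-reference quartiles
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  set.seed(33)
  d <- tibble::tibble(
    ugrs_std = c(rnorm(40, 0, 1), rnorm(35, 0.4, 1)),
    vessels = rep(0:1, c(40, 35))
  )
  a <- anova_grs_vessels(d)
  tt <- t.test(ugrs_std ~ vessels, data = d, var.equal = TRUE)
  expect_equal(a$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical group means give F = 0 and p = 1", {
  d <- tibble::tibble(
    ugrs_std = rep(c(-1, 1), 20),
    vessels = rep(0:3, each = 10)
  )
  a <- anova_grs_vessels(d)
  expect_equal(a$statistic, 0)
  expect_equal(a$p_value, 1)
})

test_that("a stratum with fewer than 2 observations is an error", {
  d <- tibble::tibble(ugrs_std = rnorm(10), vessels = c(rep(0, 9), 3))
  expect_error(anova_grs_vessels(d), "fewer than 2")
})

sim_design <- function(n, seed, q_effect = 0) {
  set.seed(seed)
  q <- sample(1:4, n, TRUE)
  tibble::tibble(
    grs_q = factor(paste0("Q", q), paste0("Q", 1:4)),
    age_q = factor(paste0("A", sample(1:4, n, TRUE)), paste0("A", 1:4)),
    male = rbinom(n, 1, 0.6),
    smoking = rbinom(n, 1, 0.25),
    bmi_cat = factor(sample(c("normal", "overweight", "obese"), n, TRUE),
                     c("normal", "underweight", "overweight", "obese")),
    diabetes = rbinom(n, 1, 0.2),
    hyperlipidemia = rbinom(n, 1, 0.5),
    stroke = rbinom(n, 1, 0.08),
    pad = rbinom(n, 1, 0.06),
    chd = rbinom(n, 1, plogis(-0.2 + q_effect * (q - 1)))
  )
}

test_that("the interaction LRT has 9 df and rejects a strong built-in interaction", {
  d <- sim_design(2500, 43)
  out <- interaction_test(d, "chd")
  expect_equal(out$df, 9)
  expect_gt(out$p_value, 0.001)  # simulated without interaction

  # inject a strong single-cell interaction
  set.seed(44)
  d2 <- sim_design(8000, 45)
  boost <- d2$grs_q == "Q4" & d2$age_q == "A4"
  d2$chd[boost] <- rbinom(sum(boost), 1, plogis(-0.2 + 1.5))
  out2 <- interaction_test(d2, "chd")
  expect_lt(out2$p_value, 0.05)
})

test_that("a single observed age quartile makes the interaction inestimable", {
  d <- sim_design(400, 53)
  d$age_q <- factor("A1", paste0("A", 1:4))
  expect_error(interaction_test(d, "chd"), "inestimable")
})

test_that("the pleiotropy screen covers binary and continuous factors and honours an empty set", {
  set.seed(63)
  d <- sim_design(1500, 63)
  d$bmi <- rnorm(1500, 26, 4)
  res <- pleiotropy_screen(d)
  expect_setequal(unique(res$outcome),
                  c("diabetes", "smoking", "hyperlipidemia", "bmi"))
  expect_true(all(is.na(res$or[res$outcome == "bmi"])))
  expect_equal(sum(res$outcome == "bmi"), 3)
  expect_equal(nrow(pleiotropy_screen(d, character(0))), 0)
})

test_that("pleiotropy recovers a built-in BMI dependence as a positive control", {
  set.seed(73)
  n <- 4000
  q <- sample(1:4, n, TRUE)
  z <- scale(q + rnorm(n, 0, 0.5))[, 1]
  d <- tibble::tibble(
    grs_q = factor(paste0("Q", q), paste0("Q", 1:4)),
    bmi = 25 + 0.5 * z + rnorm(n, 0, 1)
  )
  res <- pleiotropy_screen(d, "bmi")
  q4 <- res[res$term == "grs_qQ4", ]
  truth <- 0.5 * (mean(z[q == 4]) - mean(z[q == 1]))
  expect_lt(abs(q4$estimate - truth), 3 * q4$se)
  expect_lt(q4$p_value, 0.01)
})

test_that("covariate encoding maps BMI bands and boundaries as declared", {
  pheno <- tibble::tibble(
    individual_id = paste0("i", 1:12),
    age = seq(40, 84, by = 4),
    sex = rep(c("male", "female"), 6),
    smoking = rep(0:1, 6),
    bmi = c(17, 18.5, 24, 25, 25.1, 29.9, 30, 30.01, 35, 22, 27, 31),
    diabetes = 0, hyperlipidemia = 0, stroke = 0, pad = 0,
    chd = rep(0:1, 6), vessels = rep(0:3, 3), hypertension = rep(0:1, 6)
  )
  scores <- tibble::tibble(
    individual_id = pheno$individual_id,
    ugrs_raw = 1:12, wgrs_raw = 1:12,
    ugrs_std = scale(1:12)[, 1], wgrs_std = scale(1:12)[, 1],
    quartile_u = rep(1:4, each = 3), quartile_w = rep(1:4, each = 3),
    trait = "ALL"
  )
  d <- encode_covariates(pheno, scores)
  expect_equal(as.character(d$bmi_cat),
               c("underweight", "normal", "normal", "normal", "overweight",
                 "overweight", "overweight", "obese", "obese", "normal",
                 "overweight", "obese"))
  expect_equal(levels(d$bmi_cat)[1], "normal")
  expect_equal(levels(d$grs_q)[1], "Q1")
  expect_equal(levels(d$age_q)[1], "A1")
  expect_equal(d$male, rep(c(1L, 0L), 6))
})

test_that("rows with missing covariates are dropped with a count and bad values error", {
  pheno <- tibble::tibble(
    individual_id = paste0("i", 1:8),
    age = c(NA, 50:56), sex = "male", smoking = 0,
    bmi = 25, diabetes = 0, hyperlipidemia = 0, stroke = 0, pad = 0,
    chd = rep(0:1, 4)
  )
  scores <- tibble::tibble(
    individual_id = pheno$individual_id,
    ugrs_raw = 1:8, wgrs_raw = 1:8,
    ugrs_std = scale(1:8)[, 1], wgrs_std = scale(1:8)[, 1],
    quartile_u = rep(1:4, 2), quartile_w = rep(1:4, 2), trait = "ALL"
  )
  expect_message(d <- encode_covariates(pheno, scores), "dropping 1")
  expect_equal(nrow(d), 7)
  expect_equal(attr(d, "n_dropped"), 1)

  pheno$age[1] <- -3
  expect_error(encode_covariates(pheno, scores), "negative age")
})
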