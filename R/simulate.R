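#' Simulation configuration for a synthetic angiography cohort
#'
#' Collects every knob of the generator with defaults that emulate the
#' statistical structure of a hospital cohort referred for coronary
#' angiography: 4,809 individuals scored on a panel of 266 independent
#' biallelic blood-pressure SNPs in Hardy-Weinberg equilibrium, hypertension
#' prevalence 56.3%, and a 46.1/26.6/13.9/13.4% distribution of 0/1/2/3
#' diseased coronary vessels.
#'
#' @param n_individuals Cohort size.
#' @param n_snps Panel size (>= 4).
#' @param maf_range Allele-frequency range; frequencies are drawn uniformly.
#' @param beta_mean Mean of the exponential distribution of oriented
#'   (positive) per-allele effect sizes, in mmHg.
#' @param p_multi_trait Probability a SNP is associated with two or three of
#'   the blood-pressure traits (SBP, DBP, PP) rather than one.
#' @param ht_prevalence Target marginal hypertension prevalence.
#' @param ht_grs_logor Log-odds of hypertension per SD of standardized
#'   unweighted GRS.
#' @param vessel_prevalence Target marginal probabilities of 0/1/2/3-vessel
#'   disease (sums to 1).
#' @param vessel_quartile_logor 3 x 3 matrix of log-odds ratios: rows =
#'   outcome levels 1..3 vessels (vs 0), columns = GRS quartiles 2..4 (vs 1).
#'   The default encodes the dose-response operating point of the study
#'   design: no quartile effect on 1-vessel disease, effects concentrated on
#'   2- and 3-vessel disease.
#' @param ht_intercept,vessel_intercepts Optional intercepts; when `NULL`
#'   they are calibrated to the target prevalences by
#'   [calibrate_intercepts()].
#' @param covariate_marginals Named list of marginal rates for male sex,
#'   smoking, diabetes, hyperlipidemia, stroke, PAD, and prior AMI, plus
#'   age/BMI means and SDs.
#' @param ami_vessel_or Odds multiplier linking prior AMI to each additional
#'   diseased vessel.
#' @param variant_missingness,sample_missingness Per-entry missingness rates
#'   injected after generation (scalar, or per-variant vector for the
#'   variant-wise rate).
#' @param seed Integer RNG seed; mandatory, so identical configurations
#'   reproduce bit-identical cohorts.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_individuals = 4809,
                       n_snps = 266,
                       maf_range = c(0.05, 0.95),
                       beta_mean = 0.5,
                       p_multi_trait = 0.24,
                       ht_prevalence = 0.563,
                       ht_grs_logor = 0.25,
                       vessel_prevalence = c(0.461, 0.266, 0.139, 0.134),
                       vessel_quartile_logor = rbind(
                         c(0, 0, 0),
                         log(c(1.00, 1.33, 1.36)),
                         log(c(1.32, 1.77, 1.65))
                       ),
                       ht_intercept = NULL,
                       vessel_intercepts = NULL,
                       covariate_marginals = list(
                         male = 0.642, smoking = 0.240, diabetes = 0.175,
                         hyperlipidemia = 0.578, stroke = 0.079, pad = 0.063,
                         prior_ami = 0.146,
                         age_mean = 65.6, age_sd = 11.9,
                         bmi_mean = 26.9, bmi_sd = 4.4
                       ),
                       ami_vessel_or = 1.6,
                       variant_missingness = 0,
                       sample_missingness = 0,
                       seed) {
  if (missing(seed)) abort("sim_config() requires an explicit seed")
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = maf_range, beta_mean = beta_mean,
    p_multi_trait = p_multi_trait,
    ht_prevalence = ht_prevalence, ht_grs_logor = ht_grs_logor,
    vessel_prevalence = vessel_prevalence,
    vessel_quartile_logor = vessel_quartile_logor,
    ht_intercept = ht_intercept, vessel_intercepts = vessel_intercepts,
    covariate_marginals = covariate_marginals,
    ami_vessel_or = ami_vessel_or,
    variant_missingness = variant_missingness,
    sample_missingness = sample_missingness,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_snps < 4) abort("n_snps must be at least 4")
  if (cfg$n_individuals < 8) abort("n_individuals must be at least 8")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range >= 1) ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("maf_range must be an increasing pair inside (0, 1)")
  }
  if (cfg$beta_mean <= 0) abort("beta_mean must be positive")
  if (cfg$ht_prevalence <= 0 || cfg$ht_prevalence >= 1) {
    abort("ht_prevalence must lie in (0, 1)")
  }
  vp <- cfg$vessel_prevalence
  if (length(vp) != 4 || any(vp <= 0) || abs(sum(vp) - 1) > 1e-8) {
    abort("vessel_prevalence must be 4 positive probabilities summing to 1")
  }
  if (!all(dim(cfg$vessel_quartile_logor) == c(3, 3))) {
    abort("vessel_quartile_logor must be a 3x3 matrix (levels 1..3 x quartiles 2..4)")
  }
  rates <- cfg$covariate_marginals
  for (nm in c("male", "smoking", "diabetes", "hyperlipidemia", "stroke",
               "pad", "prior_ami")) {
    if (rates[[nm]] < 0 || rates[[nm]] > 1) {
      abort(paste0("covariate marginal '", nm, "' outside [0, 1]"))
    }
  }
  if (any(cfg$variant_missingness < 0) || any(cfg$variant_missingness >= 1) ||
      any(cfg$sample_missingness < 0) || any(cfg$sample_missingness >= 1)) {
    abort("missingness rates must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Simulate panel and genotypes under Hardy-Weinberg equilibrium
#'
#' Draws a per-variant allele frequency, then per-individual dosages as
#' Binomial(2, p) — HWE holds by construction. Panel effect sizes are drawn
#' positive (already risk-oriented) from an exponential distribution; trait
#' membership allows multi-trait SNPs with identical sign across traits.
#' Optional missingness is injected after generation.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (`grs_geno`), `panel` (`grs_panel`), and
#'   `truth` (allele frequencies and betas used).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  p_var <- config$n_snps
  freqs <- stats::runif(p_var, config$maf_range[1], config$maf_range[2])
  dos <- matrix(
    stats::rbinom(n * p_var, size = 2, prob = rep(freqs, each = n)),
    nrow = n, ncol = p_var
  )
  rsids <- paste0("rs", seq_len(p_var))

  # trait membership: single trait, or 2-3 traits with probability p_multi_trait
  n_traits <- 1L + stats::rbinom(p_var, 1, config$p_multi_trait) *
    (1L + stats::rbinom(p_var, 1, 0.3))
  traits <- vapply(n_traits, function(k) {
    paste(sort(sample(VALID_TRAITS, k)), collapse = ",")
  }, character(1))

  beta_main <- stats::rexp(p_var, rate = 1 / config$beta_mean)
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, p_var, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1), character(1))

  beta_cols <- matrix(NA_real_, nrow = p_var, ncol = 3,
                      dimnames = list(NULL, c("SBP", "DBP", "PP")))
  for (i in seq_len(p_var)) {
    members <- strsplit(traits[i], ",")[[1]]
    # member-trait effects scatter around the main effect, same sign
    b <- beta_main[i] * stats::runif(length(members), 0.6, 1.0)
    b[which.max(b)] <- beta_main[i]
    beta_cols[i, members] <- b
  }

  panel <- as_panel(tibble(
    rsid = rsids,
    chrom = as.character(sample(1:22, p_var, replace = TRUE)),
    pos = sample.int(2.5e8, p_var),
    effect_allele = ea,
    other_allele = unname(oa),
    beta_sbp = beta_cols[, "SBP"],
    beta_dbp = beta_cols[, "DBP"],
    beta_pp = beta_cols[, "PP"],
    traits = traits
  ))

  storage.mode(dos) <- "double"
  if (any(config$variant_missingness > 0)) {
    vm <- rep_len(config$variant_missingness, p_var)
    for (j in seq_len(p_var)) {
      if (vm[j] > 0) dos[stats::runif(n) < vm[j], j] <- NA_real_
    }
  }
  if (any(config$sample_missingness > 0)) {
    sm <- rep_len(config$sample_missingness, n)
    for (i in seq_len(n)) {
      if (sm[i] > 0) dos[i, stats::runif(p_var) < sm[i]] <- NA_real_
    }
  }

  df <- as_tibble(as.data.frame(dos))
  names(df) <- rsids
  geno <- as_geno(
    dplyr::bind_cols(tibble(individual_id = paste0("ind", seq_len(n))), df),
    panel[, c("rsid", "effect_allele", "other_allele")]
  )
  list(
    genotypes = geno,
    panel = panel,
    truth = list(freqs = freqs, betas = panel$beta, seed = config$seed)
  )
}

#' Simulate phenotypes and outcomes given genotypes
#'
#' Scores the cohort, then draws: hypertension from a logistic model in the
#' standardized unweighted GRS; vessel burden (0-3) from a baseline-category
#' multinomial whose level-specific linear predictors carry the configured
#' per-quartile log-odds ratios; significant CHD as the indicator of at
#' least one diseased vessel; covariates from their marginal distributions;
#' and prior AMI with odds increasing in vessel count. Intercepts are
#' calibrated to the target marginal prevalences if not supplied.
#'
#' @param geno,panel Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return List with `phenotypes` (tibble), `scores` (`grs_scores`), and
#'   `truth` (intercepts and effects actually used, sufficient to score any
#'   estimator's bias exactly).
#' @export
simulate_phenotypes <- function(geno, panel, config) {
  validate_sim_config(config)
  config <- calibrate_intercepts(config)
  set.seed(config$seed + 1L)
  n <- nrow(geno)
  scores <- compute_grs(geno, panel)
  z <- scores$ugrs_std
  q <- scores$quartile_u

  cm <- config$covariate_marginals
  age <- stats::rnorm(n, cm$age_mean, cm$age_sd)
  bmi <- pmax(stats::rnorm(n, cm$bmi_mean, cm$bmi_sd), 12)

  p_ht <- stats::plogis(config$ht_intercept + config$ht_grs_logor * z)
  hypertension <- stats::rbinom(n, 1, p_ht)

  # baseline-category multinomial over 0..3 vessels
  qi <- cbind(q == 2, q == 3, q == 4) * 1
  eta <- matrix(0, nrow = n, ncol = 4)
  for (lv in 1:3) {
    eta[, lv + 1] <- config$vessel_intercepts[lv] +
      qi %*% config$vessel_quartile_logor[lv, ]
  }
  pr <- exp(eta)
  pr <- pr / rowSums(pr)
  u <- stats::runif(n)
  cum <- t(apply(pr, 1, cumsum))
  vessels <- rowSums(u > cum)  # 0..3

  ami_lin <- stats::qlogis(cm$prior_ami) + log(config$ami_vessel_or) * vessels
  pheno <- tibble(
    individual_id = geno$individual_id,
    age = age,
    sex = ifelse(stats::rbinom(n, 1, cm$male) == 1, "male", "female"),
    smoking = stats::rbinom(n, 1, cm$smoking),
    bmi = bmi,
    diabetes = stats::rbinom(n, 1, cm$diabetes),
    hyperlipidemia = stats::rbinom(n, 1, cm$hyperlipidemia),
    stroke = stats::rbinom(n, 1, cm$stroke),
    pad = stats::rbinom(n, 1, cm$pad),
    hypertension = hypertension,
    vessels = as.integer(vessels),
    chd = as.integer(vessels >= 1),
    prior_ami = stats::rbinom(n, 1, stats::plogis(ami_lin))
  )
  list(
    phenotypes = pheno,
    scores = scores,
    truth = list(
      ht_intercept = config$ht_intercept,
      ht_grs_logor = config$ht_grs_logor,
      vessel_intercepts = config$vessel_intercepts,
      vessel_quartile_logor = config$vessel_quartile_logor,
      latent_grs = z
    )
  )
}

#' Calibrate model intercepts to target marginal prevalences
#'
#' Finds the hypertension intercept by monotone root-finding so the simulated
#' marginal prevalence matches `ht_prevalence` (closed form `qlogis(target)`
#' when the GRS effect is zero), and the multinomial intercepts by iterative
#' proportional adjustment so the marginal vessel distribution matches
#' `vessel_prevalence` (closed form `log(p_k / p_0)` under zero effects).
#' Calibration integrates over the standard-normal GRS and the uniform
#' quartile distribution rather than simulating, so it is deterministic.
#'
#' @param config A [sim_config()]; entries `ht_intercept` /
#'   `vessel_intercepts` already set are left untouched.
#' @param max_iter Iteration cap for the multinomial adjustment.
#' @param tol Convergence tolerance on achieved marginals (probability scale).
#' @return The config with intercepts filled in.
#' @export
calibrate_intercepts <- function(config, max_iter = 100, tol = 1e-6) {
  validate_sim_config(config)
  # Gauss-Hermite-style grid over the standardized GRS
  zg <- seq(-6, 6, length.out = 4001)
  wg <- stats::dnorm(zg)
  wg <- wg / sum(wg)

  if (is.null(config$ht_intercept)) {
    g <- config$ht_grs_logor
    f <- function(a) sum(wg * stats::plogis(a + g * zg)) - config$ht_prevalence
    config$ht_intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  }

  if (is.null(config$vessel_intercepts)) {
    target <- config$vessel_prevalence
    a <- log(target[2:4] / target[1])  # exact under zero effects
    B <- config$vessel_quartile_logor  # 3 levels x 3 quartile indicators
    achieved <- function(a) {
      # quartiles are uniform by construction
      pk <- matrix(0, nrow = 4, ncol = 4)  # quartile x level
      for (qq in 1:4) {
        eta <- c(0, a + if (qq == 1) 0 else B[, qq - 1])
        pk[qq, ] <- exp(eta) / sum(exp(eta))
      }
      colMeans(pk)
    }
    for (it in seq_len(max_iter)) {
      got <- achieved(a)
      if (max(abs(got - target)) < tol) break
      a <- a + log(target[2:4] / got[2:4]) - log(target[1] / got[1])
      if (it == max_iter) {
        abort(paste0("intercept calibration did not converge in ", max_iter,
                     " iterations; last marginals: ",
                     paste(round(got, 4), collapse = ", ")))
      }
    }
    got <- achieved(a)
    if (max(abs(got - target)) > 0.005) {
      warn(paste0("calibration achieved marginals ",
                  paste(round(got, 4), collapse = ", "),
                  " vs targets ", paste(target, collapse = ", ")))
    }
    config$vessel_intercepts <- a
  }
  config
}

#' Simulate a complete cohort in one call
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `panel`, `phenotypes`, `scores`, `truth`.
#' @export
simulate_cohort <- function(config) {
  g <- simulate_genotypes(config)
  p <- simulate_phenotypes(g$genotypes, g$panel, config)
  list(
    genotypes = g$genotypes, panel = g$panel,
    phenotypes = p$phenotypes, scores = p$scores,
    truth = c(g$truth, p$truth)
  )
}
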