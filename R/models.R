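wald_results <- function(est, se, terms, outcome, level, model, n) {
  tibble(
    outcome = outcome,
    level = level,
    term = terms,
    estimate = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se)),
    ci_high = exp(unname(est) + 1.96 * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(est) / unname(se))),
    model = model,
    n = n
  )
}

# empty factor levels would alias coefficients; fits use observed levels only
drop_unused_levels <- function(df) {
  for (nm in names(df)) {
    if (is.factor(df[[nm]])) df[[nm]] <- droplevels(df[[nm]])
  }
  df
}

check_separation <- function(est, limit = 15) {
  bad <- names(est)[is.finite(est) & abs(est) > limit]
  bad <- setdiff(bad, "(Intercept)")
  if (length(bad) > 0) {
    abort(paste0("quasi-separation detected (|log-odds| > ", limit,
                 ") for term(s): ", paste(bad, collapse = ", ")))
  }
}

#' Logistic regression of a binary outcome on GRS quartiles
#'
#' Fits a maximum-likelihood logit model of the outcome on GRS quartile
#' indicators (reference = lowest quartile), optionally adjusted for age
#' quartile, sex, smoking, BMI category, diabetes, hyperlipidemia, stroke and
#' peripheral artery disease. Confidence intervals are Wald 95% intervals on
#' the log-odds scale, `exp(b +/- 1.96 * SE)`.
#'
#' @param design Encoded design from [encode_covariates()] (or any tibble with
#'   a `grs_q` factor, the outcome column, and — if `adjusted` — the
#'   adjustment covariates).
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param adjusted Include the adjustment covariates.
#' @param weights Optional frequency weights (for fits on aggregated cells).
#' @return A `grs_fit` object; `tidy()` returns the per-term association
#'   table, `glance()` the model-level summary.
#' @export
fit_grs_logistic <- function(design, outcome, adjusted = TRUE, weights = NULL) {
  y <- design[[outcome]]
  if (is.null(y)) abort(paste0("no column '", outcome, "' in design"))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) abort("outcome must be binary (0/1)")
  if (length(unique(y)) < 2) {
    abort(paste0("outcome '", outcome, "' has no variation"))
  }
  dat <- drop_unused_levels(design)
  dat$.y <- y
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  f <- assoc_formula(".y", adjusted)
  fit <- suppressWarnings(
    stats::glm(f, family = stats::binomial(), data = dat, weights = .w,
               control = list(maxit = 100))
  )
  if (!fit$converged) abort("logistic fit did not converge within 100 iterations")
  est <- stats::coef(fit)
  check_separation(est)
  se <- sqrt(diag(stats::vcov(fit)))
  keep <- grepl("^grs_q", names(est))
  res <- wald_results(est[keep], se[keep], names(est)[keep], outcome,
                      level = NA_integer_,
                      model = if (adjusted) "adjusted" else "unadjusted",
                      n = sum(dat$.w))
  structure(
    list(fit = fit, results = res, outcome = outcome,
         model = if (adjusted) "adjusted" else "unadjusted",
         n = sum(dat$.w)),
    class = "grs_fit"
  )
}

#' Baseline-category multinomial regression of vessel burden on GRS quartiles
#'
#' Models the number of diseased coronary vessels (0, 1, 2, 3; baseline = 0)
#' with a baseline-category multinomial logit, giving one odds ratio with a
#' Wald 95% interval per quartile term and non-baseline level. With only two
#' outcome levels present the model is the binary logistic model.
#'
#' @param design Encoded design (see [fit_grs_logistic()]).
#' @param outcome Name of the outcome column with integer levels `0..3`
#'   (default `"vessels"`).
#' @param adjusted Include the adjustment covariates.
#' @param weights Optional frequency weights.
#' @return A `grs_multifit` object with `tidy()`/`glance()` methods.
#' @export
fit_grs_multinomial <- function(design, outcome = "vessels", adjusted = TRUE,
                                weights = NULL) {
  y <- design[[outcome]]
  if (is.null(y)) abort(paste0("no column '", outcome, "' in design"))
  levels_present <- sort(unique(y))
  if (length(levels_present) < 2) abort("outcome has fewer than 2 levels")
  dat <- drop_unused_levels(design)
  dat$.y <- factor(y, levels = levels_present)
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  f <- assoc_formula(".y", adjusted)
  fit <- nnet::multinom(f, data = dat, weights = .w, trace = FALSE,
                        maxit = 200, reltol = 1e-12, Hess = TRUE,
                        model = TRUE)
  if (fit$convergence != 0) {
    abort("multinomial fit did not converge within 200 iterations")
  }
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list(
    as.character(levels_present[2]), names(cf)))
  se_flat <- sqrt(diag(solve(fit$Hessian)))
  se <- matrix(se_flat, nrow = nrow(cf), byrow = TRUE,
               dimnames = dimnames(cf))
  check_separation(setNames(as.vector(cf), rep(colnames(cf), each = nrow(cf))))
  model_lab <- if (adjusted) "adjusted" else "unadjusted"
  res <- purrr::map_dfr(rownames(cf), function(lv) {
    keep <- grepl("^grs_q", colnames(cf))
    wald_results(cf[lv, keep], se[lv, keep], colnames(cf)[keep], outcome,
                 level = as.integer(lv), model = model_lab,
                 n = sum(dat$.w))
  })
  structure(
    list(fit = fit, results = res, outcome = outcome, model = model_lab,
         levels = levels_present, n = sum(dat$.w)),
    class = "grs_multifit"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.grs_fit <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.grs_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome, model = x$model, n = x$n,
    log_lik = as.numeric(stats::logLik(x$fit)),
    aic = stats::AIC(x$fit),
    df = x$fit$df.residual,
    converged = x$fit$converged
  )
}

#' @exportS3Method generics::tidy
tidy.grs_multifit <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.grs_multifit <- function(x, ...) {
  tibble(
    outcome = x$outcome, model = x$model, n = x$n,
    log_lik = -x$fit$value,
    aic = stats::AIC(x$fit),
    n_levels = length(x$levels),
    converged = x$fit$convergence == 0
  )
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("<grs_fit> %s (%s), n = %s\n", x$outcome, x$model, x$n))
  print(x$results)
  invisible(x)
}

#' @export
print.grs_multifit <- function(x, ...) {
  cat(sprintf("<grs_multifit> %s (%s), levels %s, n = %s\n", x$outcome,
              x$model, paste(x$levels, collapse = "/"), x$n))
  print(x$results)
  invisible(x)
}

#' One-way ANOVA of the GRS across vessel-burden strata
#'
#' Tests whether the mean standardized GRS differs across the four
#' vessel-disease strata with a fixed-effects one-way analysis of variance.
#'
#' @param data Tibble holding the score and the stratum columns.
#' @param score Name of the (standardized) score column.
#' @param strata Name of the vessel-count column.
#' @return One-row tibble with `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_grs_vessels <- function(data, score = "ugrs_std", strata = "vessels") {
  x <- data[[score]]
  g <- factor(data[[strata]])
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("stratum with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- stats::aov(x ~ g)
  tab <- summary(fit)[[1]]
  tibble(
    statistic = tab[["F value"]][1],
    df1 = tab[["Df"]][1],
    df2 = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Likelihood-ratio test for a GRS-by-age interaction
#'
#' Compares the adjusted logistic model with all nine GRS-quartile by
#' age-quartile product terms against the model without them; the statistic
#' is chi-square with 9 degrees of freedom when both factors have four
#' levels.
#'
#' @param design Encoded design from [encode_covariates()].
#' @param outcome Binary outcome column name.
#' @return One-row tibble with `statistic`, `df`, `p_value`.
#' @export
interaction_test <- function(design, outcome) {
  if (nlevels(droplevels(design$grs_q)) < 2 ||
      nlevels(droplevels(design$age_q)) < 2) {
    abort("interaction inestimable: a factor has a single observed level")
  }
  dat <- design
  dat$.y <- as.integer(dat[[outcome]])
  f0 <- assoc_formula(".y", adjusted = TRUE)
  f1 <- assoc_formula(".y", adjusted = TRUE, extra = "grs_q:age_q")
  m0 <- stats::glm(f0, family = stats::binomial(), data = dat)
  m1 <- stats::glm(f1, family = stats::binomial(), data = dat)
  if (!m0$converged || !m1$converged) {
    abort("nested logistic model did not converge")
  }
  cmp <- stats::anova(m0, m1, test = "Chisq")
  tibble(
    statistic = cmp$Deviance[2],
    df = cmp$Df[2],
    p_value = cmp$`Pr(>Chi)`[2]
  )
}

#' Pleiotropy screen of the GRS against non-target risk factors
#'
#' A blood-pressure GRS should act on coronary disease through blood
#' pressure, not through other risk factors. This screen regresses each
#' candidate factor on the GRS quartiles: binary factors (diabetes, smoking,
#' hyperlipidemia) by logistic regression, continuous factors (BMI) by linear
#' regression. Evidence of association flags possible pleiotropy.
#'
#' @param design Encoded design from [encode_covariates()].
#' @param factors Character vector naming the factor columns to screen;
#'   `"bmi"` is modelled as continuous, all others as binary.
#' @return Tidy tibble of per-quartile estimates (odds ratios for binary
#'   factors; `or`, `ci_low`, `ci_high` are `NA` for linear fits, whose
#'   `estimate` is the mean difference). Empty `factors` gives an empty
#'   tibble.
#' @export
pleiotropy_screen <- function(design,
                              factors = c("diabetes", "smoking",
                                          "hyperlipidemia", "bmi")) {
  if (length(factors) == 0) return(wald_results(numeric(), numeric(),
                                               character(), character(),
                                               integer(), character(),
                                               integer())[0, ])
  purrr::map_dfr(factors, function(fac) {
    if (!fac %in% names(design)) abort(paste0("no column '", fac, "' in design"))
    if (fac == "bmi") {
      fit <- stats::lm(bmi ~ grs_q, data = drop_unused_levels(design))
      est <- stats::coef(fit)
      sde <- sqrt(diag(stats::vcov(fit)))
      keep <- grepl("^grs_q", names(est))
      pvals <- 2 * stats::pt(-abs(est[keep] / sde[keep]),
                             df = fit$df.residual)
      tibble(
        outcome = fac, level = NA_integer_, term = names(est)[keep],
        estimate = unname(est[keep]), se = unname(sde[keep]),
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p_value = unname(pvals),
        model = "linear", n = nrow(design)
      )
    } else {
      tidy(fit_grs_logistic(design, fac, adjusted = FALSE))
    }
  })
}

#' Re-run the main associations on a sensitivity subset
#'
#' Filters the cohort (`no_hypertension`: individuals without prevalent
#' hypertension; `no_prior_ami`: individuals without a history of acute
#' myocardial infarction), recomputes GRS quartiles on the subset, and
#' refits the binary CHD model and the multinomial vessel-burden model.
#'
#' @param pheno Phenotype tibble (see [encode_covariates()]), including
#'   `hypertension` and/or `prior_ami` columns as needed.
#' @param geno A `grs_geno` tibble, oriented to risk.
#' @param panel A risk-oriented `grs_panel`.
#' @param subset `"no_hypertension"` or `"no_prior_ami"`.
#' @param score Quartile exposure, `"u"` or `"w"`.
#' @param adjusted Adjust the refitted models.
#' @return List with `subset`, `n`, `binary` (`grs_fit` for CHD),
#'   `multinomial` (`grs_multifit` for vessels), and the subset `scores`.
#' @export
run_sensitivity <- function(pheno, geno, panel,
                            subset = c("no_hypertension", "no_prior_ami"),
                            score = "u", adjusted = TRUE) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    no_hypertension = !as.logical(pheno$hypertension),
    no_prior_ami = !as.logical(pheno$prior_ami)
  )
  keep[is.na(keep)] <- FALSE
  sub_pheno <- pheno[keep, , drop = FALSE]
  sub_geno <- rebuild_geno(
    geno[geno$individual_id %in% sub_pheno$individual_id, , drop = FALSE],
    geno
  )
  if (nrow(sub_geno) < 8) abort("sensitivity subset too small for quartiles")
  scores <- compute_grs(sub_geno, panel)  # quartiles recomputed on the subset
  design <- encode_covariates(sub_pheno, scores, score = score)
  list(
    subset = subset,
    n = nrow(design),
    binary = fit_grs_logistic(design, "chd", adjusted = adjusted),
    multinomial = fit_grs_multinomial(design, "vessels", adjusted = adjusted),
    scores = scores
  )
}
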