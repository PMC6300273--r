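#' Encode the covariate design for association models
#'
#' Joins phenotypes with a score set and produces the analysis-ready design:
#' GRS quartile (factor, reference = quartile 1), age quartile (reference =
#' youngest, quartiles computed on the analysis sample), sex, smoking, BMI
#' category, diabetes, hyperlipidemia, stroke and peripheral artery disease.
#' Only complete cases on these covariates enter the design; the number of
#' dropped rows is reported.
#'
#' BMI categories follow the WHO-style bands: underweight below 18.5, normal
#' 18.5-25 (the reference), overweight above 25 up to 30, obese above 30
#' kg/m^2; boundaries 18.5, 25 and 30 fall in the lower band so the
#' categories are exhaustive and mutually exclusive.
#'
#' @param pheno Phenotype tibble with columns `individual_id`, `age`, `sex`
#'   (`"male"`/`"female"` or 0/1 with 1 = male), `smoking`, `bmi`, `diabetes`,
#'   `hyperlipidemia`, `stroke`, `pad` plus any outcome columns
#'   (`hypertension`, `chd`, `vessels`, `prior_ami`), which are carried
#'   through untouched.
#' @param scores A `grs_scores` tibble from [compute_grs()].
#' @param score Which score's quartiles define the exposure: `"u"`
#'   (unweighted, default) or `"w"`.
#' @return Tibble with factor-encoded covariates (`grs_q`, `age_q`,
#'   `bmi_cat`), the standardized scores, and the outcomes.
#' @export
encode_covariates <- function(pheno, scores, score = c("u", "w")) {
  score <- match.arg(score)
  need <- c("individual_id", "age", "sex", "smoking", "bmi", "diabetes",
            "hyperlipidemia", "stroke", "pad")
  miss <- setdiff(need, names(pheno))
  if (length(miss) > 0) {
    abort(paste0("phenotype table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  d <- dplyr::inner_join(as_tibble(pheno), as_tibble(scores),
                         by = "individual_id")
  if (nrow(d) == 0) abort("no individuals shared between phenotypes and scores")

  if (any(!is.na(d$age) & d$age < 0)) abort("negative age in phenotype table")
  if (any(!is.na(d$bmi) & d$bmi <= 0)) abort("non-positive BMI in phenotype table")

  cc <- stats::complete.cases(d[, setdiff(need, "individual_id")])
  n_drop <- sum(!cc)
  if (n_drop > 0) {
    inform(paste0("dropping ", n_drop, " individual(s) with missing covariates ",
                  "(complete-case analysis)"))
    d <- d[cc, , drop = FALSE]
  }

  sex <- d$sex
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex) == "male"
  }
  d$male <- as.integer(sex)
  q_col <- if (score == "u") d$quartile_u else d$quartile_w

  out <- d |>
    mutate(
      grs_q = factor(paste0("Q", q_col), levels = paste0("Q", 1:4)),
      age_q = factor(paste0("A", grs_quartiles(.data$age)),
                     levels = paste0("A", 1:4)),
      smoking = as.integer(d$smoking),
      bmi_cat = factor(
        dplyr::case_when(
          .data$bmi < 18.5 ~ "underweight",
          .data$bmi <= 25 ~ "normal",
          .data$bmi <= 30 ~ "overweight",
          TRUE ~ "obese"
        ),
        levels = c("normal", "underweight", "overweight", "obese")
      ),
      diabetes = as.integer(d$diabetes),
      hyperlipidemia = as.integer(d$hyperlipidemia),
      stroke = as.integer(d$stroke),
      pad = as.integer(d$pad)
    )
  attr(out, "n_dropped") <- n_drop
  out
}

adjustment_terms <- c("age_q", "male", "smoking", "bmi_cat", "diabetes",
                      "hyperlipidemia", "stroke", "pad")

assoc_formula <- function(outcome, adjusted, extra = NULL) {
  rhs <- c("grs_q", if (adjusted) adjustment_terms, extra)
  stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
}
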