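check_scoring_inputs <- function(geno, panel) {
  missing_v <- setdiff(panel$rsid, geno_variants(geno))
  if (length(missing_v) > 0) {
    abort(paste0("panel variant(s) absent from genotypes: ",
                 paste(utils::head(missing_v, 5), collapse = ", ")))
  }
  if (any(panel$beta <= 0)) {
    abort("panel is not risk-oriented (beta <= 0 present); run orient_to_risk() first")
  }
}

# dosage matrix restricted to panel variants with the missing-data policy applied
scoring_matrix <- function(geno, panel, missing = c("mean", "zero", "drop")) {
  missing <- match.arg(missing)
  m <- geno_matrix(geno)[, panel$rsid, drop = FALSE]
  if (anyNA(m)) {
    if (missing == "mean") {
      mu <- colMeans(m, na.rm = TRUE)
      mu[is.nan(mu)] <- 0
      for (j in seq_len(ncol(m))) {
        nas <- is.na(m[, j])
        if (any(nas)) m[nas, j] <- mu[j]
      }
    } else if (missing == "zero") {
      m[is.na(m)] <- 0
    }
    # "drop": leave NA so the affected individual's score is NA
  }
  m
}

#' Unweighted genetic risk score
#'
#' One point per risk allele under an additive model: for individual `i` the
#' score is the sum over panel variants of the oriented dosage `s_ij`. The
#' panel must be risk-oriented (all betas positive) so that every dosage
#' counts risk-increasing alleles.
#'
#' @param geno A `grs_geno` tibble, oriented to risk.
#' @param panel A risk-oriented `grs_panel`.
#' @param missing Missing-dosage policy at scoring time: `"mean"` (default)
#'   imputes the variant's mean observed dosage (i.e. twice its allele
#'   frequency), `"zero"` scores missing as 0 copies, `"drop"` returns `NA`
#'   for individuals with any missing panel dosage.
#' @return Tibble with `individual_id` and `score`.
#' @export
grs_unweighted <- function(geno, panel, missing = c("mean", "zero", "drop")) {
  check_scoring_inputs(geno, panel)
  m <- scoring_matrix(geno, panel, missing)
  tibble(individual_id = geno$individual_id, score = unname(rowSums(m)))
}

#' Effect-size-weighted genetic risk score
#'
#' Each risk allele is weighted by the variant's reported effect size
#' (mmHg per allele), and the weighted sum is normalized by the average
#' effect size so the score stays on the allele-count scale:
#' `wGRS_i = (N / sum(beta)) * sum_j beta_j * s_ij`.
#' With all weights equal this reduces exactly to the unweighted score, and
#' for a single-variant panel it equals the dosage itself.
#'
#' @inheritParams grs_unweighted
#' @return Tibble with `individual_id` and `score`.
#' @export
grs_weighted <- function(geno, panel, missing = c("mean", "zero", "drop")) {
  check_scoring_inputs(geno, panel)
  beta_sum <- sum(panel$beta)
  if (beta_sum <= 0) abort("sum of effect sizes must be positive to normalize")
  m <- scoring_matrix(geno, panel, missing)
  w <- m %*% panel$beta
  tibble(
    individual_id = geno$individual_id,
    score = unname(drop(w)) * nrow(panel) / beta_sum
  )
}

#' Standardize scores to mean zero and unit standard deviation
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation. Missing
#' values are ignored when computing the moments and propagate through.
#'
#' @param x Numeric vector with at least two non-missing values.
#' @return Standardized numeric vector.
#' @export
grs_standardize <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) abort("need at least 2 observations to standardize")
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0) {
    abort("zero variance: score cannot be standardized")
  }
  (x - mean(obs)) / s
}

#' Assign quartiles of a score
#'
#' Individuals are ranked ascending and cut at the empirical 25th, 50th and
#' 75th percentiles (nearest-rank, i.e. `quantile(type = 1)`). Tied values
#' share a quartile: every individual at a cut-point value falls in the lower
#' interval. Quartile 1 holds the lowest scores and is the conventional
#' reference. Assignments are invariant under strictly increasing transforms
#' of the score, so raw and standardized scores give identical labels.
#'
#' @param x Numeric vector with at least 4 distinct non-missing values.
#' @return Integer vector of labels in 1..4 (`NA` where `x` is `NA`).
#' @export
grs_quartiles <- function(x) {
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < 4) {
    abort("need at least 4 distinct values to form quartiles")
  }
  cuts <- stats::quantile(obs, probs = c(0.25, 0.5, 0.75), type = 1,
                          names = FALSE)
  1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
}

#' Compute the full score set for a cohort
#'
#' Computes raw and standardized unweighted and weighted scores plus their
#' quartile labels in one pass, optionally restricted to a single
#' blood-pressure trait's sub-panel.
#'
#' @inheritParams grs_unweighted
#' @param trait `"ALL"` (default) for the combined panel, or one of `"SBP"`,
#'   `"DBP"`, `"PP"` to score that trait's sub-panel.
#' @return A `grs_scores` tibble with columns `individual_id`, `ugrs_raw`,
#'   `wgrs_raw`, `ugrs_std`, `wgrs_std`, `quartile_u`, `quartile_w`, `trait`;
#'   the panel size is attached as attribute `panel_n`.
#' @export
compute_grs <- function(geno, panel, trait = "ALL",
                        missing = c("mean", "zero", "drop")) {
  trait <- toupper(trait)
  if (trait != "ALL") panel <- subset_by_trait(panel, trait)
  u <- grs_unweighted(geno, panel, missing)
  w <- grs_weighted(geno, panel, missing)
  out <- tibble(
    individual_id = u$individual_id,
    ugrs_raw = u$score,
    wgrs_raw = w$score,
    ugrs_std = grs_standardize(u$score),
    wgrs_std = grs_standardize(w$score),
    quartile_u = grs_quartiles(u$score),
    quartile_w = grs_quartiles(w$score),
    trait = trait
  )
  attr(out, "panel_n") <- nrow(panel)
  class(out) <- unique(c("grs_scores", class(out)))
  out
}

#' @export
print.grs_scores <- function(x, ...) {
  cat(sprintf("<grs_scores> %d individuals, panel of %s variants (trait %s)\n",
              nrow(x), attr(x, "panel_n") %||% "?", x$trait[1]))
  NextMethod()
}

#' Quartile counts and medians in descriptive-table layout
#'
#' @param scores A `grs_scores` tibble.
#' @return Tibble with one row per score type and quartile: counts,
#'   percentages, and the raw-score range of each quartile.
#' @export
score_descriptives <- function(scores) {
  long <- dplyr::bind_rows(
    tibble(score_type = "uGRS", raw = scores$ugrs_raw, q = scores$quartile_u),
    tibble(score_type = "wGRS", raw = scores$wgrs_raw, q = scores$quartile_w)
  )
  long |>
    group_by(.data$score_type, .data$q) |>
    summarise(
      n = dplyr::n(),
      min = min(.data$raw), max = max(.data$raw),
      median = stats::median(.data$raw),
      .groups = "drop_last"
    ) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
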