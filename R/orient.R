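#' Orient panel and dosages so every effect allele is the risk allele
#'
#' Harmonizes each panel variant against the genotype allele coding (allowing
#' an effect/other swap, in which case dosages are flipped to `2 - s`), then
#' orients the effect direction: variants with a negative combined effect size
#' have their alleles swapped, all trait betas negated, and dosages flipped,
#' so that after orientation every beta is positive and the dosage counts
#' risk-increasing alleles. Risk orientation ignores allele frequency: the
#' risk allele may well be the major allele.
#'
#' The operation is idempotent, and any score computed downstream changes only
#' by the affine transform the flip implies (a flipped variant contributes
#' `beta * (2 - s)` instead of `-beta * s`).
#'
#' @param geno A `grs_geno` tibble.
#' @param panel A `grs_panel` whose variants are all present in `geno`.
#' @return A list with elements `genotypes` and `panel`, both oriented.
#' @export
orient_to_risk <- function(geno, panel) {
  missing_v <- setdiff(panel$rsid, geno_variants(geno))
  if (length(missing_v) > 0) {
    abort(paste0("panel variant(s) absent from genotypes: ",
                 paste(utils::head(missing_v, 5), collapse = ", ")))
  }
  if (any(panel$beta == 0)) {
    abort(paste0("beta is exactly 0 (no risk direction) for: ",
                 paste(panel$rsid[panel$beta == 0], collapse = ", ")))
  }

  al <- geno_alleles(geno)
  gi <- match(panel$rsid, al$rsid)
  same <- al$effect_allele[gi] == panel$effect_allele &
    al$other_allele[gi] == panel$other_allele
  swapped <- al$effect_allele[gi] == panel$other_allele &
    al$other_allele[gi] == panel$effect_allele
  if (any(!(same | swapped))) {
    bad <- panel$rsid[!(same | swapped)]
    abort(paste0("alleles match neither orientation for: ",
                 paste(bad, collapse = ", ")))
  }

  # net flip: dosage must count the panel effect allele AND beta must be > 0
  flip_harmon <- swapped            # genotype coding counts panel's other allele
  flip_risk <- panel$beta < 0       # effect direction points the wrong way
  flip <- xor(flip_harmon, flip_risk)

  # panel side: risk-flip swaps alleles and negates every beta
  if (any(flip_risk)) {
    i <- which(flip_risk)
    ea <- panel$effect_allele[i]
    panel$effect_allele[i] <- panel$other_allele[i]
    panel$other_allele[i] <- ea
    for (col in c("beta_sbp", "beta_dbp", "beta_pp", "beta")) {
      panel[[col]][i] <- -panel[[col]][i]
    }
    neg_trait <- panel$beta_sbp[i] < 0 | panel$beta_dbp[i] < 0 |
      panel$beta_pp[i] < 0
    neg_trait[is.na(neg_trait)] <- FALSE
    if (any(neg_trait)) {
      warn(paste0("trait betas disagree in sign after orientation for: ",
                  paste(panel$rsid[i][neg_trait], collapse = ", ")))
    }
  }

  # genotype side: flip dosages and allele coding where needed
  if (any(flip)) {
    for (k in which(flip)) {
      id <- panel$rsid[k]
      geno[[id]] <- 2 - geno[[id]]
    }
    al2 <- attr(geno, "alleles")
    j <- match(panel$rsid[flip], al2$rsid)
    ea <- al2$effect_allele[j]
    al2$effect_allele[j] <- al2$other_allele[j]
    al2$other_allele[j] <- ea
    attr(geno, "alleles") <- al2
  }

  list(genotypes = geno, panel = panel)
}
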