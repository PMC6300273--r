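qc_report_row <- function(stage, type, id, metric, value, excluded) {
  tibble(stage = stage, type = type, id = id, metric = metric,
         value = value, excluded = excluded)
}

#' Remove variants with excessive missingness
#'
#' A variant whose fraction of missing dosages exceeds `max_missing`
#' (strictly) is dropped; a variant missing in exactly the threshold fraction
#' is kept.
#'
#' @param geno A `grs_geno` tibble.
#' @param max_missing Maximum tolerated missing fraction per variant.
#' @return List with `genotypes` (filtered) and `report`, a tibble recording
#'   every variant's missingness and whether it was excluded.
#' @export
filter_variant_missingness <- function(geno, max_missing = 0.05) {
  m <- geno_matrix(geno)
  miss <- colMeans(is.na(m))
  drop <- miss > max_missing
  report <- qc_report_row("variant_missingness", "variant", colnames(m),
                          "missing_fraction", unname(miss), unname(drop))
  keep_cols <- c("individual_id", colnames(m)[!drop])
  list(
    genotypes = rebuild_geno(geno[, keep_cols, drop = FALSE], geno),
    report = report
  )
}

#' Remove samples with a low call rate
#'
#' An individual observed at fewer than `min_callrate` of the variants
#' (strictly below) is dropped; exactly at the threshold is kept.
#'
#' @param geno A `grs_geno` tibble.
#' @param min_callrate Minimum tolerated non-missing fraction per sample.
#' @return List with `genotypes` and `report` as in
#'   [filter_variant_missingness()].
#' @export
filter_sample_callrate <- function(geno, min_callrate = 0.95) {
  m <- geno_matrix(geno)
  callrate <- rowMeans(!is.na(m))
  drop <- callrate < min_callrate
  report <- qc_report_row("sample_callrate", "sample", rownames(m),
                          "call_rate", unname(callrate), unname(drop))
  list(
    genotypes = rebuild_geno(geno[!drop, , drop = FALSE], geno),
    report = report
  )
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Tests observed genotype counts against the proportions `p^2, 2pq, q^2`
#' expected under random mating at the observed allele frequency. The default
#' is the 1-df chi-square goodness-of-fit test without continuity correction;
#' `method = "exact"` gives the conditional exact test (enumeration of all
#' heterozygote counts compatible with the observed allele counts), summing
#' the probabilities of tables no more likely than the observed one, with an
#' optional mid-p variant.
#'
#' @param n_AA,n_Aa,n_aa Non-negative integer genotype counts (vectors are
#'   accepted and tested element-wise).
#' @param method `"chisq"` (default) or `"exact"`.
#' @param midp For the exact test, count only half the probability of the
#'   observed table.
#' @return P-value(s) in \[0, 1\]. A monomorphic variant (allele frequency 0
#'   or 1) returns 1 with a warning: no departure from equilibrium is
#'   observable.
#' @export
#' @examples
#' hwe_test(25, 50, 25)          # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)           # no heterozygotes at p = 0.5: extreme
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact"),
                     midp = FALSE) {
  method <- match.arg(method)
  k <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(n_AA, k); n_Aa <- rep_len(n_Aa, k); n_aa <- rep_len(n_aa, k)
  counts <- cbind(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  if (any(rowSums(counts) < 1)) abort("total genotype count must be >= 1")

  vapply(seq_len(k), function(i) {
    nAA <- counts[i, 1]; nAa <- counts[i, 2]; naa <- counts[i, 3]
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    p <- nA / (2 * n)
    if (p == 0 || p == 1) {
      warn("monomorphic variant: HWE p-value defined as 1")
      return(1)
    }
    if (method == "chisq") {
      expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
      x2 <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
      stats::pchisq(x2, df = 1, lower.tail = FALSE)
    } else {
      hwe_exact_p(nAA, nAa, naa, midp = midp)
    }
  }, numeric(1))
}

# conditional exact test: P(het count) given allele counts, enumerated over
# all heterozygote counts with the parity of nA
hwe_exact_p <- function(nAA, nAa, naa, midp = FALSE) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nB <- 2 * n - nA
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- (nB - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == nAa)
  tail_pr <- pr[pr <= pr[obs] * (1 + 1e-12)]
  p <- sum(tail_pr)
  if (midp) p <- p - pr[obs] / 2
  min(max(p, 0), 1)
}

#' Filter variants failing Hardy-Weinberg equilibrium
#'
#' Dosages are first reduced to hard calls ([hard_calls()]); variants whose
#' HWE p-value falls below `alpha` (strict) are removed. Variants with no
#' callable genotypes are left untouched.
#'
#' @param geno A `grs_geno` tibble.
#' @param alpha Significance threshold; `alpha = 0` removes nothing.
#' @param method Passed to [hwe_test()].
#' @return List with `genotypes` and `report` (per-variant HWE p-values).
#' @export
filter_hwe <- function(geno, alpha = 1e-4, method = c("chisq", "exact")) {
  method <- match.arg(method)
  hc <- hard_calls(geno)
  vids <- colnames(hc)
  pvals <- vapply(seq_along(vids), function(j) {
    g <- hc[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    suppressWarnings(
      hwe_test(sum(g == 2), sum(g == 1), sum(g == 0), method = method)
    )
  }, numeric(1))
  drop <- !is.na(pvals) & pvals < alpha
  report <- qc_report_row("hwe", "variant", vids, "hwe_p", pvals, drop)
  keep_cols <- c("individual_id", vids[!drop])
  list(
    genotypes = rebuild_geno(geno[, keep_cols, drop = FALSE], geno),
    report = report
  )
}

#' Run the standard genotype QC sequence
#'
#' Applies, in order: variant missingness, sample call rate, and
#' Hardy-Weinberg filtering, with the conventional thresholds (>5% variant
#' missingness, <95% sample call rate, HWE p < 1e-4) as defaults.
#'
#' @param geno A `grs_geno` tibble.
#' @param max_missing,min_callrate,hwe_alpha Stage thresholds.
#' @return List with `genotypes` (post-QC) and `report` (all stages bound,
#'   in application order).
#' @export
run_genotype_qc <- function(geno, max_missing = 0.05, min_callrate = 0.95,
                            hwe_alpha = 1e-4) {
  s1 <- filter_variant_missingness(geno, max_missing)
  s2 <- filter_sample_callrate(s1$genotypes, min_callrate)
  s3 <- filter_hwe(s2$genotypes, hwe_alpha)
  list(
    genotypes = s3$genotypes,
    report = bind_rows(s1$report, s2$report, s3$report)
  )
}
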