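#' Exclude panel variants with a low minor allele count
#'
#' The minor allele count (MAC) at a variant is
#' `min(sum(dosage), 2 * n_nonmissing - sum(dosage))` over non-missing
#' entries — an imputation-aware tally in which hard calls are the rounded
#' special case. Variants with `MAC < threshold` (strict) are removed from
#' the panel and logged; a MAC exactly at the threshold is kept.
#'
#' @param panel A `grs_panel`.
#' @param geno A `grs_geno` covering every panel variant.
#' @param threshold Minimum (inclusive) minor allele count to retain.
#' @return The filtered panel, removals logged under rule `mac`.
#' @export
filter_mac <- function(panel, geno, threshold = 20) {
  stopifnot(threshold >= 0)
  missing_v <- setdiff(panel$rsid, geno_variants(geno))
  if (length(missing_v) > 0) {
    abort(paste0("panel variant(s) absent from genotypes: ",
                 paste(utils::head(missing_v, 5), collapse = ", ")))
  }
  m <- geno_matrix(geno)[, panel$rsid, drop = FALSE]
  s <- colSums(m, na.rm = TRUE)
  nn <- colSums(!is.na(m))
  mac <- pmin(s, 2 * nn - s)
  drop <- mac < threshold
  out <- restore_panel(panel[!drop, , drop = FALSE], panel)
  log_exclusions(out, panel$rsid[drop], "mac", format(mac[drop]),
                 stage = "filter_mac")
}

#' Prune panel variants in linkage disequilibrium
#'
#' Pairwise LD is measured as the squared Pearson correlation of dosages
#' across individuals (pairwise-complete observations). From each pair with
#' r-squared at or above the threshold, the variant with the smaller absolute
#' effect size is removed; on a tie the variant later in panel order goes, so
#' the result is deterministic given panel order. Zero-variance variants are
#' excluded from correlation with a warning and are never removed by this
#' rule.
#'
#' @param panel A `grs_panel`.
#' @param geno A `grs_geno` covering every panel variant.
#' @param r2_threshold Squared-correlation threshold at (and above) which a
#'   pair counts as correlated.
#' @return The pruned panel, removals logged under rule `ld_prune`.
#' @export
ld_prune <- function(panel, geno, r2_threshold = 0.8) {
  if (nrow(panel) < 2) return(panel)
  m <- geno_matrix(geno)[, panel$rsid, drop = FALSE]
  v <- apply(m, 2, stats::var, na.rm = TRUE)
  zerovar <- !is.finite(v) | v == 0
  if (any(zerovar)) {
    warn(paste0("zero-variance variant(s) excluded from LD computation: ",
                paste(panel$rsid[zerovar], collapse = ", ")))
  }
  usable <- which(!zerovar)
  removed <- logical(nrow(panel))
  r2_removed <- numeric(nrow(panel))
  if (length(usable) >= 2) {
    cc <- suppressWarnings(
      stats::cor(m[, usable, drop = FALSE], use = "pairwise.complete.obs")
    )
    r2 <- cc^2
    for (a in seq_along(usable)) {
      for (b in seq_along(usable)) {
        if (b <= a) next
        i <- usable[a]; j <- usable[b]
        if (removed[i] || removed[j]) next
        if (is.na(r2[a, b]) || r2[a, b] < r2_threshold) next
        victim <- if (abs(panel$beta[i]) < abs(panel$beta[j])) i else j
        removed[victim] <- TRUE
        r2_removed[victim] <- r2[a, b]
      }
    }
  }
  out <- restore_panel(panel[!removed, , drop = FALSE], panel)
  log_exclusions(out, panel$rsid[removed], "ld_prune",
                 format(r2_removed[removed]), stage = "ld_prune")
}
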