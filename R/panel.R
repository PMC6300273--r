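#' Read a blood-pressure SNP panel from TSV
#'
#' Loads the variant panel that defines the genetic risk score. The file is
#' tab-separated with columns `rsid`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `beta_sbp`, `beta_dbp`, `beta_pp`, `traits` (comma-joined
#' subset of `SBP,DBP,PP`), and optional `proxy_of`, `proxy_r2`. Each variant
#' must carry an effect size (mmHg per effect allele) for every trait it is a
#' member of; an empty cell means "not applicable".
#'
#' A combined per-variant effect size column `beta` is derived as the member
#' trait beta with the largest absolute value (multi-trait variants keep the
#' strongest signal); trait-specific scores use [subset_by_trait()] instead.
#'
#' @param path Path to the panel TSV.
#' @return A `grs_panel` tibble (one row per variant) with an attached,
#'   initially empty, exclusion log retrievable via [panel_exclusions()].
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "rsid\tchrom\tpos\teffect_allele\tother_allele\tbeta_sbp\tbeta_dbp\tbeta_pp\ttraits",
#'   "rs1\t1\t1000\tA\tG\t0.45\t\t\tSBP",
#'   "rs2\t2\t2000\tC\tT\t\t0.30\t0.21\tDBP,PP"
#' ), tsv)
#' panel <- read_panel(tsv)
#' panel$beta
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      rsid = readr::col_character(),
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      effect_allele = readr::col_character(),
      other_allele = readr::col_character(),
      beta_sbp = readr::col_double(),
      beta_dbp = readr::col_double(),
      beta_pp = readr::col_double(),
      traits = readr::col_character(),
      .default = readr::col_guess()
    ),
    na = c("", "NA"), progress = FALSE
  )
  required <- c(
    "rsid", "chrom", "pos", "effect_allele", "other_allele",
    "beta_sbp", "beta_dbp", "beta_pp", "traits"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("panel TSV lacks required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"proxy_of" %in% names(raw)) raw$proxy_of <- NA_character_
  if (!"proxy_r2" %in% names(raw)) raw$proxy_r2 <- NA_real_
  raw$proxy_of <- as.character(raw$proxy_of)
  raw$proxy_r2 <- as.numeric(raw$proxy_r2)

  as_panel(raw)
}

#' Build a panel from an in-memory data frame
#'
#' Validates the same contract as [read_panel()]: unique rsids, known trait
#' labels, alleles present and distinct, and an effect size for every member
#' trait. Used directly by the cohort simulator.
#'
#' @param df Data frame with the panel TSV columns.
#' @return A `grs_panel` tibble.
#' @export
as_panel <- function(df) {
  df <- as_tibble(df)
  n <- nrow(df)
  if (!"proxy_of" %in% names(df)) df$proxy_of <- NA_character_
  if (!"proxy_r2" %in% names(df)) df$proxy_r2 <- NA_real_
  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup) > 0) {
    abort(paste0("duplicate rsid(s) in panel: ", paste(dup, collapse = ", ")))
  }

  trait_list <- stringr::str_split(df$traits %||% NA_character_, ",")
  trait_list <- lapply(trait_list, function(x) stringr::str_trim(x[x != ""]))
  unknown <- setdiff(unique(unlist(trait_list)), c(VALID_TRAITS, NA))
  if (length(unknown) > 0) {
    abort(paste0("unknown trait label(s): ", paste(unknown, collapse = ", "),
                 " (expected SBP, DBP, PP)"))
  }
  empty_traits <- which(vapply(trait_list, length, 1L) == 0L | is.na(df$traits))
  if (length(empty_traits) > 0) {
    abort(paste0("rows with empty trait membership: row ",
                 paste(empty_traits, collapse = ", ")))
  }

  bad_allele <- which(
    is.na(df$effect_allele) | is.na(df$other_allele) |
      df$effect_allele == df$other_allele
  )
  if (length(bad_allele) > 0) {
    abort(paste0("missing or identical alleles at row ",
                 paste(bad_allele, collapse = ", ")))
  }

  beta_cols <- c(SBP = "beta_sbp", DBP = "beta_dbp", PP = "beta_pp")
  beta_mat <- as.matrix(df[, beta_cols])
  bad_beta <- vapply(seq_len(n), function(i) {
    any(is.na(beta_mat[i, match(trait_list[[i]], names(beta_cols))]))
  }, logical(1))
  if (any(bad_beta)) {
    abort(paste0("missing beta for a member trait at row ",
                 paste(which(bad_beta), collapse = ", ")))
  }

  # combined beta: member-trait beta of largest magnitude (signed)
  df$beta <- vapply(seq_len(n), function(i) {
    b <- beta_mat[i, match(trait_list[[i]], names(beta_cols))]
    b[which.max(abs(b))]
  }, numeric(1))

  bad_proxy <- !is.na(df$proxy_of) & (is.na(df$proxy_r2) | df$proxy_r2 <= 0.8)
  if (any(bad_proxy)) {
    abort(paste0("proxy_of set with proxy_r2 <= 0.8 at row ",
                 paste(which(bad_proxy), collapse = ", ")))
  }

  attr(df, "exclusions") <- new_exclusion_log()
  attr(df, "trait") <- "ALL"
  class(df) <- unique(c("grs_panel", class(df)))
  df
}

#' Retrieve the append-only exclusion log of a panel
#'
#' Every variant removed by a panel or QC operation is recorded exactly once
#' with the rule that removed it, the triggering value, and the pipeline stage.
#'
#' @param panel A `grs_panel`.
#' @return Tibble with columns `rsid`, `rule`, `value`, `stage`.
#' @export
panel_exclusions <- function(panel) {
  attr(panel, "exclusions") %||% new_exclusion_log()
}

#' @export
print.grs_panel <- function(x, ...) {
  cat(sprintf("<grs_panel> %d variants (trait: %s, %d logged exclusions)\n",
              nrow(x), attr(x, "trait") %||% "ALL", nrow(panel_exclusions(x))))
  NextMethod()
}

#' Restrict a panel to one blood-pressure trait
#'
#' Keeps only variants whose trait membership includes `trait` and swaps the
#' combined `beta` for that trait's effect size, so scores computed downstream
#' are trait-specific (SBP, DBP or pulse-pressure sub-scores). A variant that
#' belongs to several traits appears in each trait's panel.
#'
#' @param panel A `grs_panel`.
#' @param trait One of `"SBP"`, `"DBP"`, `"PP"`.
#' @return A `grs_panel` restricted to the trait, with `beta` set to the
#'   trait-specific effect size.
#' @export
subset_by_trait <- function(panel, trait) {
  trait <- match.arg(toupper(trait), VALID_TRAITS)
  beta_col <- c(SBP = "beta_sbp", DBP = "beta_dbp", PP = "beta_pp")[[trait]]
  member <- vapply(
    stringr::str_split(panel$traits, ","),
    function(x) trait %in% stringr::str_trim(x), logical(1)
  )
  out <- panel[member, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(paste0("no panel variants belong to trait ", trait))
  }
  out$beta <- out[[beta_col]]
  out <- restore_panel(out, panel)
  attr(out, "trait") <- trait
  out
}

#' Substitute proxies for panel variants absent from the genotype data
#'
#' Index SNPs missing from `genotyped_ids` are replaced by a proxy in high
#' linkage disequilibrium (r-squared > 0.8) when the proxy map offers one that
#' was genotyped; the best available proxy (largest r-squared) is taken.
#' Missing index SNPs without a qualifying genotyped proxy are dropped and
#' logged (`no_proxy`, or `proxy_not_genotyped` when a qualifying proxy exists
#' but was itself not genotyped). Substituted rows keep the index variant's
#' effect sizes and alleles (the proxy's dosages are assumed aligned to the
#' index risk allele) and record `proxy_of` and `proxy_r2`.
#'
#' @param panel A `grs_panel`.
#' @param proxy_map Data frame with columns `index_rsid`, `proxy_rsid`, `r2`
#'   (r-squared in (0, 1]).
#' @param genotyped_ids Character vector of rsids present in the genotype data.
#' @param r2_threshold Minimum (exclusive) r-squared for a proxy to qualify.
#' @return The panel with substitutions applied and drops logged.
#' @export
resolve_proxies <- function(panel, proxy_map, genotyped_ids, r2_threshold = 0.8) {
  proxy_map <- as_tibble(proxy_map)
  stopifnot(all(c("index_rsid", "proxy_rsid", "r2") %in% names(proxy_map)))
  if (any(proxy_map$r2 <= 0 | proxy_map$r2 > 1)) {
    abort("proxy map r2 values must lie in (0, 1]")
  }

  absent <- setdiff(panel$rsid, genotyped_ids)
  if (length(absent) == 0) return(panel)

  drop_ids <- character()
  drop_rule <- character()
  drop_val <- character()
  for (id in absent) {
    cand <- proxy_map[proxy_map$index_rsid == id & proxy_map$r2 > r2_threshold, ]
    cand <- cand[order(-cand$r2), ]
    usable <- cand[cand$proxy_rsid %in% genotyped_ids, ]
    if (nrow(usable) > 0) {
      i <- which(panel$rsid == id)
      panel$proxy_of[i] <- id
      panel$proxy_r2[i] <- usable$r2[[1]]
      panel$rsid[i] <- usable$proxy_rsid[[1]]
    } else if (nrow(cand) > 0) {
      drop_ids <- c(drop_ids, id)
      drop_rule <- c(drop_rule, "proxy_not_genotyped")
      drop_val <- c(drop_val, format(cand$r2[[1]]))
    } else {
      drop_ids <- c(drop_ids, id)
      drop_rule <- c(drop_rule, "no_proxy")
      drop_val <- c(drop_val, NA_character_)
    }
  }

  out <- panel[!panel$rsid %in% drop_ids, , drop = FALSE]
  out <- restore_panel(out, panel)
  for (k in seq_along(drop_ids)) {
    out <- log_exclusions(out, drop_ids[k], drop_rule[k], drop_val[k],
                          stage = "resolve_proxies")
  }
  out
}

#' Flag strand-ambiguous (A/T, C/G) variants
#'
#' Palindromic SNPs cannot be strand-checked against a reference; by default
#' they are retained with a warning (panel and genotypes are assumed
#' harmonized to one genome build), or dropped when `drop = TRUE`.
#'
#' @param panel A `grs_panel`.
#' @param drop Drop ambiguous variants instead of keeping them.
#' @return The panel, possibly with ambiguous variants removed and logged.
#' @export
check_ambiguous <- function(panel, drop = FALSE) {
  pair <- paste(pmin(panel$effect_allele, panel$other_allele),
                pmax(panel$effect_allele, panel$other_allele))
  amb <- pair %in% c("A T", "C G")
  if (!any(amb)) return(panel)
  if (!drop) {
    warn(paste0(sum(amb), " strand-ambiguous variant(s) retained: ",
                paste(panel$rsid[amb], collapse = ", ")))
    return(panel)
  }
  out <- restore_panel(panel[!amb, , drop = FALSE], panel)
  log_exclusions(out, panel$rsid[amb], "strand_ambiguous", pair[amb],
                 stage = "check_ambiguous")
}
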