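#' Genotype dosage tables
#'
#' Genotypes are held in a wide tibble: one `individual_id` column plus one
#' numeric column per variant holding the dosage (expected count of the
#' effect allele, in \[0, 2\], `NA` where missing). The per-variant allele
#' coding — which allele the dosage counts, and the other allele — travels in
#' an `alleles` attribute and is retrievable with [geno_alleles()].
#'
#' @param df Data frame with an `individual_id` column and numeric dosage
#'   columns named by rsid.
#' @param alleles Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, one row per dosage column.
#' @return A `grs_geno` tibble.
#' @export
as_geno <- function(df, alleles) {
  df <- as_tibble(df)
  if (!"individual_id" %in% names(df)) {
    abort("genotype table needs an 'individual_id' column")
  }
  df$individual_id <- as.character(df$individual_id)
  if (anyDuplicated(df$individual_id)) abort("duplicate individual_id")
  vids <- setdiff(names(df), "individual_id")
  if (anyDuplicated(vids)) abort("duplicate variant columns")
  dm <- as.matrix(df[, vids, drop = FALSE])
  if (!is.numeric(dm)) abort("dosage columns must be numeric")
  rng <- range(dm, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    abort("dosages must lie in [0, 2]")
  }
  alleles <- as_tibble(alleles)
  stopifnot(all(c("rsid", "effect_allele", "other_allele") %in% names(alleles)))
  missing_ref <- setdiff(vids, alleles$rsid)
  if (length(missing_ref) > 0) {
    abort(paste0("no allele coding for variant(s): ",
                 paste(utils::head(missing_ref, 5), collapse = ", ")))
  }
  attr(df, "alleles") <- alleles[match(vids, alleles$rsid), ]
  class(df) <- unique(c("grs_geno", class(df)))
  df
}

#' @rdname as_geno
#' @param geno A `grs_geno` tibble.
#' @export
geno_alleles <- function(geno) attr(geno, "alleles")

#' @rdname as_geno
#' @export
geno_variants <- function(geno) setdiff(names(geno), "individual_id")

# dosage columns as a plain numeric matrix, individuals in rows
geno_matrix <- function(geno) {
  m <- as.matrix(geno[, geno_variants(geno), drop = FALSE])
  rownames(m) <- geno$individual_id
  m
}

# rebuild a grs_geno after subsetting columns/rows of the tibble
rebuild_geno <- function(df, template) {
  as_geno(df, geno_alleles(template))
}

#' @export
print.grs_geno <- function(x, ...) {
  cat(sprintf("<grs_geno> %d individuals x %d variants\n",
              nrow(x), length(geno_variants(x))))
  NextMethod()
}

#' Read a dosage matrix from TSV
#'
#' The TSV has an `individual_id` column and one column per rsid. Allele
#' codings are supplied separately (or taken from a panel).
#'
#' @param path Path to the dosage TSV.
#' @param alleles Data frame of allele codings as in [as_geno()]; when `NULL`
#'   and `panel` is given, the panel's effect/other alleles are used.
#' @param panel Optional `grs_panel` supplying allele codings.
#' @return A `grs_geno` tibble.
#' @export
read_dosage_tsv <- function(path, alleles = NULL, panel = NULL) {
  if (is.null(alleles)) {
    if (is.null(panel)) abort("supply either 'alleles' or 'panel'")
    alleles <- panel[, c("rsid", "effect_allele", "other_allele")]
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = readr::col_character(), .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
  as_geno(df, alleles)
}

#' Read genotype dosages from a VCF
#'
#' Biallelic records only. The dosage counts copies of the ALT allele
#' (effect allele = ALT, other allele = REF). When a `DS` FORMAT field is
#' present its value is used; entries without `DS` fall back to the hard-call
#' `GT`, and missing `GT`/`DS` become missing dosages.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @return A `grs_geno` tibble, individuals in rows and variants in columns.
#' @export
read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    where <- paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])
    abort(paste0("multiallelic record(s) not supported: ",
                 paste(utils::head(where, 5), collapse = ", ")))
  }
  ids <- fix[, "ID"]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate variant id(s) in VCF: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  allele_counts <- function(g) {
    g <- sub(":.*", "", g)
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      if (length(x) == 0 || anyNA(x) || any(x == "." | x == "")) {
        return(NA_real_)
      }
      sum(x == "1")
    }, numeric(1))
  }
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  for (j in seq_len(ncol(gt))) dos[, j] <- allele_counts(gt[, j])

  fmt_has_ds <- grepl("(^|:)DS(:|$)", v@gt[, "FORMAT"])
  if (any(fmt_has_ds)) {
    ds <- suppressWarnings(
      vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    )
    use <- !is.na(ds)
    dos[use] <- ds[use]
  }

  df <- as_tibble(t(dos))
  df <- tibble(individual_id = colnames(gt)) |> dplyr::bind_cols(df)
  names(df) <- c("individual_id", ids)
  alleles <- tibble(
    rsid = ids,
    effect_allele = unname(fix[, "ALT"]),
    other_allele = unname(fix[, "REF"])
  )
  as_geno(df, alleles)
}

#' Round dosages to hard genotype calls
#'
#' Dosages within `tol` of an integer are rounded to it; anything farther is
#' treated as missing. Hardy-Weinberg testing operates on these calls, since
#' equilibrium proportions are defined for discrete genotypes.
#'
#' @param geno A `grs_geno` tibble.
#' @param tol Maximum distance from an integer for a dosage to be called.
#' @return Integer matrix (individuals x variants) with values 0/1/2 or `NA`.
#' @export
hard_calls <- function(geno, tol = 0.1) {
  m <- geno_matrix(geno)
  r <- round(m)
  r[abs(m - r) > tol] <- NA_real_
  storage.mode(r) <- "integer"
  r
}
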