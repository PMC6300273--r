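# small in-code fixtures and independent oracles shared across tests

make_panel_df <- function(n, beta = NULL, traits = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- round(runif(n, 0.1, 1), 3)
  if (is.null(traits)) traits <- sample(c("SBP", "DBP", "PP"), n, replace = TRUE)
  tibble::tibble(
    rsid = paste0("rs", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000L,
    effect_allele = rep_len(c("A", "C", "G", "T"), n),
    other_allele = rep_len(c("G", "T", "A", "C"), n),
    beta_sbp = ifelse(traits == "SBP", beta, NA_real_),
    beta_dbp = ifelse(traits == "DBP", beta, NA_real_),
    beta_pp = ifelse(traits == "PP", beta, NA_real_),
    traits = traits
  )
}

make_geno <- function(dosage, panel, ids = NULL) {
  # dosage: matrix individuals x variants, columns ordered as panel rows
  n <- nrow(dosage)
  if (is.null(ids)) ids <- paste0("i", seq_len(n))
  df <- tibble::as_tibble(as.data.frame(dosage))
  names(df) <- panel$rsid
  as_geno(
    dplyr::bind_cols(tibble::tibble(individual_id = ids), df),
    panel[, c("rsid", "effect_allele", "other_allele")]
  )
}

write_panel_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, na = "")
  path
}

# independent double-loop GRS oracles (deliberately naive)
oracle_ugrs <- function(dosage) {
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    s <- 0
    for (j in seq_len(ncol(dosage))) s <- s + dosage[i, j]
    out[i] <- s
  }
  out
}

oracle_wgrs <- function(dosage, beta) {
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    s <- 0
    for (j in seq_len(ncol(dosage))) s <- s + beta[j] * dosage[i, j]
    out[i] <- s * length(beta) / sum(beta)
  }
  out
}

# independent exact HWE test: enumerate heterozygote counts at fixed allele
# counts using exact rational-ish arithmetic via choose()
oracle_hwe_exact <- function(nAA, nAa, naa, midp = FALSE) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  prob_het <- function(h) {
    a <- (nA - h) / 2
    b <- n - a - h
    exp(lchoose(n, a) + lchoose(n - a, h) + h * log(2) -
          (lchoose(2 * n, nA)))
  }
  pr <- vapply(hets, prob_het, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == nAa]
  sum(pr[pr <= obs * (1 + 1e-12)]) - if (midp) obs / 2 else 0
}

# aggregate a design to exposure-cell counts for fast weighted refits
aggregate_binary <- function(q, y) {
  tb <- as.data.frame(table(grs_q = q, y = y))
  tb <- tb[tb$Freq > 0, ]
  tibble::tibble(
    grs_q = factor(tb$grs_q, levels = levels(q)),
    y = as.integer(as.character(tb$y)),
    w = tb$Freq
  )
}
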