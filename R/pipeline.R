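#' Assemble a validated run configuration
#'
#' Collects input paths (or a simulation config), analysis switches, and QC
#' thresholds for [run_pipeline()]. Exactly one of the real-input mode
#' (`panel` path plus `vcf`/`dosage_tsv` plus `pheno`) or simulation mode
#' (`simulation`) must be supplied. A YAML file with the same field names can
#' be read via `yaml::read_yaml()` and spliced in with `do.call()`.
#'
#' @param panel,vcf,dosage_tsv,pheno,proxy_map Input file paths (real mode).
#' @param simulation A [sim_config()] (simulation mode).
#' @param score Quartile exposure: `"u"`, `"w"`, or `"both"`.
#' @param trait `"ALL"` or one of `"SBP"`, `"DBP"`, `"PP"`.
#' @param subset `"all"`, `"no_hypertension"`, or `"no_prior_ami"`.
#' @param mac,max_missing,min_callrate,hwe_alpha,ld_r2 QC thresholds.
#' @param seed Integer seed recorded in the manifest.
#' @return A `grs_run_config` list.
#' @export
grs_config <- function(panel = NULL, vcf = NULL, dosage_tsv = NULL,
                       pheno = NULL, proxy_map = NULL, simulation = NULL,
                       score = c("u", "w", "both"), trait = "ALL",
                       subset = c("all", "no_hypertension", "no_prior_ami"),
                       mac = 20, max_missing = 0.05, min_callrate = 0.95,
                       hwe_alpha = 1e-4, ld_r2 = 0.8, seed = 1L) {
  score <- match.arg(score)
  subset <- match.arg(subset)
  real_mode <- !is.null(panel)
  sim_mode <- !is.null(simulation)
  if (real_mode == sim_mode) {
    abort("supply exactly one of real inputs (panel + genotypes + pheno) or a simulation config")
  }
  if (real_mode) {
    if (is.null(vcf) == is.null(dosage_tsv)) {
      abort("real-input mode needs exactly one of 'vcf' or 'dosage_tsv'")
    }
    if (is.null(pheno)) abort("real-input mode needs a phenotype CSV path")
  }
  stopifnot(mac >= 0, max_missing >= 0, max_missing <= 1,
            min_callrate >= 0, min_callrate <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1, ld_r2 > 0, ld_r2 <= 1)
  structure(
    list(panel = panel, vcf = vcf, dosage_tsv = dosage_tsv, pheno = pheno,
         proxy_map = proxy_map, simulation = simulation, score = score,
         trait = toupper(trait), subset = subset, mac = mac,
         max_missing = max_missing, min_callrate = min_callrate,
         hwe_alpha = hwe_alpha, ld_r2 = ld_r2, seed = as.integer(seed)),
    class = "grs_run_config"
  )
}

#' Run the full panel-to-association pipeline
#'
#' Executes the stages in order — panel loading (or simulation), genotype QC
#' (variant missingness, sample call rate, HWE), panel filters (proxy
#' resolution, risk orientation, MAC, LD pruning, optional trait subset),
#' scoring and quartile assignment, then the association models (hypertension
#' and CHD logistic, vessel-burden multinomial, ANOVA across vessel strata,
#' GRS-by-age interaction, pleiotropy screen, optional sensitivity subset) —
#' and persists every result table plus a provenance manifest under
#' `out_dir`. Identical configuration and seed give byte-identical outputs.
#'
#' @param config A [grs_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list with all in-memory results: `panel`,
#'   `genotypes`, `qc_report`, `scores`, `design`, `fits` (list of model
#'   objects), `results` (bound tidy association table), `anova`,
#'   `interaction`, `pleiotropy`, `sensitivity`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "grs_run_config"))
  stage <- "load"
  res <- tryCatch({
    if (!is.null(config$simulation)) {
      sim <- simulate_cohort(config$simulation)
      panel <- sim$panel
      geno <- sim$genotypes
      pheno <- sim$phenotypes
    } else {
      panel <- read_panel(config$panel)
      geno <- if (!is.null(config$vcf)) read_vcf_dosage(config$vcf)
        else read_dosage_tsv(config$dosage_tsv, panel = panel)
      pheno <- readr::read_csv(config$pheno, show_col_types = FALSE)
    }

    stage <- "genotype_qc"
    qc <- run_genotype_qc(geno, config$max_missing, config$min_callrate,
                          config$hwe_alpha)
    geno <- qc$genotypes

    stage <- "panel_filters"
    if (!is.null(config$proxy_map)) {
      pm <- readr::read_tsv(config$proxy_map, show_col_types = FALSE)
      panel <- resolve_proxies(panel, pm, geno_variants(geno))
    } else {
      panel <- resolve_proxies(
        panel, tibble(index_rsid = character(), proxy_rsid = character(),
                      r2 = numeric()),
        geno_variants(geno)
      )
    }
    oriented <- orient_to_risk(geno, panel)
    geno <- oriented$genotypes
    panel <- oriented$panel
    panel <- filter_mac(panel, geno, config$mac)
    panel <- ld_prune(panel, geno, config$ld_r2)

    stage <- "scoring"
    scores <- compute_grs(geno, panel, trait = config$trait)

    stage <- "subset"
    if (config$subset != "all") {
      keep_col <- switch(config$subset,
                         no_hypertension = "hypertension",
                         no_prior_ami = "prior_ami")
      keep <- !as.logical(pheno[[keep_col]])
      keep[is.na(keep)] <- FALSE
      pheno <- pheno[keep, , drop = FALSE]
      geno <- rebuild_geno(
        geno[geno$individual_id %in% pheno$individual_id, , drop = FALSE], geno)
      scores <- compute_grs(geno, panel, trait = config$trait)
    }

    stage <- "association"
    score_types <- if (config$score == "both") c("u", "w") else config$score
    fits <- list()
    for (st in score_types) {
      design <- encode_covariates(pheno, scores, score = st)
      for (adj in c(FALSE, TRUE)) {
        lab <- paste0(st, if (adj) "_adjusted" else "_unadjusted")
        if ("hypertension" %in% names(design)) {
          fits[[paste0("hypertension_", lab)]] <-
            fit_grs_logistic(design, "hypertension", adjusted = adj)
        }
        fits[[paste0("chd_", lab)]] <-
          fit_grs_logistic(design, "chd", adjusted = adj)
        fits[[paste0("vessels_", lab)]] <-
          fit_grs_multinomial(design, "vessels", adjusted = adj)
      }
    }
    design <- encode_covariates(pheno, scores,
                                score = if (config$score == "w") "w" else "u")
    anova_res <- anova_grs_vessels(design)
    inter_res <- interaction_test(design, "chd")
    pleio_res <- pleiotropy_screen(design)

    results <- purrr::map_dfr(names(fits), function(nm) {
      tidy(fits[[nm]]) |> mutate(analysis = nm, .before = 1)
    })

    stage <- "summary"
    summary_tbl <- list(
      n = nrow(design),
      panel_n = attr(scores, "panel_n"),
      outcome_prevalence = c(
        hypertension = if ("hypertension" %in% names(design))
          mean(design$hypertension) else NA_real_,
        chd = mean(design$chd)
      ),
      vessel_distribution = as.numeric(table(factor(design$vessels, 0:3))) /
        nrow(design),
      quartile_counts_u = as.numeric(table(factor(scores$quartile_u, 1:4))),
      score_descriptives = score_descriptives(scores),
      tests_performed = length(fits) + 2 + nrow(pleio_res)
    )

    list(panel = panel, genotypes = geno, qc_report = qc$report,
         scores = scores, design = design, fits = fits, results = results,
         anova = anova_res, interaction = inter_res, pleiotropy = pleio_res,
         summary = summary_tbl)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })

  if (!is.null(out_dir)) write_run(res, config, out_dir)
  invisible(res)
}

write_run <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  readr::write_csv(as_tibble(res$scores), out("scores.csv"))
  readr::write_tsv(res$qc_report, out("qc_report.tsv"))
  readr::write_tsv(panel_exclusions(res$panel), out("exclusion_log.tsv"))
  readr::write_tsv(res$results, out("associations.tsv"))
  readr::write_tsv(forest_table(res$results), out("forest_table.csv"))
  jsonlite::write_json(
    list(associations = res$results, anova = res$anova,
         interaction = res$interaction, pleiotropy = res$pleiotropy),
    out("associations.json"), auto_unbox = TRUE, digits = NA
  )
  s <- res$summary
  summary_lines <- c(
    sprintf("analysis n: %d", s$n),
    sprintf("panel variants used: %d", s$panel_n),
    sprintf("hypertension prevalence: %.3f", s$outcome_prevalence[["hypertension"]]),
    sprintf("CHD prevalence: %.3f", s$outcome_prevalence[["chd"]]),
    sprintf("vessel distribution (0/1/2/3): %s",
            paste(sprintf("%.3f", s$vessel_distribution), collapse = " / ")),
    sprintf("uGRS quartile counts: %s",
            paste(s$quartile_counts_u, collapse = " / ")),
    sprintf("statistical tests performed (no multiplicity correction): %d",
            s$tests_performed)
  )
  writeLines(summary_lines, out("summary.txt"))
  manifest <- list(
    config = config[setdiff(names(config), "simulation")],
    simulation = if (!is.null(config$simulation))
      unclass(config$simulation) else NULL,
    seed = config$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("grsburden"))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' Forest-plot-ready table of association results
#'
#' Orders rows by analysis, outcome level and quartile and inserts the
#' reference rows (quartile 1, OR 1.0, empty interval) so the table matches
#' the conventional forest-plot layout.
#'
#' @param results Tidy association tibble (from [run_pipeline()]`$results`
#'   or `tidy()` on a fit, optionally with an `analysis` column).
#' @return Tibble with one row per quartile (including the reference) per
#'   outcome level.
#' @export
forest_table <- function(results) {
  if (!"analysis" %in% names(results)) {
    results <- mutate(results, analysis = paste0(.data$outcome, "_", .data$model))
  }
  groups <- dplyr::distinct(results, .data$analysis, .data$outcome,
                            .data$level, .data$model, .data$n)
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    rows <- results |>
      filter(.data$analysis == g$analysis,
             (.data$level == g$level) | (is.na(.data$level) & is.na(g$level)))
    ref <- g |>
      mutate(term = "grs_qQ1", estimate = 0, se = NA_real_, or = 1,
             ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_)
    bind_rows(ref, rows[order(rows$term), ]) |>
      select("analysis", "outcome", "level", "model", "term", "or",
             "ci_low", "ci_high", "p_value", "n")
  })
}
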