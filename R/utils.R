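#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows left_join group_by summarise n
#' @importFrom stats quantile sd plogis qlogis rbinom runif rnorm rexp pchisq glm lm
#'   binomial coef vcov anova as.formula complete.cases aov uniroot setNames
NULL

VALID_TRAITS <- c("SBP", "DBP", "PP")

new_exclusion_log <- function() {
  tibble(
    rsid = character(), rule = character(),
    value = character(), stage = character()
  )
}

log_exclusions <- function(panel, rsid, rule, value, stage) {
  if (length(rsid) == 0L) return(panel)
  log <- panel_exclusions(panel)
  add <- tibble(
    rsid = as.character(rsid), rule = rule,
    value = as.character(value), stage = stage
  )
  attr(panel, "exclusions") <- bind_rows(log, add)
  panel
}

# rebuild panel class/attrs after a dplyr verb stripped them
restore_panel <- function(df, template) {
  attr(df, "exclusions") <- attr(template, "exclusions") %||% new_exclusion_log()
  attr(df, "trait") <- attr(template, "trait") %||% "ALL"
  class(df) <- unique(c("grs_panel", class(df)))
  df
}
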