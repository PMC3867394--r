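#' The four genetic-model contrasts
#'
#' Ways to dichotomize the three genotypes of a biallelic marker (AA/AG/GG,
#' G the variant allele) into an exposed/unexposed split:
#' `homozygote` (GG vs AA), `heterozygote` (AG vs AA), `dominant`
#' (GG+AG vs AA) and `recessive` (GG vs AG+AA). For the homozygote and
#' heterozygote contrasts the middle column is excluded, not merged.
#'
#' @return Character vector of the four model names.
#' @export
genetic_models <- function() {
  c("homozygote", "heterozygote", "dominant", "recessive")
}

#' Build per-study 2x2 exposure tables under a genetic model
#'
#' @param studies A `snp_studies` data frame.
#' @param model One of [genetic_models()].
#' @return A `contrast_tables` data frame with columns study_id and the 2x2
#'   cells a (case exposed), b (case unexposed), c (control exposed),
#'   d (control unexposed), plus a `corrected` flag (all `FALSE` here; see
#'   [continuity_correct()]). The genetic model is kept in attribute
#'   `"model"`.
#' @export
contrast_tables <- function(studies, model = genetic_models()) {
  model <- match.arg(model)
  studies <- validate_studies(studies)
  cells <- switch(model,
    homozygote = data.frame(
      a = studies$case_gg, b = studies$case_aa,
      c = studies$control_gg, d = studies$control_aa),
    heterozygote = data.frame(
      a = studies$case_ag, b = studies$case_aa,
      c = studies$control_ag, d = studies$control_aa),
    dominant = data.frame(
      a = studies$case_gg + studies$case_ag, b = studies$case_aa,
      c = studies$control_gg + studies$control_ag, d = studies$control_aa),
    recessive = data.frame(
      a = studies$case_gg, b = studies$case_aa + studies$case_ag,
      c = studies$control_gg, d = studies$control_aa + studies$control_ag)
  )
  tab <- cbind(data.frame(study_id = studies$study_id,
                          stringsAsFactors = FALSE),
               cells, corrected = FALSE)
  degen <- (tab$a + tab$b) == 0 | (tab$c + tab$d) == 0
  if (any(degen)) {
    stop("degenerate 2x2 table (empty case or control margin) for study: ",
         paste(tab$study_id[degen], collapse = ", "), call. = FALSE)
  }
  attr(tab, "model") <- model
  class(tab) <- c("contrast_tables", class(tab))
  tab
}

#' Haldane-Anscombe continuity correction
#'
#' Adds `increment` to all four cells of any table containing a zero cell,
#' leaving tables without zeros untouched. Tables whose case or control
#' margin is entirely zero are rejected rather than corrected.
#'
#' @param tables A `contrast_tables` data frame.
#' @param increment Value added to every cell of affected tables
#'   (default 0.5).
#' @return The table set with corrected rows flagged in `corrected`.
#' @export
continuity_correct <- function(tables, increment = 0.5) {
  stopifnot(is.data.frame(tables), increment > 0)
  degen <- (tables$a + tables$b) == 0 | (tables$c + tables$d) == 0
  if (any(degen)) {
    stop("degenerate 2x2 table (empty case or control margin) for study: ",
         paste(tables$study_id[degen], collapse = ", "), call. = FALSE)
  }
  zero <- tables$a == 0 | tables$b == 0 | tables$c == 0 | tables$d == 0
  for (cell in c("a", "b", "c", "d")) {
    tables[[cell]][zero] <- tables[[cell]][zero] + increment
  }
  tables$corrected <- tables$corrected | zero
  tables
}

#' Per-study odds ratios with Woolf variances
#'
#' Computes, for each 2x2 table, the log odds ratio `log(ad/bc)`, its Woolf
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`, and the 95% confidence
#' interval `exp(log OR +/- 1.96 se)`. Zero cells are handled by
#' [continuity_correct()] first (on by default).
#'
#' @param tables A `contrast_tables` data frame.
#' @param correct Apply the continuity correction to zero-cell tables
#'   (default `TRUE`). With `correct = FALSE` a zero cell is an error.
#' @param increment Continuity-correction increment.
#' @return An `effect_estimates` data frame: study_id, log_or, se, or,
#'   ci_low, ci_high, corrected. The genetic model attribute is carried
#'   over.
#' @export
study_effects <- function(tables, correct = TRUE, increment = 0.5) {
  if (correct) {
    tables <- continuity_correct(tables, increment)
  } else if (any(tables$a == 0 | tables$b == 0 |
                 tables$c == 0 | tables$d == 0)) {
    zero <- tables$a == 0 | tables$b == 0 | tables$c == 0 | tables$d == 0
    stop("zero cell without continuity correction for study: ",
         paste(tables$study_id[zero], collapse = ", "), call. = FALSE)
  }
  log_or <- log(tables$a * tables$d / (tables$b * tables$c))
  se <- sqrt(1 / tables$a + 1 / tables$b + 1 / tables$c + 1 / tables$d)
  eff <- data.frame(
    study_id = tables$study_id,
    log_or = log_or,
    se = se,
    or = exp(log_or),
    ci_low = exp(log_or - 1.96 * se),
    ci_high = exp(log_or + 1.96 * se),
    corrected = tables$corrected,
    stringsAsFactors = FALSE
  )
  attr(eff, "model") <- attr(tables, "model")
  class(eff) <- c("effect_estimates", class(eff))
  eff
}
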