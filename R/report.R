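.fmt_or_ci <- function(or, lo, hi) sprintf("%.2f(%.2f,%.2f)", or, lo, hi)

.fmt_p_het <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Shape pooled results like a publication summary table
#'
#' Pivots a stacked `meta_table` into one row per group level with, per
#' genetic model, an `OR(CI low, CI high)` cell at 2 decimals and the
#' heterogeneity p-value at 3 decimals. Single-study levels are dropped by
#' default, mirroring the usual reporting convention.
#'
#' @param tab A `meta_table` (possibly row-bound across groupings).
#' @param drop_single Hide single-study levels (default `TRUE`).
#' @return A data frame: group, level, N, then `<model>_or` and
#'   `<model>_p_het` column pairs.
#' @export
format_meta_table <- function(tab, drop_single = TRUE) {
  tab <- as.data.frame(tab)
  if (drop_single) tab <- tab[!tab$single_study, , drop = FALSE]
  keys <- unique(tab[, c("group", "level")])
  models <- unique(tab$model)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$group == keys$group[i] & tab$level == keys$level[i], ]
    row <- data.frame(group = keys$group[i], level = keys$level[i],
                      N = sub$k[1L], stringsAsFactors = FALSE)
    for (m in models) {
      cell <- sub[sub$model == m, ]
      row[[paste0(m, "_or")]] <-
        .fmt_or_ci(cell$or, cell$ci_low, cell$ci_high)
      row[[paste0(m, "_p_het")]] <- .fmt_p_het(cell$p_het)
    }
    row
  })
  do.call(rbind, rows)
}

#' Run the complete analysis and write a report bundle
#'
#' Executes, for every requested genetic model: per-study effects and
#' control HWE tests, overall and subgroup pooling (all four stratification
#' factors), leave-one-out sensitivity, and the Egger and Begg
#' publication-bias tests; then writes TSV tables (printed precision) plus
#' a JSON sidecar (full precision, with per-study weights and provenance).
#' Identical inputs and options produce byte-identical JSON.
#'
#' @param studies A `snp_studies` data frame.
#' @param out_dir Output directory (created if needed).
#' @param models Genetic models to analyse.
#' @inheritParams run_meta
#' @param seed Echoed into provenance (the analysis itself is
#'   deterministic).
#' @param input_label Free-text description of the input recorded in
#'   provenance.
#' @return The report bundle (a list), invisibly.
#' @export
meta_report <- function(studies, out_dir, models = genetic_models(),
                        selection = .selection_levels, het_threshold = 0.10,
                        seed = NULL, input_label = "study table") {
  selection <- match.arg(selection)
  studies <- validate_studies(studies)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  hwe <- hwe_table(studies)
  effects_by_model <- lapply(models, function(m) {
    eff <- study_effects(contrast_tables(studies, m))
    cbind(model = m, as.data.frame(eff))
  })
  names(effects_by_model) <- models
  study_summary <- do.call(rbind, effects_by_model)
  study_summary <- merge(study_summary, hwe, by = "study_id", sort = FALSE)
  rownames(study_summary) <- NULL

  main <- do.call(rbind, lapply(
    c("overall", "cancer_group", "ethnicity_group", "source_group",
      "size_class"),
    function(g) as.data.frame(run_meta(studies, models, grouping = g,
                                       selection = selection,
                                       het_threshold = het_threshold))
  ))

  sensitivity <- if (nrow(studies) >= 2L) {
    do.call(rbind, lapply(models, function(m) {
      cbind(model = m, leave_one_out(studies, m, selection = selection,
                                     het_threshold = het_threshold))
    }))
  } else {
    NULL
  }

  bias <- if (nrow(studies) >= 3L) {
    do.call(rbind, lapply(models, function(m) {
      eff <- effects_by_model[[m]]
      eg <- egger_test(eff)
      bg <- begg_test(eff)
      data.frame(model = m, egger_intercept = eg$intercept,
                 egger_t = eg$t, egger_p = eg$p,
                 begg_tau = bg$kendall_tau, begg_z = bg$z, begg_p = bg$p,
                 stringsAsFactors = FALSE)
    }))
  } else {
    NULL
  }

  forest <- do.call(rbind, lapply(models, function(m) {
    eff <- effects_by_model[[m]]
    labels <- classify_studies(studies)
    merge(eff, labels[, c("study_id", "cancer_group", "ethnicity_group",
                          "size_class", "source_group")],
          by = "study_id", sort = FALSE)
  }))

  bundle <- list(
    provenance = list(
      package = "snpmeta",
      version = as.character(utils::packageVersion("snpmeta")),
      input = input_label,
      n_studies = nrow(studies),
      models = models,
      selection = selection,
      het_threshold = het_threshold,
      seed = seed
    ),
    hwe = hwe,
    study_summary = study_summary,
    main_table = main,
    sensitivity_table = sensitivity,
    bias_results = bias
  )

  .write_tsv(study_summary, file.path(out_dir, "study_summary.tsv"))
  .write_tsv(format_meta_table(main), file.path(out_dir, "main_table.tsv"))
  if (!is.null(sensitivity)) {
    .write_tsv(sensitivity, file.path(out_dir, "sensitivity.tsv"))
  }
  if (!is.null(bias)) {
    .write_tsv(bias, file.path(out_dir, "bias.tsv"))
  }
  .write_tsv(forest, file.path(out_dir, "forest.tsv"))
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(bundle)
}
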