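.selection_levels <- c("paper_rule", "force_fixed_mh", "force_fixed_iv",
                       "force_random")

.grouping_levels <- c("overall", "cancer_group", "ethnicity_group",
                      "source_group", "size_class")

.pool_one <- function(tables, selection, het_threshold) {
  effects <- study_effects(tables)
  k <- nrow(effects)
  het <- if (k >= 2L) cochran_q(effects) else NULL
  method <- switch(selection,
    force_fixed_mh = "mh_fixed",
    force_fixed_iv = "iv_fixed",
    force_random = "dl_random",
    paper_rule = if (k < 2L) "iv_fixed" else select_model(het, het_threshold)
  )
  pool <- switch(method,
    mh_fixed = pool_mh(tables),
    iv_fixed = pool_iv(effects),
    dl_random = pool_dl(effects)
  )
  pool$het <- het
  pool
}

.pool_row <- function(pool) {
  het <- pool$het
  data.frame(
    k = pool$k,
    or = pool$or, ci_low = pool$ci_low, ci_high = pool$ci_high,
    log_or = pool$log_or, se = pool$se, z = pool$z, p = pool$p,
    method = pool$method,
    q = if (is.null(het)) NA_real_ else het$q,
    p_het = if (is.null(het)) NA_real_ else het$p_het,
    i2 = if (is.null(het)) NA_real_ else het$i2,
    tau2 = if (is.null(het)) NA_real_ else het$tau2,
    single_study = pool$k == 1L,
    stringsAsFactors = FALSE
  )
}

#' Run the full genetic-model meta-analysis
#'
#' For every requested genetic-model contrast, and every level of the
#' requested grouping factor, builds the per-study 2x2 tables, assesses
#' heterogeneity by Cochran's Q, selects the pooling estimator and reports
#' the pooled odds ratio with 95% CI, Z test and heterogeneity summary.
#'
#' Under `selection = "paper_rule"` the estimator is Mantel-Haenszel fixed
#' effects when the heterogeneity p-value exceeds `het_threshold` and
#' DerSimonian-Laird random effects otherwise; the `force_*` selections pin
#' one estimator for all strata. Groups containing a single study are
#' emitted with `single_study = TRUE` rather than suppressed.
#'
#' @param studies A `snp_studies` data frame.
#' @param models Genetic models to analyse (default all four).
#' @param grouping `"overall"` or one of the subgroup factors
#'   `"cancer_group"`, `"ethnicity_group"`, `"source_group"`,
#'   `"size_class"`.
#' @param selection Estimator policy (see Details).
#' @param het_threshold Heterogeneity significance threshold for
#'   `paper_rule` (default 0.10).
#' @return A `meta_table` data frame with one row per (group level, genetic
#'   model): k, or, ci_low, ci_high, log_or, se, z, p, method, q, p_het,
#'   i2, tau2, single_study.
#' @examples
#' run_meta(mcp1_studies(), grouping = "cancer_group",
#'          selection = "force_random")
#' @export
run_meta <- function(studies, models = genetic_models(),
                     grouping = .grouping_levels,
                     selection = .selection_levels,
                     het_threshold = 0.10) {
  grouping <- match.arg(grouping)
  selection <- match.arg(selection)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  studies <- validate_studies(studies)
  if (nrow(studies) == 0L) {
    stop("meta-analysis requires at least one study", call. = FALSE)
  }
  if (grouping == "overall") {
    groups <- list(all = studies)
  } else {
    labels <- classify_studies(studies)
    fac <- labels[[grouping]]
    groups <- lapply(split(seq_len(nrow(studies)), fac, drop = TRUE),
                     function(i) studies[i, , drop = FALSE])
  }
  rows <- list()
  for (model in models) {
    for (level in names(groups)) {
      tables <- contrast_tables(groups[[level]], model)
      pool <- .pool_one(tables, selection, het_threshold)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(group = grouping, level = level, model = model,
                   stringsAsFactors = FALSE),
        .pool_row(pool)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "selection") <- selection
  attr(out, "het_threshold") <- het_threshold
  class(out) <- c("meta_table", class(out))
  out
}

#' Leave-one-out sensitivity analysis
#'
#' Repeats the pooled analysis k times, each time excluding one study, to
#' assess whether any single study drives the pooled estimate. The same
#' estimator policy as the full analysis is applied within each reduced
#' set.
#'
#' @param studies A `snp_studies` data frame with k >= 2 rows.
#' @param model One of [genetic_models()].
#' @inheritParams run_meta
#' @return A data frame with one row per excluded study: excluded_study_id,
#'   k, or, ci_low, ci_high, method, p_het.
#' @export
leave_one_out <- function(studies, model = genetic_models(),
                          selection = .selection_levels,
                          het_threshold = 0.10) {
  model <- match.arg(model)
  selection <- match.arg(selection)
  studies <- validate_studies(studies)
  k <- nrow(studies)
  if (k < 2L) {
    stop("leave-one-out sensitivity analysis requires at least two studies",
         call. = FALSE)
  }
  rows <- lapply(seq_len(k), function(i) {
    tables <- contrast_tables(studies[-i, , drop = FALSE], model)
    pool <- .pool_one(tables, selection, het_threshold)
    cbind(data.frame(excluded_study_id = studies$study_id[i],
                     stringsAsFactors = FALSE),
          .pool_row(pool)[, c("k", "or", "ci_low", "ci_high", "log_or",
                              "method", "p_het")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Random-effects meta-regression on a categorical moderator
#'
#' Regresses per-study log odds ratios on indicator variables for the
#' moderator levels, with weights `1/(se^2 + tau2_residual)`. The residual
#' between-study variance is the method-of-moments estimate from the
#' weighted residual heterogeneity statistic,
#' `tau2 = max(0, (Q_E - (k - p)) / tr(P))` with
#' `P = W - W X (X' W X)^-1 X' W` at the fixed-effects weights. Whether the
#' moderator explains heterogeneity is assessed by a joint Wald chi-square
#' test of all non-reference coefficients.
#'
#' @param effects An `effect_estimates` data frame.
#' @param labels Categorical moderator, one label per study (character or
#'   factor, at least two distinct levels present).
#' @param covariate Name used for reporting (defaults to the expression
#'   passed as `labels`).
#' @return A `metareg_result` list: covariate, levels (reference first),
#'   coefficients (reference fixed at 0), se, p_model, tau2_residual, k,
#'   df_model.
#' @export
meta_regression <- function(effects, labels,
                            covariate = deparse(substitute(labels))) {
  .check_effects(effects)
  labels <- as.factor(as.character(labels))
  k <- nrow(effects)
  if (length(labels) != k) {
    stop("labels must supply one moderator value per study", call. = FALSE)
  }
  labels <- droplevels(labels)
  p <- nlevels(labels)
  if (p < 2L) {
    stop("degenerate moderator: all studies share one level", call. = FALSE)
  }
  if (k < p + 1L) {
    stop("too few studies to estimate ", p,
         " level means plus residual heterogeneity", call. = FALSE)
  }
  y <- effects$log_or
  X <- stats::model.matrix(~labels)
  w <- 1 / effects$se^2
  W <- diag(w)
  XtWX_inv <- solve(t(X) %*% W %*% X)
  H <- X %*% XtWX_inv %*% t(X) %*% W
  resid_fixed <- y - H %*% y
  q_e <- sum(w * resid_fixed^2)
  P <- W - W %*% X %*% XtWX_inv %*% t(X) %*% W
  tau2 <- max(0, (q_e - (k - p)) / sum(diag(P)))
  w_star <- 1 / (effects$se^2 + tau2)
  Ws <- diag(w_star)
  cov_b <- solve(t(X) %*% Ws %*% X)
  b <- drop(cov_b %*% t(X) %*% Ws %*% y)
  se_b <- sqrt(diag(cov_b))
  # joint Wald test of the non-reference coefficients
  idx <- seq_len(p)[-1L]
  qm <- drop(t(b[idx]) %*% solve(cov_b[idx, idx, drop = FALSE]) %*% b[idx])
  p_model <- stats::pchisq(qm, df = p - 1L, lower.tail = FALSE)
  coefs <- c(0, b[idx] )
  ses <- c(0, se_b[idx])
  names(coefs) <- names(ses) <- levels(labels)
  structure(
    list(covariate = covariate, levels = levels(labels),
         coefficients = coefs, se = ses,
         intercept = b[1L], qm = qm, df_model = p - 1L,
         p_model = p_model, tau2_residual = tau2, k = k),
    class = "metareg_result"
  )
}

#' @export
print.metareg_result <- function(x, ...) {
  cat(sprintf("Meta-regression of log OR on %s (k = %d)\n", x$covariate, x$k))
  cat(sprintf("  residual tau2 = %.4f; joint Wald QM = %.4f (df = %d), p = %.4g\n",
              x$tau2_residual, x$qm, x$df_model, x$p_model))
  tab <- data.frame(level = x$levels,
                    coefficient = x$coefficients,
                    se = x$se)
  tab$se[1L] <- NA
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
print.meta_table <- function(x, ...) {
  needed <- c("group", "level", "model", "k", "or", "ci_low", "ci_high",
              "p_het", "method")
  if (!all(needed %in% names(x))) {
    return(print.data.frame(x, ...))
  }
  cat(sprintf("Pooled genetic-model odds ratios (selection: %s)\n",
              attr(x, "selection")))
  y <- as.data.frame(x)
  y$or_ci <- sprintf("%.2f(%.2f,%.2f)", y$or, y$ci_low, y$ci_high)
  y$p_het <- ifelse(is.na(y$p_het), NA,
                    ifelse(y$p_het < 0.001, "<0.001", sprintf("%.3f", y$p_het)))
  print(y[, c("group", "level", "model", "k", "or_ci", "p_het", "method")],
        row.names = FALSE)
  invisible(x)
}
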