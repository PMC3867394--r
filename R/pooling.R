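.pool_result <- function(method, k, log_or, se, weights, het = NULL) {
  z <- log_or / se
  structure(
    list(method = method, k = k,
         log_or = log_or, se = se,
         or = exp(log_or),
         ci_low = exp(log_or - 1.96 * se),
         ci_high = exp(log_or + 1.96 * se),
         z = z,
         p = 2 * stats::pnorm(-abs(z)),
         weights = weights / sum(weights),
         het = het),
    class = "pool_result"
  )
}

.check_effects <- function(effects) {
  if (!is.data.frame(effects) || nrow(effects) == 0L) {
    stop("pooling requires at least one study effect", call. = FALSE)
  }
  if (any(!is.finite(effects$se)) || any(effects$se <= 0)) {
    stop("all standard errors must be finite and positive", call. = FALSE)
  }
  invisible(effects)
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' Pools stratified 2x2 tables as the ratio of summed cross-products,
#' `OR_MH = sum(a d / n) / sum(b c / n)`, with the Robins-Breslow-Greenland
#' variance for the log pooled OR. Zero cells are continuity-corrected per
#' study before pooling.
#'
#' @param tables A `contrast_tables` data frame (k >= 1 rows).
#' @param correct,increment Passed to [continuity_correct()].
#' @return A `pool_result` with method `"mh_fixed"`. Per-study weights are
#'   the Mantel-Haenszel weights `b c / n`, normalized.
#' @export
pool_mh <- function(tables, correct = TRUE, increment = 0.5) {
  if (!is.data.frame(tables) || nrow(tables) == 0L) {
    stop("pooling requires at least one 2x2 table", call. = FALSE)
  }
  if (correct) tables <- continuity_correct(tables, increment)
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  n <- a + b + c + d
  R <- a * d / n
  S <- b * c / n
  if (sum(R) == 0 || sum(S) == 0) {
    stop("Mantel-Haenszel pooled odds ratio undefined: a summed cross-product is zero",
         call. = FALSE)
  }
  log_or <- log(sum(R) / sum(S))
  # Robins-Breslow-Greenland variance of log OR_MH
  P <- (a + d) / n
  Q <- (b + c) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  w <- S
  names(w) <- tables$study_id
  .pool_result("mh_fixed", nrow(tables), log_or, sqrt(v), w)
}

#' Inverse-variance fixed-effects pooling
#'
#' Weights each study by the reciprocal of its squared standard error:
#' pooled log OR = sum(w y) / sum(w), se = 1/sqrt(sum(w)).
#'
#' @param effects An `effect_estimates` data frame (k >= 1 rows).
#' @return A `pool_result` with method `"iv_fixed"`.
#' @export
pool_iv <- function(effects) {
  .check_effects(effects)
  w <- 1 / effects$se^2
  names(w) <- effects$study_id
  log_or <- sum(w * effects$log_or) / sum(w)
  .pool_result("iv_fixed", nrow(effects), log_or, 1 / sqrt(sum(w)), w)
}

#' Cochran's Q test of between-study heterogeneity
#'
#' Q is the inverse-variance weighted sum of squared deviations of study
#' log ORs around the fixed-effects pooled estimate, chi-square with k - 1
#' degrees of freedom under homogeneity. Also returns Higgins'
#' `I2 = max(0, (Q - df)/Q)` and the DerSimonian-Laird moment estimate
#' `tau2 = max(0, (Q - df) / (S1 - S2/S1))` with `S1 = sum(w)`,
#' `S2 = sum(w^2)`. Heterogeneity is conventionally called significant at
#' `p_het < 0.10`.
#'
#' @param effects An `effect_estimates` data frame with k >= 2 rows.
#' @return A `heterogeneity_result` list: q, df, p_het, i2, tau2, k.
#' @export
cochran_q <- function(effects) {
  .check_effects(effects)
  k <- nrow(effects)
  if (k < 2L) {
    stop("Cochran's Q requires at least two studies", call. = FALSE)
  }
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  q <- sum(w * (effects$log_or - pooled)^2)
  df <- k - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(
    list(q = q, df = df,
         p_het = stats::pchisq(q, df = df, lower.tail = FALSE),
         i2 = i2, tau2 = tau2, k = k),
    class = "heterogeneity_result"
  )
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inflates each study's variance by the moment-estimated between-study
#' variance tau2 (from [cochran_q()], floored at zero) and pools by inverse
#' variance: weights `1/(se^2 + tau2)`. When Q <= df (tau2 = 0) the result
#' equals the inverse-variance fixed-effects pool exactly; with a single
#' study tau2 is 0 by convention.
#'
#' @param effects An `effect_estimates` data frame (k >= 1 rows).
#' @return A `pool_result` with method `"dl_random"` and the heterogeneity
#'   result attached in `$het` (NULL when k = 1).
#' @export
pool_dl <- function(effects) {
  .check_effects(effects)
  het <- if (nrow(effects) >= 2L) cochran_q(effects) else NULL
  tau2 <- if (is.null(het)) 0 else het$tau2
  w <- 1 / (effects$se^2 + tau2)
  names(w) <- effects$study_id
  log_or <- sum(w * effects$log_or) / sum(w)
  .pool_result("dl_random", nrow(effects), log_or, 1 / sqrt(sum(w)), w,
               het = het)
}

#' Heterogeneity-driven estimator selection
#'
#' The conventional rule: pool by Mantel-Haenszel fixed effects when the
#' heterogeneity p-value exceeds the threshold (default 0.10), otherwise by
#' DerSimonian-Laird random effects. The comparison is strict, so a p-value
#' exactly at the threshold selects the random-effects model.
#'
#' @param het A `heterogeneity_result`.
#' @param threshold Heterogeneity significance threshold (default 0.10).
#' @return `"mh_fixed"` or `"dl_random"`.
#' @export
select_model <- function(het, threshold = 0.10) {
  stopifnot(inherits(het, "heterogeneity_result"),
            threshold > 0, threshold < 1)
  if (het$p_het > threshold) "mh_fixed" else "dl_random"
}

#' @export
print.pool_result <- function(x, digits = 4, ...) {
  label <- c(mh_fixed = "Mantel-Haenszel fixed effects",
             iv_fixed = "inverse-variance fixed effects",
             dl_random = "DerSimonian-Laird random effects")[x$method]
  cat(sprintf("Pooled odds ratio (%s), k = %d studies\n", label, x$k))
  cat(sprintf("  OR = %.*f, 95%% CI (%.*f, %.*f), z = %.*f, p = %.4g\n",
              digits, x$or, digits, x$ci_low, digits, x$ci_high,
              digits, x$z, x$p))
  if (!is.null(x$het)) {
    cat(sprintf("  heterogeneity: Q = %.*f (df = %d), p = %.4g, I2 = %.1f%%, tau2 = %.*f\n",
                digits, x$het$q, x$het$df, x$het$p_het, 100 * x$het$i2,
                digits, x$het$tau2))
  }
  invisible(x)
}

#' @export
print.heterogeneity_result <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q = %.*f (df = %d), p = %.4g\n",
              digits, x$q, x$df, x$p_het))
  cat(sprintf("I2 = %.1f%%, tau2 = %.*f (DerSimonian-Laird)\n",
              100 * x$i2, digits, x$tau2))
  invisible(x)
}
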