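#' Egger's linear regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `log_or / se` on the
#' precision `1 / se`, with intercept. Under a symmetric funnel the
#' intercept is zero; the two-sided t test of the intercept (k - 2 degrees
#' of freedom) is the classical small-study-effects test.
#'
#' @param effects An `effect_estimates` data frame with k >= 3 rows.
#' @return An `egger_result` list: intercept, intercept_se, t, p, slope,
#'   df, k.
#' @export
egger_test <- function(effects) {
  .check_effects(effects)
  k <- nrow(effects)
  if (k < 3L) {
    stop("Egger's test requires at least three studies", call. = FALSE)
  }
  snd <- effects$log_or / effects$se
  prec <- 1 / effects$se
  fit <- stats::lm(snd ~ prec)
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(sm)
  intercept <- cf[1L, 1L]
  intercept_se <- cf[1L, 2L]
  exact_fit <- !is.finite(intercept_se) || intercept_se == 0 ||
    sm$sigma < 1e-8 * max(1, mean(abs(snd)))
  if (exact_fit) {
    # intercept estimated without residual error
    t_stat <- if (abs(intercept) < 1e-10) 0 else sign(intercept) * Inf
    p <- if (t_stat == 0) 1 else 0
  } else {
    t_stat <- intercept / intercept_se
    p <- 2 * stats::pt(-abs(t_stat), df = k - 2L)
  }
  structure(
    list(intercept = intercept, intercept_se = intercept_se,
         t = t_stat, p = p, slope = cf[2L, 1L], df = k - 2L, k = k),
    class = "egger_result"
  )
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between standardized study effects and their
#' variances. Effects are standardized as
#' `(log_or - pooled) / sqrt(se^2 - 1/sum(w))`, with the inverse-variance
#' fixed-effects pooled estimate; the subtraction removes the correlation
#' induced by the pooled mean. The normal approximation uses the
#' tie-corrected Kendall variance and (by default) a continuity correction.
#' When every pair is tied the test is degenerate and returns p = 1.
#'
#' @param effects An `effect_estimates` data frame with k >= 3 rows.
#' @param continuity Apply the continuity correction to the normal
#'   approximation (default `TRUE`).
#' @return A `begg_result` list: kendall_tau (tau-b), z, p, k.
#' @export
begg_test <- function(effects, continuity = TRUE) {
  .check_effects(effects)
  k <- nrow(effects)
  if (k < 3L) {
    stop("Begg's test requires at least three studies", call. = FALSE)
  }
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  v_star <- effects$se^2 - 1 / sum(w)
  t_i <- (effects$log_or - pooled) / sqrt(v_star)
  v_i <- effects$se^2
  dt <- outer(t_i, t_i, "-")
  dv <- outer(v_i, v_i, "-")
  s <- sign(dt) * sign(dv)
  s <- s[lower.tri(s)]
  conc <- sum(s > 0)
  disc <- sum(s < 0)
  d <- conc - disc
  # tie-corrected variance of Kendall's S
  tie_term <- function(x) {
    tt <- table(x)
    tt <- tt[tt > 1]
    c(sum(tt * (tt - 1) * (2 * tt + 5)),
      sum(tt * (tt - 1)),
      sum(tt * (tt - 1) * (tt - 2)))
  }
  ct <- tie_term(t_i)
  cv <- tie_term(v_i)
  var_s <- (k * (k - 1) * (2 * k + 5) - ct[1L] - cv[1L]) / 18 +
    ct[3L] * cv[3L] / (9 * k * (k - 1) * (k - 2)) +
    ct[2L] * cv[2L] / (2 * k * (k - 1))
  n0 <- k * (k - 1) / 2
  denom <- sqrt((n0 - ct[2L] / 2) * (n0 - cv[2L] / 2))
  tau <- if (denom > 0) d / denom else 0
  if (var_s <= 0 || (conc + disc) == 0) {
    z <- 0
    p <- 1
  } else {
    num <- if (continuity) max(0, abs(d) - 1) else abs(d)
    z <- num / sqrt(var_s)
    p <- 2 * stats::pnorm(-z)
  }
  structure(
    list(kendall_tau = tau, z = z, p = min(p, 1), k = k,
         continuity = continuity),
    class = "begg_result"
  )
}

#' Funnel-plot coordinates
#'
#' One point per study (effect on the x axis, standard error on the y axis)
#' plus pseudo-95% confidence guide lines around the fixed-effects pooled
#' estimate, `pooled +/- 1.96 se` over a grid of standard errors.
#'
#' @param effects An `effect_estimates` data frame (k >= 1 rows).
#' @param scale x-axis scale, `"log_or"` (default) or `"or"`.
#' @return A list with `points` (study_id, x, y), `guides` (se, lower,
#'   upper on the chosen scale), `pooled` and `scale`.
#' @export
funnel_coordinates <- function(effects, scale = c("log_or", "or")) {
  scale <- match.arg(scale)
  .check_effects(effects)
  w <- 1 / effects$se^2
  pooled <- sum(w * effects$log_or) / sum(w)
  se_grid <- seq(0, max(effects$se) * 1.05, length.out = 50L)
  lower <- pooled - 1.96 * se_grid
  upper <- pooled + 1.96 * se_grid
  to_scale <- function(v) if (scale == "or") exp(v) else v
  list(
    points = data.frame(study_id = effects$study_id,
                        x = to_scale(effects$log_or),
                        y = effects$se,
                        stringsAsFactors = FALSE),
    guides = data.frame(se = se_grid,
                        lower = to_scale(lower),
                        upper = to_scale(upper)),
    pooled = to_scale(pooled),
    scale = scale
  )
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger's regression test (k = %d)\n", x$k))
  cat(sprintf("  intercept = %.4f (se %.4f), t = %.4f (df = %d), p = %.4g\n",
              x$intercept, x$intercept_se, x$t, x$df, x$p))
  invisible(x)
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("Begg-Mazumdar rank-correlation test (k = %d)\n", x$k))
  cat(sprintf("  Kendall tau-b = %.4f, z = %.4f%s, p = %.4g\n",
              x$kendall_tau, x$z,
              if (x$continuity) " (continuity-corrected)" else "", x$p))
  invisible(x)
}
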