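#' Configuration for the synthetic study generator
#'
#' Defines the generating process for synthetic case-control genotype
#' studies: control genotypes are multinomial under Hardy-Weinberg
#' proportions at a per-study G-allele frequency drawn uniformly from
#' `maf_range`; case genotype probabilities are the control probabilities
#' tilted by genotype odds ratios, proportional to
#' `(P_AA, P_AG * psi_ag, P_GG * psi_gg)`. This tilt is the exact logistic
#' model, so `psi_gg` is exactly the homozygote-contrast odds ratio and
#' `psi_ag` the heterozygote one. Between-study heterogeneity adds a normal
#' deviate `u ~ N(0, tau^2)` to `log psi_gg` per study, and scales
#' `log psi_ag` proportionally (`log psi_ag * (1 + u / log psi_gg)` when
#' `psi_gg != 1`, else `u/2`).
#'
#' Defaults mirror the bundled 19-study data set's regime: around 19
#' studies of 50-600 cases and 75-650 controls with control G-allele
#' frequencies 0.2-0.6, under the null (`psi = 1`, `tau = 0`).
#'
#' @param k Number of studies.
#' @param n_cases,n_controls Ranges (min, max) for per-study sample sizes.
#' @param maf_range Range for the control G-allele frequency, within (0,1).
#' @param psi_ag,psi_gg True genotype odds ratios vs AA (both > 0).
#' @param tau Between-study standard deviation on the log psi_gg scale
#'   (>= 0).
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(k = 19, n_cases = c(50, 600), n_controls = c(75, 650),
                       maf_range = c(0.2, 0.6), psi_ag = 1, psi_gg = 1,
                       tau = 0, seed = 1L) {
  stopifnot(k >= 1, psi_ag > 0, psi_gg > 0, tau >= 0,
            length(n_cases) == 2L, length(n_controls) == 2L,
            length(maf_range) == 2L)
  if (n_cases[1L] > n_cases[2L] || n_controls[1L] > n_controls[2L] ||
      maf_range[1L] > maf_range[2L] || n_cases[1L] < 1 ||
      n_controls[1L] < 1) {
    stop("degenerate range in simulation configuration", call. = FALSE)
  }
  if (maf_range[1L] <= 0 || maf_range[2L] >= 1) {
    stop("maf_range must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(k = as.integer(k), n_cases = n_cases, n_controls = n_controls,
         maf_range = maf_range, psi_ag = psi_ag, psi_gg = psi_gg,
         tau = tau, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.sim_metadata <- function(i) {
  ethnicities <- c("Asian", "Caucasian")
  sites <- c("Gastric", "Bladder", "Prostate", "Lung", "Colorectal",
             "Breast")
  list(
    study_id = sprintf("sim%03d", i),
    first_author = sprintf("Synth%03d", i),
    year = 2000L + (i - 1L) %% 20L,
    country = "Synthetica",
    ethnicity = ethnicities[1L + (i - 1L) %% 2L],
    cancer_type = sites[1L + (i - 1L) %% length(sites)],
    control_source = c("HB", "PB")[1L + (i - 1L) %% 2L]
  )
}

#' Simulate one synthetic case-control study
#'
#' Draws a single study from the generating process in [sim_config()],
#' using the current RNG state (callers seed it; [simulate_studies()] does
#' so deterministically).
#'
#' @param cfg A `sim_config`.
#' @param index Study index, used for the synthetic metadata labels.
#' @return A one-row study record data frame in the study-table schema.
#' @export
simulate_study <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  q <- stats::runif(1L, cfg$maf_range[1L], cfg$maf_range[2L])
  p_ctrl <- c(aa = (1 - q)^2, ag = 2 * q * (1 - q), gg = q^2)
  u <- if (cfg$tau > 0) stats::rnorm(1L, 0, cfg$tau) else 0
  log_gg <- log(cfg$psi_gg) + u
  log_ag <- if (cfg$psi_gg != 1) {
    log(cfg$psi_ag) * (log_gg / log(cfg$psi_gg))
  } else {
    log(cfg$psi_ag) + u / 2
  }
  tilt <- c(1, exp(log_ag), exp(log_gg))
  p_case <- p_ctrl * tilt
  p_case <- p_case / sum(p_case)
  n_case <- round(stats::runif(1L, cfg$n_cases[1L], cfg$n_cases[2L]))
  n_ctrl <- round(stats::runif(1L, cfg$n_controls[1L], cfg$n_controls[2L]))
  g_case <- stats::rmultinom(1L, n_case, p_case)[, 1L]
  g_ctrl <- stats::rmultinom(1L, n_ctrl, p_ctrl)[, 1L]
  meta <- .sim_metadata(index)
  data.frame(
    study_id = meta$study_id, first_author = meta$first_author,
    year = meta$year, country = meta$country, ethnicity = meta$ethnicity,
    cancer_type = meta$cancer_type, control_source = meta$control_source,
    case_aa = g_case[1L], case_ag = g_case[2L], case_gg = g_case[3L],
    control_aa = g_ctrl[1L], control_ag = g_ctrl[2L],
    control_gg = g_ctrl[3L],
    stringsAsFactors = FALSE
  )
}

#' Simulate a set of synthetic studies
#'
#' Seeds the generator from `cfg$seed` and draws `cfg$k` studies; identical
#' configurations yield identical tables.
#'
#' @param cfg A `sim_config`.
#' @return A validated `snp_studies` data frame with `cfg$k` rows.
#' @export
simulate_studies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  out <- do.call(rbind, lapply(seq_len(cfg$k), function(i) {
    simulate_study(cfg, i)
  }))
  validate_studies(out)
  out
}

#' Parameter-recovery and error-rate experiment
#'
#' Repeatedly simulates a study set and pools it under one estimator,
#' reporting the mean bias of the pooled log OR against the generating
#' truth, the empirical 95% CI coverage of the truth, and the rejection
#' rate of the Z test at 0.05 (the type-I error rate when the truth is a
#' null OR of 1).
#'
#' The truth is exact for the homozygote contrast (`log psi_gg`) and the
#' heterozygote contrast (`log psi_ag`); for the dominant and recessive
#' contrasts the genotype-OR tilt does not induce a constant 2x2 odds
#' ratio unless `psi_ag = psi_gg = 1`, so those contrasts are only accepted
#' under the null.
#'
#' @param cfg A `sim_config`; replicate r uses seed `cfg$seed + r`.
#' @param reps Number of replicates (>= 100 recommended for rates).
#' @param estimator `"dl_random"`, `"iv_fixed"` or `"mh_fixed"`.
#' @param model Genetic-model contrast to pool.
#' @return A `recovery_summary` list: mean_bias (log-OR scale),
#'   ci_coverage, rejection_rate, reps, truth_log_or, estimator, model.
#' @export
recovery_experiment <- function(cfg, reps = 200,
                                estimator = c("dl_random", "iv_fixed",
                                              "mh_fixed"),
                                model = c("homozygote", "heterozygote",
                                          "dominant", "recessive")) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 1)
  estimator <- match.arg(estimator)
  model <- match.arg(model)
  null_cfg <- cfg$psi_ag == 1 && cfg$psi_gg == 1 && cfg$tau == 0
  truth <- switch(model,
    homozygote = log(cfg$psi_gg),
    heterozygote = log(cfg$psi_ag),
    {
      if (!null_cfg) {
        stop("dominant/recessive truth is only exact under the null ",
             "(psi_ag = psi_gg = 1, tau = 0)", call. = FALSE)
      }
      0
    })
  bias <- covered <- rejected <- numeric(reps)
  for (r in seq_len(reps)) {
    rep_cfg <- cfg
    rep_cfg$seed <- cfg$seed + r
    studies <- simulate_studies(rep_cfg)
    tables <- contrast_tables(studies, model)
    pool <- switch(estimator,
      mh_fixed = pool_mh(tables),
      iv_fixed = pool_iv(study_effects(tables)),
      dl_random = pool_dl(study_effects(tables))
    )
    bias[r] <- pool$log_or - truth
    covered[r] <- pool$ci_low <= exp(truth) && exp(truth) <= pool$ci_high
    rejected[r] <- pool$p < 0.05
  }
  structure(
    list(mean_bias = mean(bias), ci_coverage = mean(covered),
         rejection_rate = mean(rejected), reps = as.integer(reps),
         truth_log_or = truth, estimator = estimator, model = model),
    class = "recovery_summary"
  )
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s, %s contrast, %d replicates)\n",
              x$estimator, x$model, x$reps))
  cat(sprintf("  truth log OR = %.3f; mean bias = %.4f; 95%% CI coverage = %.3f; rejection rate = %.3f\n",
              x$truth_log_or, x$mean_bias, x$ci_coverage, x$rejection_rate))
  invisible(x)
}
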