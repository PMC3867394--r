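test_that("single-study and identical-strata pooling collapse correctly", {
  s <- mcp1_studies()
  tab <- contrast_tables(s[s$study_id == "gu2011", ], "recessive")
  eff <- study_effects(tab)

  expect_equal(pool_mh(tab)$or, eff$or, tolerance = 1e-12)
  expect_equal(pool_iv(eff)$log_or, eff$log_or, tolerance = 1e-12)
  expect_equal(pool_iv(eff)$se, eff$se, tolerance = 1e-12)
  dl1 <- pool_dl(eff)
  expect_equal(dl1$log_or, eff$log_or, tolerance = 1e-12)
  expect_null(dl1$het)

  # two copies of the same table pool to the single-table OR
  twice <- rbind(tab, transform(tab, study_id = "gu2011b"))
  expect_equal(pool_mh(twice)$or, eff$or, tolerance = 1e-12)

  # k identical effects: mean unchanged, se shrinks by sqrt(k)
  k <- 4L
  same <- make_effects(rep(0.3, k), rep(0.2, k))
  iv <- pool_iv(same)
  expect_equal(iv$log_or, 0.3, tolerance = 1e-12)
  expect_equal(iv$se, 0.2 / sqrt(k), tolerance = 1e-12)
  q0 <- cochran_q(same)
  expect_equal(q0$q, 0, tolerance = 1e-12)
  expect_equal(q0$i2, 0)
  expect_equal(q0$tau2, 0)

  expect_error(pool_iv(data.frame()), "at least one")
})

test_that("DerSimonian-Laird collapses to fixed effects when Q <= df", {
  eff <- make_effects(c(0.28, 0.30, 0.32), c(0.4, 0.5, 0.45))
  het <- cochran_q(eff)
  expect_lte(het$q, het$df)
  expect_equal(het$tau2, 0)
  dl <- pool_dl(eff)
  iv <- pool_iv(eff)
  expect_equal(dl$log_or, iv$log_or, tolerance = 1e-14)
  expect_equal(dl$se, iv$se, tolerance = 1e-14)
})

test_that("pooled estimates match brute-force oracles on small instances", {
  set.seed(7)
  for (rep in 1:30) {
    k <- sample(1:3, 1)
    tab <- random_tables(k)
    eff <- study_effects(tab)
    expect_equal(pool_mh(tab)$or, oracle_mh(tab), tolerance = 1e-12)
    o_iv <- oracle_iv(eff$log_or, eff$se)
    expect_equal(pool_iv(eff)$log_or, o_iv$log_or, tolerance = 1e-12)
    expect_equal(pool_iv(eff)$se, o_iv$se, tolerance = 1e-12)
    if (k >= 2) {
      o_dl <- oracle_dl(eff$log_or, eff$se)
      expect_equal(pool_dl(eff)$log_or, o_dl$log_or, tolerance = 1e-12)
      expect_equal(pool_dl(eff)$se, o_dl$se, tolerance = 1e-12)
      o_q <- oracle_q(eff$log_or, eff$se)
      het <- cochran_q(eff)
      expect_equal(het$q, o_q$q, tolerance = 1e-12)
      expect_equal(het$tau2, o_q$tau2, tolerance = 1e-12)
    }
  }
})

test_that("random-effects intervals are never narrower than fixed effects", {
  set.seed(13)
  for (rep in 1:25) {
    k <- sample(2:12, 1)
    eff <- make_effects(rnorm(k, 0, 0.5), runif(k, 0.05, 0.6))
    expect_gte(pool_dl(eff)$se, pool_iv(eff)$se - 1e-14)
    iv <- pool_iv(eff)
    expect_gte(iv$log_or, min(eff$log_or) - 1e-12)
    expect_lte(iv$log_or, max(eff$log_or) + 1e-12)
  }
})

test_that("MH and IV fixed effects agree in the moderate-count regime", {
  s <- mcp1_studies()
  cls <- classify_studies(s)
  groupings <- c("cancer_group", "ethnicity_group", "source_group",
                 "size_class")
  for (model in genetic_models()) {
    strata <- c(list(all = seq_len(nrow(s))),
                unlist(lapply(groupings, function(g) {
                  split(seq_len(nrow(s)), cls[[g]], drop = TRUE)
                }), recursive = FALSE))
    for (idx in strata) {
      if (length(idx) < 2) next
      tab <- contrast_tables(s[idx, ], model)
      if (any(tab[, c("a", "b", "c", "d")] < 5)) next
      mh <- pool_mh(tab)$or
      iv <- pool_iv(study_effects(tab))$or
      expect_lt(abs(mh - iv) / iv, 0.03)
    }
  }
})

test_that("pooling agrees with metafor on the bundled data", {
  library(metafor)
  s <- mcp1_studies()
  tab <- contrast_tables(s, "recessive")
  eff <- study_effects(tab)

  ref_dl <- rma(yi = eff$log_or, sei = eff$se, method = "DL")
  dl <- pool_dl(eff)
  expect_equal(dl$log_or, as.numeric(coef(ref_dl)), tolerance = 1e-10)
  expect_equal(dl$se, ref_dl$se, tolerance = 1e-10)
  expect_equal(dl$het$tau2, ref_dl$tau2, tolerance = 1e-10)
  expect_equal(dl$het$q, ref_dl$QE, tolerance = 1e-10)
  expect_equal(dl$het$i2, ref_dl$I2 / 100, tolerance = 1e-8)

  ref_mh <- rma.mh(ai = tab$a, bi = tab$b, ci = tab$c, di = tab$d,
                   correct = FALSE)
  mh <- pool_mh(tab)
  expect_equal(mh$log_or, as.numeric(coef(ref_mh)), tolerance = 1e-10)
  expect_equal(mh$se, ref_mh$se, tolerance = 1e-10)
})

test_that("estimator selection applies the strict 0.10 heterogeneity rule", {
  fake_het <- function(p) {
    structure(list(q = 1, df = 1L, p_het = p, i2 = 0, tau2 = 0, k = 2L),
              class = "heterogeneity_result")
  }
  expect_equal(select_model(fake_het(0.808)), "mh_fixed")
  expect_equal(select_model(fake_het(0.004)), "dl_random")
  expect_equal(select_model(fake_het(0.10)), "dl_random")
  expect_equal(select_model(fake_het(0.100001)), "mh_fixed")
  expect_equal(select_model(fake_het(0.04), threshold = 0.01), "mh_fixed")
})

test_that("Cochran's Q needs at least two studies", {
  expect_error(cochran_q(make_effects(0.1, 0.2)), "at least two")
})
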