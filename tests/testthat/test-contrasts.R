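bektas <- function() mcp1_studies()[mcp1_studies()$study_id == "bektas2012", ]

test_that("2x2 tables implement the four genetic-model contrasts", {
  s <- bektas()
  rec <- contrast_tables(s, "recessive")
  expect_equal(unlist(rec[, c("a", "b", "c", "d")], use.names = FALSE),
               c(6, 123, 1, 139))
  dom <- contrast_tables(s, "dominant")
  expect_equal(unlist(dom[, c("a", "b", "c", "d")], use.names = FALSE),
               c(62, 67, 46, 94))
  hom <- contrast_tables(s, "homozygote")
  expect_equal(unlist(hom[, c("a", "b", "c", "d")], use.names = FALSE),
               c(6, 67, 1, 94))
  het <- contrast_tables(s, "heterozygote")
  expect_equal(unlist(het[, c("a", "b", "c", "d")], use.names = FALSE),
               c(56, 67, 45, 94))

  # dominant/recessive conserve individuals
  all_s <- mcp1_studies()
  for (model in c("dominant", "recessive")) {
    tab <- contrast_tables(all_s, model)
    expect_equal(tab$a + tab$b,
                 all_s$case_aa + all_s$case_ag + all_s$case_gg)
    expect_equal(tab$c + tab$d,
                 all_s$control_aa + all_s$control_ag + all_s$control_gg)
  }

  # empty case margin under the homozygote contrast is degenerate
  degen <- all_s[1, ]
  degen[, c("case_aa", "case_gg")] <- 0L
  degen$case_ag <- 50L
  expect_error(contrast_tables(degen, "homozygote"), "degenerate")
})

test_that("continuity correction touches only zero-cell tables", {
  tab <- data.frame(study_id = c("z", "nz"),
                    a = c(0, 6), b = c(10, 123), c = c(5, 1), d = c(10, 139),
                    corrected = FALSE)
  out <- continuity_correct(tab)
  expect_equal(unlist(out[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(0.5, 10.5, 5.5, 10.5))
  expect_true(out$corrected[1])
  expect_equal(unlist(out[2, c("a", "b", "c", "d")], use.names = FALSE),
               c(6, 123, 1, 139))
  expect_false(out$corrected[2])

  all_zero <- data.frame(study_id = "x", a = 0, b = 0, c = 0, d = 0,
                         corrected = FALSE)
  expect_error(continuity_correct(all_zero), "degenerate")
})

test_that("Woolf odds ratios and standard errors match hand calculation", {
  eff <- study_effects(contrast_tables(bektas(), "recessive"))
  expect_equal(eff$or, 6 * 139 / (123 * 1), tolerance = 1e-12)
  expect_equal(signif(eff$or, 3), 6.78)
  expect_equal(eff$se, sqrt(1 / 6 + 1 / 123 + 1 / 1 + 1 / 139),
               tolerance = 1e-12)
  expect_equal(signif(eff$se, 4), 1.087)
  expect_equal(eff$ci_low, exp(eff$log_or - 1.96 * eff$se))
  expect_equal(eff$ci_high, exp(eff$log_or + 1.96 * eff$se))

  s <- mcp1_studies()
  saenz <- study_effects(contrast_tables(s[s$study_id == "saenz2008", ],
                                         "heterozygote"))
  expect_equal(saenz$or, 17800 / 21402, tolerance = 1e-12)
  expect_equal(signif(saenz$or, 3), 0.832)

  # balanced table: ad = bc gives OR exactly 1
  bal <- data.frame(study_id = "b", a = 6, b = 3, c = 8, d = 4,
                    corrected = FALSE)
  expect_equal(study_effects(bal)$log_or, 0)

  # zero cell without correction is a domain error
  zc <- data.frame(study_id = "z", a = 0, b = 10, c = 5, d = 10,
                   corrected = FALSE)
  expect_error(study_effects(zc, correct = FALSE), "zero cell")
})

test_that("every fixture OR equals the exact integer cross-product ratio", {
  s <- mcp1_studies()
  for (model in genetic_models()) {
    tab <- contrast_tables(s, model)
    eff <- study_effects(tab, correct = FALSE)
    expect_equal(eff$or, (tab$a * tab$d) / (tab$b * tab$c),
                 tolerance = 1e-14)
  }
})

test_that("swapping rows or columns of a 2x2 table inverts the odds ratio", {
  set.seed(42)
  for (rep in 1:20) {
    tab <- random_tables(1)
    e <- study_effects(tab)
    rows_swapped <- transform(tab, a = c, b = d, c = a, d = b)
    cols_swapped <- transform(tab, a = b, b = a, c = d, d = c)
    expect_equal(study_effects(rows_swapped)$log_or, -e$log_or,
                 tolerance = 1e-12)
    expect_equal(study_effects(cols_swapped)$log_or, -e$log_or,
                 tolerance = 1e-12)
    expect_equal(study_effects(rows_swapped)$se, e$se, tolerance = 1e-12)
  }
})
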