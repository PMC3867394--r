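#' Pearson chi-square test for Hardy-Weinberg equilibrium
#'
#' Tests a single sample of genotype counts (AA, AG, GG) against the
#' Hardy-Weinberg proportions p^2, 2pq, q^2 at the sample allele frequency.
#' The statistic has 1 degree of freedom: three genotype classes minus one
#' estimated allele frequency minus one. No continuity correction is
#' applied. Deviation at p < 0.05 is flagged; such studies are reported but
#' not excluded from pooling.
#'
#' @param aa,ag,gg Nonnegative genotype counts.
#' @return An `hwe_result` list: `chi2`, `df` (= 1), `p`, `in_hwe`
#'   (`p >= 0.05`), `expected` (named expected counts), `monomorphic`.
#'   A monomorphic sample (allele frequency 0 or 1) returns `chi2 = 0`,
#'   `p = 1` and `monomorphic = TRUE`.
#' @examples
#' hwe_test(124, 82, 5)   # deviates, p ~ 0.04
#' hwe_test(25, 50, 25)   # exact HW proportions, chi2 = 0
#' @export
hwe_test <- function(aa, ag, gg) {
  stopifnot(length(aa) == 1L, length(ag) == 1L, length(gg) == 1L,
            aa >= 0, ag >= 0, gg >= 0)
  n <- aa + ag + gg
  if (n == 0) {
    stop("cannot test Hardy-Weinberg equilibrium on an empty sample",
         call. = FALSE)
  }
  p_a <- (2 * aa + ag) / (2 * n)
  monomorphic <- p_a == 0 || p_a == 1
  expected <- n * c(aa = p_a^2, ag = 2 * p_a * (1 - p_a), gg = (1 - p_a)^2)
  if (monomorphic) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- sum((c(aa, ag, gg) - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(chi2 = chi2, df = 1L, p = p, in_hwe = p >= 0.05,
         expected = expected, monomorphic = monomorphic),
    class = "hwe_result"
  )
}

#' Hardy-Weinberg equilibrium table for study controls
#'
#' Applies [hwe_test()] to every control genotype set of a study table,
#' mirroring the HWE column of a study-characteristics table.
#'
#' @param studies A `snp_studies` data frame.
#' @return A data frame: study_id, chi2, p, in_hwe.
#' @export
hwe_table <- function(studies) {
  studies <- validate_studies(studies)
  res <- lapply(seq_len(nrow(studies)), function(i) {
    h <- hwe_test(studies$control_aa[i], studies$control_ag[i],
                  studies$control_gg[i])
    data.frame(study_id = studies$study_id[i], chi2 = h$chi2, p = h$p,
               in_hwe = h$in_hwe, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg equilibrium test: chi2 = %.4f (df = 1), p = %.4g\n",
              x$chi2, x$p))
  if (x$monomorphic) cat("sample is monomorphic\n")
  cat(sprintf("controls %s in Hardy-Weinberg equilibrium (threshold p < 0.05)\n",
              if (x$in_hwe) "are" else "are NOT"))
  invisible(x)
}
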