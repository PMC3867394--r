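#' @importFrom utils read.delim write.table
NULL

.study_columns <- c("study_id", "first_author", "year", "country",
                    "ethnicity", "cancer_type", "control_source",
                    "case_aa", "case_ag", "case_gg",
                    "control_aa", "control_ag", "control_gg")

.count_columns <- c("case_aa", "case_ag", "case_gg",
                    "control_aa", "control_ag", "control_gg")

.ethnicity_levels <- c("Asian", "Caucasian", "Mixed")
.source_levels <- c("HB", "PB")

# Cancer sites that constitute the digestive-system subgroup.
.digestive_sites <- c("oral", "gastric", "colorectal", "hepatocellular")

#' Validate a study table
#'
#' Checks the 13-column case-control study schema: column presence, integer
#' nonnegative genotype counts, positive case and control totals, closed
#' ethnicity/control-source vocabularies, 4-digit years and unique study ids.
#'
#' @param x A data frame of study records.
#' @return `x`, invisibly, with class `snp_studies` prepended.
#' @export
validate_studies <- function(x) {
  if (!is.data.frame(x)) {
    stop("study table must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(.study_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .count_columns) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != trunc(v))) {
      bad <- which(!is.finite(v) | v < 0 | v != trunc(v))
      stop(sprintf("column '%s' has a non-integer or negative count (study %s)",
                   col, paste(x$study_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  dup <- x$study_id[duplicated(x$study_id)]
  if (length(dup) > 0L) {
    stop("duplicate study_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  case_n <- x$case_aa + x$case_ag + x$case_gg
  ctrl_n <- x$control_aa + x$control_ag + x$control_gg
  if (any(case_n == 0) || any(ctrl_n == 0)) {
    bad <- x$study_id[case_n == 0 | ctrl_n == 0]
    stop("study with empty case or control genotype counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_eth <- unique(x$ethnicity[!x$ethnicity %in% .ethnicity_levels])
  if (length(bad_eth) > 0L) {
    stop("ethnicity outside {Asian, Caucasian, Mixed}: ",
         paste(bad_eth, collapse = ", "), call. = FALSE)
  }
  bad_src <- unique(x$control_source[!x$control_source %in% .source_levels])
  if (length(bad_src) > 0L) {
    stop("control_source outside {HB, PB}: ",
         paste(bad_src, collapse = ", "), call. = FALSE)
  }
  if (any(x$year < 1000 | x$year > 9999)) {
    stop("year must be a 4-digit integer", call. = FALSE)
  }
  if (!inherits(x, "snp_studies")) {
    class(x) <- c("snp_studies", class(x))
  }
  invisible(x)
}

#' Read a delimited case-control study table
#'
#' Reads a comma- or tab-delimited table of genotype-count study records.
#' The delimiter is auto-detected from the header line. The file must carry
#' the 13 schema columns: study_id, first_author, year, country, ethnicity,
#' cancer_type, control_source, case_aa, case_ag, case_gg, control_aa,
#' control_ag, control_gg.
#'
#' @param file Path to a CSV or TSV file (UTF-8).
#' @return A validated `snp_studies` data frame, one row per study.
#' @seealso [mcp1_studies()] for the bundled data set, [write_studies()].
#' @export
read_studies <- function(file) {
  if (!file.exists(file)) {
    stop("no such study table: ", file, call. = FALSE)
  }
  header <- readLines(file, n = 1L, encoding = "UTF-8")
  if (length(header) == 0L) {
    stop("empty study table: ", file, call. = FALSE)
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  x <- read.delim(file, sep = sep, stringsAsFactors = FALSE,
                  encoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(.study_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- x[, .study_columns]
  for (col in c(.count_columns, "year")) {
    v <- x[[col]]
    if (is.character(v)) {
      suppressWarnings(v_num <- as.numeric(v))
      if (anyNA(v_num)) {
        bad <- x$study_id[is.na(v_num)]
        stop(sprintf("column '%s' has a non-numeric value (study %s)",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      x[[col]] <- v_num
    }
  }
  if (nrow(x) == 0L) {
    class(x) <- c("snp_studies", class(x))
    return(x)
  }
  validate_studies(x)
}

#' Write a study table
#'
#' @param x A `snp_studies` data frame.
#' @param file Output path.
#' @param sep Field separator, `"\t"` (default) or `","`.
#' @return `file`, invisibly.
#' @export
write_studies <- function(x, file, sep = "\t") {
  write.table(x[, .study_columns], file, sep = sep, quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' The bundled MCP-1 -2518A/G study set
#'
#' Nineteen case-control studies of the MCP-1 (CCL2) -2518A/G promoter
#' polymorphism and cancer risk, with AA/AG/GG genotype counts in cases and
#' controls plus study metadata (country, ethnicity, cancer site, control
#' source), transcribed from the published study-characteristics table.
#' Two studies (Qin 2009 hepatocellular and nasopharyngeal) share one
#' control series; they are kept as separate rows, exactly as pooled in the
#' original analysis.
#'
#' Note one internal inconsistency of the published table, preserved here as
#' printed: the Arshad 2013 control genotype counts sum to 155 while the
#' published study size column says 190 controls.
#'
#' @return A validated `snp_studies` data frame with 19 rows.
#' @export
mcp1_studies <- function() {
  path <- system.file("extdata", "mcp1_2518_studies.tsv",
                      package = "snpmeta", mustWork = TRUE)
  read_studies(path)
}

#' Subgroup labels for study records
#'
#' Derives the four stratification factors used in subgroup analyses:
#' * `cancer_group`: digestive (oral, gastric, colorectal, hepatocellular),
#'   bladder, prostate, or other;
#' * `size_class`: large when cases + controls exceed 500 individuals
#'   (strict inequality; totals are genotype-count sums), else small;
#' * `ethnicity_group` and `source_group`: copied from the record.
#'
#' Unrecognized cancer sites map to `other` with a notice. Classification is
#' deterministic: it depends only on the record fields.
#'
#' @param x A `snp_studies` data frame.
#' @return A data frame with study_id and the four group labels.
#' @export
classify_studies <- function(x) {
  x <- validate_studies(x)
  site <- tolower(trimws(x$cancer_type))
  known <- c(.digestive_sites, "bladder", "prostate",
             "renal", "cervical", "breast", "lung", "endometrial",
             "nasopharyngeal")
  unknown <- unique(x$cancer_type[!site %in% known])
  if (length(unknown) > 0L) {
    message("unrecognized cancer type(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
  }
  cancer_group <- ifelse(site %in% .digestive_sites, "digestive",
                  ifelse(site == "bladder", "bladder",
                  ifelse(site == "prostate", "prostate", "other")))
  total <- x$case_aa + x$case_ag + x$case_gg +
    x$control_aa + x$control_ag + x$control_gg
  data.frame(
    study_id = x$study_id,
    cancer_group = factor(cancer_group,
                          levels = c("digestive", "bladder", "prostate",
                                     "other")),
    size_class = factor(ifelse(total > 500, "large", "small"),
                        levels = c("large", "small")),
    ethnicity_group = factor(x$ethnicity, levels = .ethnicity_levels),
    source_group = factor(x$control_source, levels = .source_levels),
    n_total = total,
    stringsAsFactors = FALSE
  )
}

#' @export
print.snp_studies <- function(x, ...) {
  cat(sprintf("Case-control genotype study table: %d studies, %d cases / %d controls\n",
              nrow(x),
              sum(x$case_aa + x$case_ag + x$case_gg),
              sum(x$control_aa + x$control_ag + x$control_gg)))
  print.data.frame(x, ...)
  invisible(x)
}
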