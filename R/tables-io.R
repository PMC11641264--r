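## Data model for the two inputs of the risk pipeline: a case series
## (counts of cases per level of each categorical determinant) and a
## population reference (proportion of the general population in each level).
## All proportions are fractions in [0, 1] internally; percentages exist only
## at I/O and rendering boundaries.

#' Construct a case series
#'
#' A case series holds, for each categorical determinant (age group, gender,
#' education, comorbidities, ...), the number of cases observed at each
#' level, together with the cohort totals. Factors flagged `exhaustive` have
#' mutually exclusive levels covering every case, so their counts must sum to
#' `n_cases`; non-exhaustive factors (comorbidities, reported symptoms) may
#' overlap across patients and are exempt.
#'
#' @param levels data.frame with columns `factor`, `level`, `count`,
#'   `exhaustive`.
#' @param n_cases positive integer, total number of cases.
#' @param n_screened positive integer, total screened cohort size
#'   (>= `n_cases`).
#' @param disease_label text label for the condition.
#' @return object of class `case_series`: the validated `levels` table with a
#'   `proportion` column (`count / n_cases`, the conditional proportion of
#'   the level among cases) and attributes `n_cases`, `n_screened`,
#'   `disease_label`.
#' @export
case_series <- function(levels, n_cases, n_screened, disease_label = "disease") {
  required <- c("factor", "level", "count", "exhaustive")
  missing_cols <- setdiff(required, names(levels))
  if (length(missing_cols))
    abort_format(paste0("case table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  if (length(n_cases) != 1L || is.na(n_cases) || n_cases < 1 ||
      n_cases != trunc(n_cases))
    abort_domain("n_cases must be a positive integer")
  if (length(n_screened) != 1L || is.na(n_screened) || n_screened < n_cases)
    abort_domain("n_screened must be an integer >= n_cases")

  lv <- data.frame(
    factor     = nfc(levels$factor),
    level      = nfc(levels$level),
    count      = as.numeric(levels$count),
    exhaustive = as.logical(levels$exhaustive),
    stringsAsFactors = FALSE
  )
  if (any(is.na(lv$count)) || any(lv$count != trunc(lv$count)))
    abort_format("counts must be integers")
  if (any(lv$count < 0))
    abort_validation("negative case count")
  if (any(is.na(lv$exhaustive)))
    abort_format("exhaustive flag must be TRUE/FALSE")
  if (anyDuplicated(paste(lv$factor, lv$level, sep = "\r")))
    abort_validation("duplicate (factor, level) pair in case table")
  for (f in unique(lv$factor)) {
    rows <- lv[lv$factor == f, ]
    if (length(unique(rows$exhaustive)) != 1L)
      abort_validation(paste0("factor '", f, "' mixes exhaustive flags"))
    if (rows$exhaustive[1] && sum(rows$count) != n_cases)
      abort_validation(paste0(
        "exhaustive factor '", f, "' has counts summing to ",
        sum(rows$count), ", expected n_cases = ", n_cases))
  }
  lv$proportion <- lv$count / n_cases

  structure(lv,
            n_cases = as.integer(n_cases),
            n_screened = as.integer(n_screened),
            disease_label = disease_label,
            class = c("case_series", "data.frame"))
}

#' @export
print.case_series <- function(x, ...) {
  cat(sprintf("Case series: %s (%d cases among %d screened)\n",
              attr(x, "disease_label"), attr(x, "n_cases"),
              attr(x, "n_screened")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a case table from CSV
#'
#' Expects a UTF-8 CSV with header `factor,level,count,exhaustive`. Level
#' proportions among cases are computed from the counts and `n_cases`.
#'
#' @param path file path.
#' @param n_cases,n_screened cohort totals (these are study-level constants
#'   printed alongside the tables, not derivable from the per-factor counts
#'   when non-exhaustive factors are present).
#' @param disease_label text label for the condition.
#' @return a [case_series].
#' @export
read_case_table <- function(path, n_cases, n_screened,
                            disease_label = "disease") {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  if (file.size(path) == 0) abort_format(paste0("empty case table: ", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) abort_format(paste0("cannot parse ", path, ": ",
                                            conditionMessage(e))))
  case_series(df, n_cases = n_cases, n_screened = n_screened,
              disease_label = disease_label)
}

#' Write a case table to CSV
#'
#' Inverse of [read_case_table()]: counts round-trip exactly.
#'
#' @param x a [case_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(x, path) {
  stopifnot(inherits(x, "case_series"))
  out <- data.frame(factor = x$factor, level = x$level,
                    count = as.integer(x$count), exhaustive = x$exhaustive)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Construct a population reference
#'
#' Maps each determinant level to the proportion of the general (reference)
#' population exhibiting it. Proportions are fractions in (0, 1\]. Levels of
#' one exhaustive factor need not sum to 1: a reference table restricted to
#' adults covers only part of the full population (the packaged age levels
#' cover 30.92% of it).
#'
#' @param proportions named numeric vector, `level -> fraction`.
#' @param source_note provenance text for the reference proportions.
#' @return object of class `population_reference`.
#' @export
population_reference <- function(proportions, source_note = "") {
  if (is.null(names(proportions)) || any(!nzchar(names(proportions))))
    abort_format("population proportions must be named by level")
  p <- as.numeric(proportions)
  names(p) <- nfc(names(proportions))
  if (anyDuplicated(names(p)))
    abort_validation("duplicate level in population reference")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    abort_validation("population proportions must lie in (0, 1]")
  structure(list(entries = p, source_note = source_note),
            class = "population_reference")
}

#' @export
print.population_reference <- function(x, ...) {
  cat("Population reference (", length(x$entries), " levels)\n", sep = "")
  if (nzchar(x$source_note)) cat("Source: ", x$source_note, "\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Read a population reference from CSV
#'
#' Expects columns `level,proportion` and optionally `units` (`"percent"` or
#' `"fraction"` per row). Percentages are converted to fractions; values must
#' lie in (0, 1\] after normalization. A zero proportion is rejected because
#' it makes the posterior undefined for any level that has cases.
#'
#' @param path file path.
#' @param units default unit when the file has no `units` column.
#' @param source_note provenance text.
#' @return a [population_reference].
#' @export
read_population_reference <- function(path,
                                      units = c("fraction", "percent"),
                                      source_note = "") {
  units <- match.arg(units)
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  if (file.size(path) == 0)
    abort_format(paste0("empty population reference: ", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) abort_format(paste0("cannot parse ", path, ": ",
                                            conditionMessage(e))))
  if (!all(c("level", "proportion") %in% names(df)))
    abort_format("population reference needs columns level,proportion")
  ## tolerate values written as "3.55%" by stripping the sign
  raw <- df$proportion
  pct_suffix <- grepl("%\\s*$", as.character(raw))
  val <- suppressWarnings(as.numeric(sub("%\\s*$", "", as.character(raw))))
  if (any(is.na(val))) abort_format("non-numeric population proportion")
  row_units <- if ("units" %in% names(df)) df$units else rep(units, nrow(df))
  row_units[pct_suffix] <- "percent"
  if (!all(row_units %in% c("percent", "fraction")))
    abort_format("units column must be 'percent' or 'fraction'")
  val[row_units == "percent"] <- val[row_units == "percent"] / 100
  p <- stats::setNames(val, df$level)
  population_reference(p, source_note = source_note)
}

#' Packaged fixtures: the Hail glaucoma case series
#'
#' Case counts of the published cross-sectional glaucoma study in the Hail
#' region (200 cases among 9407 screened outpatients): age groups, gender,
#' education, reported symptoms, diagnostic context, glaucoma type, disease
#' duration and comorbidities.
#'
#' @return a [case_series] with `n_cases = 200`, `n_screened = 9407`.
#' @export
hail_case_series <- function() {
  read_case_table(
    system.file("extdata", "hail_cases.csv", package = "postrisk",
                mustWork = TRUE),
    n_cases = 200, n_screened = 9407, disease_label = "glaucoma")
}

#' Packaged fixtures: general-population reference proportions
#'
#' Proportion of the general population in each determinant level used by the
#' published risk table (UN statistics per the study's source note). Age
#' levels cover only the adult (40+) part of the population and do not sum
#' to 1.
#'
#' @return a [population_reference].
#' @export
hail_population_reference <- function() {
  read_population_reference(
    system.file("extdata", "hail_population.csv", package = "postrisk",
                mustWork = TRUE),
    source_note = "Unstats.un.org")
}

#' Packaged fixtures: published posterior risk table
#'
#' The published per-level chances of glaucoma (posterior probabilities, in
#' percent in the source, fractions here), used to calibrate the study's
#' unpublished prior by algebraic inversion — see [calibrate_prior()].
#'
#' @return named numeric vector of posterior fractions, `level -> posterior`.
#' @export
hail_published_posteriors <- function() {
  path <- system.file("extdata", "hail_posteriors.csv", package = "postrisk",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stats::setNames(df$posterior / 100, nfc(df$level))
}
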