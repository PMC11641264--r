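## Assembles every output table of the pipeline into one bundle and renders
## it as Markdown, CSV or JSON. Percent cells follow the package-wide
## rounding rule (half-up); every cell is traceable to an operation output.

#' Run the full reporting pipeline
#'
#' Reads the case table and population reference, computes the prevalence
#' with its confidence interval, per-level proportions with confidence
#' intervals for every factor, the posterior risk table, and the top-k
#' summary.
#'
#' @param cases_path CSV path for the case table (see [read_case_table()]).
#' @param population_path CSV path for the population reference.
#' @param n_cases,n_screened cohort totals.
#' @param prior prior specification as in [build_risk_table()].
#' @param published_path optional CSV (`level,posterior,units`) with a
#'   published posterior table, needed for `prior = "auto"`.
#' @param confidence confidence level for all intervals.
#' @param ci_method binomial CI method for the proportion tables.
#' @param top_k number of top-risk levels to summarize.
#' @param bootstrap number of bootstrap replicates to attach interval columns
#'   to the risk table (0 = none; >= 100 otherwise).
#' @param seed seed for the bootstrap.
#' @return object of class `report_bundle`.
#' @export
run_report <- function(cases_path, population_path, n_cases, n_screened,
                       prior = "observed", published_path = NULL,
                       confidence = 0.95, ci_method = "wald", top_k = 7,
                       bootstrap = 0, seed = 1L) {
  cases <- read_case_table(cases_path, n_cases = n_cases,
                           n_screened = n_screened)
  pop <- read_population_reference(population_path)
  published <- NULL
  if (!is.null(published_path)) {
    df <- utils::read.csv(published_path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
    if (!all(c("level", "posterior") %in% names(df)))
      abort_format("published posterior table needs columns level,posterior")
    val <- as.numeric(df$posterior)
    if ("units" %in% names(df)) val[df$units == "percent"] <- val[df$units == "percent"] / 100
    published <- stats::setNames(val, df$level)
  }

  prev_ci <- binom_interval(attr(cases, "n_cases"), attr(cases, "n_screened"),
                            confidence, method = ci_method)
  factor_tables <- lapply(split(seq_len(nrow(cases)), cases$factor)[
    unique(cases$factor)], function(idx) {
      rows <- cases[idx, , drop = FALSE]
      cis <- lapply(rows$count, binom_interval, n = attr(cases, "n_cases"),
                    confidence = confidence, method = ci_method)
      data.frame(
        level = rows$level,
        count = as.integer(rows$count),
        percent = format_percent(rows$proportion, 2),
        ci = vapply(cis, format, character(1), decimals = 1),
        stringsAsFactors = FALSE)
    })

  risk <- build_risk_table(cases, pop, prior = prior, published = published)
  boot <- NULL
  if (bootstrap > 0) {
    boot <- bootstrap_posterior(cases, pop, prior = attr(risk, "prior"),
                                replicates = bootstrap, seed = seed,
                                confidence = confidence)
  }
  top <- rank_top_factors(risk, min(top_k, nrow(risk)))
  diagnostics <- lapply(unique(risk$factor), function(f)
    c(list(factor = f), total_probability_diagnostic(risk, f, pop)))

  structure(list(
    disease_label = attr(cases, "disease_label"),
    n_cases = attr(cases, "n_cases"),
    n_screened = attr(cases, "n_screened"),
    prevalence = prev_ci,
    factor_tables = factor_tables,
    risk_table = risk,
    bootstrap = boot,
    top = top,
    diagnostics = diagnostics,
    confidence = confidence
  ), class = "report_bundle")
}

risk_table_frame <- function(bundle, decimals = 2) {
  rt <- bundle$risk_table
  out <- data.frame(
    factor = rt$factor,
    level = rt$level,
    count = rt$case_count,
    case_percent = format_percent(rt$case_proportion, 1, trim = TRUE,
                                  symbol = FALSE),
    population_percent = format_percent(rt$population_proportion, 2,
                                        trim = TRUE, symbol = FALSE),
    risk_percent = ifelse(rt$infeasible, "INFEASIBLE",
                          format_percent(pmin(rt$posterior, 1), decimals,
                                         trim = TRUE, symbol = FALSE)),
    prior = rep(attr(rt, "prior"), nrow(rt)),
    infeasible = rt$infeasible,
    stringsAsFactors = FALSE)
  if (!is.null(bundle$bootstrap)) {
    out$risk_lower <- vapply(bundle$bootstrap[rt$level], `[[`, numeric(1),
                             "lower")
    out$risk_upper <- vapply(bundle$bootstrap[rt$level], `[[`, numeric(1),
                             "upper")
  }
  out
}

md_table <- function(df) {
  esc <- function(x) gsub("\\|", "\\\\|", as.character(x))
  header <- paste0("| ", paste(esc(names(df)), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r)
    paste0("| ", paste(esc(r), collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Render a report bundle as Markdown
#'
#' Deterministic: identical input gives byte-identical output. Sections for
#' factors absent from the input are omitted.
#'
#' @param bundle a `report_bundle` from [run_report()].
#' @return a single Markdown string.
#' @export
render_markdown <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  parts <- character(0)
  parts <- c(parts, paste0("# ", bundle$disease_label, " risk report"), "")
  parts <- c(parts, "## Prevalence", "")
  prev_df <- data.frame(
    status = c(bundle$disease_label, "total screened"),
    count = c(bundle$n_cases, bundle$n_screened),
    percent = c(format_percent(bundle$prevalence$point, 1), "100.0%"),
    ci = c(format(bundle$prevalence, decimals = 1), ""))
  parts <- c(parts, md_table(prev_df), "")
  for (f in names(bundle$factor_tables)) {
    parts <- c(parts, paste0("## Cases by ", f), "",
               md_table(bundle$factor_tables[[f]]), "")
  }
  parts <- c(parts,
             sprintf("## Posterior risk (prior = %.4f, %s)",
                     attr(bundle$risk_table, "prior"),
                     attr(bundle$risk_table, "prior_provenance")), "",
             md_table(risk_table_frame(bundle)), "")
  if (nrow(bundle$top)) {
    parts <- c(parts, paste0("## Top ", nrow(bundle$top), " risk levels"), "",
               md_table(data.frame(
                 level = bundle$top$level,
                 risk_percent = format_percent(pmin(bundle$top$posterior, 1),
                                               2, trim = TRUE,
                                               symbol = FALSE))), "")
  }
  paste(parts, collapse = "\n")
}

#' Render the risk table of a report bundle as CSV
#'
#' @param bundle a `report_bundle`.
#' @param path output path; `NULL` returns the CSV text instead.
#' @return `path` invisibly, or the CSV text when `path = NULL`.
#' @export
render_csv <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  df <- risk_table_frame(bundle)
  if (is.null(path)) {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    return(paste(out, collapse = "\n"))
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Render a report bundle as JSON
#'
#' @param bundle a `report_bundle`.
#' @return a JSON string.
#' @export
render_json <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  jsonlite::toJSON(list(
    disease = bundle$disease_label,
    n_cases = bundle$n_cases,
    n_screened = bundle$n_screened,
    prevalence = list(point = bundle$prevalence$point,
                      lower = bundle$prevalence$lower,
                      upper = bundle$prevalence$upper,
                      method = bundle$prevalence$method,
                      confidence = bundle$prevalence$confidence),
    prior = attr(bundle$risk_table, "prior"),
    prior_provenance = attr(bundle$risk_table, "prior_provenance"),
    risk_table = risk_table_frame(bundle),
    top = bundle$top,
    diagnostics = bundle$diagnostics
  ), auto_unbox = TRUE, digits = NA)
}
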