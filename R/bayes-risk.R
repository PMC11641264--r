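## The core computation: posterior disease risk per determinant level via
## Bayes' theorem,
##
##   P(D | RF) = P(RF | D) * P(D) / P(RF)
##
## where P(RF | D) is the proportion of cases exhibiting the level,
## P(RF) the proportion of the general population exhibiting it, and P(D)
## the marginal (prior) disease probability. The prior used by the published
## risk table is nowhere printed; calibrate_prior() recovers it by algebraic
## inversion of the published posteriors.

#' Posterior disease risk for one determinant level
#'
#' Computes `case_proportion * prior / population_proportion`. A result
#' above 1 signals mutually inconsistent inputs; it is returned as-is with
#' the `infeasible` attribute set, never silently clamped.
#'
#' @param case_proportion P(RF | D): proportion of cases with the level,
#'   fraction in (0, 1\].
#' @param population_proportion P(RF): proportion of the reference population
#'   with the level, fraction in (0, 1\].
#' @param prior P(D): marginal disease probability, fraction in (0, 1).
#' @return numeric vector of posterior probabilities P(D | RF), with a
#'   logical attribute `infeasible` marking entries > 1.
#' @examples
#' posterior_risk(0.275, 0.0355, 0.056)  # 0.4338
#' @export
posterior_risk <- function(case_proportion, population_proportion, prior) {
  if (any(population_proportion <= 0))
    abort_domain("population_proportion must be > 0")
  if (any(case_proportion < 0 | case_proportion > 1) ||
      any(population_proportion > 1))
    abort_domain("proportions must be fractions in [0, 1]")
  if (any(prior <= 0 | prior >= 1))
    abort_domain("prior must lie in (0, 1)")
  post <- case_proportion * prior / population_proportion
  structure(post, infeasible = post > 1)
}

#' Prior implied by a published posterior
#'
#' Algebraic inversion of the posterior formula:
#' `prior = posterior * population_proportion / case_proportion`.
#'
#' @param posterior published P(D | RF), fraction.
#' @param case_proportion P(RF | D), fraction in (0, 1\].
#' @param population_proportion P(RF), fraction in (0, 1\].
#' @return implied prior P(D), numeric vector.
#' @examples
#' implied_prior(0.4338, 0.275, 0.0355)  # 0.056
#' @export
implied_prior <- function(posterior, case_proportion, population_proportion) {
  if (any(case_proportion <= 0))
    abort_domain("case_proportion must be > 0")
  if (any(posterior <= 0 | posterior > 1) ||
      any(case_proportion > 1) ||
      any(population_proportion <= 0 | population_proportion > 1))
    abort_domain("arguments must be fractions in (0, 1]")
  posterior * population_proportion / case_proportion
}

#' Calibrate the common prior behind a published posterior table
#'
#' Each row of a posterior table implies a prior by inversion; if the table
#' was computed with one common prior, the implied values agree. Returns
#' their median as the calibrated prior and the maximum absolute deviation
#' from that median as a consistency diagnostic. On the packaged table all
#' 14 rows agree to within about 1e-4, far below the 1e-3 tolerance used by
#' the fixture test.
#'
#' @param rows data.frame with columns `posterior`, `case_proportion`,
#'   `population_proportion` (fractions); >= 2 rows.
#' @param tolerance dispersion above which a warning is logged.
#' @return list with `prior` (median implied prior), `dispersion` (max
#'   absolute deviation from the median), and `implied` (per-row priors).
#' @export
calibrate_prior <- function(rows, tolerance = 1e-3) {
  if (is.null(rows) || nrow(rows) < 2)
    abort_domain("calibrate_prior() needs at least 2 rows")
  needed <- c("posterior", "case_proportion", "population_proportion")
  if (!all(needed %in% names(rows)))
    abort_format(paste0("rows must have columns: ",
                        paste(needed, collapse = ", ")))
  implied <- implied_prior(rows$posterior, rows$case_proportion,
                           rows$population_proportion)
  prior <- stats::median(implied)
  dispersion <- max(abs(implied - prior))
  if (dispersion > tolerance)
    risk_log("warn", sprintf(
      "implied priors disagree: max deviation %.2e exceeds %.1e; the table was likely not computed with a single prior",
      dispersion, tolerance))
  list(prior = prior, dispersion = dispersion, implied = implied)
}

resolve_prior <- function(prior, cases, pop, published) {
  if (is.numeric(prior)) {
    if (length(prior) != 1L || prior <= 0 || prior >= 1)
      abort_domain("numeric prior must be a single value in (0, 1)")
    return(list(prior = prior, provenance = "user_supplied"))
  }
  if (identical(prior, "observed")) {
    return(list(prior = attr(cases, "n_cases") / attr(cases, "n_screened"),
                provenance = "observed_prevalence"))
  }
  if (identical(prior, "auto")) {
    if (is.null(published))
      abort_domain("prior = 'auto' needs a published posterior table")
    lev <- nfc(names(published))
    idx <- match(lev, cases$level)
    if (anyNA(idx))
      abort_validation(paste0("published posterior level(s) absent from the case series: ",
                              paste(lev[is.na(idx)], collapse = ", ")))
    pp <- pop$entries[lev]
    if (anyNA(pp))
      abort_validation("published posterior level(s) absent from the population reference")
    cal <- calibrate_prior(data.frame(
      posterior = as.numeric(published),
      case_proportion = cases$proportion[idx],
      population_proportion = as.numeric(pp)))
    return(list(prior = cal$prior, provenance = "calibrated",
                dispersion = cal$dispersion))
  }
  abort_domain("prior must be numeric, 'observed', or 'auto'")
}

#' Build the per-level posterior risk table
#'
#' Joins the case series with the population reference and computes the
#' posterior disease probability for every level of the selected factors.
#'
#' @param cases a [case_series].
#' @param pop a [population_reference].
#' @param prior a fraction in (0, 1); `"observed"` for the cohort prevalence
#'   `n_cases / n_screened`; or `"auto"` to calibrate the prior from
#'   `published` (see [calibrate_prior()]).
#' @param factors character vector of factor names to include; default: every
#'   factor all of whose levels appear in the population reference.
#' @param published named numeric vector `level -> posterior fraction`,
#'   required when `prior = "auto"`.
#' @return a `risk_table`: data.frame with columns `factor`, `level`,
#'   `case_count`, `case_proportion`, `population_proportion`, `posterior`,
#'   `infeasible`; attributes `prior`, `prior_provenance`.
#' @examples
#' \dontrun{
#' rt <- build_risk_table(hail_case_series(), hail_population_reference(),
#'                        prior = "auto", published = hail_published_posteriors())
#' }
#' @export
build_risk_table <- function(cases, pop, prior = "auto", factors = NULL,
                             published = NULL) {
  stopifnot(inherits(cases, "case_series"),
            inherits(pop, "population_reference"))
  if (is.null(factors)) {
    covered <- vapply(split(cases$level, cases$factor),
                      function(lv) all(lv %in% names(pop$entries)), logical(1))
    factors <- names(covered)[covered]
    ## keep the case-table ordering, not split()'s alphabetical one
    factors <- unique(cases$factor)[unique(cases$factor) %in% factors]
  }
  sel <- cases[cases$factor %in% factors, , drop = FALSE]
  miss <- setdiff(sel$level, names(pop$entries))
  if (length(miss))
    abort_validation(paste0("no population reference entry for level(s): ",
                            paste(miss, collapse = ", ")))
  pr <- resolve_prior(prior, cases, pop, published)
  pop_prop <- as.numeric(pop$entries[sel$level])
  post <- posterior_risk(sel$proportion, pop_prop, pr$prior)
  out <- data.frame(
    factor = sel$factor,
    level = sel$level,
    case_count = as.integer(sel$count),
    case_proportion = sel$proportion,
    population_proportion = pop_prop,
    posterior = as.numeric(post),
    infeasible = attr(post, "infeasible"),
    stringsAsFactors = FALSE
  )
  if (any(out$infeasible))
    risk_log("warn", paste0(
      "posterior > 1 (inconsistent inputs) for level(s): ",
      paste(out$level[out$infeasible], collapse = ", ")))
  structure(out,
            prior = pr$prior,
            prior_provenance = pr$provenance,
            class = c("risk_table", "data.frame"))
}

#' @export
print.risk_table <- function(x, decimals = 2, ...) {
  cat(sprintf("Posterior risk table (prior = %.4f, %s)\n",
              attr(x, "prior"), attr(x, "prior_provenance")))
  shown <- data.frame(
    factor = x$factor, level = x$level, cases = x$case_count,
    `case %` = format_percent(x$case_proportion, 1, symbol = FALSE),
    `pop %` = format_percent(x$population_proportion, 2, symbol = FALSE),
    `risk %` = ifelse(x$infeasible, "INFEASIBLE",
                      format_percent(pmin(x$posterior, 1), decimals,
                                     trim = TRUE, symbol = FALSE)),
    check.names = FALSE)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Rank the determinant levels with the highest posterior risk
#'
#' @param table a `risk_table`.
#' @param k number of levels to return (<= number of rows).
#' @return data.frame with columns `level`, `posterior`, sorted by posterior
#'   descending; ties broken lexicographically on the level label.
#' @export
rank_top_factors <- function(table, k) {
  stopifnot(inherits(table, "risk_table"))
  if (k < 0 || k > nrow(table))
    abort_domain("k must lie between 0 and the number of rows")
  ord <- order(-table$posterior, table$level, method = "radix")
  head_idx <- ord[seq_len(k)]
  data.frame(level = table$level[head_idx],
             posterior = table$posterior[head_idx],
             stringsAsFactors = FALSE)
}

#' Law-of-total-probability consistency diagnostic
#'
#' For a factor whose levels partition the cases, the population-weighted
#' average of the posteriors reconstructs the prior when the population
#' proportions cover the whole reference population (coverage 1):
#' sum_i P(D | RF_i) P(RF_i) = P(D). Coverage below 1 means the reference
#' proportions describe only part of the population (e.g. age groups
#' restricted to adults), in which case the reconstruction is reported but
#' rescaled by the coverage. Reported, never raised as an error.
#'
#' @param table a `risk_table`.
#' @param factor_name factor to diagnose.
#' @param pop the [population_reference] used to build the table.
#' @return list with `coverage` (sum of population proportions over the
#'   factor's levels) and `reconstructed_prior`
#'   (`sum(posterior * population_proportion) / coverage`; `NA` when the
#'   factor's case proportions do not sum to 1).
#' @export
total_probability_diagnostic <- function(table, factor_name, pop) {
  stopifnot(inherits(table, "risk_table"))
  rows <- table[table$factor == factor_name, , drop = FALSE]
  if (nrow(rows) == 0)
    abort_domain(paste0("factor '", factor_name, "' not in the risk table"))
  coverage <- sum(rows$population_proportion)
  exhaustive_cases <- isTRUE(all.equal(sum(rows$case_proportion), 1,
                                       tolerance = 1e-9))
  reconstructed <- if (exhaustive_cases)
    sum(rows$posterior * rows$population_proportion) / coverage
  else NA_real_
  list(coverage = coverage, reconstructed_prior = reconstructed)
}
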