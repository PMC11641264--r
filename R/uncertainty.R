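## Parametric-bootstrap uncertainty for the posterior risks. Case counts are
## resampled from the fitted multinomial (exhaustive factors) or binomial
## (overlapping factors such as comorbidities) at the observed proportions,
## posteriors are recomputed per replicate, and percentile intervals are
## returned. The prior is an external constant of the model and is held
## fixed by default; when it is the observed cohort prevalence its own
## sampling variability can be propagated with `resample_prior = TRUE`.

draw_factor_counts <- function(counts, exhaustive, n_cases, sizes) {
  B <- length(sizes)
  if (exhaustive) {
    if (length(unique(sizes)) == 1L) {
      rmultinom(B, sizes[1], prob = counts / n_cases)
    } else {
      vapply(sizes, function(s) rmultinom(1, s, prob = counts / n_cases)[, 1],
             numeric(length(counts)))
    }
  } else {
    ## overlapping binary flags: each level is an independent binomial
    t(vapply(counts / n_cases,
             function(p) stats::rbinom(B, sizes, p), numeric(B)))
  }
}

perturb_population_draws <- function(pop_prop, factor_of, B, concentration) {
  ## Per exhaustive block: Dirichlet centred on the reference proportions,
  ## rescaled to keep the block's total coverage; implemented via gamma draws.
  out <- matrix(0, nrow = length(pop_prop), ncol = B)
  for (f in unique(factor_of)) {
    idx <- which(factor_of == f)
    p <- pop_prop[idx]
    s <- sum(p)
    g <- matrix(stats::rgamma(length(idx) * B, shape = concentration * p / s),
                nrow = length(idx))
    out[idx, ] <- s * sweep(g, 2, colSums(g), "/")
  }
  out
}

#' Parametric-bootstrap intervals for posterior risks
#'
#' @param cases a [case_series].
#' @param pop a [population_reference].
#' @param prior fraction in (0, 1) or `"observed"` (cohort prevalence). The
#'   prior is held fixed across replicates unless `resample_prior = TRUE`.
#' @param replicates number of bootstrap replicates (>= 100).
#' @param seed integer seed; the same seed yields identical output. Sampling
#'   is wrapped in [withr::with_seed()], so the caller's RNG state is
#'   untouched.
#' @param confidence confidence level for the percentile intervals.
#' @param factors factors to bootstrap; default as in [build_risk_table()].
#' @param resample_prior when `prior = "observed"`, additionally resample the
#'   case total from its screened-cohort binomial so the interval reflects
#'   prevalence uncertainty too. Ignored for a fixed numeric prior.
#' @param perturb_population also perturb the reference proportions with a
#'   Dirichlet centred on the reference (concentration `concentration`),
#'   per exhaustive block.
#' @param concentration Dirichlet concentration mass when
#'   `perturb_population = TRUE`; larger means tighter around the reference.
#' @return named list `level -> interval_estimate`; each point estimate is
#'   the non-resampled posterior. Attribute `risk_table` carries the point
#'   table; attribute `draws` the replicate-by-level posterior matrix.
#' @export
bootstrap_posterior <- function(cases, pop, prior = "observed",
                                replicates = 2000, seed = 1L,
                                confidence = 0.95, factors = NULL,
                                resample_prior = FALSE,
                                perturb_population = FALSE,
                                concentration = 1000) {
  if (replicates < 100)
    abort_domain("replicates must be >= 100 for interval output")
  if (confidence <= 0 || confidence >= 1)
    abort_domain("confidence must lie in (0, 1)")
  base <- build_risk_table(cases, pop, prior = prior, factors = factors)
  n_cases <- attr(cases, "n_cases")
  n_screened <- attr(cases, "n_screened")
  prior_hat <- attr(base, "prior")
  observed <- identical(attr(base, "prior_provenance"), "observed_prevalence")

  draws <- withr::with_seed(as.integer(seed), {
    if (resample_prior && observed) {
      sizes <- stats::rbinom(replicates, n_screened, prior_hat)
      sizes[sizes == 0] <- 1L  # a zero-case replicate has no case table
      prior_b <- sizes / n_screened
    } else {
      sizes <- rep(n_cases, replicates)
      prior_b <- rep(prior_hat, replicates)
    }
    pop_b <- if (perturb_population)
      perturb_population_draws(base$population_proportion, base$factor,
                               replicates, concentration)
    else
      matrix(base$population_proportion, nrow = nrow(base),
             ncol = replicates)

    mat <- matrix(NA_real_, nrow = nrow(base), ncol = replicates)
    for (f in unique(base$factor)) {
      idx <- which(base$factor == f)
      key <- paste(cases$factor, cases$level, sep = "\r")
      exh <- isTRUE(cases$exhaustive[match(paste(f, base$level[idx][1],
                                                 sep = "\r"), key)])
      cnt <- draw_factor_counts(base$case_count[idx], exhaustive = exh,
                                n_cases = n_cases, sizes = sizes)
      mat[idx, ] <- cnt
    }
    sweep(mat, 2, sizes, "/") * rep(prior_b, each = nrow(base)) / pop_b
  })

  alpha <- (1 - confidence) / 2
  out <- lapply(seq_len(nrow(base)), function(i) {
    q <- stats::quantile(draws[i, ], probs = c(alpha, 1 - alpha), names = FALSE)
    new_interval_estimate(base$posterior[i], q[1], q[2],
                          "bootstrap_percentile", confidence)
  })
  names(out) <- base$level
  structure(out, risk_table = base, draws = draws)
}
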