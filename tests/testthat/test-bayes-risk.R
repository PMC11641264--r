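test_that("posterior risk reproduces published rows and flags infeasible input", {
  # age 60-69 with the calibrated prior
  p <- posterior_risk(0.275, 0.0355, 0.056)
  expect_equal(as.numeric(p), 0.43380, tolerance = 1e-4)
  expect_equal(format_percent(as.numeric(p), 2, symbol = FALSE), "43.38")
  # cataract
  p2 <- posterior_risk(0.11, 0.04, 0.056)
  expect_equal(as.numeric(p2), 0.15400, tolerance = 1e-6)
  # a determinant independent of disease leaves the prior unchanged
  for (q in c(0.05, 0.3, 0.9))
    expect_equal(as.numeric(posterior_risk(q, q, 0.056)), 0.056)
  # inconsistent inputs: posterior > 1 is tagged, never clamped
  bad <- posterior_risk(0.5, 0.01, 0.5)
  expect_equal(as.numeric(bad), 25)
  expect_true(attr(bad, "infeasible"))
  expect_false(attr(posterior_risk(0.1, 0.2, 0.056), "infeasible"))
  expect_error(posterior_risk(0.5, 0, 0.056),
               class = "postrisk_domain_error")
})

test_that("implied prior inverts the posterior formula", {
  expect_equal(implied_prior(0.4338, 0.275, 0.0355), 0.05600,
               tolerance = 1e-5)
  expect_equal(implied_prior(0.0509, 0.525, 0.5778), 0.05602,
               tolerance = 1e-4)
  # inversion of the independence identity
  expect_equal(implied_prior(0.3, 0.25, 0.25), 0.3)
  expect_error(implied_prior(0.3, 0, 0.25), class = "postrisk_domain_error")
})

test_that("forward/backward consistency holds to machine precision", {
  withr::with_seed(3, {
    for (rep in 1:200) {
      a <- runif(1, 0.01, 1)       # case proportion
      b <- runif(1, 0.01, 1)       # population proportion
      p <- runif(1, 0.001, 0.5)    # prior
      post <- as.numeric(posterior_risk(a, b, p))
      if (post > 0 && post <= 1)
        expect_equal(implied_prior(post, a, b), p, tolerance = 1e-12)
    }
  })
})

test_that("posterior is monotone in each argument", {
  withr::with_seed(5, {
    for (rep in 1:100) {
      a <- runif(1, 0.05, 0.9); b <- runif(1, 0.05, 0.9)
      p <- runif(1, 0.01, 0.3); eps <- runif(1, 0.001, 0.05)
      base <- as.numeric(posterior_risk(a, b, p))
      expect_gt(as.numeric(posterior_risk(min(a + eps, 1), b, p)), base)
      expect_gt(as.numeric(posterior_risk(a, b, min(p + eps, 0.99))), base)
      expect_lt(as.numeric(posterior_risk(a, min(b + eps, 1), p)), base)
    }
  })
})

test_that("prior calibration recovers the common prior of the published table", {
  cs <- hail_case_series()
  pop <- hail_population_reference()
  pub <- hail_published_posteriors()
  rows <- data.frame(
    posterior = as.numeric(pub),
    case_proportion = cs$proportion[match(names(pub), cs$level)],
    population_proportion = as.numeric(pop$entries[names(pub)]))
  cal <- calibrate_prior(rows)
  expect_equal(cal$prior, 0.0560, tolerance = 1e-3)
  expect_lt(cal$dispersion, 1e-3)
  expect_length(cal$implied, 14)
})

test_that("prior calibration round-trips an exactly consistent table and flags a corrupted one", {
  # rows generated from a known prior are recovered exactly
  withr::with_seed(9, {
    a <- runif(6, 0.05, 0.9); b <- runif(6, 0.05, 0.9)
    post <- as.numeric(posterior_risk(a, b, 0.021))
    keep <- post <= 1
    rows <- data.frame(posterior = post[keep], case_proportion = a[keep],
                       population_proportion = b[keep])
    cal <- calibrate_prior(rows)
    expect_equal(cal$prior, 0.021, tolerance = 1e-12)
    expect_lt(cal$dispersion, 1e-12)
    # perturb one published posterior by 10%: dispersion blows past tolerance
    rows$posterior[1] <- rows$posterior[1] * 1.1
    expect_message(cal_bad <- calibrate_prior(rows), "disagree")
    expect_gt(cal_bad$dispersion, 1e-3)
  })
  expect_error(calibrate_prior(data.frame(posterior = 0.1,
                                          case_proportion = 0.2,
                                          population_proportion = 0.3)),
               class = "postrisk_domain_error")
})

test_that("the risk table reproduces every published chance-of-disease value", {
  rt <- build_risk_table(hail_case_series(), hail_population_reference(),
                         prior = "auto",
                         published = hail_published_posteriors())
  expect_s3_class(rt, "risk_table")
  expect_identical(attr(rt, "prior_provenance"), "calibrated")
  expect_equal(nrow(rt), 14L)
  rendered <- format_percent(rt$posterior, 2, trim = TRUE, symbol = FALSE)
  expect_identical(rendered, unname(table5_expected[rt$level]))
  expect_false(any(rt$infeasible))
})

test_that("the observed-prevalence prior yields the documented alternative posterior", {
  rt <- build_risk_table(hail_case_series(), hail_population_reference(),
                         prior = "observed")
  expect_equal(attr(rt, "prior"), 200 / 9407)
  expect_equal(rt$posterior[rt$level == "60–69 years"], 0.1647,
               tolerance = 1e-4)
  expect_identical(attr(rt, "prior_provenance"), "observed_prevalence")
})

test_that("risk table validation and factor selection behave", {
  cs <- tiny_case_series()
  pop <- tiny_population_reference()
  # a level without a population entry is named in the error
  pop_missing <- population_reference(c(small = 0.5, medium = 0.3,
                                        large = 0.2))
  expect_error(build_risk_table(cs, pop_missing, prior = 0.05,
                                factors = c("size", "flag")),
               regexp = "present", class = "postrisk_validation_error")
  # by default only fully covered factors enter the table
  rt <- build_risk_table(cs, pop_missing, prior = 0.05)
  expect_identical(unique(rt$factor), "size")
  # dropping an optional factor is not an error
  rt2 <- build_risk_table(cs, pop, prior = 0.05)
  expect_setequal(rt2$factor, c("size", "flag"))
})

test_that("ranking sorts by posterior with lexicographic tie-break", {
  rt <- build_risk_table(hail_case_series(), hail_population_reference(),
                         prior = "auto",
                         published = hail_published_posteriors())
  top7 <- rank_top_factors(rt, 7)
  expect_setequal(top7$level,
                  c("60–69 years", "≥80 years", "70–79 years", "50–59 years",
                    "Illiterate", "Diabetes Mellitus", "Cataract"))
  top1 <- rank_top_factors(rt, 1)
  expect_identical(top1$level, "60–69 years")
  expect_equal(top1$posterior, 0.43380, tolerance = 1e-4)
  expect_identical(nrow(rank_top_factors(rt, 0)), 0L)
  expect_error(rank_top_factors(rt, 15), class = "postrisk_domain_error")
  # deterministic tie-break on the level label
  cs <- case_series(data.frame(factor = "f", level = c("b", "a"),
                               count = c(5, 5), exhaustive = TRUE), 10, 100)
  pop <- population_reference(c(a = 0.5, b = 0.5))
  tie <- rank_top_factors(build_risk_table(cs, pop, prior = 0.1), 2)
  expect_identical(tie$level, c("a", "b"))
})

test_that("total-probability diagnostic reports coverage and reconstructs the prior", {
  pop <- hail_population_reference()
  rt <- build_risk_table(hail_case_series(), pop, prior = "auto",
                         published = hail_published_posteriors())
  age <- total_probability_diagnostic(rt, "age", pop)
  expect_equal(age$coverage, 0.3092, tolerance = 1e-6)
  gender <- total_probability_diagnostic(rt, "gender", pop)
  expect_equal(gender$coverage, 1.0000, tolerance = 1e-6)
  expect_equal(gender$reconstructed_prior, 0.056, tolerance = 1e-3)
  # single-level factor covering the whole population: prior exactly
  cs <- case_series(data.frame(factor = "all", level = "everyone",
                               count = 20, exhaustive = TRUE), 20, 400)
  pop1 <- population_reference(c(everyone = 1))
  rt1 <- build_risk_table(cs, pop1, prior = 0.05)
  d <- total_probability_diagnostic(rt1, "all", pop1)
  expect_equal(d$reconstructed_prior, 0.05, tolerance = 1e-12)
  # non-exhaustive case proportions: reconstruction not defined
  rt2 <- build_risk_table(tiny_case_series(), tiny_population_reference(),
                          prior = 0.05)
  expect_true(is.na(total_probability_diagnostic(rt2, "flag",
                    tiny_population_reference())$reconstructed_prior))
})

test_that("population-weighted posterior equals the prior for exhaustive unit-coverage factors", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      m <- sample(2:6, 1)
      pop_w <- as.numeric(rmultinom(1, 1000, rep(1, m))) / 1000
      pop_w[pop_w == 0] <- 1e-3
      pop_w <- pop_w / sum(pop_w)
      counts <- as.numeric(rmultinom(1, 100, runif(m, 0.1, 1)))
      lv <- sprintf("L%02d", seq_len(m))
      cs <- case_series(data.frame(factor = "f", level = lv, count = counts,
                                   exhaustive = TRUE), 100, 5000)
      pop <- population_reference(stats::setNames(pop_w, lv))
      prior <- runif(1, 0.005, 0.2)
      rt <- build_risk_table(cs, pop, prior = prior)
      expect_equal(sum(rt$posterior * rt$population_proportion), prior,
                   tolerance = 1e-12)
    }
  })
})
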