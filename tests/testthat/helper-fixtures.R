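# Shared fixtures built in code.

# A small two-factor case series with one overlapping (non-exhaustive) factor.
tiny_case_series <- function(n_cases = 50, n_screened = 1000) {
  case_series(data.frame(
    factor = c("size", "size", "size", "flag"),
    level = c("small", "medium", "large", "present"),
    count = c(20, 20, 10, 15),
    exhaustive = c(TRUE, TRUE, TRUE, FALSE)
  ), n_cases = n_cases, n_screened = n_screened, disease_label = "toy")
}

tiny_population_reference <- function() {
  population_reference(c(small = 0.5, medium = 0.3, large = 0.2,
                         present = 0.1))
}

# The published per-level posterior strings, keyed by level, in fixture order.
table5_expected <- c(
  "40–49 years" = "8.42",  "50–59 years" = "22.78", "60–69 years" = "43.38",
  "70–79 years" = "35.52", "≥80 years" = "37.33",
  "Male" = "5.09", "Female" = "6.3",
  "Illiterate" = "22.58", "Literate" = "5.49",
  "Diabetes Mellitus" = "16.1", "Hypertension" = "4.59", "Asthma" = "2.77",
  "Cardiovascular Disease" = "1.02", "Cataract" = "15.4")

# Every printed 95% CI of the demographic / clinical / comorbidity tables,
# keyed by level, as (lower, upper) on the percent scale at 1 dp.
printed_cis <- local({
  txt <- c(
    "40–49 years" = "19.5,31.5", "50–59 years" = "27.9,41.1",
    "60–69 years" = "21.3,33.7", "70–79 years" = "4.6,12.4",
    "≥80 years" = "1.3,6.7",
    "Male" = "45.6,59.4", "Female" = "40.6,54.4",
    "Illiterate" = "0.3,4.7", "Literate" = "95.3,99.7",
    "Blurry vision" = "5.8,14.2", "Decreased vision" = "19.5,31.5",
    "Headache/Pain" = "3.8,11.2",
    "Developed during follow-up" = "20.8,33.2",
    "Diagnosed in routine checkup" = "2.0,8.0", "Other/NA" = "14.5,25.5",
    "Primary" = "97.6,100", "Secondary" = "0.0,2.4",
    "Newly diagnosed" = "65.8,78.2", "≤1 year" = "0.1,3.9",
    "2–5 year" = "2.7,9.3", "6–9 year" = "9.6,19.4", "≥10 year" = "2.3,8.7",
    "Diabetes Mellitus" = "39.6,53.4", "Hypertension" = "14.9,26.1",
    "Asthma" = "0.1,3.9", "Cardiovascular Disease" = "0.0,2.4",
    "Cataract" = "6.7,15.3")
  m <- do.call(rbind, lapply(strsplit(txt, ","), as.numeric))
  data.frame(level = names(txt), lower = m[, 1], upper = m[, 2],
             stringsAsFactors = FALSE)
})
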