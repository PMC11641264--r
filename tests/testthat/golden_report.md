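# disease risk report

## Prevalence

| status | count | percent | ci |
|---|---|---|---|
| disease |  200 | 2.1% | 1.8–2.4% |
| total screened | 9407 | 100.0% |  |

## Cases by age

| level | count | percent | ci |
|---|---|---|---|
| 40–49 years | 51 | 25.50% | 19.5–31.5% |
| 50–59 years | 69 | 34.50% | 27.9–41.1% |
| 60–69 years | 55 | 27.50% | 21.3–33.7% |
| 70–79 years | 17 | 8.50% | 4.6–12.4% |
| ≥80 years |  8 | 4.00% | 1.3–6.7% |

## Cases by gender

| level | count | percent | ci |
|---|---|---|---|
| Male | 105 | 52.50% | 45.6–59.4% |
| Female |  95 | 47.50% | 40.6–54.4% |

## Cases by education

| level | count | percent | ci |
|---|---|---|---|
| Illiterate |   5 | 2.50% | 0.3–4.7% |
| Literate | 195 | 97.50% | 95.3–99.7% |

## Cases by symptom

| level | count | percent | ci |
|---|---|---|---|
| Blurry vision | 20 | 10.00% | 5.8–14.2% |
| Decreased vision | 51 | 25.50% | 19.5–31.5% |
| Headache/Pain | 15 | 7.50% | 3.8–11.2% |

## Cases by diagnostic_context

| level | count | percent | ci |
|---|---|---|---|
| Developed during follow-up | 54 | 27.00% | 20.8–33.2% |
| Diagnosed in routine checkup | 10 | 5.00% | 2.0–8.0% |
| Other/NA | 40 | 20.00% | 14.5–25.5% |

## Cases by glaucoma_type

| level | count | percent | ci |
|---|---|---|---|
| Primary | 198 | 99.00% | 97.6–100.0% |
| Secondary |   2 | 1.00% | 0.0–2.4% |

## Cases by duration

| level | count | percent | ci |
|---|---|---|---|
| Newly diagnosed | 144 | 72.00% | 65.8–78.2% |
| ≤1 year |   4 | 2.00% | 0.1–3.9% |
| 2–5 year |  12 | 6.00% | 2.7–9.3% |
| 6–9 year |  29 | 14.50% | 9.6–19.4% |
| ≥10 year |  11 | 5.50% | 2.3–8.7% |

## Cases by comorbidity

| level | count | percent | ci |
|---|---|---|---|
| Diabetes Mellitus | 93 | 46.50% | 39.6–53.4% |
| Hypertension | 41 | 20.50% | 14.9–26.1% |
| Asthma |  4 | 2.00% | 0.1–3.9% |
| Cardiovascular Disease |  2 | 1.00% | 0.0–2.4% |
| Cataract | 22 | 11.00% | 6.7–15.3% |

## Posterior risk (prior = 0.0560, calibrated)

| factor | level | count | case_percent | population_percent | risk_percent | prior | infeasible |
|---|---|---|---|---|---|---|---|
| age | 40–49 years |  51 | 25.5 | 16.95 | 8.42 | 0.05599664 | FALSE |
| age | 50–59 years |  69 | 34.5 | 8.48 | 22.78 | 0.05599664 | FALSE |
| age | 60–69 years |  55 | 27.5 | 3.55 | 43.38 | 0.05599664 | FALSE |
| age | 70–79 years |  17 | 8.5 | 1.34 | 35.52 | 0.05599664 | FALSE |
| age | ≥80 years |   8 | 4 | 0.6 | 37.33 | 0.05599664 | FALSE |
| gender | Male | 105 | 52.5 | 57.78 | 5.09 | 0.05599664 | FALSE |
| gender | Female |  95 | 47.5 | 42.22 | 6.3 | 0.05599664 | FALSE |
| education | Illiterate |   5 | 2.5 | 0.62 | 22.58 | 0.05599664 | FALSE |
| education | Literate | 195 | 97.5 | 99.38 | 5.49 | 0.05599664 | FALSE |
| comorbidity | Diabetes Mellitus |  93 | 46.5 | 16.17 | 16.1 | 0.05599664 | FALSE |
| comorbidity | Hypertension |  41 | 20.5 | 25 | 4.59 | 0.05599664 | FALSE |
| comorbidity | Asthma |   4 | 2 | 4.05 | 2.77 | 0.05599664 | FALSE |
| comorbidity | Cardiovascular Disease |   2 | 1 | 5.5 | 1.02 | 0.05599664 | FALSE |
| comorbidity | Cataract |  22 | 11 | 4 | 15.4 | 0.05599664 | FALSE |

## Top 7 risk levels

| level | risk_percent |
|---|---|
| 60–69 years | 43.38 |
| ≥80 years | 37.33 |
| 70–79 years | 35.52 |
| 50–59 years | 22.78 |
| Illiterate | 22.58 |
| Diabetes Mellitus | 16.1 |
| Cataract | 15.4 |

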