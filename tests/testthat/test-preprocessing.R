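# Minimal cohort builder for preprocessing tests: two biomarkers are enough
# to exercise the zero / worst-latency imputation split.
mini_specs <- function() {
  specs <- study_biomarkers()
  specs[specs$name %in% c("verbal_fluency", "srt_mean_latency"), ]
}

mini_cohort <- function(fluency, srt, eng_fluency = "completed",
                        eng_srt = "completed",
                        id_level = "moderate", age_group = "YA") {
  n <- length(fluency)
  recycle <- function(v) rep_len(v, n)
  data.frame(participant_id = paste0("P", seq_len(n)),
             age = ifelse(recycle(age_group) == "YA", 25, 50),
             age_group = recycle(age_group), sex = "F",
             id_level = recycle(id_level), dementia = "none",
             apoe_group = "APOE3",
             score_verbal_fluency = fluency, score_srt_mean_latency = srt,
             eng_verbal_fluency = recycle(eng_fluency),
             eng_srt_mean_latency = recycle(eng_srt),
             stringsAsFactors = FALSE)
}

test_that("attempted-not-understood imputes zero, or the cohort-worst latency", {
  co <- mini_cohort(fluency = c(12, NA, 8), srt = c(900, NA, 2500),
                    eng_fluency = c("completed", "attempted_not_understood",
                                    "completed"),
                    eng_srt = c("completed", "attempted_not_understood",
                                "completed"))
  out <- impute_performance_scores(co, mini_specs())
  expect_equal(out$score_verbal_fluency[2], 0)
  expect_equal(out$score_srt_mean_latency[2], 2500)  # poorest recorded
  # untouched rows
  expect_equal(out$score_verbal_fluency[c(1, 3)], c(12, 8))
})

test_that("not-attempted stays missing and full completion is the identity", {
  co <- mini_cohort(fluency = c(12, NA), srt = c(900, NA),
                    eng_fluency = c("completed", "not_attempted"),
                    eng_srt = c("completed", "not_attempted"))
  out <- impute_performance_scores(co, mini_specs())
  expect_true(is.na(out$score_verbal_fluency[2]))
  expect_true(is.na(out$score_srt_mean_latency[2]))

  complete <- mini_cohort(fluency = c(3, 7), srt = c(500, 700))
  expect_identical(impute_performance_scores(complete, mini_specs()),
                   complete)
})

test_that("SRT imputation without any completed latency errors", {
  co <- mini_cohort(fluency = c(1, 2), srt = c(NA, NA),
                    eng_srt = c("attempted_not_understood",
                                "attempted_not_understood"))
  expect_error(impute_performance_scores(co, mini_specs()),
               "no completed scores")
})

test_that("questionnaire item imputation follows the 15% rule", {
  # 10 items, 1 missing, completed mean 31/9 = 3.44 -> nearest integer 3
  r <- impute_questionnaire_items(c(2, 4, 3, 4, 3, 4, 3, 4, 4, NA))
  expect_equal(r$items[10], 3)
  expect_false(r$domain_missing)
  expect_equal(r$total, sum(c(2, 4, 3, 4, 3, 4, 3, 4, 4, 3)))

  # 3 of 10 missing (30% > 15%) -> domain missing
  r2 <- impute_questionnaire_items(c(1, 2, 3, 4, 5, 6, 7, NA, NA, NA))
  expect_true(r2$domain_missing)
  expect_true(is.na(r2$total))

  # identity with no missing items; completed items never altered
  v <- c(5, 1, 4, 2)
  r3 <- impute_questionnaire_items(v)
  expect_identical(r3$items, v)
  expect_equal(r3$total, 12)

  # all items missing -> domain missing without error
  r4 <- impute_questionnaire_items(c(NA_real_, NA_real_))
  expect_true(r4$domain_missing)
})

test_that("imputed item rounding breaks .5 ties away from zero", {
  # completed mean 2.5 -> 3
  r <- impute_questionnaire_items(c(2, 3, NA), max_missing_frac = 0.5)
  expect_equal(r$items[3], 3)
})

test_that("the YA regression on ID level matches closed forms", {
  specs <- mini_specs()
  # fluency scores exactly linear in the ordinal code: mild 10, moderate 6,
  # severe 2 (two each) -> slope -4, intercept 14
  co <- mini_cohort(fluency = c(10, 10, 6, 6, 2, 2),
                    srt = c(500, 510, 520, 530, 540, 550),
                    id_level = c("mild", "mild", "moderate", "moderate",
                                 "severe", "severe"))
  m <- fit_residual_model(co, specs)
  cf <- m$coefficients$verbal_fluency
  expect_equal(unname(cf[1]), 14)
  expect_equal(unname(cf[2]), -4)
  expect_equal(unname(m$predictions["verbal_fluency", ]), c(10, 6, 2))

  # constant scores -> zero slope, intercept c
  co2 <- mini_cohort(fluency = rep(7, 6), srt = c(500, 510, 520, 530, 540, 550),
                     id_level = c("mild", "mild", "moderate", "moderate",
                                  "severe", "severe"))
  m2 <- fit_residual_model(co2, specs)
  expect_equal(unname(m2$coefficients$verbal_fluency[1]), 7)
  expect_equal(unname(m2$coefficients$verbal_fluency[2]), 0)

  # perfect linear fit -> residuals exactly zero for YA
  r <- residualize(co, m, specs)
  expect_equal(r$score_verbal_fluency, rep(0, 6))
})

test_that("residual model demands enough usable YA data", {
  co <- mini_cohort(fluency = c(1, 2), srt = c(500, 600))
  expect_error(fit_residual_model(co, mini_specs()), "fewer than 3")
  co3 <- mini_cohort(fluency = c(1, 2, 3), srt = c(500, 600, 700),
                     id_level = "moderate")
  expect_error(fit_residual_model(co3, mini_specs()), "distinct ID levels")
})

test_that("residualize subtracts predictions for YA and OA alike", {
  specs <- mini_specs()
  ya <- mini_cohort(fluency = c(10, 10, 6, 6, 2, 2),
                    srt = c(500, 500, 600, 600, 700, 700),
                    id_level = c("mild", "mild", "moderate", "moderate",
                                 "severe", "severe"))
  m <- fit_residual_model(ya, specs)
  oa <- mini_cohort(fluency = 5, srt = 1200, id_level = "mild",
                    age_group = "OA")
  r <- residualize(oa, m, specs)
  expect_equal(r$score_verbal_fluency, 5 - 10)   # observed - predicted
  expect_equal(r$score_srt_mean_latency, 1200 - 500)
})

test_that("residualization preserves missingness and warns on unknown levels", {
  specs <- mini_specs()
  ya <- mini_cohort(fluency = c(10, 10, 6, 6, 2, 2),
                    srt = c(500, 500, 600, 600, 700, 700),
                    id_level = c("mild", "mild", "moderate", "moderate",
                                 "severe", "severe"))
  m <- fit_residual_model(ya, specs)
  co <- mini_cohort(fluency = c(4, NA), srt = c(NA, 800),
                    id_level = c("moderate", "unknown"))
  expect_warning(r <- residualize(co, m, specs), "unknown ID level")
  expect_equal(nrow(r), 2)
  expect_true(is.na(r$score_srt_mean_latency[1]))  # missing stays missing
  expect_true(is.na(r$score_verbal_fluency[2]))    # unknown level -> missing
  expect_equal(r$score_verbal_fluency[1], 4 - 6)
})

test_that("YA residuals average zero per ID level on noisy data", {
  set.seed(42)
  lev <- sample(c("mild", "moderate", "severe"), 60, replace = TRUE)
  base <- c(mild = 20, moderate = 14, severe = 9)[lev]
  co <- mini_cohort(fluency = base + rnorm(60, 0, 2),
                    srt = 500 + rnorm(60, 0, 50), id_level = lev)
  m <- fit_residual_model(co, mini_specs())
  r <- residualize(co, m, mini_specs())
  # least-squares property holds for the pooled mean under ordinal coding;
  # refitting on residuals must give (numerically) zero coefficients
  m2 <- fit_residual_model(r, mini_specs())
  expect_lt(abs(m2$coefficients$verbal_fluency[2]), 1e-10)
  expect_lt(abs(m2$coefficients$verbal_fluency[1]), 1e-10)
})

test_that("dummy coding reproduces per-level means", {
  specs <- mini_specs()
  co <- mini_cohort(fluency = c(10, 12, 6, 8, 2, 4),
                    srt = c(500, 500, 600, 600, 700, 700),
                    id_level = c("mild", "mild", "moderate", "moderate",
                                 "severe", "severe"))
  m <- fit_residual_model(co, specs, coding = "dummy")
  expect_equal(unname(m$predictions["verbal_fluency", ]), c(11, 7, 3))
})
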