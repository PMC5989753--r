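test_that("battery specification is internally consistent", {
  specs <- study_biomarkers()
  expect_equal(nrow(specs), 16L)
  expect_equal(sum(specs$modality == "informant"), 4L)
  expect_setequal(
    specs$name[specs$decline_direction == "increasing"],
    c("srt_mean_latency", "dld_cognitive", "dld_social", "omq_revised"))
  finite <- is.finite(specs$score_max)
  expect_true(all(specs$score_min[finite] < specs$score_max[finite]))
})

test_that("generation is bitwise deterministic under a fixed seed", {
  cfg <- cohort_config(n_ya = 30, n_oa = 40, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$sequence, b$truth$sequence)
  expect_identical(a$truth$stage_of, b$truth$stage_of)
  c <- generate_cohort(cohort_config(n_ya = 30, n_oa = 40, seed = 100))
  expect_false(identical(a$cohort, c$cohort))
})

test_that("zero noise with extreme stages puts scores at component locations", {
  cfg <- cohort_config(n_ya = 15, n_oa = 15, noise_scale = 0,
                       ya_stage_leak = 0,
                       oa_stage_probs = c(rep(0, 16), 1),  # all OA at stage 16
                       informant_missing_rate = 0, struggler_rate = 0,
                       not_attempted_rate = 0, id_offset_scale = 0, seed = 5)
  sim <- generate_cohort(cfg)
  specs <- study_biomarkers()
  params <- sim$truth$event_params
  for (b in seq_len(16)) {
    sc <- sim$cohort[[paste0("score_", specs$name[b])]]
    expect_pre <- params$pre_mean[b]
    expect_post <- params$post_mean[b]
    if (specs$integer_valued[b]) {
      expect_pre <- round(expect_pre); expect_post <- round(expect_post)
    }
    expect_pre <- min(max(expect_pre, specs$score_min[b]), specs$score_max[b])
    expect_post <- min(max(expect_post, specs$score_min[b]),
                       specs$score_max[b])
    expect_equal(sc[sim$cohort$age_group == "YA"], rep(expect_pre, 15))
    expect_equal(sc[sim$cohort$age_group == "OA"], rep(expect_post, 15))
  }
})

test_that("zero missingness config yields a complete score table", {
  cfg <- cohort_config(n_ya = 25, n_oa = 25, informant_missing_rate = 0,
                       struggler_rate = 0, not_attempted_rate = 0, seed = 3)
  sim <- generate_cohort(cfg)
  score_cols <- paste0("score_", study_biomarkers()$name)
  expect_false(anyNA(sim$cohort[, score_cols]))
  expect_true(all(sim$cohort[, paste0("eng_", study_biomarkers()$name)] ==
                    "completed"))
})

test_that("OA-minus-YA mean differences carry the decline sign for all 16 outcomes", {
  specs <- study_biomarkers()
  hits <- 0L
  for (s in 1:10) {
    sim <- generate_cohort(cohort_config(seed = s))
    co <- sim$cohort
    ok <- TRUE
    for (b in seq_len(16)) {
      x <- co[[paste0("score_", specs$name[b])]]
      d <- mean(x[co$age_group == "OA"], na.rm = TRUE) -
        mean(x[co$age_group == "YA"], na.rm = TRUE)
      want <- if (specs$decline_direction[b] == "decreasing") d < 0 else d > 0
      if (!want) ok <- FALSE
    }
    hits <- hits + ok
  }
  expect_gte(hits, 9L)
})

test_that("marginal means shift monotonically with the fraction past the event", {
  # concentrate OA stages early vs late: later stage mass drags decreasing
  # biomarkers further down
  specs <- study_biomarkers()
  early <- cohort_config(n_ya = 10, n_oa = 150, seed = 8,
                         oa_stage_probs = c(1, rep(0, 16)))   # nobody past
  late <- cohort_config(n_ya = 10, n_oa = 150, seed = 8,
                        oa_stage_probs = c(rep(0, 16), 1))    # all past
  mid <- cohort_config(n_ya = 10, n_oa = 150, seed = 8)
  sims <- lapply(list(early, mid, late), generate_cohort)
  for (b in c("kbit_verbal", "verbal_fluency", "srt_mean_latency")) {
    m <- vapply(sims, function(s) {
      co <- s$cohort
      mean(co[[paste0("score_", b)]][co$age_group == "OA"], na.rm = TRUE)
    }, numeric(1))
    dirn <- specs$decline_direction[specs$name == b]
    if (dirn == "decreasing") {
      expect_true(m[1] > m[2] && m[2] > m[3])
    } else {
      expect_true(m[1] < m[2] && m[2] < m[3])
    }
  }
})

test_that("YA floor fraction for delayed object memory stays below 1%", {
  # pool YA across seeds for a tight binomial bound
  floors <- 0L; n <- 0L
  for (s in 1:5) {
    sim <- generate_cohort(cohort_config(n_ya = 400, n_oa = 1, seed = s,
                                         struggler_rate = 0,
                                         not_attempted_rate = 0,
                                         ya_stage_leak = 0))
    x <- sim$cohort$score_obj_mem_delayed[sim$cohort$age_group == "YA"]
    floors <- floors + sum(x == 0, na.rm = TRUE)
    n <- n + sum(!is.na(x))
  }
  frac <- floors / n
  expect_lt(frac - 2 * sqrt(frac * (1 - frac) / n), 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_ya = 0), "n_ya")
  expect_error(cohort_config(informant_missing_rate = -0.1), "rates")
  expect_error(cohort_config(struggler_rate = 1.5), "rates")
  expect_error(cohort_config(oa_stage_probs = rep(1, 5)), "oa_stage_probs")
  expect_error(cohort_config(apoe_probs_ya = c(bogus = 1)), "apoe_probs_ya")
  expect_error(generate_cohort(cohort_config(true_sequence = c(1:15, 15L))),
               "permutation")
})

test_that("generated cohorts respect structural invariants", {
  sim <- generate_cohort(cohort_config(n_ya = 60, n_oa = 80, seed = 21))
  co <- sim$cohort
  specs <- study_biomarkers()
  expect_true(all(co$age[co$age_group == "YA"] >= 16 &
                    co$age[co$age_group == "YA"] <= 35))
  expect_true(all(co$age[co$age_group == "OA"] >= 36))
  expect_true(all(sim$truth$stage_of >= 0 & sim$truth$stage_of <= 16))
  expect_true(all(co$dementia[co$age_group == "YA"] == "none"))
  for (b in seq_len(16)) {
    x <- co[[paste0("score_", specs$name[b])]]
    expect_true(all(is.na(x) | (x >= specs$score_min[b] &
                                  x <= specs$score_max[b])),
                info = specs$name[b])
  }
})

test_that("cohort and ground truth round-trip through their text formats", {
  sim <- generate_cohort(cohort_config(n_ya = 12, n_oa = 15, seed = 77))
  dir <- withr::local_tempdir()
  cp <- file.path(dir, "cohort.csv")
  gp <- file.path(dir, "truth.json")
  write_cohort(sim$cohort, cp)
  write_ground_truth(sim$truth, gp)
  co2 <- read_cohort(cp)
  expect_equal(co2, sim$cohort)
  tr2 <- read_ground_truth(gp)
  expect_identical(tr2$sequence, sim$truth$sequence)
  expect_identical(tr2$stage_of, sim$truth$stage_of)
})
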