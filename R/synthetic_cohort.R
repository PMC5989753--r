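#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration list for [generate_cohort()]. Defaults
#' emulate the cross-sectional structure the event-based model assumes: a
#' young-adult (YA, age 16-35) pre-decline control group, an older-adult (OA,
#' age >= 36) group presumed to carry Alzheimer's neuropathology at varying
#' latent stages, a latent ground-truth ordering of the 16 battery events,
#' per-biomarker pre/post-event truncated-Gaussian score distributions
#' calibrated to the battery's published YA/OA group means and SDs,
#' intellectual-disability (ID) level offsets on direct tests, questionnaire
#' missingness and participant-level task non-engagement.
#'
#' @param n_ya,n_oa Group sizes (defaults: the study's 119 YA and 164 OA).
#' @param separation Multiplier on the pre-to-post event location gap. 1 =
#'   calibrated to the observed group means (the default post-event location
#'   is pre + 2 x (OA mean - YA mean), since under a uniform OA stage
#'   distribution roughly half the OA group is past any given event); 2 is
#'   used as the "strong separation" regime in validation runs.
#' @param ya_stage_leak Probability a YA participant has latent stage > 0
#'   (subclinical decline in the control group).
#' @param oa_stage_probs Probability vector over stages 0..16 for OA
#'   participants; default uniform.
#' @param apoe4_stage_shift Additive latent-stage shift (capped at 16) for OA
#'   participants in the APOE4 group, mirroring e4-driven earlier onset.
#' @param dementia_midpoint,dementia_slope Logistic model
#'   `P(dementia | stage) = plogis(slope * (stage - midpoint))` used to label
#'   OA participants with a clinical dementia diagnosis; defaults give ~26%
#'   OA dementia prevalence under a uniform stage distribution.
#' @param id_offset_scale Multiplier on the ID-level ability offsets
#'   (expressed in pre-event SD units: mild +0.5, moderate 0, severe -1.0 on
#'   the "better score" side of each direct test). 0 disables them.
#' @param informant_missing_rate Per-questionnaire probability the informant
#'   measure is missing.
#' @param struggler_rate Probability a participant broadly struggles to
#'   engage with direct testing.
#' @param struggler_not_understood_prob For strugglers, per-task probability
#'   the task was attempted but not understood (score imputable).
#' @param not_attempted_rate Per-task probability a direct test was not
#'   attempted at all (score stays missing).
#' @param noise_scale Multiplier on the pre/post-event score SDs; 0 gives
#'   deterministic scores at the component locations.
#' @param apoe_probs_ya,apoe_probs_oa Named probability vectors over
#'   `c("APOE2","APOE3","APOE4","APOE24","unknown")`.
#' @param id_level_probs_ya,id_level_probs_oa Named probability vectors over
#'   `c("mild","moderate","severe")`.
#' @param true_sequence Optional integer permutation of `1:16` (or biomarker
#'   name vector) fixing the latent event ordering; default: drawn from the
#'   seed.
#' @param seed Integer seed; identical seed and config give a bitwise
#'   identical cohort.
#' @return A list of class `ebm_cohort_config`.
#' @export
cohort_config <- function(n_ya = 119L, n_oa = 164L,
                          separation = 1,
                          ya_stage_leak = 0.05,
                          oa_stage_probs = NULL,
                          apoe4_stage_shift = 5L,
                          dementia_midpoint = 12,
                          dementia_slope = 1.5,
                          id_offset_scale = 1,
                          informant_missing_rate = 0.05,
                          struggler_rate = 0.05,
                          struggler_not_understood_prob = 0.6,
                          not_attempted_rate = 0.02,
                          noise_scale = 1,
                          apoe_probs_ya = c(APOE2 = 19, APOE3 = 60,
                                            APOE4 = 31, APOE24 = 1,
                                            unknown = 8) / 119,
                          apoe_probs_oa = c(APOE2 = 22, APOE3 = 90,
                                            APOE4 = 35, APOE24 = 4,
                                            unknown = 13) / 164,
                          id_level_probs_ya = c(mild = 45, moderate = 63,
                                                severe = 11) / 119,
                          id_level_probs_oa = c(mild = 69, moderate = 67,
                                                severe = 28) / 164,
                          true_sequence = NULL,
                          seed = 1L) {
  cfg <- list(
    n_ya = as.integer(n_ya), n_oa = as.integer(n_oa),
    separation = separation, ya_stage_leak = ya_stage_leak,
    oa_stage_probs = oa_stage_probs,
    apoe4_stage_shift = as.integer(apoe4_stage_shift),
    dementia_midpoint = dementia_midpoint, dementia_slope = dementia_slope,
    id_offset_scale = id_offset_scale,
    informant_missing_rate = informant_missing_rate,
    struggler_rate = struggler_rate,
    struggler_not_understood_prob = struggler_not_understood_prob,
    not_attempted_rate = not_attempted_rate,
    noise_scale = noise_scale,
    apoe_probs_ya = apoe_probs_ya, apoe_probs_oa = apoe_probs_oa,
    id_level_probs_ya = id_level_probs_ya,
    id_level_probs_oa = id_level_probs_oa,
    true_sequence = true_sequence,
    seed = as.integer(seed)
  )
  class(cfg) <- "ebm_cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_ya < 1L || cfg$n_oa < 1L) {
    stop("configuration error: n_ya and n_oa must be >= 1")
  }
  rates <- c(ya_stage_leak = cfg$ya_stage_leak,
             informant_missing_rate = cfg$informant_missing_rate,
             struggler_rate = cfg$struggler_rate,
             struggler_not_understood_prob = cfg$struggler_not_understood_prob,
             not_attempted_rate = cfg$not_attempted_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    bad <- names(rates)[!is.finite(rates) | rates < 0 | rates > 1]
    stop("configuration error: rates must lie in [0, 1]: ",
         paste(bad, collapse = ", "))
  }
  if (!is.finite(cfg$separation) || !is.finite(cfg$noise_scale) ||
      cfg$noise_scale < 0) {
    stop("configuration error: separation and noise_scale must be finite, ",
         "noise_scale >= 0")
  }
  apoe_levels <- c("APOE2", "APOE3", "APOE4", "APOE24", "unknown")
  for (nm in c("apoe_probs_ya", "apoe_probs_oa")) {
    p <- cfg[[nm]]
    if (!all(names(p) %in% apoe_levels) || any(p < 0)) {
      stop("configuration error: ", nm, " must be nonnegative and named ",
           "among ", paste(apoe_levels, collapse = "/"))
    }
  }
  for (nm in c("id_level_probs_ya", "id_level_probs_oa")) {
    p <- cfg[[nm]]
    if (!setequal(names(p), c("mild", "moderate", "severe")) || any(p < 0)) {
      stop("configuration error: ", nm,
           " must be nonnegative over mild/moderate/severe")
    }
  }
  if (!is.null(cfg$oa_stage_probs)) {
    if (length(cfg$oa_stage_probs) != 17L || any(cfg$oa_stage_probs < 0)) {
      stop("configuration error: oa_stage_probs must be 17 nonnegative ",
           "weights over stages 0..16")
    }
  }
  invisible(cfg)
}

# Per-biomarker pre/post-event distribution parameters for a given separation.
event_params_table <- function(separation = 1) {
  specs <- study_biomarkers()
  cal <- group_score_summary()
  gap <- 2 * (cal$oa_mean - cal$ya_mean)
  data.frame(
    name = specs$name,
    pre_mean = cal$ya_mean,
    pre_sd = cal$ya_sd,
    post_mean = cal$ya_mean + separation * gap,
    post_sd = cal$oa_sd,
    stringsAsFactors = FALSE
  )
}

# ID-level additive offsets per biomarker (direct tests only), in score units.
# Better-functioning (mild) participants score on the healthy side.
id_offsets_table <- function(scale = 1) {
  specs <- study_biomarkers()
  params <- event_params_table()
  dir_sign <- ifelse(specs$decline_direction == "decreasing", 1, -1)
  direct <- specs$modality == "direct_test"
  base <- c(mild = 0.5, moderate = 0, severe = -1.0) * scale
  off <- sapply(names(base), function(l) {
    ifelse(direct, base[[l]] * params$pre_sd * dir_sign, 0)
  })
  rownames(off) <- specs$name
  off
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a participant table with demographics, APOE groups, dementia labels
#' and the 16 biomarker scores, together with the latent ground truth used to
#' generate it (true event sequence, per-participant latent stage, event
#' distribution parameters, ID-level offsets). Each score is drawn from the
#' biomarker's pre-event distribution if its position in the true sequence
#' exceeds the participant's latent stage, and from the post-event
#' distribution otherwise, then shifted by the participant's ID-level offset,
#' rounded if integer-valued, and truncated to the valid score range (which
#' reproduces the floor/ceiling effects typical of these instruments).
#'
#' @param config An `ebm_cohort_config`, see [cohort_config()].
#' @return A list of class `ebm_synthetic_cohort` with elements `cohort` (data
#'   frame: `participant_id`, demographics, `score_*` and `eng_*` columns) and
#'   `truth` (class `ebm_ground_truth`: `sequence` — biomarker indices,
#'   earliest first; `sequence_names`; `stage_of` — named integer vector;
#'   `event_params`; `id_level_offsets`).
#' @export
#' @examples
#' sim <- generate_cohort(cohort_config(n_ya = 20, n_oa = 30, seed = 7))
#' table(sim$cohort$age_group)
#' sim$truth$sequence_names[1:3] # earliest events
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  specs <- study_biomarkers()
  n_events <- nrow(specs)
  set.seed(config$seed)

  if (is.null(config$true_sequence)) {
    sequence <- sample.int(n_events)
  } else {
    sequence <- config$true_sequence
    if (is.character(sequence)) sequence <- match(sequence, specs$name)
    if (length(sequence) != n_events || anyNA(sequence) ||
        !setequal(sequence, seq_len(n_events))) {
      stop("configuration error: true_sequence must be a permutation of the ",
           n_events, " biomarkers")
    }
    sequence <- as.integer(sequence)
  }
  # position_of[b] = rank of biomarker b in the ordering (1 = earliest)
  position_of <- match(seq_len(n_events), sequence)

  n <- config$n_ya + config$n_oa
  age_group <- rep(c("YA", "OA"), c(config$n_ya, config$n_oa))
  is_ya <- age_group == "YA"

  age <- numeric(n)
  age[is_ya] <- pmin(pmax(round(stats::rnorm(config$n_ya, 25.2, 5.6)), 16), 35)
  age[!is_ya] <- pmin(pmax(round(stats::rnorm(config$n_oa, 49.6, 7.5)), 36), 75)

  sex <- character(n)
  sex[is_ya] <- sample(c("M", "F"), config$n_ya, TRUE, c(57, 62) / 119)
  sex[!is_ya] <- sample(c("M", "F"), config$n_oa, TRUE, c(87, 77) / 164)

  id_level <- character(n)
  id_level[is_ya] <- sample(names(config$id_level_probs_ya), config$n_ya,
                            TRUE, config$id_level_probs_ya)
  id_level[!is_ya] <- sample(names(config$id_level_probs_oa), config$n_oa,
                             TRUE, config$id_level_probs_oa)

  apoe <- character(n)
  apoe[is_ya] <- sample(names(config$apoe_probs_ya), config$n_ya,
                        TRUE, config$apoe_probs_ya)
  apoe[!is_ya] <- sample(names(config$apoe_probs_oa), config$n_oa,
                         TRUE, config$apoe_probs_oa)

  # Latent stages: YA concentrated at 0 with a configurable leak; OA spread
  # over 0..n_events, shifted later for APOE4 carriers.
  stage <- integer(n)
  leak <- stats::runif(config$n_ya) < config$ya_stage_leak
  if (any(leak)) {
    w <- 0.6^seq_len(n_events)
    stage[which(is_ya)[leak]] <- sample.int(n_events, sum(leak), TRUE, w)
  }
  oa_probs <- config$oa_stage_probs
  if (is.null(oa_probs)) oa_probs <- rep(1, n_events + 1L)
  stage[!is_ya] <- sample(0:n_events, config$n_oa, TRUE, oa_probs)
  shift_idx <- !is_ya & apoe == "APOE4"
  stage[shift_idx] <- pmin(stage[shift_idx] + config$apoe4_stage_shift,
                           n_events)

  dementia <- rep("none", n)
  p_dem <- stats::plogis(config$dementia_slope *
                           (stage - config$dementia_midpoint))
  dem_draw <- stats::runif(n) < p_dem
  dementia[!is_ya & dem_draw] <- "diagnosed"

  params <- event_params_table(config$separation)
  offsets <- id_offsets_table(config$id_offset_scale)

  scores <- matrix(NA_real_, n, n_events,
                   dimnames = list(NULL, score_col(specs$name)))
  for (b in seq_len(n_events)) {
    occurred <- stage >= position_of[b]
    mu <- ifelse(occurred, params$post_mean[b], params$pre_mean[b])
    sdv <- ifelse(occurred, params$post_sd[b], params$pre_sd[b]) *
      config$noise_scale
    x <- stats::rnorm(n, mu, sdv) + offsets[b, id_level]
    if (specs$integer_valued[b]) x <- round(x)
    x <- pmin(pmax(x, specs$score_min[b]), specs$score_max[b])
    scores[, b] <- x
  }

  # Non-engagement (direct tests) and questionnaire missingness.
  eng <- matrix("completed", n, n_events,
                dimnames = list(NULL, eng_col(specs$name)))
  struggler <- stats::runif(n) < config$struggler_rate
  for (b in seq_len(n_events)) {
    if (specs$modality[b] == "direct_test") {
      nu <- struggler &
        stats::runif(n) < config$struggler_not_understood_prob
      na_draw <- stats::runif(n) < config$not_attempted_rate
      eng[nu, b] <- "attempted_not_understood"
      eng[na_draw, b] <- "not_attempted"
      scores[nu | na_draw, b] <- NA_real_
    } else {
      miss <- stats::runif(n) < config$informant_missing_rate
      scores[miss, b] <- NA_real_
    }
  }

  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age, age_group = age_group, sex = sex, id_level = id_level,
    dementia = dementia, apoe_group = apoe,
    scores, eng, stringsAsFactors = FALSE, check.names = FALSE
  )

  truth <- structure(list(
    sequence = sequence,
    sequence_names = specs$name[sequence],
    stage_of = stats::setNames(stage, cohort$participant_id),
    event_params = params,
    id_level_offsets = offsets
  ), class = "ebm_ground_truth")

  structure(list(cohort = cohort, truth = truth, config = config),
            class = "ebm_synthetic_cohort")
}

#' Read and write cohort tables and ground-truth sidecars
#'
#' Cohorts are stored as comma-separated text with a header row and `NA` for
#' missing values; ground truth is stored as JSON (sequence as ordered
#' biomarker names, stages as id/stage pairs).
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame; writers return the
#'   path invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname write_cohort
#' @param truth An `ebm_ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    sequence = truth$sequence_names,
    stages = data.frame(participant_id = names(truth$stage_of),
                        stage = unname(truth$stage_of)),
    event_params = truth$event_params
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- study_biomarkers()
  structure(list(
    sequence = match(raw$sequence, specs$name),
    sequence_names = raw$sequence,
    stage_of = stats::setNames(as.integer(raw$stages$stage),
                               raw$stages$participant_id),
    event_params = as.data.frame(raw$event_params)
  ), class = "ebm_ground_truth")
}
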