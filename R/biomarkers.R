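#' The 16-outcome cognitive and informant biomarker battery
#'
#' Returns the specification of the study battery: 12 direct cognitive test
#' outcomes (including orientation) and 4 informant questionnaire outcomes.
#' Each row records the valid score range, the direction in which decline
#' moves the score (`"decreasing"` = lower scores are worse, `"increasing"` =
#' higher scores are worse, as for reaction-time latency and symptom counts),
#' the modality, whether scores are integer-valued, and how a score is imputed
#' when a participant attempted the task but could not understand the
#' instructions (`"zero"`, or `"cohort_worst"` for latency, where zero would
#' be a perfect score).
#'
#' @return A data frame with one row per biomarker and columns `name`,
#'   `label`, `score_min`, `score_max`, `decline_direction`, `modality`,
#'   `integer_valued`, `not_understood_value`.
#' @export
#' @examples
#' specs <- study_biomarkers()
#' nrow(specs) # 16
study_biomarkers <- function() {
  specs <- data.frame(
    name = c(
      "kbit_verbal", "kbit_nonverbal", "pal_first_trial", "ied_stages",
      "srt_mean_latency", "obj_mem_delayed", "obj_mem_immediate",
      "nepsy_car_motorbike", "tower_of_london", "finger_nose",
      "verbal_fluency", "orientation",
      "dld_cognitive", "dld_social", "abs_total", "omq_revised"
    ),
    label = c(
      "KBIT-2 verbal raw", "KBIT-2 nonverbal raw", "PAL first trial memory",
      "IED stages completed", "SRT mean latency", "Delayed object memory",
      "Immediate object memory", "NEPSY car/motorbike", "Tower of London",
      "Finger-nose pointing", "Verbal fluency", "Orientation",
      "DLD cognitive", "DLD social", "Short ABS total", "Revised OMQ"
    ),
    score_min = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 18),
    score_max = c(108, 46, 26, 9, Inf, 7, 14, 52, 10, Inf, Inf, 12,
                  44, 60, 113, 90),
    decline_direction = c(
      "decreasing", "decreasing", "decreasing", "decreasing",
      "increasing", "decreasing", "decreasing", "decreasing",
      "decreasing", "decreasing", "decreasing", "decreasing",
      "increasing", "increasing", "decreasing", "increasing"
    ),
    modality = c(rep("direct_test", 12), rep("informant", 4)),
    integer_valued = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                       TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    not_understood_value = c(
      "zero", "zero", "zero", "zero", "cohort_worst", "zero", "zero",
      "zero", "zero", "zero", "zero", "zero",
      "zero", "zero", "zero", "zero"
    ),
    stringsAsFactors = FALSE
  )
  validate_biomarker_specs(specs)
  specs
}

validate_biomarker_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  required <- c("name", "score_min", "score_max", "decline_direction",
                "modality", "integer_valued")
  missing <- setdiff(required, names(specs))
  if (length(missing) > 0) {
    stop("biomarker specs missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(specs$name)) stop("duplicate biomarker names")
  bad <- is.finite(specs$score_min) & is.finite(specs$score_max) &
    specs$score_min >= specs$score_max
  if (any(bad)) {
    stop("score_min must be < score_max for: ",
         paste(specs$name[bad], collapse = ", "))
  }
  if (!all(specs$decline_direction %in% c("decreasing", "increasing"))) {
    stop("decline_direction must be 'decreasing' or 'increasing'")
  }
  if (!all(specs$modality %in% c("direct_test", "informant"))) {
    stop("modality must be 'direct_test' or 'informant'")
  }
  invisible(specs)
}

# Young-adult / older-adult group means (SDs) used to calibrate the synthetic
# generator's pre/post-event score distributions. Not an acceptance surface.
group_score_summary <- function() {
  data.frame(
    name = study_biomarkers()$name,
    ya_mean = c(34.95, 15.00, 10.19, 6.52, 695.72, 5.78, 10.26, 17.12,
                7.24, 11.02, 10.81, 9.55, 7.57, 9.31, 79.60, 43.42),
    ya_sd   = c(16.99, 6.94, 5.67, 2.59, 455.97, 1.52, 3.00, 9.56,
                3.12, 5.25, 5.91, 3.56, 8.35, 6.87, 19.46, 12.31),
    oa_mean = c(23.02, 9.78, 4.53, 3.41, 1423.08, 3.60, 6.41, 8.05,
                4.41, 6.09, 6.10, 6.52, 15.68, 14.66, 64.79, 56.38),
    oa_sd   = c(18.77, 7.43, 5.61, 3.06, 793.61, 2.66, 4.75, 8.91,
                3.97, 5.48, 5.92, 4.71, 12.75, 10.52, 27.00, 17.16),
    stringsAsFactors = FALSE
  )
}

score_col <- function(name) paste0("score_", name)
eng_col <- function(name) paste0("eng_", name)
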