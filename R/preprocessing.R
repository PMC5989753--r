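#' Impute scores for participants who attempted but could not understand a task
#'
#' Participants who attempted a task but were clearly unable to understand the
#' instructions (engagement flag `"attempted_not_understood"`) are allocated a
#' score of zero — except for outcomes whose `not_understood_value` is
#' `"cohort_worst"` (SRT mean latency), which receive the poorest (maximum)
#' score recorded among completed administrations in the cohort. Tasks flagged
#' `"not_attempted"` stay missing; completed scores are untouched.
#'
#' @param cohort A cohort data frame with `score_*` and `eng_*` columns.
#' @param specs Biomarker specification, see [study_biomarkers()].
#' @return The cohort with imputed scores.
#' @export
impute_performance_scores <- function(cohort, specs = study_biomarkers()) {
  for (b in seq_len(nrow(specs))) {
    sc <- score_col(specs$name[b])
    ec <- eng_col(specs$name[b])
    if (!ec %in% names(cohort)) next
    nu <- !is.na(cohort[[ec]]) & cohort[[ec]] == "attempted_not_understood"
    if (!any(nu)) next
    if (identical(specs$not_understood_value[b], "cohort_worst")) {
      completed <- cohort[[sc]][cohort[[ec]] == "completed"]
      completed <- completed[!is.na(completed)]
      if (length(completed) == 0) {
        stop("cannot impute ", specs$name[b],
             ": no completed scores recorded in the cohort")
      }
      cohort[[sc]][nu] <- max(completed)
    } else {
      cohort[[sc]][nu] <- 0
    }
  }
  cohort
}

# Nearest integer, ties rounded half away from zero.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Impute missing questionnaire items within a domain
#'
#' Missing items are imputed with the nearest integer to the mean of the
#' completed items, provided the missing fraction does not exceed
#' `max_missing_frac` (default 15%). Above the threshold (or with no
#' completed items at all) the domain total is marked missing. Completed
#' items are never altered. Ties at .5 round half away from zero.
#'
#' @param items Numeric vector of item scores, `NA` for missing.
#' @param max_missing_frac Maximum tolerated missing fraction in (0, 1].
#' @return A list with `items` (imputed vector), `total` (domain sum, `NA` if
#'   the threshold was exceeded), `n_imputed`, and `domain_missing`.
#' @export
#' @examples
#' impute_questionnaire_items(c(3, 4, NA, 3))$items
impute_questionnaire_items <- function(items, max_missing_frac = 0.15) {
  if (!is.numeric(max_missing_frac) || max_missing_frac <= 0 ||
      max_missing_frac > 1) {
    stop("max_missing_frac must lie in (0, 1]")
  }
  miss <- is.na(items)
  if (all(miss)) {
    return(list(items = items, total = NA_real_, n_imputed = 0L,
                domain_missing = TRUE))
  }
  frac <- mean(miss)
  if (frac > max_missing_frac) {
    return(list(items = items, total = NA_real_, n_imputed = 0L,
                domain_missing = TRUE))
  }
  if (any(miss)) items[miss] <- round_half_away(mean(items[!miss]))
  list(items = items, total = sum(items), n_imputed = sum(miss),
       domain_missing = FALSE)
}

id_level_code <- function(id_level) {
  c(mild = 1, moderate = 2, severe = 3)[id_level]
}

#' Fit the ID-level residualization model on the young-adult group
#'
#' For each biomarker, regresses the score on intellectual-disability (ID)
#' level using young-adult (YA) rows only, so that predicted scores capture
#' baseline ability rather than decline. ID level is coded ordinally by
#' default (mild = 1, moderate = 2, severe = 3), matching its monotone
#' severity semantics; `coding = "dummy"` fits a separate mean per level.
#'
#' @param cohort A cohort data frame (after performance-score imputation).
#' @param specs Biomarker specification.
#' @param coding `"ordinal"` or `"dummy"`.
#' @return An object of class `ebm_residual_model`: per-biomarker
#'   coefficients and a prediction for each of the three ID levels.
#' @export
fit_residual_model <- function(cohort, specs = study_biomarkers(),
                               coding = c("ordinal", "dummy")) {
  coding <- match.arg(coding)
  ya <- cohort[cohort$age_group == "YA", , drop = FALSE]
  levels3 <- c("mild", "moderate", "severe")
  pred <- matrix(NA_real_, nrow(specs), 3,
                 dimnames = list(specs$name, levels3))
  coefs <- vector("list", nrow(specs))
  names(coefs) <- specs$name
  for (b in seq_len(nrow(specs))) {
    sc <- score_col(specs$name[b])
    use <- !is.na(ya[[sc]]) & ya$id_level %in% levels3
    if (sum(use) < 3) {
      stop("fewer than 3 usable YA rows for biomarker ", specs$name[b])
    }
    y <- ya[[sc]][use]
    lev <- ya$id_level[use]
    if (length(unique(lev)) < 2) {
      stop("need >= 2 distinct ID levels among YA rows for biomarker ",
           specs$name[b])
    }
    if (coding == "ordinal") {
      fit <- stats::lm(y ~ code, data = data.frame(y = y,
                                                   code = id_level_code(lev)))
      coefs[[b]] <- stats::coef(fit)
      pred[b, ] <- stats::coef(fit)[1] + stats::coef(fit)[2] * (1:3)
    } else {
      fit <- stats::lm(y ~ lev,
                       data = data.frame(y = y,
                                         lev = factor(lev, levels = levels3)))
      coefs[[b]] <- stats::coef(fit)
      newd <- data.frame(lev = factor(levels3, levels = levels3))
      present <- levels3 %in% unique(lev)
      p <- rep(NA_real_, 3)
      p[present] <- stats::predict(fit, newd[present, , drop = FALSE])
      pred[b, ] <- p
    }
  }
  structure(list(coding = coding, predictions = pred, coefficients = coefs,
                 fitted_on = "YA"),
            class = "ebm_residual_model")
}

#' Residualize biomarker scores on ID level
#'
#' Replaces every non-missing score by the observed score minus the
#' YA-model's prediction for the participant's ID level, for YA and OA rows
#' alike. Missing scores stay missing; participants with an unknown ID level
#' (or a level the model cannot predict) get missing residuals with a
#' warning.
#'
#' @param cohort A cohort data frame.
#' @param model An `ebm_residual_model` from [fit_residual_model()].
#' @param specs Biomarker specification.
#' @return The cohort with `score_*` columns replaced by residuals.
#' @export
residualize <- function(cohort, model, specs = study_biomarkers()) {
  stopifnot(inherits(model, "ebm_residual_model"))
  levels3 <- colnames(model$predictions)
  unknown <- !cohort$id_level %in% levels3
  if (any(unknown)) {
    warning(sum(unknown), " participant(s) with unknown ID level; ",
            "their residuals are set to missing")
  }
  for (b in seq_len(nrow(specs))) {
    sc <- score_col(specs$name[b])
    p <- rep(NA_real_, nrow(cohort))
    p[!unknown] <- model$predictions[specs$name[b], cohort$id_level[!unknown]]
    cohort[[sc]] <- cohort[[sc]] - p
  }
  cohort
}

#' @rdname fit_residual_model
#' @param model An `ebm_residual_model`.
#' @param path File path for the serialized model (JSON).
#' @export
write_residual_model <- function(model, path) {
  out <- list(coding = model$coding,
              predictions = as.data.frame(model$predictions),
              biomarkers = rownames(model$predictions),
              fitted_on = model$fitted_on)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
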