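logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Stage a single participant
#'
#' Given a participant's per-biomarker event/non-event densities and the
#' fitted maximum-likelihood sequence, computes the likelihood of every
#' stage `k = 0..I` (abnormal densities for the first `k` events in the
#' sequence, normal densities for the rest) and returns the argmax stage.
#' Ties are broken toward the smallest stage, which conservatively favours
#' "no decline"; missing biomarkers contribute the uninformative pair so an
#' all-missing participant receives a flat likelihood and stage 0.
#'
#' @param pE,pnE Numeric vectors of abnormal/normal densities per biomarker
#'   (in battery order, not sequence order).
#' @param S_hat The fitted sequence (integer permutation, earliest first).
#' @return A list with `stage` (integer in 0..I) and `stage_likelihoods`
#'   (length I+1, normalized to sum to 1).
#' @export
stage_participant <- function(pE, pnE, S_hat) {
  I <- length(pE)
  S_hat <- check_permutation(S_hat, I)
  d <- log(pE[S_hat]) - log(pnE[S_hat])
  ll <- sum(log(pnE)) + c(0, cumsum(d))
  lse <- logsumexp(ll)
  list(stage = which.max(ll) - 1L,
       stage_likelihoods = exp(ll - lse))
}

#' Stage every participant in a cohort
#'
#' Assigns each participant the maximum-likelihood disease stage under the
#' fitted event sequence. Participants with all biomarkers missing get a
#' flat likelihood, stage 0, and a `flagged` marker.
#'
#' @param cohort A residualized cohort data frame.
#' @param fits Named list of `ebm_mixture_fit` objects.
#' @param S_hat The fitted maximum-likelihood sequence.
#' @param specs Biomarker specification.
#' @return A data frame (class `ebm_stage_assignments`) with
#'   `participant_id`, `stage`, `flagged`, and the normalized per-stage
#'   likelihood matrix in attribute `"stage_likelihoods"`.
#' @export
stage_cohort <- function(cohort, fits, S_hat, specs = study_biomarkers()) {
  P <- probability_matrix(cohort, fits, specs)
  res <- stage_matrix(P, S_hat)
  all_missing <- rowSums(!is.na(as.matrix(
    cohort[, score_col(specs$name), drop = FALSE]))) == 0
  out <- data.frame(participant_id = cohort$participant_id,
                    stage = res$stage,
                    flagged = all_missing,
                    stringsAsFactors = FALSE)
  attr(out, "stage_likelihoods") <- res$stage_likelihoods
  class(out) <- c("ebm_stage_assignments", "data.frame")
  out
}

# Vectorized staging over an ebm_probability_matrix.
stage_matrix <- function(P, S_hat) {
  lp <- log_probs(P)
  I <- ncol(P$pE)
  S_hat <- check_permutation(S_hat, I)
  d <- lp$logpE[, S_hat, drop = FALSE] - lp$logpnE[, S_hat, drop = FALSE]
  cums <- t(apply(d, 1, cumsum))
  if (I == 1) cums <- matrix(cums, ncol = 1)
  ll <- cbind(0, cums) + rowSums(lp$logpnE)
  stage <- max.col(ll, ties.method = "first") - 1L
  m <- apply(ll, 1, max)
  lik <- exp(ll - m)
  lik <- lik / rowSums(lik)
  colnames(lik) <- paste0("stage", 0:I)
  list(stage = stage, stage_likelihoods = lik)
}

#' @rdname stage_cohort
#' @param stages An `ebm_stage_assignments` data frame.
#' @param path Output path (comma-separated text).
#' @export
write_stages <- function(stages, path) {
  utils::write.csv(stages, path, row.names = FALSE)
  invisible(path)
}
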