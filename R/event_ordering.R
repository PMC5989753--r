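check_permutation <- function(S, I) {
  if (length(S) != I || anyNA(S) || !setequal(S, seq_len(I))) {
    stop("S must be a permutation of 1..", I)
  }
  as.integer(S)
}

log_probs <- function(P) {
  stopifnot(inherits(P, "ebm_probability_matrix"))
  list(logpE = log(P$pE), logpnE = log(P$pnE))
}

#' Log-likelihood of an event sequence
#'
#' Evaluates the stage-marginalised data likelihood of an ordering `S`: for
#' each participant the likelihood sums, over all stages `k = 0..I`, the
#' product of abnormal densities for the first `k` events in `S` and normal
#' densities for the rest. Computed in log space. A uniform stage prior
#' `1/(I+1)` is included by default; it is constant in `S`, so the
#' maximum-likelihood ordering is unchanged, and `stage_prior = FALSE`
#' recovers the bare sum-of-products form.
#'
#' @param P An `ebm_probability_matrix` from [probability_matrix()].
#' @param S Integer permutation of `1:I` (position 1 = earliest event).
#' @param stage_prior Include the uniform stage prior term.
#' @return The log-likelihood (a scalar).
#' @export
sequence_log_likelihood <- function(P, S, stage_prior = TRUE) {
  lp <- log_probs(P)
  S <- check_permutation(S, ncol(P$pE))
  ebm_loglik_cpp(lp$logpE, lp$logpnE, S - 1L, isTRUE(stage_prior))
}

#' Greedy ascent over event sequences
#'
#' From each of `n_starts` random initial permutations, repeatedly applies
#' the best pairwise position swap until no swap improves the
#' log-likelihood, and returns the best local optimum found. Deterministic
#' under a fixed seed.
#'
#' @inheritParams sequence_log_likelihood
#' @param n_starts Number of random restarts.
#' @param seed Optional integer seed.
#' @return Integer permutation (the fitted ordering) with attribute
#'   `log_lik`.
#' @export
greedy_ascent <- function(P, n_starts = 10L, seed = NULL,
                          stage_prior = TRUE) {
  stopifnot(n_starts >= 1)
  if (!is.null(seed)) set.seed(seed)
  lp <- log_probs(P)
  I <- ncol(P$pE)
  best <- NULL
  best_ll <- -Inf
  for (s in seq_len(n_starts)) {
    init <- sample.int(I) - 1L
    res <- ebm_greedy_cpp(lp$logpE, lp$logpnE, init, isTRUE(stage_prior))
    if (res$log_lik > best_ll) {
      best_ll <- res$log_lik
      best <- res$order + 1L
    }
  }
  structure(best, log_lik = best_ll)
}

#' Metropolis MCMC over event sequences
#'
#' Runs a Metropolis chain on the permutation space: proposals swap two
#' positions chosen uniformly at random and are accepted with probability
#' `min(1, exp(delta log-likelihood))`. The current state is recorded at
#' every post-burn-in iteration (the positional variance diagram built from
#' these states weights sequences by how long the chain dwells in them);
#' accepted proposals are flagged so an accepted-states-only summary is also
#' available.
#'
#' @inheritParams sequence_log_likelihood
#' @param init Initial permutation (typically the greedy-ascent fit).
#' @param n_iter Total iterations (default 100000).
#' @param burn_in Iterations discarded before recording (default 10000,
#'   truncated below `n_iter`).
#' @param seed Optional integer seed.
#' @return An object of class `ebm_sequence_samples`: `samples` (matrix,
#'   one recorded state per row), `log_lik`, `accepted`, `best_order`,
#'   `best_log_lik`, `acceptance_rate`, `kind = "mcmc"`.
#' @export
mcmc_sample <- function(P, init, n_iter = 100000L, burn_in = 10000L,
                        seed = NULL, stage_prior = TRUE) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  lp <- log_probs(P)
  I <- ncol(P$pE)
  init <- check_permutation(init, I)
  burn_in <- max(0L, min(as.integer(burn_in), as.integer(n_iter) - 1L))
  res <- ebm_mcmc_cpp(lp$logpE, lp$logpnE, init - 1L, as.integer(n_iter),
                      burn_in, isTRUE(stage_prior))
  structure(list(samples = res$samples, log_lik = res$log_lik,
                 accepted = res$accepted, best_order = res$best_order,
                 best_log_lik = res$best_log_lik,
                 acceptance_rate = res$acceptance_rate,
                 biomarkers = P$biomarkers, kind = "mcmc"),
            class = "ebm_sequence_samples")
}

#' Positional variance matrix of a bag of sequences
#'
#' Entry `(b, p)` is the fraction of sampled sequences that place biomarker
#' `b` at position `p`. Rows are ordered by the reference (maximum-
#' likelihood) sequence, so a confident fit shows up as a dark diagonal.
#'
#' @param samples An `ebm_sequence_samples`, or a matrix with one sequence
#'   per row (1-based biomarker indices by position).
#' @param order_by Optional reference sequence for row ordering; defaults to
#'   the samples' `best_order` (matrix input: identity order).
#' @param accepted_only For MCMC samples, use only iterations whose proposal
#'   was accepted.
#' @return An `I x I` matrix of proportions; rows named by biomarker index
#'   (and biomarker name when available), columns by position.
#' @export
positional_variance <- function(samples, order_by = NULL,
                                accepted_only = FALSE) {
  nms <- NULL
  if (inherits(samples, "ebm_sequence_samples")) {
    m <- samples$samples
    if (accepted_only) m <- m[samples$accepted, , drop = FALSE]
    if (is.null(order_by)) order_by <- samples$best_order
    nms <- samples$biomarkers
  } else {
    m <- samples
  }
  if (is.null(dim(m)) || nrow(m) == 0) stop("samples must be nonempty")
  I <- ncol(m)
  if (is.null(order_by)) order_by <- seq_len(I)
  pv <- matrix(0, I, I)
  for (p in seq_len(I)) {
    tab <- tabulate(m[, p], nbins = I)
    pv[, p] <- tab / nrow(m)
  }
  pv <- pv[order_by, , drop = FALSE]
  rn <- if (!is.null(nms)) nms[order_by] else as.character(order_by)
  dimnames(pv) <- list(rn, paste0("pos", seq_len(I)))
  pv
}

#' Fit the maximum-likelihood event sequence
#'
#' Convenience wrapper: greedy ascent from random restarts followed by an
#' MCMC refinement; returns the best sequence seen by either, plus the MCMC
#' samples for positional variance diagrams.
#'
#' @inheritParams mcmc_sample
#' @param n_starts Greedy restarts.
#' @return A list with `order` (ML sequence, 1-based), `log_lik`, and
#'   `samples` (`ebm_sequence_samples`).
#' @export
fit_event_sequence <- function(P, n_starts = 10L, n_iter = 100000L,
                               burn_in = 10000L, seed = NULL,
                               stage_prior = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  g <- greedy_ascent(P, n_starts = n_starts, stage_prior = stage_prior)
  sam <- mcmc_sample(P, init = as.integer(g), n_iter = n_iter,
                     burn_in = burn_in, stage_prior = stage_prior)
  if (sam$best_log_lik >= attr(g, "log_lik")) {
    list(order = sam$best_order, log_lik = sam$best_log_lik, samples = sam)
  } else {
    list(order = as.integer(g), log_lik = attr(g, "log_lik"), samples = sam)
  }
}

#' Bootstrap uncertainty in the event sequence
#'
#' Resamples participants with replacement (stratified by age group, so the
#' control/disease split that initialises the mixtures is never lost),
#' re-runs the full fit on each replicate — performance-score imputation,
#' YA residual model, residualization, mixture fitting, greedy ascent plus
#' MCMC — and collects the replicate maximum-likelihood sequences. A
#' replicate whose mixtures degenerate (e.g. a biomarker with no variance in
#' a group) is retried with a fresh resample; more than 20% retries aborts.
#'
#' @param cohort A raw (imputed or unimputed) cohort data frame.
#' @param n_boot Number of bootstrap replicates (study analyses use 100).
#' @param seed Integer seed.
#' @param specs Biomarker specification.
#' @param n_starts,n_iter,burn_in Search controls per replicate. `n_iter`
#'   defaults to 20000: the greedy fit already sits at a local optimum, so
#'   replicates need a shorter refinement chain than the primary fit.
#' @param stratified Stratify the resample by age group (default); plain
#'   resampling otherwise.
#' @param resample Set `FALSE` to re-run on the original data each replicate
#'   (identity resample, useful for testing).
#' @param stage_prior Include the uniform stage prior.
#' @return An `ebm_sequence_samples` of kind `"bootstrap"`: one ML sequence
#'   per replicate, `best_order` = the full-data ML sequence, and the number
#'   of retried replicates in `n_retries`.
#' @export
bootstrap_orderings <- function(cohort, n_boot = 100L, seed = 1L,
                                specs = study_biomarkers(),
                                n_starts = 5L, n_iter = 20000L,
                                burn_in = 2000L, stratified = TRUE,
                                resample = TRUE, stage_prior = TRUE) {
  stopifnot(n_boot >= 1)
  set.seed(seed)

  fit_once <- function(dat) {
    dat <- impute_performance_scores(dat, specs)
    rm_model <- fit_residual_model(dat, specs)
    dat <- residualize(dat, rm_model, specs)
    fits <- fit_all_mixtures(dat, specs)
    P <- probability_matrix(dat, fits, specs)
    fit_event_sequence(P, n_starts = n_starts, n_iter = n_iter,
                       burn_in = burn_in, stage_prior = stage_prior)
  }

  full_fit <- fit_once(cohort)
  I <- nrow(specs)
  ya_idx <- which(cohort$age_group == "YA")
  oa_idx <- which(cohort$age_group == "OA")

  draw_indices <- function() {
    if (!resample) return(seq_len(nrow(cohort)))
    if (stratified) {
      c(sample(ya_idx, length(ya_idx), replace = TRUE),
        sample(oa_idx, length(oa_idx), replace = TRUE))
    } else {
      sample.int(nrow(cohort), nrow(cohort), replace = TRUE)
    }
  }

  seqs <- matrix(NA_integer_, n_boot, I)
  lls <- numeric(n_boot)
  n_retries <- 0L
  max_retries <- ceiling(0.2 * n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      res <- tryCatch(fit_once(cohort[draw_indices(), , drop = FALSE]),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      n_retries <- n_retries + 1L
      message("bootstrap replicate ", b, " retried: ",
              conditionMessage(res))
      if (n_retries > max_retries) {
        stop("more than 20% of bootstrap replicates degenerate (",
             n_retries, " retries)")
      }
    }
    seqs[b, ] <- res$order
    lls[b] <- res$log_lik
  }

  structure(list(samples = seqs, log_lik = lls,
                 accepted = rep(TRUE, n_boot),
                 best_order = full_fit$order,
                 best_log_lik = full_fit$log_lik,
                 n_retries = n_retries,
                 biomarkers = specs$name, kind = "bootstrap"),
            class = "ebm_sequence_samples")
}

#' @rdname positional_variance
#' @param pv A positional variance matrix.
#' @param path File path for the delimited-text output.
#' @export
write_positional_variance <- function(pv, path) {
  utils::write.csv(as.data.frame(pv), path, row.names = TRUE)
  invisible(path)
}
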