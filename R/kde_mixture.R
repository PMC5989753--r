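# Weighted Gaussian-kernel density machinery. Components are represented
# exactly as weighted mixtures of kernels centred on the observed residuals,
# so densities can be evaluated at arbitrary points and serialized losslessly.

weighted_mean <- function(x, w) sum(w * x) / sum(w)

weighted_sd <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

# Silverman's rule with an effective sample size for weighted data.
silverman_bw <- function(x, w) {
  neff <- sum(w)^2 / sum(w^2)
  s <- weighted_sd(x, w)
  iqr <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
  spread <- if (iqr > 0) min(s, iqr / 1.34) else s
  if (!is.finite(spread) || spread <= 0) {
    stop("degenerate component: zero spread under current weights")
  }
  0.9 * spread * neff^(-1 / 5)
}

kde_density <- function(x, centers, weights, bw) {
  if (length(x) == 0) return(numeric(0))
  out <- numeric(length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    k <- stats::dnorm(outer(x[ok], centers, "-"), sd = bw)
    out[ok] <- as.vector(k %*% weights) / sum(weights)
  }
  out[!ok] <- NA_real_
  out
}

# Project responsibilities onto the set monotone in x (antitonic for
# decreasing biomarkers, where abnormal scores are low). This is the
# unimodality constraint of the two-component model: the probability of
# being in the abnormal component cannot recover as scores get healthier.
# Without it, free-form KDE mixture EM degenerates (one flexible component
# absorbs the whole sample).
monotone_responsibilities <- function(x, r, direction) {
  ord <- if (direction == "increasing") order(x) else order(-x)
  fit <- stats::isoreg(seq_along(ord), r[ord])
  r[ord] <- pmin(pmax(fit$yf, 0), 1)
  r
}

#' Fit a semisupervised two-component KDE mixture for one biomarker
#'
#' Models the distribution of (residualized) scores as a mixture of a
#' "normal" (pre-event) and an "abnormal" (post-event) component, each a
#' Gaussian kernel density estimate. The young-adult (YA) and older-adult
#' (OA) group labels define the initial components: YA values initialise the
#' normal component, OA values the abnormal one. The fit is then refined by
#' alternating steps — compute each observation's responsibility for the
#' abnormal component, refit both weighted KDEs (one pooled Silverman
#' bandwidth per biomarker, shared by the two components) and the mixture
#' weight — until the mean
#' absolute change in responsibilities falls below `tol` or `max_iter` steps.
#' Each responsibility update is projected onto the set of responsibilities
#' monotone in the score (abnormality cannot recover toward the healthy
#' side): this is the unimodality constraint that keeps two free-form
#' components identifiable.
#' Two anchors keep the semisupervised fit identifiable: YA rows keep zero
#' responsibility for the abnormal component (they are the premorbid control
#' population), and scores beyond the observed premorbid (YA) range on the
#' declining side keep responsibility one (an event is precisely a
#' transition outside the premorbid range). OA rows in between are
#' relabelled freely, so OA participants who have not yet declined drift
#' back toward the normal component and the abnormal component converges to
#' the truly declined subpopulation rather than the whole OA group.
#'
#' @param values Numeric scores or residuals (missing values dropped).
#' @param group_labels Character vector, `"YA"` or `"OA"`, one per value.
#' @param direction `"decreasing"` if abnormal values are smaller than
#'   normal ones, `"increasing"` otherwise.
#' @param biomarker Optional biomarker name carried in the fit.
#' @param max_iter,tol Refinement controls (defaults 200 and 1e-4 on the mean
#'   absolute responsibility change).
#' @param assignment `"soft"` (weighted-KDE refit, default) or `"hard"`
#'   (0/1 responsibilities).
#' @return An object of class `ebm_mixture_fit`: kernel centers, per-center
#'   abnormal responsibilities, the two bandwidths, the mixture weight of the
#'   abnormal component, and convergence diagnostics.
#' @export
fit_mixture <- function(values, group_labels, direction,
                        biomarker = NA_character_,
                        max_iter = 200L, tol = 1e-4,
                        assignment = c("soft", "hard")) {
  assignment <- match.arg(assignment)
  stopifnot(direction %in% c("decreasing", "increasing"))
  keep <- !is.na(values)
  x <- as.numeric(values[keep])
  g <- group_labels[keep]
  if (!all(g %in% c("YA", "OA"))) stop("group labels must be YA or OA")
  if (sum(g == "YA") < 10 || sum(g == "OA") < 10) {
    stop("need at least 10 non-missing values per group")
  }
  if (length(unique(x)) == 1) stop("degenerate input: all values identical")

  r <- as.numeric(g == "OA")
  ya <- g == "YA"
  converged <- FALSE
  iter <- 0L
  eps <- 1e-12
  # One pooled bandwidth per biomarker, shared by both components.
  # Component-specific bandwidths recomputed from the evolving weights turn
  # degenerate when one component's mass concentrates on a few points, and
  # the resulting spiky/washed-out density ratios destabilise the fit.
  bw <- silverman_bw(x, rep(1, length(x)))
  # Anchors, from the model's definition of an event as a transition outside
  # the premorbid range: the YA core (within a Tukey-style fence on the
  # declining side) is trusted as never-event, while any score beyond the
  # core's declining-side extreme is an event by definition. YA values
  # beyond the fence are left free — they may be genuinely declined
  # (mislabelled or subclinical) controls, and hard-anchoring them would
  # make the fit fragile to control contamination.
  ya_x <- x[ya]
  qs <- stats::quantile(ya_x, c(0.25, 0.75), names = FALSE)
  spread <- max(qs[2] - qs[1], stats::sd(ya_x))
  if (direction == "decreasing") {
    fence <- qs[1] - 1.5 * spread
    ya_core <- ya & x >= fence
    beyond <- x < min(x[ya_core])
  } else {
    fence <- qs[2] + 1.5 * spread
    ya_core <- ya & x <= fence
    beyond <- x > max(x[ya_core])
  }
  if (!any(beyond & !ya)) {
    # every score sits inside the premorbid range (typically a shared task
    # floor): seed the abnormal component with the decline-side extreme of
    # the disease group, otherwise it collapses onto the pooled density and
    # the biomarker loses all ordering information
    extreme <- if (direction == "decreasing") {
      min(x[!ya])
    } else {
      max(x[!ya])
    }
    beyond <- beyond | (!ya & x == extreme)
  }
  # pooled bandwidth is fixed, so the kernel matrix is constant across
  # refinement steps
  K <- stats::dnorm(outer(x, x, "-"), sd = bw)
  for (iter in seq_len(max_iter)) {
    w <- mean(r)
    wE <- pmax(r, eps); wN <- pmax(1 - r, eps)
    fE <- as.vector(K %*% wE) / sum(wE)
    fN <- as.vector(K %*% wN) / sum(wN)
    denom <- w * fE + (1 - w) * fN
    r_new <- ifelse(denom > 0, w * fE / denom, 0.5)
    # project, then anchor: anchored zeros may legitimately sit at the
    # abnormal extreme (premorbid participants at a task floor) and must not
    # drag the monotone curve down through the pooled-means projection
    r_new <- monotone_responsibilities(x, r_new, direction)
    r_new[ya_core] <- 0
    r_new[beyond] <- 1
    if (assignment == "hard") r_new <- as.numeric(r_new >= 0.5)
    delta <- mean(abs(r_new - r))
    r <- r_new
    if (delta < tol) { converged <- TRUE; break }
  }
  bwE <- bwN <- bw

  fit <- structure(list(
    biomarker = biomarker, direction = direction,
    centers = x, resp = r,
    bw_event = bwE, bw_nonevent = bwN,
    mixture_weight = mean(r),
    n_iter = iter, converged = converged, assignment = assignment
  ), class = "ebm_mixture_fit")

  medE <- weighted_median(x, pmax(fit$resp, 1e-12))
  medN <- weighted_median(x, pmax(1 - fit$resp, 1e-12))
  ok <- if (direction == "decreasing") medE < medN else medE > medN
  if (!ok) {
    stop("direction violation after fit for ", biomarker,
         ": abnormal component is not on the declining side; ",
         "review bandwidths/inputs")
  }
  fit
}

#' Evaluate event and non-event densities at a score
#'
#' Returns the abnormal-component density `pE = P(x | E)` and the
#' normal-component density `pnE = P(x | not E)` at each value of `x`.
#' Missing values return the uninformative pair `(1, 1)`, so a participant's
#' stage likelihood is invariant to where a missing biomarker sits in the
#' sequence.
#'
#' @param fit An `ebm_mixture_fit`.
#' @param x Numeric vector of (residualized) scores; may contain `NA`.
#' @return A two-column matrix with columns `pE` and `pnE`.
#' @export
event_probabilities <- function(fit, x) {
  stopifnot(inherits(fit, "ebm_mixture_fit"))
  pE <- kde_density(x, fit$centers, pmax(fit$resp, 1e-12), fit$bw_event)
  pnE <- kde_density(x, fit$centers, pmax(1 - fit$resp, 1e-12),
                     fit$bw_nonevent)
  miss <- is.na(x)
  pE[miss] <- 1
  pnE[miss] <- 1
  cbind(pE = pE, pnE = pnE)
}

#' Fit mixtures for every biomarker in a cohort
#'
#' @param cohort A residualized cohort data frame with `age_group`.
#' @param specs Biomarker specification.
#' @param ... Passed to [fit_mixture()].
#' @return A named list of `ebm_mixture_fit` objects.
#' @export
fit_all_mixtures <- function(cohort, specs = study_biomarkers(), ...) {
  fits <- lapply(seq_len(nrow(specs)), function(b) {
    fit_mixture(cohort[[score_col(specs$name[b])]], cohort$age_group,
                specs$decline_direction[b], biomarker = specs$name[b], ...)
  })
  names(fits) <- specs$name
  fits
}

#' Build the participant-by-biomarker probability matrix
#'
#' Evaluates every participant's residual under each biomarker's two mixture
#' components and clips the densities below at `clip` (default 1e-12) so that
#' log-space products in the sequence likelihood never hit `-Inf`.
#'
#' @param cohort A residualized cohort data frame.
#' @param fits Named list of `ebm_mixture_fit` objects.
#' @param specs Biomarker specification.
#' @param clip Lower clip applied to both densities.
#' @return An object of class `ebm_probability_matrix`: matrices `pE`, `pnE`
#'   (participants x biomarkers), `biomarkers`, `participant_ids`.
#' @export
probability_matrix <- function(cohort, fits, specs = study_biomarkers(),
                               clip = 1e-12) {
  nms <- specs$name
  stopifnot(all(nms %in% names(fits)))
  J <- nrow(cohort)
  pE <- pnE <- matrix(NA_real_, J, length(nms),
                      dimnames = list(cohort$participant_id, nms))
  for (b in nms) {
    ev <- event_probabilities(fits[[b]], cohort[[score_col(b)]])
    pE[, b] <- pmax(ev[, "pE"], clip)
    pnE[, b] <- pmax(ev[, "pnE"], clip)
  }
  structure(list(pE = pE, pnE = pnE, biomarkers = nms,
                 participant_ids = cohort$participant_id),
            class = "ebm_probability_matrix")
}

#' Serialize and reload a mixture fit
#'
#' Fits are written as JSON with full floating-point precision (kernel
#' centers, responsibilities, bandwidths, metadata) and reload bit-exactly.
#'
#' @param fit An `ebm_mixture_fit`.
#' @param path File path.
#' @return `read_mixture_fit` returns the fit; the writer returns the path
#'   invisibly.
#' @export
write_mixture_fit <- function(fit, path) {
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(unclass(fit), path, digits = I(17), auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname write_mixture_fit
#' @export
read_mixture_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$centers <- as.numeric(raw$centers)
  raw$resp <- as.numeric(raw$resp)
  raw$n_iter <- as.integer(raw$n_iter)
  structure(raw, class = "ebm_mixture_fit")
}
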