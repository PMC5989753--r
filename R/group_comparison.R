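#' Mann-Whitney U test for stage distributions
#'
#' Computes the Mann-Whitney statistic `U` for group `a` (the number of pairs
#' where `a` exceeds `b`, ties counting one half) and a two-sided p-value.
#' Disease stages are heavily tied integers, so `U` uses midranks and the
#' p-value comes from the normal approximation with tie-corrected variance
#' and a continuity correction. When `length(a) * length(b) <= 400` an
#' exact-enumeration mode is used: `U` is computed by counting all pairs
#' directly, and for tie-free inputs the exact null distribution
#' ([stats::pwilcox]) replaces the approximation.
#'
#' @param a,b Numeric vectors (e.g. stages) for the two groups.
#' @param exact Force exact mode on/off; default (`NULL`) uses exact mode
#'   when `length(a) * length(b) <= 400`.
#' @param continuity Apply the continuity correction in the approximation.
#' @return A list with `U` (for group `a`), `p` (two-sided), `n_a`, `n_b`,
#'   and `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U # 0: complete separation
mann_whitney_u <- function(a, b, exact = NULL, continuity = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a == 0 || n_b == 0) stop("both groups must be nonempty")
  use_exact <- if (is.null(exact)) n_a * n_b <= 400 else isTRUE(exact)

  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2

  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (use_exact) {
    # pair-counting definition of U (identical to the rank-sum form)
    U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    if (!has_ties) {
      p <- if (U > n_a * n_b / 2) {
        2 * stats::pwilcox(U - 1, n_a, n_b, lower.tail = FALSE)
      } else {
        2 * stats::pwilcox(U, n_a, n_b)
      }
      p <- min(1, p)
      return(list(U = U, p = p, n_a = n_a, n_b = n_b, method = "exact"))
    }
  }

  mu <- n_a * n_b / 2
  n <- n_a + n_b
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations identical: no evidence either way
    return(list(U = U, p = 1, n_a = n_a, n_b = n_b,
                method = "approximate"))
  }
  z <- U - mu
  if (continuity) z <- z - sign(z) * 0.5
  z <- z / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, n_a = n_a, n_b = n_b, method = "approximate")
}

#' Run the study's group contrasts on stage distributions
#'
#' Compares assigned disease stages between: (1) the YA and OA age groups;
#' (2) OA participants with and without a clinical dementia diagnosis;
#' (3, 4) the APOE4 group against the APOE2 and APOE3 groups, separately
#' within each age group. APOE 2:4 carriers are omitted from the APOE
#' contrasts. A contrast with an empty cell is skipped with a warning;
#' the others still run.
#'
#' @param stages An `ebm_stage_assignments` data frame (or any data frame
#'   with `participant_id` and `stage`).
#' @param cohort The cohort data frame (for the grouping variables).
#' @return A data frame with one row per contrast: `contrast`, `group`
#'   (which subset it ran in), `n_a`, `n_b`, `U`, `p`, and `direction`
#'   (which side is staged later, by comparing `U` to its null mean).
#' @export
run_contrasts <- function(stages, cohort) {
  d <- merge(cohort, as.data.frame(stages)[, c("participant_id", "stage")],
             by = "participant_id")
  rows <- list()

  add <- function(contrast, group, a, b, label_a, label_b) {
    res <- tryCatch(mann_whitney_u(a, b), error = function(e) e)
    if (inherits(res, "error")) {
      warning("contrast ", contrast, " (", group, ") skipped: ",
              conditionMessage(res))
      return(invisible(NULL))
    }
    direction <- if (res$U > res$n_a * res$n_b / 2) {
      paste(label_a, "later")
    } else if (res$U < res$n_a * res$n_b / 2) {
      paste(label_b, "later")
    } else "tied"
    rows[[length(rows) + 1]] <<- data.frame(
      contrast = contrast, group = group,
      n_a = res$n_a, n_b = res$n_b, U = res$U, p = res$p,
      direction = direction, stringsAsFactors = FALSE)
  }

  add("YA_vs_OA", "all",
      d$stage[d$age_group == "OA"], d$stage[d$age_group == "YA"],
      "OA", "YA")

  oa <- d[d$age_group == "OA", , drop = FALSE]
  add("dementia_vs_none_within_OA", "OA",
      oa$stage[oa$dementia == "diagnosed"],
      oa$stage[oa$dementia == "none"],
      "dementia", "no dementia")

  for (grp in c("YA", "OA")) {
    g <- d[d$age_group == grp & d$apoe_group != "APOE24", , drop = FALSE]
    add("APOE4_vs_APOE2_within_group", grp,
        g$stage[g$apoe_group == "APOE4"], g$stage[g$apoe_group == "APOE2"],
        "APOE4", "APOE2")
    add("APOE4_vs_APOE3_within_group", grp,
        g$stage[g$apoe_group == "APOE4"], g$stage[g$apoe_group == "APOE3"],
        "APOE4", "APOE3")
  }

  if (length(rows) == 0) {
    return(data.frame(contrast = character(), group = character(),
                      n_a = integer(), n_b = integer(), U = numeric(),
                      p = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
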