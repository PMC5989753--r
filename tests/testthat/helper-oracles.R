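# Independent oracles used to freeze expected values. These deliberately use
# naive formulations (triple loops, exhaustive enumeration, pair counting)
# and stay independent of the package's computational paths.

# Literal triple-loop evaluation of the stage-marginalised likelihood:
# P(X|S) = prod_j sum_k prod_{i<=k} pE(order_i) * prod_{i>k} pnE(order_i)
oracle_loglik <- function(pE, pnE, ord, stage_prior = TRUE) {
  J <- nrow(pE); I <- ncol(pE)
  total <- 0
  for (j in seq_len(J)) {
    s <- 0
    for (k in 0:I) {
      prod_jk <- 1
      for (pos in seq_len(I)) {
        b <- ord[pos]
        prod_jk <- prod_jk * if (pos <= k) pE[j, b] else pnE[j, b]
      }
      s <- s + prod_jk
    }
    total <- total + log(s)
  }
  if (stage_prior) total <- total - J * log(I + 1)
  as.numeric(total)
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- as.integer(append(p, n, after = pos - 1))
    }
  }
  out
}

# Exhaustive-search maximum-likelihood sequence (small I only).
oracle_best_sequence <- function(P, stage_prior = TRUE) {
  perms <- all_perms(ncol(P$pE))
  lls <- vapply(perms, function(s) oracle_loglik(P$pE, P$pnE, s, stage_prior),
                numeric(1))
  list(order = perms[[which.max(lls)]], log_lik = max(lls))
}

make_pm <- function(pE, pnE, names = NULL) {
  if (is.null(names)) names <- paste0("bm", seq_len(ncol(pE)))
  dimnames(pE) <- dimnames(pnE) <- list(NULL, names)
  structure(list(pE = pE, pnE = pnE, biomarkers = names,
                 participant_ids = paste0("P", seq_len(nrow(pE)))),
            class = "ebm_probability_matrix")
}

random_pm <- function(I, J) {
  make_pm(matrix(runif(J * I, 0.05, 1), J, I),
          matrix(runif(J * I, 0.05, 1), J, I))
}

# A well-separated instance: participants at known stages along a known
# order, with near-deterministic event evidence.
separated_pm <- function(I, J, order = sample.int(I), p_hi = 0.95,
                         p_lo = 0.05) {
  stage <- sample(0:I, J, replace = TRUE)
  pos_of <- match(seq_len(I), order)
  occurred <- outer(stage, pos_of, ">=")
  pE <- ifelse(occurred, p_hi, p_lo)
  pnE <- ifelse(occurred, p_lo, p_hi)
  pm <- make_pm(pE, pnE)
  attr(pm, "true_order") <- order
  attr(pm, "true_stage") <- stage
  pm
}

# Brute-force Mann-Whitney U for group a: count of pairs where a beats b,
# ties counting one half.
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

kendall_tau_orders <- function(order_a, order_b) {
  I <- length(order_a)
  cor(match(seq_len(I), order_a), match(seq_len(I), order_b),
      method = "kendall")
}
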