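#' Build the event-probability matrices for a cohort
#'
#' Evaluates each fitted per-biomarker mixture at every subject's score,
#' giving the `N x M` pre-event and post-event density matrices that enter
#' the sequence likelihood. Missing scores contribute (1, 1) and so cancel.
#'
#' @param mixtures Named list of `ebm_mixture` fits, one per biomarker.
#' @param cohort Cohort tibble with matching biomarker columns.
#' @return List with `p_pre` and `p_post` (`N x M` matrices, strictly
#'   positive) and `biomarkers`.
#' @export
event_probability_matrix <- function(mixtures, cohort) {
  bm <- names(mixtures)
  x <- score_matrix(cohort, bm)
  p_pre <- matrix(1, nrow(x), length(bm), dimnames = list(NULL, bm))
  p_post <- p_pre
  for (i in seq_along(bm)) {
    p <- event_probabilities(mixtures[[i]], x[, i])
    p_pre[, i] <- p$p_pre
    p_post[, i] <- p$p_post
  }
  list(p_pre = p_pre, p_post = p_post, biomarkers = bm)
}

check_permutation <- function(s, m) {
  s <- as.integer(s)
  if (length(s) != m || !setequal(s, seq_len(m))) {
    stop("sequence must be a permutation of 1..", m, call. = FALSE)
  }
  s
}

# row-wise cumulative sums (N x M in, N x M out)
row_cumsum <- function(x) {
  if (ncol(x) == 1) return(x)
  t(apply(x, 1, cumsum))
}

#' Log-likelihood of an event sequence
#'
#' The event-based model likelihood of the data given an ordering: each
#' subject is summed over all `M + 1` latent stages, a stage-`m` term being
#' the product of post-event densities for the first `m` events in the
#' sequence and pre-event densities for the rest. Stage terms are
#' accumulated as cumulative log-products and combined by log-sum-exp, so
#' the value is stable for large cohorts.
#'
#' @param probs Event-probability matrices from
#'   [event_probability_matrix()] (or any list with strictly positive
#'   `p_pre`, `p_post` of equal shape).
#' @param s Integer permutation of `1..M`: `s[k]` is the biomarker occupying
#'   position `k`.
#' @return Total log-likelihood (a scalar).
#' @export
sequence_log_likelihood <- function(probs, s) {
  lp_pre <- log(probs$p_pre)
  lp_post <- log(probs$p_post)
  s <- check_permutation(s, ncol(lp_pre))
  sum(subject_stage_logliks(lp_pre, lp_post, s, logsumexp = TRUE))
}

# per-subject stage log-likelihood matrix (N x (M+1)), or its row-wise
# log-sum-exp when logsumexp = TRUE
subject_stage_logliks <- function(lp_pre, lp_post, s, logsumexp = FALSE) {
  n <- nrow(lp_pre)
  a <- cbind(0, row_cumsum(lp_post[, s, drop = FALSE]))     # sum_{k<=m} post
  pre_tot <- rowSums(lp_pre[, s, drop = FALSE])
  b <- pre_tot - cbind(0, row_cumsum(lp_pre[, s, drop = FALSE]))  # sum_{k>m} pre
  terms <- a + b
  if (!logsumexp) return(terms)
  mx <- apply(terms, 1, max)
  mx + log(rowSums(exp(terms - mx)))
}
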