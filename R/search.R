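#' Greedy ascent over event orderings
#'
#' From each of `n_starts` random permutations, repeatedly applies the best
#' improving pairwise swap (first-best in row-major scan order on ties)
#' until no swap increases the sequence log-likelihood, and returns the best
#' local optimum found. Each start uses its own RNG stream derived from
#' `seed`, so results are reproducible and independent of start order.
#'
#' @inheritParams sequence_log_likelihood
#' @param n_starts Number of random initialisations.
#' @param seed Integer seed.
#' @return Integer permutation (the best ordering found), with attribute
#'   `log_likelihood`.
#' @export
greedy_ascent <- function(probs, n_starts = 16, seed = 1) {
  stopifnot(n_starts >= 1)
  m <- ncol(probs$p_pre)
  lp_pre <- log(probs$p_pre)
  lp_post <- log(probs$p_post)
  ll <- function(s) sum(subject_stage_logliks(lp_pre, lp_post, s, TRUE))

  swaps <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  swaps <- swaps[order(swaps[, 1], swaps[, 2]), , drop = FALSE]

  best_s <- NULL
  best_ll <- -Inf
  for (start in seq_len(n_starts)) {
    s <- withr::with_seed(seed + start, sample.int(m))
    cur <- ll(s)
    repeat {
      cand_best <- cur
      cand_s <- NULL
      for (r in seq_len(nrow(swaps))) {
        s2 <- s
        s2[c(swaps[r, 1], swaps[r, 2])] <- s2[c(swaps[r, 2], swaps[r, 1])]
        v <- ll(s2)
        if (v > cand_best) {
          cand_best <- v
          cand_s <- s2
        }
      }
      if (is.null(cand_s)) break
      s <- cand_s
      cur <- cand_best
    }
    if (cur > best_ll) {
      best_ll <- cur
      best_s <- s
    }
  }
  structure(best_s, log_likelihood = best_ll)
}

#' Metropolis MCMC over event orderings
#'
#' Samples the posterior over orderings under a uniform prior: proposals
#' swap two distinct uniformly chosen positions and are accepted with
#' probability `min(1, exp(delta log-likelihood))`. Draws after `burn_in`
#' are recorded.
#'
#' @inheritParams sequence_log_likelihood
#' @param init Starting permutation (typically the greedy optimum).
#' @param n_samples Number of post-burn-in samples to keep.
#' @param burn_in Number of initial iterations to discard.
#' @param seed Integer seed.
#' @return List of class `ebm_samples`: `sequences` (`n_samples x M`
#'   integer matrix), `log_likelihoods`, `accept_rate`, `settings`.
#' @export
mcmc_sample <- function(probs, init, n_samples = 10000, burn_in = 1000,
                        seed = 1) {
  m <- ncol(probs$p_pre)
  s <- check_permutation(init, m)
  stopifnot(n_samples >= 1, burn_in >= 0)
  lp_pre <- log(probs$p_pre)
  lp_post <- log(probs$p_post)
  ll <- function(s) sum(subject_stage_logliks(lp_pre, lp_post, s, TRUE))

  total <- n_samples + burn_in
  keep <- matrix(NA_integer_, n_samples, m)
  keep_ll <- numeric(n_samples)
  n_accept <- 0L

  withr::with_seed(seed, {
    cur <- ll(s)
    for (it in seq_len(total)) {
      pos <- sample.int(m, 2)
      s2 <- s
      s2[pos] <- s2[rev(pos)]
      v <- ll(s2)
      if (log(stats::runif(1)) < v - cur) {
        s <- s2
        cur <- v
        n_accept <- n_accept + 1L
      }
      if (it > burn_in) {
        keep[it - burn_in, ] <- s
        keep_ll[it - burn_in] <- cur
      }
    }
  })

  structure(
    list(
      sequences = keep,
      log_likelihoods = keep_ll,
      accept_rate = n_accept / total,
      settings = list(proposal = "random transposition",
                      n_samples = n_samples, burn_in = burn_in, seed = seed)
    ),
    class = "ebm_samples"
  )
}

#' Positional variance of sampled orderings
#'
#' Condenses a set of sampled orderings into the `M x M` matrix of how
#' often each event occupies each position. Rows follow the reference
#' (maximum-likelihood) ordering, so a confident posterior reads down the
#' diagonal. Because every sample is a permutation, the matrix is doubly
#' stochastic.
#'
#' @param samples An `ebm_samples` object, or an integer matrix with one
#'   ordering per row.
#' @param reference Permutation fixing the row order (the ML sequence).
#' @param event_names Optional row names.
#' @return `M x M` matrix; `rownames` are events in reference order.
#' @export
positional_variance <- function(samples, reference,
                                event_names = NULL) {
  seqs <- if (inherits(samples, "ebm_samples")) samples$sequences else samples
  if (!is.matrix(seqs)) seqs <- matrix(seqs, nrow = 1)
  m <- ncol(seqs)
  reference <- check_permutation(reference, m)
  stopifnot(nrow(seqs) >= 1)

  counts <- matrix(0, m, m)
  for (pos in seq_len(m)) {
    tab <- tabulate(seqs[, pos], nbins = m)
    counts[, pos] <- tab
  }
  pvd <- counts[reference, , drop = FALSE] / nrow(seqs)
  rownames(pvd) <- if (!is.null(event_names)) {
    event_names[reference]
  } else {
    paste0("event_", reference)
  }
  colnames(pvd) <- seq_len(m)
  pvd
}

#' Mean positional entropy of a positional variance matrix
#'
#' Shannon entropy (nats) of each event's position distribution, averaged
#' over events. Zero for a point-mass ordering, `log(M)` for a uniform one.
#' Useful for comparing posterior uncertainty with bootstrap uncertainty.
#'
#' @param pvd `M x M` positional variance matrix.
#' @return Mean row entropy in nats.
#' @export
positional_entropy <- function(pvd) {
  stopifnot(is.matrix(pvd), nrow(pvd) == ncol(pvd))
  rows <- apply(pvd, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
  mean(rows)
}
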