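# shared fixtures and independent oracles

# random strictly-positive event-probability matrices
rand_probs <- function(seed, n, m, lo = 0.2, hi = 1) {
  withr::with_seed(seed, list(
    p_pre = matrix(stats::runif(n * m, lo, hi), n, m),
    p_post = matrix(stats::runif(n * m, lo, hi), n, m)
  ))
}

# brute-force sequence likelihood: literal nested loops in linear space,
# independent of the log-space implementation under test
brute_force_ll <- function(probs, s) {
  n <- nrow(probs$p_pre)
  m <- ncol(probs$p_pre)
  total <- 0
  for (j in seq_len(n)) {
    subj <- 0
    for (stage in 0:m) {
      term <- 1
      for (k in seq_len(m)) {
        term <- term * if (k <= stage) probs$p_post[j, s[k]] else
          probs$p_pre[j, s[k]]
      }
      subj <- subj + term
    }
    total <- total + log(subj)
  }
  total
}

# all permutations of 1..m (m small)
all_perms <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(m - 1)
  out <- NULL
  for (k in seq_len(m)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  unname(out)
}

# exhaustive maximum-likelihood ordering
exhaustive_best <- function(probs) {
  perms <- all_perms(ncol(probs$p_pre))
  lls <- apply(perms, 1, function(p) sequence_log_likelihood(probs, p))
  list(order = perms[which.max(lls), ], ll = max(lls))
}

# planted instance: patients strongly post-event on early markers
planted_probs <- function(order, n = 40, strong = 0.99, weak = 0.01) {
  m <- length(order)
  p_pre <- matrix(NA_real_, n, m)
  p_post <- matrix(NA_real_, n, m)
  pos <- order(order)
  stage <- rep(seq_len(m), length.out = n)
  for (j in seq_len(n)) {
    for (i in seq_len(m)) {
      if (pos[i] <= stage[j]) {
        p_post[j, i] <- strong
        p_pre[j, i] <- weak
      } else {
        p_post[j, i] <- weak
        p_pre[j, i] <- strong
      }
    }
  }
  list(p_pre = p_pre, p_post = p_post)
}

# the 17-test neuropsychological battery column names used in examples
battery_names <- function() {
  c("ACancelTime", "ACancelMissed", "FragmentedLetters", "DotCounting",
    "ShapeDiscrimination", "ObjectDecision", "SRMT_Words", "SRMT_Faces",
    "PAL", "DigitSpanF", "DigitSpanFMax", "DigitSpanB", "DigitSpanBMax",
    "MMSE", "GDA_add", "GDA_sub", "GDA_total")
}

# well-separated two-group fixture for mixture tests
sep_fixture <- function(seed = 1, n = 150, delta = 4) {
  withr::with_seed(seed, {
    x <- c(stats::rnorm(n / 2, 0, 1), stats::rnorm(n / 2, delta, 1))
    list(values = x, labels = rep(c(FALSE, TRUE), each = n / 2))
  })
}

# per-point posterior post-event probability under a fitted mixture
posterior_post <- function(fit, x) {
  p <- event_probabilities(fit, x)
  fit$w * p$p_post / (fit$w * p$p_post + (1 - fit$w) * p$p_pre)
}

write_temp_cohort_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
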