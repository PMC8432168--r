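co_st <- simulate_cohort(m = 5, n_patients = 50, n_controls = 25,
                         shape = "gaussian", seed = 41)
fit_st <- fit_ebm(co_st, mcmc_samples = 400, burn_in = 100, seed = 41)

test_that("extreme profiles stage at the ends and ties break low", {
  bm <- fit_st$biomarkers
  healthy <- co_st[co_st$label == "control", ][1, ]
  healthy[bm] <- -2       # deep in the normal mode for every marker
  sick <- healthy
  sick[bm] <- 6           # deep in the abnormal mode
  two <- as_ebm_cohort(as.data.frame(dplyr::bind_rows(healthy, sick)) |>
                         dplyr::mutate(subject_id = c("h", "s")))
  st <- stage_cohort(fit_st, two)
  expect_equal(st$stage, c(0L, 5L))
})

test_that("stage equals the argmax over enumerated stage terms", {
  # ratio > 1 for exactly the first 3 sequence positions -> stage 3
  m <- 6
  p_pre <- rep(0.2, m)
  p_post <- c(0.8, 0.8, 0.8, 0.05, 0.05, 0.05)
  probs <- list(p_pre = matrix(p_pre, 1), p_post = matrix(p_post, 1))
  terms <- vapply(0:m, function(stage) {
    prod(p_post[seq_len(stage)]) * prod(p_pre[setdiff(seq_len(m), seq_len(stage))])
  }, numeric(1))
  expect_equal(which.max(terms) - 1L, 3L)
  lt <- kdeebm:::subject_stage_logliks(log(probs$p_pre), log(probs$p_post),
                                       1:m)
  expect_equal(unname(apply(lt, 1, which.max) - 1L), 3L)
  expect_equal(exp(lt[1, ]), terms, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("an all-missing subject stages at zero and is flagged", {
  bm <- fit_st$biomarkers
  row <- co_st[1, ]
  row[bm] <- NA_real_
  one <- as_ebm_cohort(as.data.frame(row))
  st <- stage_cohort(fit_st, one)
  expect_equal(st$stage, 0L)
  expect_true(st$all_missing)
})

test_that("staging is invariant to biomarker column order", {
  st1 <- stage_cohort(fit_st, co_st)
  shuffled <- co_st[, c("subject_id", "visit", "label",
                        rev(fit_st$biomarkers))]
  shuffled <- kdeebm:::new_ebm_cohort(shuffled, rev(fit_st$biomarkers))
  st2 <- stage_cohort(fit_st, shuffled)
  expect_equal(st1, st2)
})

test_that("column mismatches are reported by name", {
  co2 <- co_st
  names(co2)[names(co2) == "bm1"] <- "other"
  co2 <- kdeebm:::new_ebm_cohort(co2, c("other", paste0("bm", 2:5)))
  expect_error(stage_cohort(fit_st, co2), "missing: bm1")
  expect_error(stage_cohort(fit_st, co2), "extra: other")
})

test_that("turning markers abnormal along the sequence never lowers stage", {
  bm <- fit_st$biomarkers
  ord <- fit_st$ml_order
  prev_stage <- -1L
  for (k in 0:5) {
    prof <- co_st[1, ]
    prof[bm] <- -2
    if (k > 0) prof[bm[ord[seq_len(k)]]] <- 6
    one <- as_ebm_cohort(as.data.frame(prof))
    st <- stage_cohort(fit_st, one)
    expect_gte(st$stage, prev_stage)
    prev_stage <- st$stage
  }
})

test_that("controls stage earlier than patients on simulated data", {
  st <- stage_cohort(fit_st, co_st)
  means <- tapply(st$stage, st$label, mean)
  expect_lt(means["control"], means["patient"])
  hist <- stage_histogram(st, m = 5)
  expect_equal(sum(hist$n), nrow(co_st))
  expect_equal(nrow(hist), 2 * 6)
})

test_that("longitudinal consistency counts all within-subject pairs", {
  stages <- tibble::tibble(
    subject_id = c("a", "a", "a", "b", "b"),
    visit = c(0L, 1L, 2L, 0L, 1L),
    stage = c(1L, 2L, 4L, 5L, 3L)
  )
  # subject a: 3 ordered pairs all non-decreasing; b: one pair 5 -> 3
  r0 <- longitudinal_consistency(stages, tolerance = 0)
  expect_equal(r0$n_pairs, 4L)
  expect_equal(r0$n_consistent, 3L)
  expect_equal(r0$proportion, 0.75)
  r1 <- longitudinal_consistency(stages, tolerance = 1)
  expect_equal(r1$n_consistent, 3L)   # 3 >= 5 - 1 is still false
  r2 <- longitudinal_consistency(stages, tolerance = 2)
  expect_equal(r2$proportion, 1)
  expect_error(
    longitudinal_consistency(stages[c(1, 4), ], tolerance = 0),
    "more than one visit"
  )
})

test_that("strictly increasing stages are fully consistent at any tolerance", {
  stages <- tibble::tibble(subject_id = rep(letters[1:3], each = 3),
                           visit = rep(0:2, 3),
                           stage = rep(c(0L, 2L, 4L), 3))
  expect_equal(longitudinal_consistency(stages, tolerance = 0)$proportion, 1)
})

test_that("default tolerance derives from the positional variance", {
  expect_equal(stage_tolerance(diag(5)), 0L)
  expect_equal(stage_tolerance(matrix(0.25, 4, 4)),
               as.integer(round(sqrt(sum(0.25 * (1:4 - 2.5)^2)))))
})

test_that("bootstrap positional variance is doubly stochastic and aligned", {
  co <- simulate_cohort(m = 4, n_patients = 50, n_controls = 25,
                        shape = "gaussian", separation = 5, seed = 43)
  fit <- fit_ebm(co, mcmc_samples = 0, n_starts = 8, seed = 43)
  boot <- bootstrap_model(co, n_boot = 8, n_starts = 8, seed = 43,
                          reference_order = fit$ml_order)
  expect_equal(dim(boot$orders), c(8, 4))
  expect_equal(rowSums(boot$pvd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colSums(boot$pvd), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # high-signal cohort: every event's modal position within 1 of the ML one
  modal <- apply(boot$pvd, 1, which.max)
  expect_true(all(abs(modal - seq_len(4)) <= 1))
})
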