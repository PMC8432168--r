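#' Assign maximum-likelihood model stages to a cohort
#'
#' For every row (all visits, not just baseline), evaluates the likelihood
#' of the subject's score profile at each stage `m = 0..M` of the model's
#' maximum-likelihood ordering — post-event densities for the first `m`
#' events, pre-event for the rest, accumulated in log space — and assigns
#' the argmax stage. Ties break toward the lowest stage, so a subject with
#' every score missing (whose stage terms all cancel to the same value)
#' stages at 0 and is flagged.
#'
#' @param model An `ebm_fit` (fresh or restored via [read_model()]).
#' @param cohort A cohort tibble whose biomarker columns match the model's
#'   (any column order; extra or missing columns are an error).
#' @return A tibble: `subject_id`, `visit`, `label`, `stage`,
#'   `max_log_likelihood`, `all_missing`.
#' @export
stage_cohort <- function(model, cohort) {
  stopifnot(inherits(model, "ebm_fit"))
  bm <- model$biomarkers
  have <- cohort_biomarkers(cohort)
  missing_cols <- setdiff(bm, have)
  extra_cols <- setdiff(have, bm)
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    stop("cohort biomarkers do not match model",
         if (length(missing_cols)) paste0("; missing: ",
                                          paste(missing_cols, collapse = ", ")),
         if (length(extra_cols)) paste0("; extra: ",
                                        paste(extra_cols, collapse = ", ")),
         call. = FALSE)
  }

  probs <- event_probability_matrix(model$mixtures, cohort)
  terms <- subject_stage_logliks(log(probs$p_pre), log(probs$p_post),
                                 model$ml_order)
  stage <- apply(terms, 1, which.max) - 1L   # which.max takes first maximum
  best <- terms[cbind(seq_len(nrow(terms)), stage + 1L)]
  x <- score_matrix(cohort, bm)

  tibble::tibble(
    subject_id = cohort$subject_id,
    visit = cohort$visit,
    label = cohort$label,
    stage = as.integer(stage),
    max_log_likelihood = best,
    all_missing = rowSums(is.finite(x)) == 0
  )
}

#' Stage histogram per diagnostic group
#'
#' Counts of assigned stages 0..M per label group, including empty bins,
#' ready for plotting or tabulation.
#'
#' @param stages Output of [stage_cohort()].
#' @param m Number of events (defaults to the maximum stage present).
#' @return Tibble with `label`, `stage`, `n`.
#' @export
stage_histogram <- function(stages, m = max(stages$stage)) {
  tidyr::crossing(label = factor(c("control", "patient"),
                                 levels = c("control", "patient")),
                  stage = 0:m) |>
    dplyr::left_join(
      dplyr::count(stages, .data$label, .data$stage),
      by = c("label", "stage")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Positional-uncertainty stage tolerance from a positional variance matrix
#'
#' The default tolerance used by [longitudinal_consistency()]: the standard
#' deviation of each event's position distribution, averaged over events
#' and rounded to an integer number of positions.
#'
#' @param pvd `M x M` positional variance matrix.
#' @return Non-negative integer tolerance.
#' @export
stage_tolerance <- function(pvd) {
  pos <- seq_len(ncol(pvd))
  mean_pos <- as.numeric(pvd %*% pos)
  sd_pos <- sqrt(pmax(as.numeric(pvd %*% pos^2) - mean_pos^2, 0))
  as.integer(round(mean(sd_pos)))
}

#' Longitudinal self-consistency of model staging
#'
#' A progressive disease should not move subjects to earlier stages at
#' later visits. For every within-subject ordered visit pair (v1 < v2) —
#' all pairs, not only adjacent ones — the pair is consistent when
#' `stage(v2) >= stage(v1) - tolerance`, the tolerance (in positions)
#' reflecting how uncertain the ordering itself is. With `tolerance = 0`
#' this is strict non-decrease.
#'
#' @param stages Output of [stage_cohort()] (all visits).
#' @param pvd Positional variance matrix used to derive the default
#'   tolerance via [stage_tolerance()]; ignored when `tolerance` is given.
#' @param tolerance Optional explicit non-negative integer tolerance.
#' @return One-row tibble: `n_pairs`, `n_consistent`, `proportion`,
#'   `tolerance`.
#' @export
longitudinal_consistency <- function(stages, pvd = NULL, tolerance = NULL) {
  if (is.null(tolerance)) {
    if (is.null(pvd)) {
      stop("supply either a positional variance matrix or a tolerance",
           call. = FALSE)
    }
    tolerance <- stage_tolerance(pvd)
  }
  stopifnot(tolerance >= 0)

  pairs <- stages |>
    dplyr::select("subject_id", "visit", "stage") |>
    dplyr::inner_join(
      stages |> dplyr::select("subject_id", visit2 = "visit", stage2 = "stage"),
      by = "subject_id", relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$visit < .data$visit2)

  if (nrow(pairs) == 0) {
    stop("no subject has more than one visit", call. = FALSE)
  }
  consistent <- pairs$stage2 >= pairs$stage - tolerance
  tibble::tibble(
    n_pairs = nrow(pairs),
    n_consistent = sum(consistent),
    proportion = mean(consistent),
    tolerance = as.integer(tolerance)
  )
}

#' Bootstrap cross-validation of the full model
#'
#' Re-estimates the full model (mixtures and maximum-likelihood ordering)
#' on bootstrap resamples of the baseline cohort, drawn with replacement
#' within each label group so both groups keep their size. The replicate
#' orderings are aggregated into a positional frequency matrix aligned to
#' the original ML ordering. Bootstrap positional variance tends to exceed
#' the MCMC posterior's — it is the conservative uncertainty estimate.
#'
#' A replicate that leaves some biomarker with fewer than 2 non-missing
#' controls or patients is redrawn (up to 10 times, then an error).
#'
#' @inheritParams fit_ebm
#' @param n_boot Number of bootstrap replicates.
#' @param reference_order Permutation to align rows to; defaults to the ML
#'   ordering of a fit on the full baseline data with the same settings.
#' @return List of class `ebm_bootstrap`: `pvd`, `orders` (`n_boot x M`),
#'   `reference_order`, `n_boot`.
#' @export
bootstrap_model <- function(cohort, n_boot = 100,
                            mixture = c("kde", "gaussian", "gmm"),
                            n_starts = 16, include_controls = TRUE,
                            seed = 1, reference_order = NULL) {
  mixture <- match.arg(mixture)
  if (mixture == "gmm") mixture <- "gaussian"
  stopifnot(n_boot >= 1)
  bm <- cohort_biomarkers(cohort)
  base <- baseline_rows(cohort)

  if (is.null(reference_order)) {
    ref_fit <- fit_ebm(cohort, mixture = mixture, n_starts = n_starts,
                       mcmc_samples = 0, include_controls = include_controls,
                       seed = seed)
    reference_order <- ref_fit$ml_order
  }
  reference_order <- check_permutation(reference_order, length(bm))

  ctl <- which(base$label == "control")
  pat <- which(base$label == "patient")
  orders <- matrix(NA_integer_, n_boot, length(bm))

  for (b in seq_len(n_boot)) {
    rep_base <- NULL
    for (try in 0:10) {
      idx <- withr::with_seed(seed + 1000L * b + try, {
        c(sample(ctl, length(ctl), replace = TRUE),
          sample(pat, length(pat), replace = TRUE))
      })
      cand <- new_ebm_cohort(base[idx, ], bm)
      if (replicate_viable(cand, bm)) {
        rep_base <- cand
        break
      }
    }
    if (is.null(rep_base)) {
      stop("bootstrap replicate ", b, " could not reach 2 usable controls ",
           "and patients per biomarker after 10 redraws", call. = FALSE)
    }
    mixtures <- fit_mixtures(rep_base, mixture)
    lik_rows <- if (include_controls) rep_base else
      rep_base[rep_base$label == "patient", ]
    probs <- event_probability_matrix(mixtures, lik_rows)
    orders[b, ] <- as.integer(
      greedy_ascent(probs, n_starts = n_starts, seed = seed + b)
    )
  }

  structure(
    list(
      pvd = positional_variance(orders, reference_order, event_names = bm),
      orders = orders,
      reference_order = reference_order,
      n_boot = n_boot
    ),
    class = "ebm_bootstrap"
  )
}

# >= 2 non-missing values per group per marker, and non-constant pooled data
replicate_viable <- function(base, bm) {
  x <- score_matrix(base, bm)
  pat <- base$label == "patient"
  for (i in seq_along(bm)) {
    ok <- is.finite(x[, i])
    if (sum(ok & pat) < 2 || sum(ok & !pat) < 2) return(FALSE)
    if (stats::sd(x[ok, i]) == 0) return(FALSE)
  }
  TRUE
}
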