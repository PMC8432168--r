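#' Fit an event-based model to a cohort
#'
#' The full pipeline: per-biomarker two-component mixtures are fit on
#' baseline rows using the diagnostic labels; event probabilities are then
#' evaluated for all baseline subjects (controls included — once the
#' mixtures are fit the model needs no labels, and controls populate the
#' early stages); greedy ascent finds the maximum-likelihood ordering;
#' Metropolis MCMC initialised there characterises posterior uncertainty as
#' a positional variance matrix.
#'
#' @param cohort A cohort tibble (see [as_ebm_cohort()] / [read_cohort()]).
#' @param mixture `"kde"` (nonparametric, default) or `"gaussian"`
#'   (`"gmm"` accepted as an alias).
#' @param n_starts Greedy-ascent restarts.
#' @param mcmc_samples Post-burn-in MCMC draws; 0 skips MCMC (the
#'   positional variance matrix is then the point-mass of the ML ordering).
#' @param burn_in MCMC burn-in iterations.
#' @param include_controls Include control subjects in the sequence
#'   likelihood (default TRUE).
#' @param seed Integer seed controlling search and MCMC.
#' @return An object of class `ebm_fit`: mixtures, `ml_order`, `pvd`,
#'   MCMC samples, and settings. Methods: [tidy()], [glance()],
#'   [autoplot()][ggplot2::autoplot], `print()`.
#' @examples
#' cohort <- simulate_cohort(m = 4, n_patients = 40, n_controls = 20,
#'                           shape = "gaussian", seed = 1)
#' fit <- fit_ebm(cohort, mcmc_samples = 500, burn_in = 100, seed = 1)
#' tidy(fit)
#' @export
fit_ebm <- function(cohort, mixture = c("kde", "gaussian", "gmm"),
                    n_starts = 16, mcmc_samples = 10000, burn_in = 1000,
                    include_controls = TRUE, seed = 1) {
  mixture <- match.arg(mixture)
  if (mixture == "gmm") mixture <- "gaussian"
  bm <- cohort_biomarkers(cohort)
  base <- baseline_rows(cohort)
  if (!any(base$label == "control") || !any(base$label == "patient")) {
    stop("cohort needs baseline rows for both controls and patients",
         call. = FALSE)
  }

  mixtures <- fit_mixtures(base, mixture)
  lik_rows <- if (include_controls) base else base[base$label == "patient", ]
  probs <- event_probability_matrix(mixtures, lik_rows)

  ml <- greedy_ascent(probs, n_starts = n_starts, seed = seed)
  ml_order <- as.integer(ml)

  if (mcmc_samples > 0) {
    samples <- mcmc_sample(probs, ml_order, n_samples = mcmc_samples,
                           burn_in = burn_in, seed = seed)
    pvd <- positional_variance(samples, ml_order, event_names = bm)
  } else {
    samples <- NULL
    pvd <- positional_variance(matrix(ml_order, 1), ml_order,
                               event_names = bm)
  }

  structure(
    list(
      biomarkers = bm,
      mixture_kind = mixture,
      mixtures = mixtures,
      ml_order = ml_order,
      ml_log_likelihood = attr(ml, "log_likelihood"),
      pvd = pvd,
      samples = samples,
      bootstrap = NULL,
      settings = list(n_starts = n_starts, mcmc_samples = mcmc_samples,
                      burn_in = burn_in, include_controls = include_controls,
                      seed = seed),
      n_fit = nrow(base)
    ),
    class = "ebm_fit"
  )
}

fit_mixtures <- function(base, mixture) {
  bm <- cohort_biomarkers(base)
  fits <- vector("list", length(bm))
  names(fits) <- bm
  for (i in seq_along(bm)) {
    fits[[i]] <- tryCatch(
      if (mixture == "kde") {
        fit_kde_mixture(base[[bm[i]]], base$label)
      } else {
        fit_gaussian_mixture(base[[bm[i]]], base$label)
      },
      error = function(e) {
        stop("mixture fit failed for biomarker '", bm[i], "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  fits
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat(sprintf("<ebm_fit: %d events, %s mixtures, fit on %d baseline rows>\n",
              length(x$biomarkers), x$mixture_kind, x$n_fit))
  cat("Maximum-likelihood ordering:\n")
  cat(paste(sprintf("  %2d. %s", seq_along(x$ml_order),
                    x$biomarkers[x$ml_order]), collapse = "\n"), "\n")
  cat(sprintf("log-likelihood %.3f", x$ml_log_likelihood))
  if (!is.null(x$samples)) {
    cat(sprintf("; MCMC %d samples, acceptance %.2f",
                x$samples$settings$n_samples, x$samples$accept_rate))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an event-based model fit
#'
#' One row per event (biomarker), in maximum-likelihood order, with the
#' posterior mean and standard deviation of its position and the mixture
#' weight of its post-event component.
#'
#' @param x An `ebm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `event`, `ml_position`, `mean_position`,
#'   `sd_position`, `mixture_weight`.
#' @method tidy ebm_fit
#' @export
tidy.ebm_fit <- function(x, ...) {
  m <- length(x$biomarkers)
  pos <- seq_len(m)
  mean_pos <- as.numeric(x$pvd %*% pos)
  sd_pos <- sqrt(as.numeric(x$pvd %*% pos^2) - mean_pos^2)
  tibble::tibble(
    event = x$biomarkers[x$ml_order],
    ml_position = pos,
    mean_position = mean_pos,
    sd_position = pmax(sd_pos, 0),
    mixture_weight = purrr::map_dbl(x$mixtures[x$ml_order], "w")
  )
}

#' Glance at an event-based model fit
#'
#' @inheritParams tidy.ebm_fit
#' @return One-row tibble: event count, fit size, mixture kind, ML
#'   log-likelihood, MCMC settings and acceptance rate, mean positional
#'   entropy.
#' @method glance ebm_fit
#' @export
glance.ebm_fit <- function(x, ...) {
  tibble::tibble(
    n_events = length(x$biomarkers),
    n_fit = x$n_fit,
    mixture = x$mixture_kind,
    log_likelihood = x$ml_log_likelihood,
    mcmc_samples = x$settings$mcmc_samples,
    accept_rate = if (is.null(x$samples)) NA_real_ else x$samples$accept_rate,
    positional_entropy = positional_entropy(x$pvd)
  )
}

serialize_mixture <- function(mx) {
  out <- list(kind = mx$kind, w = mx$w, direction = mx$direction, n = mx$n)
  if (mx$kind == "gaussian") {
    out$pre <- list(mean = mx$pre$mean, sd = mx$pre$sd)
    out$post <- list(mean = mx$post$mean, sd = mx$post$sd)
  } else {
    out$h <- mx$h
    out$pre <- list(support = mx$pre$support, weights = mx$pre$weights)
    out$post <- list(support = mx$post$support, weights = mx$post$weights)
  }
  out$diagnostics <- list(nll = mx$diagnostics$nll,
                          iterations = mx$diagnostics$iterations,
                          converged = mx$diagnostics$converged)
  out
}

deserialize_mixture <- function(obj) {
  comp <- function(c) {
    if (obj$kind == "gaussian") {
      list(mean = c$mean, sd = c$sd)
    } else {
      list(support = as.numeric(c$support), weights = as.numeric(c$weights))
    }
  }
  new_ebm_mixture(
    kind = obj$kind, w = obj$w,
    pre = comp(obj$pre), post = comp(obj$post),
    h = obj$h, direction = obj$direction,
    diagnostics = obj$diagnostics, n = obj$n
  )
}

#' Serialize a fitted model to JSON
#'
#' Writes everything staging needs (mixture parameters, ML ordering,
#' positional variance, settings) as one JSON document with full float
#' precision. MCMC sample traces are not stored. [read_model()] restores an
#' `ebm_fit` whose staging output is identical to the original's.
#'
#' @param fit An `ebm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "ebm_fit"))
  doc <- list(
    biomarkers = fit$biomarkers,
    mixture_kind = fit$mixture_kind,
    mixtures = purrr::map(fit$mixtures, serialize_mixture),
    ml_order = fit$ml_order,
    ml_log_likelihood = fit$ml_log_likelihood,
    pvd = unname(apply(fit$pvd, 1, identity, simplify = FALSE)),
    pvd_rownames = rownames(fit$pvd),
    settings = fit$settings,
    n_fit = fit$n_fit
  )
  if (!is.null(fit$bootstrap)) {
    doc$bootstrap <- list(
      pvd = unname(apply(fit$bootstrap$pvd, 1, identity, simplify = FALSE)),
      n_boot = fit$bootstrap$n_boot
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path Path written by [write_model()].
#' @return An `ebm_fit` (without MCMC sample traces).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  pvd <- do.call(rbind, lapply(doc$pvd, as.numeric))
  rownames(pvd) <- doc$pvd_rownames
  colnames(pvd) <- seq_len(ncol(pvd))
  boot <- NULL
  if (!is.null(doc$bootstrap)) {
    bpvd <- do.call(rbind, lapply(doc$bootstrap$pvd, as.numeric))
    rownames(bpvd) <- doc$pvd_rownames
    colnames(bpvd) <- seq_len(ncol(bpvd))
    boot <- list(pvd = bpvd, n_boot = doc$bootstrap$n_boot)
  }
  structure(
    list(
      biomarkers = as.character(doc$biomarkers),
      mixture_kind = doc$mixture_kind,
      mixtures = purrr::map(doc$mixtures, deserialize_mixture) |>
        stats::setNames(as.character(doc$biomarkers)),
      ml_order = as.integer(doc$ml_order),
      ml_log_likelihood = doc$ml_log_likelihood,
      pvd = pvd,
      samples = NULL,
      bootstrap = boot,
      settings = doc$settings,
      n_fit = doc$n_fit
    ),
    class = "ebm_fit"
  )
}
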