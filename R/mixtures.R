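#' Scott's normal reference bandwidth
#'
#' Bandwidth for a univariate Gaussian-kernel density estimate,
#' `h = sd(x) * n^(-1/5)` with the sample (n-1) standard deviation.
#' For mixture fitting it is computed once on the pooled control + patient
#' values, so both components share one bandwidth.
#'
#' @param values Numeric vector; missing values are dropped.
#' @return Positive bandwidth.
#' @examples
#' scott_bandwidth(rnorm(100))
#' @export
scott_bandwidth <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2) {
    stop("need at least 2 finite values for a bandwidth", call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) {
    stop("all values identical: zero-variance data has no usable bandwidth",
         call. = FALSE)
  }
  s * length(x)^(-1 / 5)
}

DENSITY_FLOOR <- 1e-300

# weighted Gaussian-kernel density estimate evaluated at x:
# f(x) = sum_s w_s * dnorm(x, support_s, h), weights sum to 1
weighted_kde_density <- function(x, support, weights, h) {
  k <- stats::dnorm(outer(x, support, "-"), sd = h)
  as.numeric(k %*% weights)
}

component_density <- function(comp, x, kind, h = NULL) {
  if (kind == "gaussian") {
    stats::dnorm(x, mean = comp$mean, sd = comp$sd)
  } else {
    weighted_kde_density(x, comp$support, comp$weights, h)
  }
}

new_ebm_mixture <- function(kind, w, pre, post, h = NULL, direction,
                            diagnostics, n) {
  structure(
    list(kind = kind, w = w, pre = pre, post = post, h = h,
         direction = direction, diagnostics = diagnostics, n = n),
    class = "ebm_mixture"
  )
}

#' @export
print.ebm_mixture <- function(x, ...) {
  cat(sprintf(
    "<ebm_mixture: %s>  w(post) = %.3f  direction = %s  NLL = %.4f (%s)\n",
    x$kind, x$w, x$direction, x$diagnostics$nll,
    if (isTRUE(x$diagnostics$converged)) "converged" else "not converged"
  ))
  invisible(x)
}

check_mixture_groups <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values)
  lab <- as_patient_flag(labels)
  if (sum(ok & !lab) < 2 || sum(ok & lab) < 2) {
    stop("mixture fitting needs >= 2 non-missing controls and >= 2 ",
         "non-missing patients", call. = FALSE)
  }
  list(x = values[ok], patient = lab[ok])
}

# accepts logical patient flags, the cohort label factor, or strings
as_patient_flag <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) %in% c("patient", "TRUE")
}

#' Infer a biomarker's direction of abnormality
#'
#' Test batteries mix scores where lower is worse (accuracy counts) with
#' scores where higher is worse (timed tasks). The direction is taken from
#' the group medians: `lower_is_abnormal` if the patient median is below the
#' control median, `higher_is_abnormal` if above, `undetermined` (with a
#' warning) on a tie. Used for diagnostics and for the post-fit
#' component-order check of the KDE mixture.
#'
#' @param values Numeric scores.
#' @param labels Control/patient labels (logical patient flags or the
#'   cohort `label` factor).
#' @return One of `"lower_is_abnormal"`, `"higher_is_abnormal"`,
#'   `"undetermined"`.
#' @export
infer_direction <- function(values, labels) {
  lab <- as_patient_flag(labels)
  ok <- is.finite(values)
  med_c <- stats::median(values[ok & !lab])
  med_p <- stats::median(values[ok & lab])
  if (is.na(med_c) || is.na(med_p)) {
    stop("both groups must contain non-missing values", call. = FALSE)
  }
  if (med_p < med_c) {
    "lower_is_abnormal"
  } else if (med_p > med_c) {
    "higher_is_abnormal"
  } else {
    warning("patient and control medians are equal; direction undetermined",
            call. = FALSE)
    "undetermined"
  }
}

#' Fit a two-component Gaussian mixture for one biomarker
#'
#' The classic event-probability model: a pre-event (control-like) and a
#' post-event (patient-like) Gaussian plus a mixture weight. Components are
#' initialised from the diagnostic labels, the weight starts at 0.5, and the
#' negative log-likelihood is minimised by box-constrained quasi-Newton
#' optimisation with the weight bounded to [0.1, 0.9] so that neither
#' component vanishes. Component standard deviations are bounded below by
#' 1e-3 times the pooled SD to avoid singularities on discrete scores.
#'
#' @inheritParams infer_direction
#' @return An `ebm_mixture` object with `kind = "gaussian"`.
#' @export
fit_gaussian_mixture <- function(values, labels) {
  g <- check_mixture_groups(values, labels)
  x <- g$x
  pat <- g$patient
  sd_floor <- 1e-3 * stats::sd(x)
  if (sd_floor == 0) {
    stop("all values identical: cannot fit a mixture", call. = FALSE)
  }

  init <- c(
    mu_pre = mean(x[!pat]),
    sd_pre = max(stats::sd(x[!pat]), sd_floor, na.rm = TRUE),
    mu_post = mean(x[pat]),
    sd_post = max(stats::sd(x[pat]), sd_floor, na.rm = TRUE),
    w = 0.5
  )
  nll <- function(par) {
    d <- (1 - par[5]) * stats::dnorm(x, par[1], par[2]) +
      par[5] * stats::dnorm(x, par[3], par[4])
    -sum(log(pmax(d, DENSITY_FLOOR)))
  }
  opt <- stats::optim(
    init, nll, method = "L-BFGS-B",
    lower = c(-Inf, sd_floor, -Inf, sd_floor, 0.1),
    upper = c(Inf, Inf, Inf, Inf, 0.9),
    control = list(maxit = 200)
  )
  if (opt$convergence %in% c(51, 52) && !is.finite(opt$value)) {
    stop("Gaussian mixture optimisation failed: ", opt$message, call. = FALSE)
  }
  p <- opt$par
  new_ebm_mixture(
    kind = "gaussian",
    w = min(max(p[5], 0.1), 0.9),
    pre = list(mean = unname(p[1]), sd = unname(p[2])),
    post = list(mean = unname(p[3]), sd = unname(p[4])),
    direction = infer_direction(values, labels),
    diagnostics = list(
      nll = opt$value,
      iterations = unname(opt$counts[1]),
      converged = opt$convergence == 0,
      message = opt$message
    ),
    n = length(x)
  )
}

#' Fit a two-component kernel-density mixture for one biomarker
#'
#' The nonparametric analogue of [fit_gaussian_mixture()] for scores with
#' ceiling/floor effects or other strong non-Gaussianity. Both components
#' are Gaussian-kernel density estimates over all observed values, sharing
#' one Scott's-rule bandwidth computed on the pooled groups; what differs
#' between components is the per-point kernel weights. Fitting alternates
#' EM-style:
#' responsibilities are initialised hard from the diagnostic labels with
#' mixture weight 0.5; the E-step computes each point's posterior
#' probability of being post-event; the M-step refits each component as a
#' responsibility-weighted KDE (kernel weights normalised to sum 1) and sets
#' the mixture weight to the mean responsibility, clipped to [0.1, 0.9].
#' Iteration stops when the total negative log-likelihood changes by less
#' than `1e-6 * n` or after `max_iter` sweeps (then `converged = FALSE` with
#' a warning). After convergence, if the post-event component's weighted
#' mean sits on the normal side of the pre-event mean (per
#' [infer_direction()]), the component roles are swapped.
#'
#' @inheritParams infer_direction
#' @param max_iter Maximum EM sweeps.
#' @return An `ebm_mixture` object with `kind = "kde"`.
#' @export
fit_kde_mixture <- function(values, labels, max_iter = 500) {
  g <- check_mixture_groups(values, labels)
  x <- g$x
  pat <- g$patient
  n <- length(x)
  h <- scott_bandwidth(x)

  # precompute the n x n kernel matrix once; columns = support points
  K <- stats::dnorm(outer(x, x, "-"), sd = h)

  # Classification EM with hard assignments. Soft kernel weights let each
  # mis-assigned point seed the wrong component with its own kernel, which
  # self-reinforces; hard assignment keeps the component densities disjoint
  # in their support weights and lets them specialise. Controls are anchored
  # to the pre-event component throughout (they define normality); patients
  # are reassigned each sweep by comparing the two component densities on
  # equal footing, so the larger group cannot absorb the other through the
  # mixture weight alone.
  direction <- infer_direction(values, labels)
  # patients ordered from most to least abnormal (per the group medians)
  pat_idx <- which(pat)
  pat_ord <- pat_idx[order(x[pat_idx],
                           decreasing = direction != "lower_is_abnormal")]

  r <- as.numeric(pat)        # hard post-event assignment, init from labels
  w <- 0.5
  nll_path <- numeric(0)
  converged <- FALSE
  iter <- 0

  repeat {
    iter <- iter + 1
    # M-step: each component is a KDE over its currently assigned points
    # (kernel weights normalised to sum 1); mixture weight = assigned
    # fraction clipped to [0.1, 0.9]
    w_post <- r / sum(r)
    w_pre <- (1 - r) / sum(1 - r)
    f_post <- as.numeric(K %*% w_post)
    f_pre <- as.numeric(K %*% w_pre)
    w <- min(max(mean(r), 0.1), 0.9)

    mix <- w * f_post + (1 - w) * f_pre
    nll_path <- c(nll_path, -sum(log(pmax(mix, DENSITY_FLOOR))))

    # E-step: reassign patients to the component with the higher density,
    # keeping the post-event support contiguous in score space — the block
    # of patients running from the abnormal extreme up to the first point
    # where the pre-event density wins. Controls stay pre-event throughout:
    # they define normality, and unconstrained reassignment lets a
    # component capture an interior slice of the normal mode instead of the
    # abnormal tail.
    better <- f_post > f_pre
    r_new <- numeric(n)
    if (direction == "undetermined") {
      r_new[pat_idx] <- as.numeric(better[pat_idx])
    } else {
      keep <- cumprod(as.numeric(better[pat_ord]))  # prefix while post wins
      r_new[pat_ord] <- keep
    }
    if (sum(r_new) == 0) {
      # post-event component would vanish; keep the last viable assignment
      converged <- TRUE
      break
    }
    if (identical(r_new, r)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    r <- r_new
  }
  if (!converged) {
    warning("KDE mixture did not converge in ", max_iter,
            " iterations; returning best fit", call. = FALSE)
  }

  direction <- infer_direction(values, labels)
  pre_w <- (1 - r) / sum(1 - r)
  post_w <- r / sum(r)

  # component-order guard: post-event mass must sit on the abnormal side
  pre_mean <- sum(pre_w * x)
  post_mean <- sum(post_w * x)
  flipped <- (direction == "lower_is_abnormal" && post_mean > pre_mean) ||
    (direction == "higher_is_abnormal" && post_mean < pre_mean)
  if (flipped) {
    tmp <- pre_w
    pre_w <- post_w
    post_w <- tmp
    w <- min(max(1 - w, 0.1), 0.9)
  }

  new_ebm_mixture(
    kind = "kde",
    w = w,
    pre = list(support = x, weights = pre_w),
    post = list(support = x, weights = post_w),
    h = h,
    direction = direction,
    diagnostics = list(
      nll = nll_path[length(nll_path)],
      iterations = iter,
      converged = converged,
      nll_path = nll_path,
      swapped = flipped
    ),
    n = n
  )
}

#' Evaluate pre- and post-event densities at observed scores
#'
#' Returns the two component densities `Pr(x | no event)` and
#' `Pr(x | event)` of a fitted mixture at each score. A missing score
#' returns (1, 1): it then contributes the same factor to every stage term
#' of the sequence likelihood and cancels. Densities are floored at 1e-300
#' so likelihood ratios stay defined.
#'
#' @param fit An `ebm_mixture`.
#' @param x Numeric scores; `NA` allowed.
#' @return A tibble with columns `p_pre` and `p_post`, one row per score.
#' @export
event_probabilities <- function(fit, x) {
  stopifnot(inherits(fit, "ebm_mixture"))
  p_pre <- rep(1, length(x))
  p_post <- rep(1, length(x))
  ok <- is.finite(x)
  if (any(ok)) {
    p_pre[ok] <- pmax(component_density(fit$pre, x[ok], fit$kind, fit$h),
                      DENSITY_FLOOR)
    p_post[ok] <- pmax(component_density(fit$post, x[ok], fit$kind, fit$h),
                       DENSITY_FLOOR)
  }
  tibble::tibble(p_pre = p_pre, p_post = p_post)
}
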