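test_that("Scott's rule matches its closed form and scales with the data", {
  x <- withr::with_seed(1, rnorm(32))
  x <- as.numeric(scale(x))          # sample sd exactly 1
  expect_equal(scott_bandwidth(x), 32^(-0.2), tolerance = 1e-12)
  expect_equal(scott_bandwidth(x), 0.5, tolerance = 1e-12)
  expect_equal(scott_bandwidth(2 * x), 2 * scott_bandwidth(x),
               tolerance = 1e-12)
  expect_error(scott_bandwidth(rep(3, 10)), "identical")
  expect_error(scott_bandwidth(c(1, NA, NaN)), "at least 2")
})

test_that("Gaussian mixture recovers well-separated components", {
  fx <- withr::with_seed(2, {
    list(values = c(rnorm(200, 0, 1), rnorm(200, 10, 1)),
         labels = rep(c(FALSE, TRUE), each = 200))
  })
  fit <- fit_gaussian_mixture(fx$values, fx$labels)
  expect_lt(abs(fit$pre$mean - 0), 0.5)
  expect_lt(abs(fit$post$mean - 10), 0.5)
  expect_lt(abs(fit$w - 0.5), 0.1)
  expect_true(fit$diagnostics$converged)
})

test_that("Gaussian mixture weight stays in [0.1, 0.9] on overlapping data", {
  x <- withr::with_seed(3, rnorm(120))
  lb <- rep(c(FALSE, TRUE), 60)
  fit <- fit_gaussian_mixture(x, lb)
  expect_gte(fit$w, 0.1)
  expect_lte(fit$w, 0.9)
  expect_gt(fit$pre$sd, 0)
  expect_gt(fit$post$sd, 0)
})

test_that("degenerate patient group keeps a positive post-event variance", {
  x <- c(withr::with_seed(4, rnorm(50)), 8, 8.0001)
  lb <- rep(c(FALSE, TRUE), c(50, 2))
  fit <- fit_gaussian_mixture(x, lb)
  expect_gte(fit$post$sd, 1e-3 * sd(x) - 1e-12)
  expect_true(all(is.finite(unlist(fit$pre))))
})

test_that("KDE mixture puts the post-event mode at the floor pile", {
  fx <- withr::with_seed(5, {
    xc <- pmin(rnorm(100, 28, 1.5), 30)
    xp <- pmax(rnorm(100, 1.5, 2.5), 0)
    xp[1:60] <- 0                      # 60% of patients at the floor
    list(values = c(xc, xp), labels = rep(c(FALSE, TRUE), each = 100))
  })
  fit <- fit_kde_mixture(fx$values, fx$labels)
  grid <- seq(0, 30, by = 0.1)
  f_post <- event_probabilities(fit, grid)$p_post
  # density at the floor is essentially the post-event maximum
  expect_gte(f_post[1], 0.9 * max(f_post))
  p0 <- event_probabilities(fit, 0)
  expect_gt(p0$p_post, p0$p_pre)
})

test_that("KDE and Gaussian mixtures agree on easy Gaussian data", {
  fx <- sep_fixture(seed = 6, n = 300, delta = 4)
  kf <- fit_kde_mixture(fx$values, fx$labels)
  gf <- fit_gaussian_mixture(fx$values, fx$labels)
  rk <- posterior_post(kf, fx$values)
  rg <- posterior_post(gf, fx$values)
  expect_gte(mean(sign(rk - 0.5) == sign(rg - 0.5)), 0.9)
})

test_that("densities are finite, floored and defined far outside the data", {
  fx <- sep_fixture(seed = 7)
  for (fit in list(fit_kde_mixture(fx$values, fx$labels),
                   fit_gaussian_mixture(fx$values, fx$labels))) {
    p <- event_probabilities(fit, c(-1e4, 1e4))
    expect_true(all(is.finite(unlist(p))))
    expect_true(all(unlist(p) > 0))
    ratio <- p$p_post / p$p_pre
    expect_true(all(is.finite(ratio)))
  }
})

test_that("event probabilities at group medians favour the right component", {
  fx <- sep_fixture(seed = 8)
  fit <- fit_kde_mixture(fx$values, fx$labels)
  med_c <- median(fx$values[!fx$labels])
  med_p <- median(fx$values[fx$labels])
  pc <- event_probabilities(fit, med_c)
  pp <- event_probabilities(fit, med_p)
  expect_gt(pc$p_pre, pc$p_post)
  expect_gt(pp$p_post, pp$p_pre)
  expect_equal(event_probabilities(fit, NA_real_),
               tibble::tibble(p_pre = 1, p_post = 1))
})

test_that("abnormality direction follows the group medians", {
  expect_equal(infer_direction(c(28, 29, 30, 15, 18, 20),
                               rep(c(FALSE, TRUE), each = 3)),
               "lower_is_abnormal")
  expect_equal(infer_direction(c(20, 25, 30, 90, 120, 200),
                               rep(c(FALSE, TRUE), each = 3)),
               "higher_is_abnormal")
  expect_warning(
    dir <- infer_direction(c(1, 2, 3, 1, 2, 3), rep(c(FALSE, TRUE), each = 3)),
    "undetermined"
  )
  expect_equal(dir, "undetermined")
})

test_that("component densities integrate to one", {
  fx <- sep_fixture(seed = 9)
  kf <- fit_kde_mixture(fx$values, fx$labels)
  gf <- fit_gaussian_mixture(fx$values, fx$labels)

  trapz <- function(f, grid) sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
  g_kde <- seq(min(fx$values) - 3 * kf$h, max(fx$values) + 3 * kf$h,
               length.out = 4000)
  for (comp in c("pre", "post")) {
    fk <- event_probabilities(kf, g_kde)[[paste0("p_", comp)]]
    expect_equal(trapz(fk, g_kde), 1, tolerance = 1e-3)
  }
  sd_max <- max(gf$pre$sd, gf$post$sd)
  g_g <- seq(min(fx$values) - 6 * sd_max, max(fx$values) + 6 * sd_max,
             length.out = 4000)
  for (comp in c("pre", "post")) {
    fg <- event_probabilities(gf, g_g)[[paste0("p_", comp)]]
    expect_equal(trapz(fg, g_g), 1, tolerance = 1e-3)
  }
})

test_that("mixture fits are deterministic and EM likelihood is monotone", {
  withr::with_seed(10, {
    for (k in 1:10) {
      delta <- sample(1:5, 1)
      x <- c(rnorm(40), rnorm(60, delta))
      lb <- rep(c(FALSE, TRUE), c(40, 60))
      a <- fit_kde_mixture(x, lb)
      b <- fit_kde_mixture(x, lb)
      expect_identical(a, b)
      expect_gte(a$w, 0.1)
      expect_lte(a$w, 0.9)
      inc <- diff(a$diagnostics$nll_path)
      if (length(inc) > 0) expect_lte(max(inc), 1e-9)
    }
  })
  fx <- sep_fixture(seed = 11)
  expect_identical(fit_gaussian_mixture(fx$values, fx$labels),
                   fit_gaussian_mixture(fx$values, fx$labels))
})

test_that("mixture fitting demands two usable values per group", {
  expect_error(fit_kde_mixture(c(1, 2, 3, NA), c(FALSE, FALSE, TRUE, TRUE)),
               ">= 2")
  expect_error(fit_gaussian_mixture(c(1, 2), c(FALSE, TRUE)), ">= 2")
})
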