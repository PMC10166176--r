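test_that("Kaplan-Meier matches the brute-force product-limit estimator", {
  # censored-only data give the constant curve 1
  d0 <- survival_dataset(rep(12, 5), rep(0, 5))
  km0 <- km_estimate(d0)
  expect_length(km0$times, 0)
  expect_equal(km_survival(km0, c(0, 6, 24)), rep(1, 3))

  # single event among four subjects: S(2) = 0.75
  d1 <- survival_dataset(c(2, 5, 7, 9), c(1, 0, 0, 0))
  km1 <- km_estimate(d1)
  expect_equal(km1$times, 2)
  expect_equal(km1$survival, 0.75)

  # random 200-record dataset, ties and censoring included
  set.seed(7)
  time <- round(stats::rexp(200, 0.05), 1) + 0.1
  event <- stats::rbinom(200, 1, 0.7)
  km <- km_estimate(survival_dataset(time, event))
  oracle <- km_brute_force(time, event)
  expect_equal(km$times, oracle$times)
  expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
})

test_that("exponential MLE equals the events/exposure closed form", {
  d <- survival_dataset(c(1, 2, 3), c(1, 1, 1))
  f <- fit_parametric(d, "exponential")
  expect_equal(exp(unname(f$params)), 0.5, tolerance = 1e-10)
  expect_equal(f$aic, 2 - 2 * f$loglik)

  # with censoring: rate = events / total exposure
  d2 <- survival_dataset(c(4, 8, 10, 2), c(1, 0, 1, 0))
  f2 <- fit_parametric(d2, "exponential")
  expect_equal(exp(unname(f2$params)), 2 / 24, tolerance = 1e-10)
  expect_error(fit_parametric(survival_dataset(c(1, 2), c(0, 0)),
                              "exponential"), "no events")
})

test_that("Weibull fitting recovers the generating parameters", {
  set.seed(11)
  n <- 2000
  t_ev <- stats::rweibull(n, shape = 1.3, scale = 30)
  cens <- stats::qunif(stats::runif(n), 5, 110)  # ~20% censoring
  d <- survival_dataset(pmin(t_ev, cens), as.numeric(t_ev <= cens))
  expect_lt(abs(mean(d$event) - 0.8), 0.05)
  f <- fit_parametric(d, "weibull")
  se <- sqrt(diag(f$covariance))
  expect_lt(abs(f$params[[1]] - log(1.3)) / se[1], 3)
  expect_lt(abs(f$params[[2]] - log(30)) / se[2], 3)
  # the true family beats a misspecified exponential on AIC at this n
  f_exp <- fit_parametric(d, "exponential")
  expect_lt(f$aic, f_exp$aic)
})

test_that("returned optimum dominates randomly perturbed parameters", {
  d <- toy_dataset()
  loglik_at <- function(family, params) {
    # independent right-censored log-likelihood via numerical derivative
    s <- function(t) seqpsm:::surv_from_params(family, params, t)
    h <- 1e-6
    dens <- (s(d$time_months - h) - s(d$time_months + h)) / (2 * h)
    sum(ifelse(d$event == 1, log(pmax(dens, 1e-300)),
               log(pmax(s(d$time_months), 1e-300))))
  }
  set.seed(3)
  for (family in c("exponential", "weibull", "lognormal")) {
    f <- fit_parametric(d, family)
    expect_equal(loglik_at(family, f$params), f$loglik, tolerance = 1e-4)
    for (i in 1:100) {
      pert <- f$params + stats::rnorm(length(f$params), 0, 0.15)
      expect_lte(loglik_at(family, pert), f$loglik + 1e-6)
    }
  }
})

test_that("survival grids agree with numerically integrated hazards", {
  d <- toy_dataset()
  for (family in c("weibull", "gompertz", "loglogistic", "lognormal")) {
    f <- fit_parametric(d, family)
    g <- survival_on_grid(f, 60)
    expect_equal(g[1], 1)
    expect_true(all(diff(g) <= 0))
    expect_true(all(g > 0 & g <= 1))
    s <- function(t) seqpsm:::surv_from_params(family, f$params, t)
    hzd <- function(t) {
      h <- 1e-6
      (s(t - h) - s(t + h)) / (2 * h) / s(t)
    }
    for (t in c(6, 24, 60)) {
      # integrate the hazard piecewise by month for numerical robustness
      cum_h <- sum(vapply(seq_len(t), function(k)
        stats::integrate(hzd, k - 1, k, rel.tol = 1e-10)$value,
        numeric(1)))
      expect_equal(g[t + 1], exp(-cum_h), tolerance = 1e-8)
    }
  }
})

test_that("degenerate and closed-form grids are exact", {
  f0 <- parametric_fit("exponential", log(1e-300))
  expect_equal(survival_on_grid(f0, 24), rep(1, 25))
  f <- parametric_fit("exponential", log(0.1))
  g <- survival_on_grid(f, 24)
  expect_equal(g[13], exp(-1.2), tolerance = 1e-12)
})

test_that("hazard-ratio transform is the pointwise power", {
  g <- exp_grid(0.08, 120)
  expect_identical(apply_hazard_ratio(g, 1), g)
  expect_equal(apply_hazard_ratio(g, 0.5), exp_grid(0.04, 120))
  expect_equal(apply_hazard_ratio(g, 0.47), g ^ 0.47)
  # composition: hr a then hr b == hr a*b
  expect_equal(apply_hazard_ratio(apply_hazard_ratio(g, 0.47), 2),
               apply_hazard_ratio(g, 0.94), tolerance = 1e-12)
  # median of an exponential curve scales by 1/hr: log(2)/0.04 vs log(2)/0.08
  halved <- apply_hazard_ratio(g, 0.5)
  expect_equal(which(halved <= 0.5)[1] - 1, ceiling(log(2) / 0.04))
  expect_equal(2 * (log(2) / 0.08), log(2) / 0.04)
  expect_error(apply_hazard_ratio(g, -1), "positive")
  expect_error(apply_hazard_ratio(g, hazard_ratio(0.5)), NA)
})

test_that("hazard_ratio validates its interval", {
  h <- hazard_ratio(0.47, 0.37, 0.59, "trial")
  expect_equal(h$value, 0.47)
  expect_error(hazard_ratio(-1), "positive")
  expect_error(hazard_ratio(0.47, 0.5, 0.59), "lower95")
})

test_that("scenario fit selection matches an exhaustive RMST comparison", {
  slow <- parametric_fit("exponential", log(0.05), loglik = -10, aic = 22)
  fast <- parametric_fit("exponential", log(0.10), loglik = -11, aic = 24)
  sel <- select_scenario_fits(list(slow, fast), 120)
  expect_identical(sel$best, slow)
  expect_identical(sel$worst, fast)
  expect_identical(sel$base, slow)  # lower AIC

  d <- toy_dataset()
  fits <- lapply(parametric_families(), function(fm) fit_parametric(d, fm))
  sel <- select_scenario_fits(fits, 180)
  rmst <- vapply(fits, function(f) {
    g <- survival_on_grid(f, 180)
    sum(g) - (g[1] + g[181]) / 2
  }, numeric(1))
  expect_identical(sel$best$family, fits[[which.max(rmst)]]$family)
  expect_identical(sel$worst$family, fits[[which.min(rmst)]]$family)
  expect_identical(sel$base$family,
                   fits[[which.min(vapply(fits, `[[`, numeric(1),
                                          "aic"))]]$family)
  expect_error(select_scenario_fits(fits[1], 180), "at least 2")
})

test_that("fits serialize to JSON and back", {
  f <- fit_parametric(toy_dataset(), "weibull")
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  f2 <- read_fit_json(path)
  expect_equal(f2$family, f$family)
  expect_equal(unname(f2$params), unname(f$params))
  expect_equal(f2$covariance, f$covariance, ignore_attr = TRUE)
  expect_equal(f2$aic, f$aic)
})
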