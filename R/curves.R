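#' @importFrom survival Surv survfit
#' @importFrom stats pexp pweibull plnorm qexp qweibull qlnorm rexp runif
NULL

# Family registry: the standard HTA extrapolation suite. Parameters are kept
# on an unconstrained internal scale (log for positive parameters, identity
# otherwise) so that multivariate-normal PSA draws are always valid.
.families <- list(
  exponential = list(
    dist = "exp", pars = "log(rate)", npars = 1L,
    natural = function(p) list(rate = exp(p[1L]))),
  weibull = list(
    dist = "weibull", pars = c("log(shape)", "log(scale)"), npars = 2L,
    natural = function(p) list(shape = exp(p[1L]), scale = exp(p[2L]))),
  gompertz = list(
    dist = "gompertz", pars = c("shape", "log(rate)"), npars = 2L,
    natural = function(p) list(shape = p[1L], rate = exp(p[2L]))),
  loglogistic = list(
    dist = "llogis", pars = c("log(shape)", "log(scale)"), npars = 2L,
    natural = function(p) list(shape = exp(p[1L]), scale = exp(p[2L]))),
  lognormal = list(
    dist = "lnorm", pars = c("meanlog", "log(sdlog)"), npars = 2L,
    natural = function(p) list(meanlog = p[1L], sdlog = exp(p[2L]))),
  generalized_gamma = list(
    dist = "gengamma", pars = c("mu", "log(sigma)", "Q"), npars = 3L,
    natural = function(p) list(mu = p[1L], sigma = exp(p[2L]), Q = p[3L]))
)

#' Supported parametric survival families
#'
#' The six-distribution suite conventionally used for survival extrapolation
#' in health-technology assessment.
#' @return Character vector of family names.
#' @export
parametric_families <- function() names(.families)

.family_info <- function(family) {
  info <- .families[[family]]
  if (is.null(info))
    stop("unknown parametric family '", family, "'; choose one of: ",
         paste(names(.families), collapse = ", "))
  info
}

# S(t) for a family given unconstrained parameters.
surv_from_params <- function(family, params, t) {
  info <- .family_info(family)
  if (length(params) != info$npars)
    stop(family, " expects ", info$npars, " parameters, got ", length(params))
  nat <- info$natural(as.numeric(params))
  s <- switch(family,
    exponential = stats::pexp(t, rate = nat$rate, lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = nat$shape, scale = nat$scale,
                              lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = nat$shape, rate = nat$rate,
                                   lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = nat$shape, scale = nat$scale,
                                    lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = nat$meanlog, sdlog = nat$sdlog,
                              lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = nat$mu, sigma = nat$sigma,
                                            Q = nat$Q, lower.tail = FALSE))
  pmin(pmax(s, 0), 1)
}

# Quantile of S: smallest t with S(t) <= s, given unconstrained parameters.
quantile_from_params <- function(family, params, s) {
  info <- .family_info(family)
  nat <- info$natural(as.numeric(params))
  switch(family,
    exponential = stats::qexp(s, rate = nat$rate, lower.tail = FALSE),
    weibull = stats::qweibull(s, shape = nat$shape, scale = nat$scale,
                              lower.tail = FALSE),
    gompertz = flexsurv::qgompertz(s, shape = nat$shape, rate = nat$rate,
                                   lower.tail = FALSE),
    loglogistic = flexsurv::qllogis(s, shape = nat$shape, scale = nat$scale,
                                    lower.tail = FALSE),
    lognormal = stats::qlnorm(s, meanlog = nat$meanlog, sdlog = nat$sdlog,
                              lower.tail = FALSE),
    generalized_gamma = flexsurv::qgengamma(s, mu = nat$mu, sigma = nat$sigma,
                                            Q = nat$Q, lower.tail = FALSE))
}

#' Construct a fitted parametric survival distribution
#'
#' Normally produced by [fit_parametric()]; the constructor is exported so
#' that probabilistic-sensitivity-analysis draws (new parameter vectors on
#' the unconstrained scale) can be rewrapped for grid evaluation.
#'
#' @param family One of [parametric_families()].
#' @param params Parameter vector on the unconstrained internal scale
#'   (log for positive parameters, identity otherwise).
#' @param covariance Covariance matrix of `params` (symmetric PSD); defaults
#'   to a zero matrix (a point mass).
#' @param loglik,aic,n Fit statistics; `NA` when not applicable.
#' @param label Optional label carried from the fitted dataset.
#' @return An object of class `parametric_fit`.
#' @export
parametric_fit <- function(family, params, covariance = NULL,
                           loglik = NA_real_, aic = NA_real_, n = NA_integer_,
                           label = NULL) {
  info <- .family_info(family)
  params <- as.numeric(params)
  if (length(params) != info$npars)
    stop(family, " expects ", info$npars, " parameters")
  if (is.null(covariance))
    covariance <- matrix(0, info$npars, info$npars)
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == info$npars))
    stop("covariance must be ", info$npars, "x", info$npars)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semidefinite")
  names(params) <- info$pars
  structure(
    list(family = family, params = params, covariance = covariance,
         loglik = loglik, aic = aic, n = n, label = label),
    class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("<parametric_fit: %s%s> loglik = %.3f, AIC = %.3f, n = %s\n",
              x$family,
              if (is.null(x$label)) "" else paste0(" on '", x$label, "'"),
              x$loglik, x$aic, x$n))
  print(x$params)
  invisible(x)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function for one cohort. The step
#' curve changes only at event times; a censored-only dataset yields the
#' constant curve 1.
#'
#' @param data A [survival_dataset()].
#' @return An object of class `step_curve` with fields `times` (distinct
#'   event times), `survival` (estimate just after each event time),
#'   `n_at_risk` (risk-set size at each time) and `label`.
#' @examples
#' d <- survival_dataset(c(2, 5, 5, 8), c(1, 1, 0, 1))
#' km <- km_estimate(d)
#' km$survival
#' @export
km_estimate <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                          data = as.data.frame(data), conf.type = "none")
  keep <- sf$n.event > 0
  structure(
    list(times = sf$time[keep], survival = sf$surv[keep],
         n_at_risk = sf$n.risk[keep], label = attr(data, "label")),
    class = "step_curve")
}

#' Evaluate a Kaplan-Meier step curve
#'
#' @param curve A `step_curve` from [km_estimate()].
#' @param t Times (months) at which to read the estimate.
#' @return Survival probabilities at `t` (right-continuous step function).
#' @export
km_survival <- function(curve, t) {
  stopifnot(inherits(curve, "step_curve"))
  if (length(curve$times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$times)
  c(1, curve$survival)[idx + 1L]
}

#' Fit a parametric survival distribution by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)}.
#' The exponential family uses its closed-form solution (rate =
#' events / total exposure); the other families are fitted numerically via
#' \pkg{flexsurv}, with deterministic fallback starting values and a fixed
#' set of jittered restarts if the default fit fails. Parameters and their
#' covariance (inverse observed information) are reported on the
#' unconstrained internal scale.
#'
#' @param data A [survival_dataset()].
#' @param family One of [parametric_families()].
#' @return A [parametric_fit()].
#' @examples
#' d <- survival_dataset(c(1, 2, 3), c(1, 1, 1))
#' f <- fit_parametric(d, "exponential")
#' exp(f$params)  # rate = 3 events / 6 months = 0.5
#' @export
fit_parametric <- function(data, family) {
  stopifnot(inherits(data, "survival_dataset"))
  info <- .family_info(family)
  d <- sum(data$event)
  if (d < 1L) stop("fit_parametric: no events in '", attr(data, "label"), "'")
  if (info$npars > 1L && d < 2L)
    stop("fit_parametric: ", family, " requires at least 2 events")

  if (family == "exponential") {
    exposure <- sum(data$time_months)
    rate <- d / exposure
    loglik <- d * log(rate) - rate * exposure
    # observed information for log(rate) is d, hence var(log rate) = 1/d
    return(parametric_fit("exponential", log(rate),
                          covariance = matrix(1 / d, 1, 1),
                          loglik = loglik, aic = 2 - 2 * loglik,
                          n = nrow(data), label = attr(data, "label")))
  }

  df <- as.data.frame(data)
  fit1 <- function(inits) {
    flexsurv::flexsurvreg(survival::Surv(time_months, event) ~ 1,
                          data = df, dist = info$dist, inits = inits)
  }
  attempts <- list(NULL)
  # deterministic fallback inits anchored at the exponential-equivalent rate
  rate0 <- d / sum(df$time_months)
  lt <- log(df$time_months[df$event == 1])
  sdlt <- max(stats::sd(lt), 0.1)
  base_inits <- switch(family,
    weibull = c(1, 1 / rate0),
    gompertz = c(1e-3, rate0),
    loglogistic = c(1, 1 / rate0),
    lognormal = c(mean(lt), sdlt),
    generalized_gamma = c(mean(lt), sdlt, 1))
  for (jit in c(1, 0.5, 2))
    attempts <- c(attempts, list(base_inits * jit))
  errors <- character(0)
  for (inits in attempts) {
    fit <- tryCatch(suppressWarnings(fit1(inits)), error = function(e) e)
    if (!inherits(fit, "error")) {
      cov <- fit$cov
      if (is.null(cov)) cov <- matrix(0, info$npars, info$npars)
      cov <- (cov + t(cov)) / 2
      return(parametric_fit(family, fit$res.t[, "est"], covariance = cov,
                            loglik = fit$loglik, aic = stats::AIC(fit),
                            n = nrow(df), label = attr(data, "label")))
    }
    errors <- c(errors, conditionMessage(fit))
  }
  stop("fit_parametric: ", family, " did not converge after ",
       length(attempts), " starts; last error: ", errors[length(errors)])
}

#' Evaluate a fitted distribution on the monthly cycle grid
#'
#' @param fit A [parametric_fit()].
#' @param horizon_cycles Number of monthly cycles (>= 1); the grid has
#'   `horizon_cycles + 1` points at t = 0, 1, ..., horizon months.
#' @return Numeric survival grid with S(0) = 1, nonincreasing, in (0, 1].
#' @export
survival_on_grid <- function(fit, horizon_cycles) {
  stopifnot(inherits(fit, "parametric_fit"))
  horizon_cycles <- as.integer(horizon_cycles)
  if (horizon_cycles < 1L) stop("horizon_cycles must be >= 1")
  s <- surv_from_params(fit$family, fit$params, 0:horizon_cycles)
  s[1L] <- 1
  s <- cummin(s)  # guard against numerical non-monotonicity at machine level
  s
}

#' Hazard ratio with optional 95% confidence interval
#'
#' @param value Positive hazard-ratio point estimate.
#' @param lower95,upper95 Optional positive confidence limits bracketing
#'   `value`; required if the ratio is to be drawn in a PSA.
#' @param source_label Free-text provenance, e.g. the trial or meta-analysis.
#' @return An object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(value, lower95 = NA_real_, upper95 = NA_real_,
                         source_label = "") {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("hazard_ratio: value must be a positive scalar")
  if (!is.na(lower95) && !is.na(upper95)) {
    if (lower95 <= 0 || lower95 > value || upper95 < value)
      stop("hazard_ratio: need 0 < lower95 <= value <= upper95")
  }
  structure(list(value = value, lower95 = lower95, upper95 = upper95,
                 source_label = source_label),
            class = "hazard_ratio")
}

#' Derive a comparator survival curve by proportional hazards
#'
#' Under proportional hazards, a hazard ratio `hr` maps a baseline survival
#' curve to \eqn{S_{new}(t) = S_{base}(t)^{hr}} pointwise. This is how
#' comparator-arm time-to-next-treatment curves are derived from a
#' reference arm and a published hazard ratio.
#'
#' @param base Numeric survival grid (S(0) = 1, nonincreasing).
#' @param hr A [hazard_ratio()] or a positive scalar.
#' @return Transformed survival grid of the same length.
#' @export
apply_hazard_ratio <- function(base, hr) {
  if (inherits(hr, "hazard_ratio")) hr <- hr$value
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0)
    stop("apply_hazard_ratio: hr must be a positive scalar")
  assert_survival_grid(base)
  base ^ hr
}

# Restricted mean survival over the grid, in months (trapezoid rule).
grid_rmst <- function(grid) {
  n <- length(grid)
  sum(grid) - (grid[1L] + grid[n]) / 2
}

#' Select base/best/worst fits for scenario analyses
#'
#' From candidate fits of the same dataset, selects the base case (lowest
#' AIC), the best case (highest restricted mean survival over the model
#' horizon, i.e. highest survival benefit) and the worst case (lowest
#' restricted mean survival). Ties are broken by family name in the order
#' of [parametric_families()].
#'
#' @param fits List of at least two [parametric_fit()] objects.
#' @param horizon_cycles Horizon in monthly cycles for the RMST comparison.
#' @return List with elements `base`, `best`, `worst`.
#' @export
select_scenario_fits <- function(fits, horizon_cycles) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("select_scenario_fits: need at least 2 fits")
  stopifnot(all(vapply(fits, inherits, logical(1), "parametric_fit")))
  fam_rank <- match(vapply(fits, `[[`, character(1), "family"),
                    names(.families))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  rmst <- vapply(fits, function(f)
    grid_rmst(survival_on_grid(f, horizon_cycles)), numeric(1))
  list(base  = fits[[order(aic, fam_rank)[1L]]],
       best  = fits[[order(-rmst, fam_rank)[1L]]],
       worst = fits[[order(rmst, fam_rank)[1L]]])
}

#' Serialize a fitted distribution to JSON
#'
#' @param fit A [parametric_fit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "parametric_fit"))
  jsonlite::write_json(
    list(family = fit$family, params = unname(fit$params),
         param_names = names(fit$params),
         covariance = fit$covariance, loglik = fit$loglik, aic = fit$aic,
         n = fit$n, label = fit$label),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted distribution from JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return A [parametric_fit()].
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  parametric_fit(x$family, x$params, covariance = x$covariance,
                 loglik = x$loglik, aic = x$aic, n = x$n, label = x$label)
}
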