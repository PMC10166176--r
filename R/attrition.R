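#' Attrition-rate estimate
#'
#' An attrition rate is the proportion of patients leaving first-line
#' therapy who die (or otherwise never start second line) before second
#' line. Stored with its defining counts so that probabilistic draws
#' (beta with shapes numerator, denominator - numerator) are well defined.
#'
#' @param label Method name, e.g. `"predicted"` or `"crude"`.
#' @param numerator Event count (0 <= numerator <= denominator).
#' @param denominator Total count (> 0).
#' @return An object of class `attrition_estimate` with fields `label`,
#'   `rate` (= numerator / denominator), `numerator`, `denominator`, and
#'   `percent` (rate in percent, rounded half-even to one decimal).
#' @export
attrition_estimate <- function(label, numerator, denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      denominator <= 0)
    stop("attrition_estimate: denominator must be a positive count")
  if (!is.numeric(numerator) || length(numerator) != 1L ||
      numerator < 0 || numerator > denominator)
    stop("attrition_estimate: need 0 <= numerator <= denominator")
  rate <- numerator / denominator
  structure(list(label = label, rate = rate, numerator = numerator,
                 denominator = denominator,
                 percent = round(100 * rate, 1)),
            class = "attrition_estimate")
}

#' @export
print.attrition_estimate <- function(x, ...) {
  cat(sprintf("<attrition_estimate '%s'> %s%% (%g/%g)\n",
              x$label, format(x$percent, nsmall = 1), x$numerator,
              x$denominator))
  invisible(x)
}

#' Crude attrition rate
#'
#' Proportion of treated patients who did not receive subsequent therapy,
#' censored patients included in the denominator.
#'
#' @param no_subsequent Count of patients without subsequent therapy.
#' @param total Total treated patients.
#' @return An [attrition_estimate()] labelled `"crude"`.
#' @examples
#' crude_attrition(429, 729)$percent  # 58.8
#' @export
crude_attrition <- function(no_subsequent, total) {
  attrition_estimate("crude", no_subsequent, total)
}

#' Predicted attrition rate
#'
#' Predicted number of death events (e.g. from a binomial logistic model)
#' divided by the total number of patients in the arm.
#'
#' @param deaths_pred Predicted death count.
#' @param total Total patients.
#' @return An [attrition_estimate()] labelled `"predicted"`.
#' @examples
#' predicted_attrition(110, 368)$percent  # 29.9
#' @export
predicted_attrition <- function(deaths_pred, total) {
  attrition_estimate("predicted", deaths_pred, total)
}

#' Pool attrition estimates across arms
#'
#' Sums numerators and denominators, e.g. to form an overall trial-level
#' rate for an arm with no direct data.
#'
#' @param ... [attrition_estimate()] objects.
#' @return An [attrition_estimate()] labelled `"pooled"`.
#' @examples
#' pool_attrition(predicted_attrition(110, 368),
#'                predicted_attrition(90, 369))$percent  # 27.1
#' @export
pool_attrition <- function(...) {
  ests <- list(...)
  stopifnot(length(ests) >= 1L,
            all(vapply(ests, inherits, logical(1), "attrition_estimate")))
  attrition_estimate("pooled",
                     sum(vapply(ests, `[[`, numeric(1), "numerator")),
                     sum(vapply(ests, `[[`, numeric(1), "denominator")))
}

#' Patient disposition table
#'
#' Per-patient first-line outcome records used to fit the attrition model.
#'
#' @param arm Arm label per patient.
#' @param received_subsequent 0/1: started second-line therapy.
#' @param died_before_2L 0/1: died before second line (mutually exclusive
#'   with `received_subsequent`).
#' @param censored 0/1: neither outcome observed (implies both outcome
#'   columns are 0).
#' @param ... Optional per-patient covariate columns (e.g. `age`,
#'   `followup_months`).
#' @return A data frame of class `patient_disposition`.
#' @export
patient_disposition <- function(arm, received_subsequent, died_before_2L,
                                censored, ...) {
  n <- length(arm)
  df <- data.frame(arm = as.character(arm),
                   received_subsequent = as.numeric(received_subsequent),
                   died_before_2L = as.numeric(died_before_2L),
                   censored = as.numeric(censored), ...)
  if (nrow(df) != n) stop("patient_disposition: column lengths differ")
  if (any(df$received_subsequent == 1 & df$died_before_2L == 1))
    stop("patient_disposition: death before 2L and subsequent therapy are ",
         "mutually exclusive")
  if (any(df$censored == 1 &
          (df$received_subsequent == 1 | df$died_before_2L == 1)))
    stop("patient_disposition: censored patients have no observed outcome")
  class(df) <- c("patient_disposition", "data.frame")
  df
}

#' Binomial logistic attrition model
#'
#' Fits death-before-second-line on the non-censored patients by maximum
#' likelihood with a logit link, and reports per-arm predicted death counts
#' (the sum of fitted probabilities over each arm) and the implied
#' attrition rates. With arm as the only covariate the predicted per-arm
#' counts equal the observed per-arm death counts exactly (the
#' saturated-margin property of logistic regression); an empty covariate
#' list fits the intercept-only model.
#'
#' @param data A [patient_disposition()] table.
#' @param covariates Character vector of covariate column names; `"arm"`
#'   by default.
#' @return A list of class `attrition_fit`: `model` (the [stats::glm()]
#'   fit), `predicted` (data frame with per-arm predicted deaths, totals
#'   and rates) and `estimates` (list of per-arm [attrition_estimate()]s).
#' @export
fit_attrition_logit <- function(data, covariates = "arm") {
  stopifnot(inherits(data, "patient_disposition"))
  obs <- data[data$censored == 0, , drop = FALSE]
  if (sum(obs$died_before_2L) < 1 ||
      sum(obs$died_before_2L) >= nrow(obs))
    stop("fit_attrition_logit: need at least one death and one non-death")
  missing_cov <- setdiff(covariates, names(obs))
  if (length(missing_cov))
    stop("fit_attrition_logit: unknown covariates: ",
         paste(missing_cov, collapse = ", "))
  fml <- if (length(covariates) == 0L) died_before_2L ~ 1 else
    stats::reformulate(covariates, response = "died_before_2L")
  model <- stats::glm(fml, family = stats::binomial(), data = obs)
  if (!model$converged)
    stop("fit_attrition_logit: glm did not converge (possible complete ",
         "separation); coefficients: ",
         paste(round(stats::coef(model), 2), collapse = ", "))
  fitted_p <- stats::fitted(model)
  pred <- vapply(split(fitted_p, obs$arm), sum, numeric(1))
  tot <- vapply(split(fitted_p, obs$arm), length, integer(1))
  arms <- names(pred)
  predicted <- data.frame(arm = arms, predicted_deaths = unname(pred),
                          total = unname(tot),
                          rate = unname(pred / tot), row.names = NULL)
  estimates <- lapply(seq_along(arms), function(i)
    predicted_attrition(pred[[i]], tot[[i]]))
  names(estimates) <- arms
  structure(list(model = model, predicted = predicted,
                 estimates = estimates),
            class = "attrition_fit")
}

#' @export
print.attrition_fit <- function(x, ...) {
  cat("<attrition_fit> binomial logistic model\n")
  print(x$predicted, digits = 4)
  invisible(x)
}
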