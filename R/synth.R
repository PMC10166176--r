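#' Specification of a synthetic two-arm-plus-derived-arm trial
#'
#' Parameters for generating pseudo individual-patient time-to-next-
#' treatment (TTNT) data emulating a first-line trial in transplant-
#' ineligible newly diagnosed myeloma: a reference Rd-like arm drawn from a
#' parametric family, a D-Rd-like arm with a target TTNT hazard ratio, a
#' VRd-like arm derived by a proportional-hazards transform, independent
#' exponential censoring plus an administrative cutoff, and per-arm
#' attrition truths for the disposition table.
#'
#' Defaults give a reference-arm median TTNT of about 32 months, a D-Rd
#' hazard ratio of 0.47, a VRd hazard ratio of 0.70, roughly 20% censoring
#' by the 72-month administrative cutoff, and attrition truths of 0.299
#' (D-Rd-like), 0.244 (Rd-like) and 0.271 (VRd-like).
#'
#' @param n_per_arm Patients per arm (default 369).
#' @param ttnt_family Parametric family of the reference TTNT curve.
#' @param ttnt_params Unconstrained-scale parameters of that family
#'   (default Weibull shape 1.2, scale 43.4 months).
#' @param hr_drd Target TTNT hazard ratio, D-Rd-like vs reference.
#' @param hr_vrd Target hazard ratio, VRd-like vs reference.
#' @param censor_rate Exponential censoring hazard per month.
#' @param admin_censor Administrative censoring time (months).
#' @param attrition_truth Named probabilities of death-before-2L among 1L
#'   leavers, names `Rd`, `D-Rd`, `VRd`.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A list of class `trial_spec`.
#' @export
trial_spec <- function(n_per_arm = 369L,
                       ttnt_family = "weibull",
                       ttnt_params = c(log(1.2), log(43.4)),
                       hr_drd = 0.47, hr_vrd = 0.70,
                       censor_rate = 0.004, admin_censor = 72,
                       attrition_truth = c(`Rd` = 0.244, `D-Rd` = 0.299,
                                           `VRd` = 0.271),
                       seed = 1L) {
  stopifnot(n_per_arm >= 1L, hr_drd > 0, hr_vrd > 0, censor_rate >= 0,
            admin_censor > 0,
            all(attrition_truth >= 0 & attrition_truth <= 1),
            all(c("Rd", "D-Rd", "VRd") %in% names(attrition_truth)))
  .family_info(ttnt_family)
  structure(list(n_per_arm = as.integer(n_per_arm),
                 ttnt_family = ttnt_family, ttnt_params = ttnt_params,
                 hr_drd = hr_drd, hr_vrd = hr_vrd,
                 censor_rate = censor_rate, admin_censor = admin_censor,
                 attrition_truth = attrition_truth, seed = as.integer(seed)),
            class = "trial_spec")
}

# Draw event times whose survival is S_ref(t)^hr (proportional hazards),
# via inverse transform: S_ref(T) = U^(1/hr) with U ~ Unif(0,1).
.draw_ph_times <- function(n, family, params, hr) {
  u <- stats::runif(n)
  t <- quantile_from_params(family, params, u ^ (1 / hr))
  pmax(t, 1e-6)  # guard the measure-zero chance of a zero time
}

.censor <- function(t_event, censor_rate, admin_censor) {
  n <- length(t_event)
  c_time <- if (censor_rate > 0)
    pmin(stats::rexp(n, censor_rate), admin_censor) else rep(admin_censor, n)
  list(time = pmin(t_event, c_time), event = as.numeric(t_event <= c_time))
}

#' Generate synthetic trial TTNT data and a disposition table
#'
#' Draws first-line time-to-next-treatment records for the three arms
#' (reference Rd-like, D-Rd-like via `hr_drd`, VRd-like via `hr_vrd`) with
#' proportional hazards across arms and independent censoring, and a
#' per-patient disposition table in which each observed 1L leaver dies
#' before second line with the arm's `attrition_truth` probability.
#'
#' @param spec A [trial_spec()].
#' @return A list with elements `rd`, `drd`, `vrd` (each a
#'   [survival_dataset()]) and `disposition` (a [patient_disposition()]).
#' @export
generate_trial_ipd <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  arms <- list(`Rd` = 1, `D-Rd` = spec$hr_drd, `VRd` = spec$hr_vrd)
  out <- list()
  disp <- list()
  for (arm in names(arms)) {
    t_ev <- .draw_ph_times(spec$n_per_arm, spec$ttnt_family,
                           spec$ttnt_params, arms[[arm]])
    obs <- .censor(t_ev, spec$censor_rate, spec$admin_censor)
    key <- c(`Rd` = "rd", `D-Rd` = "drd", `VRd` = "vrd")[[arm]]
    out[[key]] <- survival_dataset(obs$time, obs$event,
                                   label = paste0(arm, "-TTNT"))
    left <- obs$event == 1
    died <- left & (stats::runif(spec$n_per_arm) <
                      spec$attrition_truth[[arm]])
    disp[[arm]] <- data.frame(
      arm = arm,
      received_subsequent = as.numeric(left & !died),
      died_before_2L = as.numeric(died),
      censored = as.numeric(!left),
      age = round(stats::rnorm(spec$n_per_arm, 74.1, 5), 1),
      followup_months = obs$time)
  }
  dd <- do.call(rbind, disp)
  out$disposition <- patient_disposition(
    dd$arm, dd$received_subsequent, dd$died_before_2L, dd$censored,
    age = dd$age, followup_months = dd$followup_months)
  out
}

#' Specification of synthetic second-line overall-survival cohorts
#'
#' Parameters for generating pseudo individual-patient 2L overall-survival
#' data emulating real-world cohorts: one daratumumab-based class and one
#' pomalidomide/carfilzomib-based class with distinct hazards. Defaults
#' give median 2L OS of roughly 36 and 24 months respectively.
#'
#' @param n Patients per regimen class (default 800).
#' @param os_family Parametric family of the 2L OS curves.
#' @param params_dara,params_pomcar Unconstrained-scale parameters for the
#'   two classes.
#' @param censor_rate Exponential censoring hazard per month.
#' @param admin_censor Administrative censoring time (months).
#' @param seed Integer seed.
#' @return A list of class `second_line_spec`.
#' @export
second_line_spec <- function(n = 800L, os_family = "weibull",
                             params_dara = c(log(1.1), log(50.2)),
                             params_pomcar = c(log(1.1), log(33.5)),
                             censor_rate = 0.006, admin_censor = 72,
                             seed = 2L) {
  stopifnot(n >= 1L, censor_rate >= 0, admin_censor > 0)
  .family_info(os_family)
  structure(list(n = as.integer(n), os_family = os_family,
                 params_dara = params_dara, params_pomcar = params_pomcar,
                 censor_rate = censor_rate, admin_censor = admin_censor,
                 seed = as.integer(seed)),
            class = "second_line_spec")
}

#' Generate synthetic second-line overall-survival cohorts
#'
#' @param spec A [second_line_spec()].
#' @return A list with elements `dara` and `pomcar`, each a
#'   [survival_dataset()].
#' @export
generate_2l_ipd <- function(spec) {
  stopifnot(inherits(spec, "second_line_spec"))
  set.seed(spec$seed)
  gen <- function(params, label) {
    t_ev <- .draw_ph_times(spec$n, spec$os_family, params, 1)
    obs <- .censor(t_ev, spec$censor_rate, spec$admin_censor)
    survival_dataset(obs$time, obs$event, label = label)
  }
  list(dara = gen(spec$params_dara, "2L-dara-OS"),
       pomcar = gen(spec$params_pomcar, "2L-pomcar-OS"))
}

#' Generate a synthetic general-population life table
#'
#' The default `"gompertz"` profile has annual death probability
#' \eqn{q_x = \min(a e^{b\,age}, 0.99)} with the doubling time and level
#' calibrated to resemble an elderly general population (about 0.03 at age
#' 74, doubling every 8 years); `"constant"` holds `qx0` at every age.
#'
#' @param start_age First tabulated age (years).
#' @param span Number of ages tabulated (>= 1).
#' @param qx_profile `"gompertz"` (default) or `"constant"`.
#' @param qx0 Constant annual death probability for the constant profile.
#' @return A [lifetable()].
#' @export
generate_lifetable <- function(start_age = 60L, span = 50L,
                               qx_profile = c("gompertz", "constant"),
                               qx0 = 0.05) {
  qx_profile <- match.arg(qx_profile)
  if (span < 1L) stop("generate_lifetable: span must be >= 1")
  ages <- seq.int(start_age, start_age + span - 1L)
  qx <- switch(qx_profile,
    constant = rep(qx0, length(ages)),
    gompertz = {
      b <- log(2) / 8
      a <- 0.03 / exp(b * 74)
      pmin(a * exp(b * ages), 0.99)
    })
  lifetable(ages, qx)
}
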