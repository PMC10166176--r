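#' Probabilistic sensitivity analysis configuration
#'
#' Standard health-technology-assessment uncertainty distributions:
#' multivariate normal on the unconstrained survival-parameter scale (using
#' the fit covariance), beta for attrition proportions (shapes = numerator
#' and denominator - numerator), and lognormal for hazard ratios (sigma
#' matched to the published 95% interval as
#' (ln upper - ln lower) / (2 * 1.959964)).
#'
#' @param n_draws Number of draws (default 1000).
#' @param seed Root integer seed; per-parameter substreams are derived
#'   deterministically from it, so adding a parameter block does not
#'   perturb the draws of the others.
#' @param attrition_point_mass If `TRUE`, attrition rates are held at
#'   their point estimates.
#' @param hr_point_mass If `TRUE`, hazard ratios are held at their point
#'   estimates.
#' @return A list of class `psa_config`.
#' @export
psa_config <- function(n_draws = 1000L, seed = 1L,
                       attrition_point_mass = FALSE,
                       hr_point_mass = FALSE) {
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("psa_config: n_draws must be >= 1")
  structure(list(n_draws = n_draws, seed = as.integer(seed),
                 attrition_point_mass = isTRUE(attrition_point_mass),
                 hr_point_mass = isTRUE(hr_point_mass)),
            class = "psa_config")
}

# Deterministic substream seed for parameter block `index` (kept < 2^31).
.substream_seed <- function(seed, index) {
  (abs(seed) + 7919L * index) %% 2147483647L
}

# Nearest-PSD repair: clamp negative eigenvalues to zero.
.repair_psd <- function(sigma) {
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (min(ev$values) >= -1e-10 * max(abs(ev$values), 1)) return(sigma)
  warning("covariance not positive semidefinite; repaired to nearest PSD")
  ev$values <- pmax(ev$values, 0)
  ev$vectors %*% diag(ev$values, nrow = length(ev$values)) %*% t(ev$vectors)
}

#' Draw parameter sets for probabilistic sensitivity analysis
#'
#' Reproducible given the config seed. Survival parameters are drawn on
#' the unconstrained scale and can be rewrapped with [parametric_fit()];
#' attrition draws lie in (0, 1); hazard-ratio draws are positive. Each
#' named block uses its own deterministic substream.
#'
#' @param config A [psa_config()].
#' @param fits Named list of [parametric_fit()] objects.
#' @param attritions Named list of [attrition_estimate()] objects.
#' @param hrs Named list of [hazard_ratio()] objects (may be empty).
#' @return A list of `n_draws` parameter sets, each with named elements
#'   `fits` (parameter vectors), `attritions` (scalars), `hrs` (scalars).
#' @export
draw_parameters <- function(config, fits, attritions, hrs = list()) {
  stopifnot(inherits(config, "psa_config"))
  n <- config$n_draws
  block <- 0L
  fit_draws <- lapply(fits, function(f) {
    block <<- block + 1L
    set.seed(.substream_seed(config$seed, block))
    sigma <- .repair_psd(f$covariance)
    if (max(abs(sigma)) == 0)
      matrix(rep(f$params, each = n), nrow = n)
    else
      MASS::mvrnorm(n, mu = f$params, Sigma = sigma)
  })
  att_draws <- lapply(attritions, function(a) {
    block <<- block + 1L
    set.seed(.substream_seed(config$seed, block))
    s1 <- a$numerator
    s2 <- a$denominator - a$numerator
    if (config$attrition_point_mass || s1 <= 0 || s2 <= 0)
      rep(a$rate, n)
    else
      stats::rbeta(n, s1, s2)
  })
  hr_draws <- lapply(hrs, function(h) {
    block <<- block + 1L
    set.seed(.substream_seed(config$seed, block))
    if (config$hr_point_mass || is.na(h$lower95) || is.na(h$upper95))
      rep(h$value, n)
    else {
      sdlog <- (log(h$upper95) - log(h$lower95)) / (2 * 1.959964)
      stats::rlnorm(n, meanlog = log(h$value), sdlog = sdlog)
    }
  })
  lapply(seq_len(n), function(i) list(
    fits = lapply(fit_draws, function(m) m[i, ]),
    attritions = lapply(att_draws, `[[`, i),
    hrs = lapply(hr_draws, `[[`, i)))
}

#' Template for one sequence in a configured model
#'
#' References parameter blocks by name so that blocks shared between
#' sequences (e.g. a common reference time-to-next-treatment fit) receive
#' identical probabilistic draws.
#'
#' @param label Sequence label.
#' @param s1 Name of the first-line TTNT fit block.
#' @param attrition Name of the attrition block, or a fixed numeric rate.
#' @param s2 Name of the second-line OS fit block.
#' @param s1_hr Optional name of a hazard-ratio block applied to the
#'   first-line curve (comparator arms derived by proportional hazards).
#' @param start_age Cohort starting age in years.
#' @param horizon_cycles Horizon in monthly cycles.
#' @return A list of class `sequence_template`.
#' @export
sequence_template <- function(label, s1, attrition, s2, s1_hr = NULL,
                              start_age = 74.1, horizon_cycles = 180L) {
  structure(list(label = label, s1 = s1, attrition = attrition, s2 = s2,
                 s1_hr = s1_hr, start_age = start_age,
                 horizon_cycles = as.integer(horizon_cycles)),
            class = "sequence_template")
}

# Materialize sequence_spec objects from templates and parameter blocks,
# optionally substituting one PSA draw.
build_sequence_specs <- function(templates, fits, attritions,
                                 hrs = list(), draw = NULL) {
  grid_cache <- new.env(parent = emptyenv())
  get_grid <- function(name, horizon) {
    key <- paste0(name, "@", horizon)
    if (!is.null(grid_cache[[key]])) return(grid_cache[[key]])
    f <- fits[[name]]
    if (is.null(f)) stop("unknown fit block '", name, "'")
    if (!is.null(draw))
      f <- parametric_fit(f$family, draw$fits[[name]])
    g <- survival_on_grid(f, horizon)
    grid_cache[[key]] <- g
    g
  }
  lapply(templates, function(tp) {
    stopifnot(inherits(tp, "sequence_template"))
    s1 <- get_grid(tp$s1, tp$horizon_cycles)
    if (!is.null(tp$s1_hr)) {
      h <- hrs[[tp$s1_hr]]
      if (is.null(h)) stop("unknown hazard-ratio block '", tp$s1_hr, "'")
      hv <- if (!is.null(draw)) draw$hrs[[tp$s1_hr]] else h$value
      s1 <- apply_hazard_ratio(s1, hv)
    }
    a <- if (is.numeric(tp$attrition)) tp$attrition else {
      ae <- attritions[[tp$attrition]]
      if (is.null(ae)) stop("unknown attrition block '", tp$attrition, "'")
      if (!is.null(draw)) draw$attritions[[tp$attrition]] else ae$rate
    }
    sequence_spec(tp$label, s1, a, get_grid(tp$s2, tp$horizon_cycles),
                  start_age = tp$start_age,
                  horizon_cycles = tp$horizon_cycles)
  })
}

# One deterministic model evaluation -> per-sequence outcome data frame.
.evaluate_model <- function(templates, fits, attritions, hrs, table,
                            reference, draw = NULL,
                            second_line = "semi-markov",
                            background = "hazard-floor") {
  specs <- build_sequence_specs(templates, fits, attritions, hrs, draw)
  traces <- lapply(specs, run_sequence, table = table,
                   second_line = second_line, background = background)
  cmp <- compare_sequences(traces, reference = reference)
  cmp$summary
}

#' Run the probabilistic sensitivity analysis
#'
#' One engine run per draw per sequence. The point estimate is the
#' deterministic base-case run (no draws); 95% credible intervals are
#' equal-tailed empirical 2.5th/97.5th percentiles (inverse-ECDF order
#' statistics) of the per-draw outcomes. Draws for which any engine run
#' fails are rejected, redrawn from a fresh substream, and counted in the
#' diagnostics; redraws are capped at 10 times `n_draws`.
#'
#' @param templates List of [sequence_template()] objects.
#' @param config A [psa_config()].
#' @param table A [lifetable()].
#' @param fits,attritions,hrs Named parameter blocks as in
#'   [draw_parameters()].
#' @param reference Reference sequence index or label for differences.
#' @param second_line,background Engine switches, see [run_sequence()].
#' @return A list of class `psa_result`: `draws` (per-draw outcome table),
#'   `summary` (point estimate with credible limits per sequence and
#'   outcome), `diagnostics` (rejected-draw count).
#' @export
run_psa <- function(templates, config, table, fits, attritions,
                    hrs = list(), reference = 1L,
                    second_line = "semi-markov",
                    background = "hazard-floor") {
  stopifnot(inherits(config, "psa_config"))
  point <- .evaluate_model(templates, fits, attritions, hrs, table,
                           reference, second_line = second_line,
                           background = background)
  draws <- draw_parameters(config, fits, attritions, hrs)
  rows <- vector("list", config$n_draws)
  rejected <- 0L
  for (i in seq_len(config$n_draws)) {
    dr <- draws[[i]]
    repeat {
      res <- tryCatch(
        .evaluate_model(templates, fits, attritions, hrs, table,
                        reference, draw = dr,
                        second_line = second_line,
                        background = background),
        error = function(e) e)
      if (!inherits(res, "error")) break
      rejected <- rejected + 1L
      if (rejected > 10L * config$n_draws)
        stop("run_psa: rejected-draw cap exceeded; last error: ",
             conditionMessage(res))
      cfg1 <- psa_config(1L, .substream_seed(config$seed,
                                             1000L + rejected),
                         config$attrition_point_mass, config$hr_point_mass)
      dr <- draw_parameters(cfg1, fits, attritions, hrs)[[1L]]
    }
    res$draw <- i
    rows[[i]] <- res
  }
  per_draw <- do.call(rbind, rows)
  outcome_cols <- setdiff(names(per_draw), c("label", "draw"))
  q <- function(x, p) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    sort(x)[max(1L, ceiling(p * length(x)))]
  }
  summ <- do.call(rbind, lapply(split(per_draw, per_draw$label),
    function(d) {
      lab <- d$label[1L]
      do.call(rbind, lapply(outcome_cols, function(col) data.frame(
        label = lab, outcome = col,
        point = point[[col]][point$label == lab],
        lower95 = q(d[[col]], 0.025), upper95 = q(d[[col]], 0.975),
        n_not_reached = sum(is.na(d[[col]])), row.names = NULL)))
    }))
  rownames(summ) <- NULL
  structure(list(draws = per_draw, summary = summ,
                 diagnostics = list(rejected = rejected,
                                    n_draws = config$n_draws,
                                    seed = config$seed)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d, %d rejected)\n",
              x$diagnostics$n_draws, x$diagnostics$seed,
              x$diagnostics$rejected))
  keep <- x$summary$outcome %in% c("median_os_years", "life_years")
  print(x$summary[keep, ], digits = 4)
  invisible(x)
}

#' Deterministic scenario grid
#'
#' Reruns the base-case model under a list of named overrides. Allowed
#' override keys per scenario: `attrition` (a single rate applied to every
#' sequence, or a named vector by sequence label), `hrs` (named list of
#' replacement [hazard_ratio()]s or scalars), `fits` (named list of
#' replacement [parametric_fit()]s, e.g. the best/worst-case
#' distributions from [select_scenario_fits()]), `second_line` and
#' `background` engine switches.
#'
#' @param base A list with elements `templates`, `fits`, `attritions`,
#'   `hrs`, `table` and optionally `reference` (default 1).
#' @param scenarios Named list of override lists; an empty list yields the
#'   base case only.
#' @return Data frame of per-scenario, per-sequence outcomes; the base
#'   case appears first with scenario label `"base"`.
#' @export
scenario_grid <- function(base, scenarios = list()) {
  req <- c("templates", "fits", "attritions", "table")
  if (!all(req %in% names(base)))
    stop("scenario_grid: base must contain ",
         paste(req, collapse = ", "))
  hrs <- if (is.null(base$hrs)) list() else base$hrs
  reference <- if (is.null(base$reference)) 1L else base$reference
  allowed <- c("attrition", "hrs", "fits", "second_line", "background")
  eval_one <- function(name, ov) {
    bad <- setdiff(names(ov), allowed)
    if (length(bad))
      stop("scenario_grid: unknown override key(s) in '", name, "': ",
           paste(bad, collapse = ", "))
    tps <- base$templates
    fits <- base$fits
    h <- hrs
    if (!is.null(ov$fits)) {
      unknown <- setdiff(names(ov$fits), names(fits))
      if (length(unknown))
        stop("scenario_grid: override of unknown fit block(s): ",
             paste(unknown, collapse = ", "))
      fits[names(ov$fits)] <- ov$fits
    }
    if (!is.null(ov$hrs)) {
      unknown <- setdiff(names(ov$hrs), names(h))
      if (length(unknown))
        stop("scenario_grid: override of unknown hazard-ratio block(s): ",
             paste(unknown, collapse = ", "))
      h[names(ov$hrs)] <- lapply(ov$hrs, function(x)
        if (inherits(x, "hazard_ratio")) x else hazard_ratio(x))
    }
    if (!is.null(ov$attrition)) {
      av <- ov$attrition
      tps <- lapply(tps, function(tp) {
        tp$attrition <- if (length(av) == 1L && is.null(names(av)))
          as.numeric(av)
        else if (tp$label %in% names(av)) as.numeric(av[[tp$label]])
        else tp$attrition
        tp
      })
    }
    out <- .evaluate_model(
      tps, fits, base$attritions, h, base$table, reference,
      second_line = if (is.null(ov$second_line)) "semi-markov"
                    else ov$second_line,
      background = if (is.null(ov$background)) "hazard-floor"
                   else ov$background)
    out$scenario <- name
    out
  }
  rows <- c(list(eval_one("base", list())),
            lapply(names(scenarios), function(nm)
              eval_one(nm, scenarios[[nm]])))
  out <- do.call(rbind, rows)
  out[, c("scenario", setdiff(names(out), "scenario"))]
}
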