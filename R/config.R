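#' Default run configuration for the synthetic base case
#'
#' A complete, self-contained configuration mirroring the base-case model
#' structure: three sequences (D-Rd then pomalidomide/carfilzomib-based,
#' VRd then daratumumab-based, Rd then daratumumab-based) on a 180-cycle
#' (15-year) horizon starting at age 74.1. First-line curves for the
#' D-Rd-like and Rd-like arms are fitted directly to the generated trial
#' TTNT data; the VRd-like curve is the reference (Rd) curve transformed
#' by a progression-free-survival hazard ratio used as a proxy for the
#' time-to-next-treatment ratio. Attrition is the predicted-deaths rate
#' per arm (29.9% and 24.4%), with the pooled rate (27.1%) for the VRd
#' sequence. All data come from the synthetic generator.
#'
#' @param seed Root seed for data generation and the PSA.
#' @return A nested configuration list accepted by [cmd_run()],
#'   [cmd_psa()] and [cmd_scenarios()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    start_age = 74.1,
    horizon_cycles = 180L,
    families = list("exponential", "weibull", "loglogistic", "lognormal",
                    "gompertz", "generalized_gamma"),
    lifetable = list(synthetic = TRUE),
    data = list(synthetic = TRUE),
    hazard_ratios = list(
      hr_vrd = list(value = 0.70, source = "VRd vs Rd PFS HR proxy")),
    attrition = list(
      drd = list(numerator = 110, denominator = 368),
      rd = list(numerator = 90, denominator = 369),
      vrd = list(numerator = 200, denominator = 737)),
    sequences = list(
      list(label = "D-Rd -> Pom/Car", s1 = "drd_ttnt",
           attrition = "drd", s2 = "pomcar_os"),
      list(label = "VRd -> Dara", s1 = "rd_ttnt", s1_hr = "hr_vrd",
           attrition = "vrd", s2 = "dara_os"),
      list(label = "Rd -> Dara", s1 = "rd_ttnt",
           attrition = "rd", s2 = "dara_os")),
    reference = "D-Rd -> Pom/Car",
    psa = list(n_draws = 1000L),
    scenarios = list(
      attrition_crude_58.8 = list(attrition = 0.588),
      attrition_excl_censored_27.2 = list(attrition = 0.272))
  )
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML configuration (see [default_run_config()]
#'   for the schema).
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  yaml::read_yaml(path)
}

# Validate a configuration, collecting all failures into one error.
validate_run_config <- function(config) {
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(is.list(config), "config must be a list")
  need(!is.null(config$sequences) && length(config$sequences) >= 1,
       "at least one sequence required")
  need(!is.null(config$lifetable), "lifetable block required")
  need(!is.null(config$data), "data block required")
  fams <- unlist(config$families)
  need(length(fams) >= 1, "at least one candidate family required")
  need(all(fams %in% parametric_families()),
       paste0("unknown families: ",
              paste(setdiff(fams, parametric_families()), collapse = ", ")))
  labels <- vapply(config$sequences, function(s)
    if (is.null(s$label)) NA_character_ else s$label, character(1))
  need(!anyNA(labels) && !anyDuplicated(labels),
       "every sequence needs a unique label")
  for (s in config$sequences) {
    need(!is.null(s$s1) && !is.null(s$s2),
         paste0("sequence '", s$label, "' needs s1 and s2 cohort names"))
    need(!is.null(s$attrition),
         paste0("sequence '", s$label, "' needs an attrition source"))
  }
  if (!is.null(config$reference))
    need(config$reference %in% labels ||
           (is.numeric(config$reference) &&
              config$reference <= length(labels)),
         "reference must name an existing sequence")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

# Polynomial rolling hash of the canonical JSON form, for output provenance.
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 131 + b) %% 1e9
  sprintf("%09.0f", h)
}

# Assemble data, fits, attrition estimates and hazard ratios from a config.
#' Build the model objects described by a run configuration
#'
#' Generates or loads the cohorts and life table, fits every candidate
#' family per cohort, selects each cohort's base-case fit by lowest AIC,
#' and assembles the attrition and hazard-ratio blocks and sequence
#' templates.
#'
#' @param config Configuration list or YAML path.
#' @return A list with `templates`, `fits` (selected per cohort),
#'   `all_fits` (per cohort, per family), `attritions`, `hrs`, `table`,
#'   `reference`, `datasets`, `disposition`, `config` and `config_hash`.
#' @export
build_model_from_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  horizon <- if (is.null(config$horizon_cycles)) 180L else
    as.integer(config$horizon_cycles)
  start_age <- if (is.null(config$start_age)) 74.1 else config$start_age

  # life table
  table <- if (!is.null(config$lifetable$path))
    load_lifetable(config$lifetable$path)
  else
    generate_lifetable(
      start_age = if (is.null(config$lifetable$start_age)) 60L else
        config$lifetable$start_age,
      span = if (is.null(config$lifetable$span)) 50L else
        config$lifetable$span,
      qx_profile = if (is.null(config$lifetable$profile)) "gompertz" else
        config$lifetable$profile)

  # cohorts
  datasets <- list()
  disposition <- NULL
  if (isTRUE(config$data$synthetic)) {
    tspec <- trial_spec(seed = seed)
    if (!is.null(config$data$n_per_arm))
      tspec$n_per_arm <- as.integer(config$data$n_per_arm)
    trial <- generate_trial_ipd(tspec)
    sspec <- second_line_spec(seed = seed + 1L)
    if (!is.null(config$data$n_2l))
      sspec$n <- as.integer(config$data$n_2l)
    sl <- generate_2l_ipd(sspec)
    datasets <- list(rd_ttnt = trial$rd, drd_ttnt = trial$drd,
                     vrd_ttnt = trial$vrd, dara_os = sl$dara,
                     pomcar_os = sl$pomcar)
    disposition <- trial$disposition
  } else {
    for (nm in names(config$data$cohorts))
      datasets[[nm]] <- read_survival_dataset(config$data$cohorts[[nm]],
                                              label = nm)
  }

  # fits: every candidate family per cohort actually referenced
  fams <- unlist(config$families)
  used <- unique(unlist(lapply(config$sequences, function(s)
    c(s$s1, s$s2))))
  missing_cohorts <- setdiff(used, names(datasets))
  if (length(missing_cohorts))
    stop("sequences reference unknown cohorts: ",
         paste(missing_cohorts, collapse = ", "))
  all_fits <- lapply(datasets[used], function(d) {
    fl <- list()
    for (fam in fams)
      fl[[fam]] <- tryCatch(fit_parametric(d, fam), error = function(e) NULL)
    fl[!vapply(fl, is.null, logical(1))]
  })
  fits <- lapply(all_fits, function(fl) {
    if (length(fl) == 0L) stop("no family converged for a cohort")
    if (length(fl) == 1L) fl[[1L]] else
      select_scenario_fits(fl, horizon)$base
  })

  # attrition blocks
  attritions <- list()
  for (nm in names(config$attrition)) {
    blk <- config$attrition[[nm]]
    attritions[[nm]] <- if (!is.null(blk$numerator))
      predicted_attrition(blk$numerator, blk$denominator)
    else
      attrition_estimate(nm, blk$value * 1000, 1000)
  }

  # hazard ratios
  hrs <- list()
  for (nm in names(config$hazard_ratios)) {
    blk <- config$hazard_ratios[[nm]]
    hrs[[nm]] <- hazard_ratio(
      blk$value,
      lower95 = if (is.null(blk$lower95)) NA_real_ else blk$lower95,
      upper95 = if (is.null(blk$upper95)) NA_real_ else blk$upper95,
      source_label = if (is.null(blk$source)) "" else blk$source)
  }

  templates <- lapply(config$sequences, function(s)
    sequence_template(s$label, s$s1,
                      attrition = if (is.numeric(s$attrition)) s$attrition
                                  else s$attrition,
                      s2 = s$s2, s1_hr = s$s1_hr,
                      start_age = start_age, horizon_cycles = horizon))

  reference <- if (is.null(config$reference)) 1L else config$reference
  list(templates = templates, fits = fits, all_fits = all_fits,
       attritions = attritions, hrs = hrs, table = table,
       reference = reference, datasets = datasets,
       disposition = disposition, config = config,
       config_hash = .config_hash(config))
}

.write_outputs <- function(obj, output_dir, stem, hash) {
  if (is.null(output_dir)) return(invisible(NULL))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(obj)) {
    x <- obj[[nm]]
    path <- file.path(output_dir, paste0(stem, "-", nm))
    if (is.data.frame(x)) {
      x$config_hash <- hash
      utils::write.csv(x, paste0(path, ".csv"), row.names = FALSE)
    } else {
      jsonlite::write_json(c(x, list(config_hash = hash)),
                           paste0(path, ".json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(NULL)
}

#' Run the deterministic base case from a configuration
#'
#' Builds the model, runs every sequence through the cohort engine, and
#' tabulates median overall survival, 5/10/15-year landmark rates,
#' life-years and pairwise differences against the declared reference.
#'
#' @param config Configuration list or YAML path (see
#'   [default_run_config()]).
#' @param output_dir Optional directory for CSV/JSON reports and per-
#'   sequence cohort traces; every file carries the config hash.
#' @return A list of class `seqpsm_run`: `comparison` (a
#'   [compare_sequences()] result), `traces`, `fit_diagnostics` (per
#'   cohort AIC table) and `model`.
#' @export
cmd_run <- function(config = default_run_config(), output_dir = NULL) {
  model <- build_model_from_config(config)
  specs <- build_sequence_specs(model$templates, model$fits,
                                model$attritions, model$hrs)
  traces <- lapply(specs, run_sequence, table = model$table)
  cmp <- compare_sequences(traces, reference = model$reference)
  fit_diag <- do.call(rbind, lapply(names(model$all_fits), function(ch)
    data.frame(cohort = ch,
               family = vapply(model$all_fits[[ch]], `[[`, character(1),
                               "family"),
               aic = vapply(model$all_fits[[ch]], `[[`, numeric(1), "aic"),
               selected = vapply(model$all_fits[[ch]], function(f)
                 identical(f$family, model$fits[[ch]]$family), logical(1)),
               row.names = NULL)))
  out <- structure(list(comparison = cmp, traces = traces,
                        fit_diagnostics = fit_diag, model = model),
                   class = "seqpsm_run")
  if (!is.null(output_dir)) {
    .write_outputs(list(summary = cmp$summary,
                        differences = cmp$differences,
                        fit_diagnostics = fit_diag),
                   output_dir, "run", model$config_hash)
    for (tr in traces)
      write_trace_csv(tr, file.path(output_dir,
        paste0("trace-", gsub("[^A-Za-z0-9]+", "_", tr$label), ".csv")))
  }
  out
}

#' @export
print.seqpsm_run <- function(x, ...) {
  print(x$comparison)
  invisible(x)
}

#' Run the probabilistic sensitivity analysis from a configuration
#'
#' @inheritParams cmd_run
#' @param n_draws Optional override of the configured draw count.
#' @return A `psa_result` (see [run_psa()]).
#' @export
cmd_psa <- function(config = default_run_config(), output_dir = NULL,
                    n_draws = NULL) {
  model <- build_model_from_config(config)
  cfg <- model$config
  nd <- if (!is.null(n_draws)) n_draws else
    if (!is.null(cfg$psa$n_draws)) cfg$psa$n_draws else 1000L
  pc <- psa_config(n_draws = nd,
                   seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  res <- run_psa(model$templates, pc, model$table, model$fits,
                 model$attritions, model$hrs,
                 reference = model$reference)
  if (!is.null(output_dir))
    .write_outputs(list(draws = res$draws, psa_summary = res$summary,
                        diagnostics = res$diagnostics),
                   output_dir, "psa", model$config_hash)
  res
}

#' Run the scenario grid from a configuration
#'
#' Scenario overrides come from the config's `scenarios` block; the
#' special fit-choice values `"best"`/`"worst"` select, per cohort, the
#' candidate family with the highest/lowest restricted mean survival over
#' the horizon (see [select_scenario_fits()]).
#'
#' @inheritParams cmd_run
#' @return Data frame of per-scenario, per-sequence outcomes.
#' @export
cmd_scenarios <- function(config = default_run_config(),
                          output_dir = NULL) {
  model <- build_model_from_config(config)
  cfg <- model$config
  horizon <- model$templates[[1L]]$horizon_cycles
  scenarios <- lapply(cfg$scenarios, function(ov) {
    if (!is.null(ov$fit_choice)) {
      choice <- ov$fit_choice
      ov$fit_choice <- NULL
      ov$fits <- lapply(model$all_fits, function(fl)
        if (length(fl) >= 2L)
          select_scenario_fits(fl, horizon)[[choice]]
        else fl[[1L]])
    }
    ov
  })
  grid <- scenario_grid(
    list(templates = model$templates, fits = model$fits,
         attritions = model$attritions, hrs = model$hrs,
         table = model$table, reference = model$reference),
    scenarios)
  if (!is.null(output_dir))
    .write_outputs(list(scenario_grid = grid), output_dir, "scenarios",
                   model$config_hash)
  grid
}
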