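#' General-population life table
#'
#' Age-indexed annual probabilities of death, used to keep modelled
#' mortality at or above general-population mortality at the cohort's
#' attained age. Lookups above the last tabulated age clamp to the last row.
#'
#' @param age Contiguous ascending integer ages (years).
#' @param qx Annual probability of death per age, each in [0, 1).
#' @return An object of class `lifetable`.
#' @export
lifetable <- function(age, qx) {
  if (length(age) == 0L) stop("lifetable: at least one row required")
  if (length(age) != length(qx)) stop("lifetable: age and qx lengths differ")
  age <- as.integer(age)
  bad <- which(!is.finite(qx) | qx < 0 | qx >= 1)
  if (length(bad))
    stop("lifetable: qx outside [0, 1) at row ", bad[1L],
         " (age ", age[bad[1L]], ")")
  if (length(age) > 1L && any(diff(age) != 1L))
    stop("lifetable: ages must be contiguous ascending integers")
  structure(list(ages = age, qx = as.numeric(qx), max_age = age[length(age)]),
            class = "lifetable")
}

#' @export
print.lifetable <- function(x, ...) {
  cat(sprintf("<lifetable> ages %d-%d, qx in [%.5f, %.5f]\n",
              x$ages[1L], x$max_age, min(x$qx), max(x$qx)))
  invisible(x)
}

#' Load a life-table CSV (`age,qx`)
#'
#' @param path CSV with header `age,qx`.
#' @return A validated [lifetable()].
#' @export
load_lifetable <- function(path) {
  if (!file.exists(path)) stop("load_lifetable: file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("load_lifetable: header must be 'age,qx'")
  lifetable(df$age, df$qx)
}

#' Write a life-table CSV (`age,qx`)
#'
#' @param table A [lifetable()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(table, path) {
  stopifnot(inherits(table, "lifetable"))
  utils::write.csv(data.frame(age = table$ages, qx = table$qx),
                   path, row.names = FALSE)
  invisible(path)
}

# Annual qx at an attained age, clamped to the tabulated range.
.qx_at_age <- function(table, attained_age) {
  idx <- pmin(pmax(attained_age, table$ages[1L]), table$max_age) -
    table$ages[1L] + 1L
  table$qx[idx]
}

#' Background monthly mortality hazard at a model cycle
#'
#' The attained age at cycle `k` is `floor(start_age + k / 12)`; the annual
#' death probability at that age converts to a constant monthly hazard
#' \eqn{-\ln(1 - q_x)/12}, so that 12 consecutive cycles within one
#' age-year compound to exactly `1 - qx` survival.
#'
#' @param table A [lifetable()].
#' @param start_age Cohort age (years) at cycle 0; must not precede the
#'   first tabulated age.
#' @param cycle Model cycle(s), integer months >= 0 (vectorised).
#' @return Monthly hazard(s).
#' @export
background_monthly_hazard <- function(table, start_age, cycle) {
  stopifnot(inherits(table, "lifetable"))
  if (start_age < table$ages[1L])
    stop("background_monthly_hazard: start_age precedes the table")
  attained <- floor(start_age + cycle / 12)
  -log(1 - .qx_at_age(table, attained)) / 12
}

#' Adjust model survival for general-population mortality
#'
#' Default (`"hazard-floor"`): per cycle, the effective hazard is the
#' maximum of the model hazard and the background monthly hazard, and the
#' adjusted curve is rebuilt by compounding effective hazards. This
#' guarantees modelled mortality is never below general-population
#' mortality without double counting, and is idempotent. The multiplicative
#' alternative (`"multiplicative"`) returns
#' \eqn{S_{model}(t) \cdot S_{background}(t)}.
#'
#' @param model_grid Monthly survival grid (S(0) = 1, nonincreasing).
#' @param table A [lifetable()].
#' @param start_age Cohort age (years) at cycle 0.
#' @param method `"hazard-floor"` (default) or `"multiplicative"`.
#' @return Adjusted survival grid, pointwise <= `model_grid`.
#' @export
adjust_for_background <- function(model_grid, table, start_age,
                                  method = c("hazard-floor",
                                             "multiplicative")) {
  method <- match.arg(method)
  assert_survival_grid(model_grid, "model_grid")
  stopifnot(inherits(table, "lifetable"))
  n <- length(model_grid)
  h_bg <- background_monthly_hazard(table, start_age, seq_len(n - 1L))
  if (method == "multiplicative")
    return(model_grid * c(1, exp(-cumsum(h_bg))))
  # model hazard over cycle (k-1, k]; 0/0 (already-extinct curve) -> Inf
  ratio <- model_grid[-1L] / model_grid[-n]
  h_model <- ifelse(model_grid[-1L] <= 0, Inf, -log(ratio))
  c(1, exp(-cumsum(pmax(h_model, h_bg))))
}
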