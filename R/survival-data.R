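#' Right-censored survival dataset for one cohort
#'
#' Container for pseudo individual-patient data: one record per subject with
#' a follow-up time in months and an event indicator (1 = event observed,
#' 0 = right-censored). This is the fitting input for [km_estimate()] and
#' [fit_parametric()].
#'
#' @param time Numeric vector of strictly positive, finite times in months.
#' @param event Integer/numeric vector of 0/1 event indicators, same length.
#' @param label Cohort identifier (single string).
#' @return An object of class `survival_dataset`: a data frame with columns
#'   `time_months` and `event`, plus a `label` attribute.
#' @examples
#' d <- survival_dataset(c(3, 7.5, 12), c(1, 0, 1), label = "example")
#' nrow(d)
#' @export
survival_dataset <- function(time, event, label = "cohort") {
  if (length(time) == 0L) stop("survival_dataset: at least one record required")
  if (length(time) != length(event))
    stop("survival_dataset: time and event lengths differ")
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival_dataset: all times must be strictly positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("survival_dataset: event indicator must be 0 or 1")
  if (!is.character(label) || length(label) != 1L)
    stop("survival_dataset: label must be a single string")
  out <- data.frame(time_months = time, event = event)
  attr(out, "label") <- label
  class(out) <- c("survival_dataset", "data.frame")
  out
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("<survival_dataset '%s'>: %d records, %d events, %d censored\n",
              attr(x, "label"), nrow(x), sum(x$event == 1), sum(x$event == 0)))
  invisible(x)
}

#' Read a cohort CSV (`time_months,event`)
#'
#' @param path Path to a CSV file with header `time_months,event`.
#' @param label Cohort label; defaults to the file name without extension.
#' @return A [survival_dataset()].
#' @export
read_survival_dataset <- function(path, label = NULL) {
  if (!file.exists(path)) stop("read_survival_dataset: file not found: ", path)
  df <- utils::read.csv(path)
  req <- c("time_months", "event")
  if (!all(req %in% names(df)))
    stop("read_survival_dataset: missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  survival_dataset(df$time_months, df$event, label = label)
}

#' Write a cohort CSV (`time_months,event`)
#'
#' @param data A [survival_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_dataset <- function(data, path) {
  stopifnot(inherits(data, "survival_dataset"))
  utils::write.csv(as.data.frame(data)[, c("time_months", "event")],
                   path, row.names = FALSE)
  invisible(path)
}

# Internal: validate a monthly survival grid S(0), S(1), ..., S(h).
assert_survival_grid <- function(grid, what = "survival grid") {
  if (!is.numeric(grid) || length(grid) < 2L)
    stop(what, " must be a numeric vector of length >= 2")
  if (any(!is.finite(grid)))
    stop(what, " contains non-finite values")
  if (abs(grid[1L] - 1) > 1e-12)
    stop(what, " must start at S(0) = 1")
  if (any(grid < 0) || any(grid > 1 + 1e-12))
    stop(what, " values must lie in [0, 1]")
  if (any(diff(grid) > 1e-12))
    stop(what, " must be nonincreasing")
  invisible(grid)
}
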