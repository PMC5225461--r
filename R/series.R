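#' Daily training/performance time series
#'
#' The model input: one row per consecutive day starting at day 0, with the
#' training dose in training units (tu) and, on trial days, the measured
#' performance (mean power over a 5-min maximal trial, watts). Days without
#' a measurement carry `NA` in `performance_w`.
#'
#' Invariants enforced: days run 0..N in steps of 1; all loads are finite
#' and non-negative; the load on day 0 is 0 (the recursion initialises the
#' day-0 dose to zero); at least two measurements exist. The first
#' measurement defines the baseline performance `Perf_0` used by the model.
#'
#' @param load numeric vector of daily doses (tu), one per day.
#' @param performance numeric vector of the same length; `NA` on days
#'   without a trial.
#' @param day optional integer day index; defaults to `0:(length(load)-1)`.
#' @return a `training_series`, a `data.frame` with columns `day`,
#'   `load_tu`, `performance_w`.
#' @seealso [read_series()], [write_series()], [generate_subject()]
#' @examples
#' s <- training_series(load = c(0, 200, 0, 0, 0),
#'                      performance = c(250, NA, NA, 252, 251))
#' n_measurements(s)
#' perf0(s)
#' @export
training_series <- function(load, performance, day = seq_along(load) - 1L) {
  x <- data.frame(day = as.integer(day),
                  load_tu = as.numeric(load),
                  performance_w = as.numeric(performance))
  class(x) <- c("training_series", "data.frame")
  validate_series(x)
  x
}

validate_series <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("day", "load_tu", "performance_w") %in% names(x)))
  n <- nrow(x)
  if (n < 2L) stop("series needs at least 2 days", call. = FALSE)
  if (!identical(as.integer(x$day), seq.int(0L, n - 1L))) {
    gap <- which(x$day != seq.int(0L, n - 1L))[1]
    stop("days must run 0..N in steps of 1; first problem at row ", gap,
         " (day ", x$day[gap], ")", call. = FALSE)
  }
  if (any(!is.finite(x$load_tu))) {
    stop("non-finite load at row ", which(!is.finite(x$load_tu))[1],
         call. = FALSE)
  }
  if (any(x$load_tu < 0)) {
    stop("negative load at row ", which(x$load_tu < 0)[1], call. = FALSE)
  }
  if (x$load_tu[1] != 0) {
    stop("load on day 0 must be 0 (the recursion initialises W_0 = 0)",
         call. = FALSE)
  }
  meas <- !is.na(x$performance_w)
  if (sum(meas) < 2L) {
    stop("series needs at least 2 performance measurements", call. = FALSE)
  }
  if (any(!is.finite(x$performance_w[meas]))) {
    stop("non-finite performance measurement", call. = FALSE)
  }
  invisible(x)
}

#' @rdname training_series
#' @param x a `training_series`.
#' @export
n_measurements <- function(x) sum(!is.na(x$performance_w))

#' @rdname training_series
#' @export
measurement_days <- function(x) x$day[!is.na(x$performance_w)]

#' @rdname training_series
#' @export
measurements <- function(x) x$performance_w[!is.na(x$performance_w)]

#' @rdname training_series
#' @return `perf0()` returns the first measured performance, which anchors
#'   the model's baseline (it is not a fitted parameter).
#' @export
perf0 <- function(x) measurements(x)[1]

#' @export
print.training_series <- function(x, ...) {
  cat(sprintf("Training series: %d days, %d measurements\n",
              nrow(x), n_measurements(x)))
  cat(sprintf("  total load %.0f tu; baseline (first measurement) %.1f W\n",
              sum(x$load_tu), perf0(x)))
  invisible(x)
}
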