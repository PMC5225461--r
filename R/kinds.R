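#' Model kinds of the secondary-signal family
#'
#' Four nested variants of the secondary-signal training model are supported:
#' \describe{
#'   \item{`"T"`}{training effect only: a secondary signal is produced in
#'     proportion to each day's training dose, dissipates first-order, and is
#'     transformed into production of performance (3 parameters).}
#'   \item{`"TI"`}{adds same-day, dose-proportional inhibition of the
#'     transformation of signal into performance (4 parameters).}
#'   \item{`"TF"`}{adds a fatigue component subtracted from performance; the
#'     observable is net performance (5 parameters).}
#'   \item{`"TIF"`}{both inhibition and fatigue (6 parameters).}
#' }
#'
#' @format `MODEL_KINDS` is a character vector of the four kind names.
#' @export
MODEL_KINDS <- c("T", "TI", "TF", "TIF")

#' @rdname MODEL_KINDS
#' @param kind model kind, one of `"T"`, `"TI"`, `"TF"`, `"TIF"`.
#' @return `model_n_params()` returns the number of free parameters of the
#'   kind (3, 4, 5, 6 respectively); the baseline production rate is tied to
#'   `k_off` by stationarity and is never counted.
#' @export
model_n_params <- function(kind) {
  kind <- match_kind(kind)
  c("T" = 3L, "TI" = 4L, "TF" = 5L, "TIF" = 6L)[[kind]]
}

#' @rdname MODEL_KINDS
#' @return `model_param_names()` returns the names of the kind's parameters,
#'   in canonical order.
#' @export
model_param_names <- function(kind) {
  kind <- match_kind(kind)
  switch(kind,
    "T"   = c("k_off", "k_s1", "k_s2"),
    "TI"  = c("k_off", "k_s1", "k_s2", "k_i"),
    "TF"  = c("k_off", "k_s1", "k_s2", "k_f1", "k_f2"),
    "TIF" = c("k_off", "k_s1", "k_s2", "k_i", "k_f1", "k_f2")
  )
}

match_kind <- function(kind) {
  kind <- as.character(kind)
  if (length(kind) != 1L || !kind %in% MODEL_KINDS) {
    stop("unknown model kind: ", paste(kind, collapse = ", "),
         " (expected one of ", paste(MODEL_KINDS, collapse = ", "), ")",
         call. = FALSE)
  }
  kind
}

#' Construct and validate a parameter set for a model kind
#'
#' Rate constants of the daily recursion, all per-day unless noted:
#' `k_off` (first-order removal of performance, 1/day, > 0), `k_s1`
#' (first-order dissipation of the secondary signal, 1/day, > 0), `k_s2`
#' (gain transforming signal into production of performance, W/day per tu,
#' >= 0), `k_i` (inhibition per training unit, 1/tu, >= 0; TI/TIF), `k_f1`
#' (fatigue production gain, W per tu, sign unconstrained; TF/TIF) and
#' `k_f2` (first-order dissipation of fatigue, 1/day, > 0; TF/TIF).
#' The baseline production `k_off * Perf_0` is derived, never stored.
#'
#' @param kind model kind (see [MODEL_KINDS]).
#' @param k_off,k_s1,k_s2,k_i,k_f1,k_f2 parameter values; only those
#'   belonging to `kind` may be given.
#' @return named numeric vector with exactly the kind's parameters.
#' @examples
#' model_params("TI", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
#'              k_i = 0.0021)
#' @export
model_params <- function(kind, k_off, k_s1, k_s2, k_i = NULL, k_f1 = NULL,
                         k_f2 = NULL) {
  kind <- match_kind(kind)
  given <- list(k_off = k_off, k_s1 = k_s1, k_s2 = k_s2)
  if (!is.null(k_i))  given$k_i  <- k_i
  if (!is.null(k_f1)) given$k_f1 <- k_f1
  if (!is.null(k_f2)) given$k_f2 <- k_f2
  wanted <- model_param_names(kind)
  extra <- setdiff(names(given), wanted)
  if (length(extra)) {
    stop("parameter(s) ", paste(extra, collapse = ", "),
         " do not belong to Model ", kind, call. = FALSE)
  }
  missing <- setdiff(wanted, names(given))
  if (length(missing)) {
    stop("Model ", kind, " requires parameter(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- vapply(given[wanted], as.numeric, numeric(1))
  validate_params(kind, p)
  p
}

validate_params <- function(kind, params) {
  kind <- match_kind(kind)
  wanted <- model_param_names(kind)
  if (!all(wanted %in% names(params))) {
    stop("Model ", kind, " requires parameter(s) ",
         paste(setdiff(wanted, names(params)), collapse = ", "),
         call. = FALSE)
  }
  p <- params[wanted]
  if (any(!is.finite(p))) {
    stop("non-finite model parameter(s): ",
         paste(wanted[!is.finite(p)], collapse = ", "), call. = FALSE)
  }
  strictly_pos <- intersect(c("k_off", "k_s1", "k_f2"), wanted)
  bad <- strictly_pos[p[strictly_pos] <= 0]
  if (length(bad)) {
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nonneg <- intersect(c("k_s2", "k_i"), wanted)
  bad <- nonneg[p[nonneg] < 0]
  if (length(bad)) {
    stop("parameter(s) must be >= 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

# parameter value or 0 when the kind lacks it
param_or_zero <- function(params, name) {
  if (name %in% names(params)) unname(params[[name]]) else 0
}
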