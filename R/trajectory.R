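# bare recursion core shared by simulate_trajectory and the fitting
# objective: no validation, no data.frame, returns the state vectors
ssm_recur <- function(loads, perf0, keep, k_s2, decay_s, k_i, k_f1,
                      decay_f) {
  n <- length(loads)
  k0 <- (1 - keep) * perf0
  sig <- inh <- prod <- perf <- fat <- numeric(n)
  perf[1] <- perf0
  prod[1] <- k0
  if (n > 1L) {
    for (i in 2:n) {
      perf[i] <- keep * perf[i - 1] + prod[i - 1]
      sig[i]  <- sig[i - 1] * decay_s + loads[i]
      inh[i]  <- k_i * loads[i]
      prod[i] <- k0 + k_s2 * (1 - inh[i]) * sig[i]
      fat[i]  <- fat[i - 1] * decay_f + k_f1 * loads[i]
    }
  }
  list(sig = sig, inh = inh, prod = prod, perf = perf, fat = fat)
}

# model observable (net performance for TF/TIF) from a raw parameter
# vector, for the optimiser's inner loop
ssm_netperf <- function(params, loads, perf0, euler) {
  k_off <- params[["k_off"]]
  keep <- if (euler) 1 - k_off else exp(-k_off)
  st <- ssm_recur(loads, perf0, keep,
                  params[["k_s2"]], exp(-params[["k_s1"]]),
                  param_or_zero(params, "k_i"),
                  param_or_zero(params, "k_f1"),
                  if ("k_f2" %in% names(params)) exp(-params[["k_f2"]])
                  else 1)
  st$perf - st$fat
}

#' Simulate the daily state trajectory of a secondary-signal model
#'
#' Runs the discrete daily recursion. With day-0 state
#' `Signal_0 = Inhib_0 = Fatigue_0 = 0`, `Perf_0 = perf0`, for day i >= 1:
#' \deqn{Signal_i = Signal_{i-1} e^{-k_{s1}} + W_i}
#' \deqn{Inhib_i  = k_i W_i \quad (0 \textrm{ for T/TF})}
#' \deqn{Prod_i   = k_0 + k_{s2} (1 - Inhib_i)\, Signal_i}
#' \deqn{Perf_i   = Perf_{i-1} + Prod_{i-1} - k_{off} Perf_{i-1}}
#' \deqn{Fatigue_i = Fatigue_{i-1} e^{-k_{f2}} + k_{f1} W_i \quad (TF/TIF)}
#' with net performance `Perf_i - Fatigue_i` for TF/TIF and `Perf_i`
#' otherwise. The baseline production \eqn{k_0} is tied to the removal rate
#' by stationarity (`k_0 = k_off * perf0` under the default discretisation),
#' so performance is exactly constant in the absence of training.
#'
#' The inhibition term `1 - Inhib_i` is deliberately not clamped at zero:
#' doses above `1/k_i` legitimately drive marginal production negative,
#' which is what produces the inverted-U steady-state dose-response.
#'
#' @param kind model kind (see [MODEL_KINDS]).
#' @param params named parameter vector for `kind` (see [model_params()]).
#' @param loads numeric vector of daily doses (tu), day 0 first; the day-0
#'   load must be 0.
#' @param perf0 baseline performance (watts), > 0.
#' @param perf_decay one-day removal factor for performance: `"euler"` keeps
#'   `(1 - k_off)` of the previous day's performance (the default, matching
#'   the recursion's production/removal balance), `"exp"` keeps
#'   `exp(-k_off)`. Signal and fatigue always decay by the exact exponential
#'   factor. The two differ by O(k_off^2) per day.
#' @return an `ssm_trajectory`: a `data.frame` with one row per day and
#'   columns `day`, `load_tu`, `signal_tu`, `inhib`, `prod_w_per_day`,
#'   `perf_w`, `fatigue_w`, `netperf_w` (fatigue is identically 0 and
#'   `netperf_w == perf_w` for kinds T and TI).
#' @examples
#' p <- model_params("TI", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
#'                   k_i = 0.0021)
#' tr <- simulate_trajectory("TI", p, loads = c(0, 300, rep(0, 28)),
#'                           perf0 = 250)
#' max(tr$perf_w - 250)
#' @export
simulate_trajectory <- function(kind, params, loads, perf0,
                                perf_decay = c("euler", "exp")) {
  kind <- match_kind(kind)
  perf_decay <- match.arg(perf_decay)
  validate_params(kind, params)
  loads <- as.numeric(loads)
  if (length(loads) < 1L) stop("empty load series", call. = FALSE)
  if (any(!is.finite(loads))) {
    stop("non-finite load at day ", which(!is.finite(loads))[1] - 1L,
         call. = FALSE)
  }
  if (any(loads < 0)) {
    stop("negative load at day ", which(loads < 0)[1] - 1L, call. = FALSE)
  }
  if (loads[1] != 0) {
    stop("load on day 0 must be 0 (W_0 is initialised to 0)", call. = FALSE)
  }
  if (!is.finite(perf0) || perf0 <= 0) {
    stop("perf0 must be a positive number of watts", call. = FALSE)
  }

  k_off <- params[["k_off"]]
  k_s1  <- params[["k_s1"]]
  k_s2  <- params[["k_s2"]]
  k_i   <- param_or_zero(params, "k_i")
  k_f1  <- param_or_zero(params, "k_f1")
  k_f2  <- if ("k_f2" %in% names(params)) params[["k_f2"]] else 1

  n <- length(loads)
  keep <- if (perf_decay == "euler") 1 - k_off else exp(-k_off)
  st <- ssm_recur(loads, perf0, keep, k_s2, exp(-k_s1), k_i, k_f1,
                  exp(-k_f2))
  has_fatigue <- kind %in% c("TF", "TIF")
  if (!has_fatigue) st$fat <- numeric(n)
  out <- data.frame(day = seq.int(0L, n - 1L),
                    load_tu = loads,
                    signal_tu = st$sig,
                    inhib = st$inh,
                    prod_w_per_day = st$prod,
                    perf_w = st$perf,
                    fatigue_w = st$fat,
                    netperf_w = st$perf - st$fat)
  attr(out, "kind") <- kind
  attr(out, "perf_decay") <- perf_decay
  class(out) <- c("ssm_trajectory", "data.frame")
  out
}

#' Model predictions on the measurement days of a series
#'
#' Simulates the model over the full span of the series with `Perf_0` fixed
#' at the first measured performance, then returns the model observable on
#' exactly the measurement days: net performance (performance minus fatigue)
#' for kinds TF and TIF, performance itself for T and TI. A measurement on
#' day i is unaffected by that day's load, since performance on day i uses
#' production from day i - 1; the trial's own 100 tu influence later days
#' only.
#'
#' @inheritParams simulate_trajectory
#' @param series a [training_series()].
#' @return `data.frame` with columns `day` and `predicted_w`, one row per
#'   measurement, in day order.
#' @export
predict_performance <- function(kind, params, series,
                                perf_decay = c("euler", "exp")) {
  validate_series(series)
  if (n_measurements(series) == 0L) {
    stop("series has no performance measurements", call. = FALSE)
  }
  tr <- simulate_trajectory(kind, params, series$load_tu, perf0(series),
                            perf_decay = match.arg(perf_decay))
  idx <- which(!is.na(series$performance_w))
  data.frame(day = series$day[idx], predicted_w = tr$netperf_w[idx])
}

#' @export
print.ssm_trajectory <- function(x, ...) {
  cat(sprintf("Model %s trajectory: %d days\n", attr(x, "kind"), nrow(x)))
  cat(sprintf("  performance %.1f -> %.1f W (peak %.1f W)\n",
              x$netperf_w[1], x$netperf_w[nrow(x)], max(x$netperf_w)))
  NextMethod()
}
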