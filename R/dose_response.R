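#' Steady-state performance under a constant daily dose
#'
#' When the same dose w (tu) is applied every day, the signal converges to
#' `S* = w / (1 - exp(-k_s1))` and performance (sampled daily, after the
#' day's update) to the closed form
#' \deqn{Perf^* = baseline + k_{s2} (1 - k_i w)\, S^* / k_{rem}}
#' where \eqn{k_{rem}} is the one-day removal fraction of performance
#' (`k_off` under the default Euler discretisation) and `k_i = 0` for kinds
#' without inhibition. For TF/TIF the observable subtracts the fatigue
#' steady state `k_f1 w / (1 - exp(-k_f2))`. Iterating
#' [simulate_trajectory()] converges to this value.
#'
#' @inheritParams simulate_trajectory
#' @param dose constant daily dose (tu/day), >= 0.
#' @param baseline baseline performance (watts).
#' @return steady-state performance (watts).
#' @examples
#' p <- model_params("TI", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
#'                   k_i = 0.0021)
#' steady_state_performance("TI", p, dose = 250, baseline = 250)
#' @export
steady_state_performance <- function(kind, params, dose, baseline,
                                     perf_decay = c("euler", "exp")) {
  kind <- match_kind(kind)
  perf_decay <- match.arg(perf_decay)
  validate_params(kind, params)
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("dose must be finite and >= 0", call. = FALSE)
  }
  k_off <- params[["k_off"]]
  k_rem <- if (perf_decay == "euler") k_off else 1 - exp(-k_off)
  if (k_rem <= 0) {
    stop("k_off must be > 0: no steady state without removal",
         call. = FALSE)
  }
  k_s1 <- params[["k_s1"]]
  k_s2 <- params[["k_s2"]]
  k_i <- param_or_zero(params, "k_i")
  s_star <- dose / (1 - exp(-k_s1))
  perf <- baseline + k_s2 * (1 - k_i * dose) * s_star / k_rem
  if (kind %in% c("TF", "TIF")) {
    perf <- perf - param_or_zero(params, "k_f1") * dose /
      (1 - exp(-params[["k_f2"]]))
  }
  perf
}

#' Optimal constant daily training dose
#'
#' For a model with inhibition (`k_i > 0`) the steady-state dose-response
#' is an inverted U: the training term is proportional to
#' `w (1 - k_i w)`, maximised analytically at `w = 1/(2 k_i)`. The default
#' golden-section search maximises [steady_state_performance()] numerically
#' and agrees with the analytic value to well under 0.5 tu.
#'
#' @param params named parameters of a TI (or TIF) model with `k_i > 0`.
#' @param method `"numeric"` (golden-section search, default) or
#'   `"analytic"` (`1/(2 k_i)`).
#' @param kind model kind, default `"TI"`.
#' @param baseline baseline performance used by the numeric search (the
#'   optimiser's location does not depend on it).
#' @inheritParams simulate_trajectory
#' @return optimal dose (tu/day).
#' @examples
#' optimal_dose(c(k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
#'                k_i = 0.0021))
#' @export
optimal_dose <- function(params, method = c("numeric", "analytic"),
                         kind = "TI", baseline = 250,
                         perf_decay = c("euler", "exp")) {
  method <- match.arg(method)
  perf_decay <- match.arg(perf_decay)
  k_i <- param_or_zero(params, "k_i")
  if (k_i <= 0) {
    stop("optimal dose requires k_i > 0 (no interior optimum otherwise)",
         call. = FALSE)
  }
  if (method == "analytic") return(1 / (2 * k_i))
  opt <- stats::optimize(
    function(w) steady_state_performance(kind, params, w, baseline,
                                         perf_decay = perf_decay),
    interval = c(0, 1 / k_i), maximum = TRUE, tol = 1e-6)
  opt$maximum
}

#' Steady-state dose-response curve
#'
#' Evaluates [steady_state_performance()] on a dose grid and records the
#' grid optimum. For Model TI with `k_i > 0` the curve is an inverted U
#' through `(0, baseline)` with interior maximum near `1/(2 k_i)`; for
#' Model T it increases without bound.
#'
#' @inheritParams steady_state_performance
#' @param dose_grid increasing vector of non-negative doses (tu/day).
#' @return a `dose_response_curve`: `data.frame` with columns `dose_tu`,
#'   `perf_w`; attributes `optimum_dose` and `optimum_performance` hold the
#'   grid maximum.
#' @export
dose_response_curve <- function(kind, params, dose_grid, baseline,
                                perf_decay = c("euler", "exp")) {
  if (length(dose_grid) == 0L) stop("empty dose grid", call. = FALSE)
  if (any(dose_grid < 0) || is.unsorted(dose_grid, strictly = TRUE)) {
    stop("dose grid must be non-negative and strictly increasing",
         call. = FALSE)
  }
  perf <- steady_state_performance(kind, params, dose_grid, baseline,
                                   perf_decay = match.arg(perf_decay))
  out <- data.frame(dose_tu = dose_grid, perf_w = perf)
  i <- which.max(perf)
  attr(out, "optimum_dose") <- dose_grid[i]
  attr(out, "optimum_performance") <- perf[i]
  attr(out, "kind") <- match_kind(kind)
  class(out) <- c("dose_response_curve", "data.frame")
  out
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf(
    "Model %s steady-state dose-response: %d doses in [%g, %g] tu/day\n",
    attr(x, "kind"), nrow(x), min(x$dose_tu), max(x$dose_tu)))
  cat(sprintf("  optimum %.1f W at %.1f tu/day\n",
              attr(x, "optimum_performance"), attr(x, "optimum_dose")))
  invisible(x)
}

#' Performance response to one, two consecutive, or two spaced sessions
#'
#' Simulates the gain in performance over baseline after a training session
#' of `dose` tu performed on day 1, under three schedules: the session
#' alone (`"single"`), the same session repeated the next day (`"plus1"`)
#' and repeated two days after (`"plus2"`). All scenarios start from rest
#' (no prior training). Under Model T the responses superpose exactly;
#' under TI a second session inhibits the transformation of the residual
#' signal of the first, so the combined peak gain falls short of the sum of
#' single-session peaks.
#'
#' @inheritParams simulate_trajectory
#' @param dose session dose (tu), > 0.
#' @param baseline baseline performance (watts).
#' @param scenarios subset of `c("single", "plus1", "plus2")`.
#' @param horizon number of days simulated (>= 30).
#' @return `data.frame` with columns `scenario`, `day`, `delta_perf_w` (the
#'   model observable minus baseline); attribute `"summary"` is a
#'   `data.frame` per scenario with `n_sessions`, `peak_gain_w`,
#'   `peak_day`, `per_session_gain_w` (peak gain divided by the number of
#'   sessions).
#' @export
session_interaction <- function(kind, params, dose, baseline = 250,
                                scenarios = c("single", "plus1", "plus2"),
                                horizon = 120L,
                                perf_decay = c("euler", "exp")) {
  kind <- match_kind(kind)
  perf_decay <- match.arg(perf_decay)
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (horizon < 30L) stop("horizon must be at least 30 days", call. = FALSE)
  known <- c(single = 1L, plus1 = 2L, plus2 = 3L)  # session days
  bad <- setdiff(scenarios, names(known))
  if (length(bad)) {
    stop("unknown scenario(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  res <- lapply(scenarios, function(sc) {
    loads <- numeric(horizon + 1L)
    loads[1L + 1L] <- dose                      # day 1
    if (sc != "single") loads[known[[sc]] + 1L] <- dose
    tr <- simulate_trajectory(kind, params, loads, baseline,
                              perf_decay = perf_decay)
    data.frame(scenario = sc, day = tr$day,
               delta_perf_w = tr$netperf_w - baseline)
  })
  out <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(res, function(d) {
    i <- which.max(d$delta_perf_w)
    ns <- if (d$scenario[1] == "single") 1L else 2L
    data.frame(scenario = d$scenario[1], n_sessions = ns,
               peak_gain_w = d$delta_perf_w[i], peak_day = d$day[i],
               per_session_gain_w = d$delta_perf_w[i] / ns)
  }))
  attr(out, "summary") <- summ
  out
}
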