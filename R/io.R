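#' Read a daily load/performance series from CSV
#'
#' The file format is one row per day with header
#' `day,load_tu,performance_w`: `day` an integer running 0..N in steps of
#' 1, `load_tu` a non-negative decimal, `performance_w` a decimal or empty
#' on days without a measurement. Validation errors name the offending file
#' row (header = row 1) and column.
#'
#' @param path path to the CSV file.
#' @return a [training_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  expected <- c("day", "load_tu", "performance_w")
  if (!identical(names(raw), expected)) {
    stop("bad header in ", path, ": expected '",
         paste(expected, collapse = ","), "', got '",
         paste(names(raw), collapse = ","), "'", call. = FALSE)
  }
  n <- nrow(raw)
  parse_col <- function(x, col, allow_empty = FALSE) {
    empty <- !nzchar(x)
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!empty & is.na(v))
    if (length(bad)) {
      stop("malformed value '", x[bad[1]], "' in column ", col, " at row ",
           bad[1] + 1L, " of ", path, call. = FALSE)
    }
    if (!allow_empty && any(empty)) {
      stop("empty value in column ", col, " at row ",
           which(empty)[1] + 1L, " of ", path, call. = FALSE)
    }
    v
  }
  day <- parse_col(raw$day, "day")
  load <- parse_col(raw$load_tu, "load_tu")
  perf <- parse_col(raw$performance_w, "performance_w", allow_empty = TRUE)
  if (!identical(as.integer(day), seq.int(0L, n - 1L))) {
    i <- which(day != seq.int(0L, n - 1L))[1]
    stop("days must run 0..N in steps of 1: gap or misorder at row ",
         i + 1L, " of ", path, " (day ", day[i], ")", call. = FALSE)
  }
  if (any(load < 0)) {
    stop("negative load at row ", which(load < 0)[1] + 1L, " of ", path,
         call. = FALSE)
  }
  if (sum(!is.na(perf)) < 2L) {
    stop("fewer than 2 performance measurements in ", path, call. = FALSE)
  }
  training_series(load = load, performance = perf, day = day)
}

#' @rdname read_series
#' @param series a [training_series()].
#' @export
write_series <- function(series, path) {
  validate_series(series)
  df <- data.frame(day = series$day,
                   load_tu = series$load_tu,
                   performance_w = series$performance_w)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a trajectory decomposition to CSV
#'
#' One row per day with the full state decomposition: columns `day`,
#' `load_tu`, `signal_tu`, `inhib`, `prod_w_per_day`, `perf_w`,
#' `fatigue_w`, `netperf_w`.
#'
#' @param trajectory an `ssm_trajectory` from [simulate_trajectory()].
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ssm_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("trainsignal"))
}

fit_to_list <- function(fit) {
  list(package = "trainsignal",
       version = pkg_version(),
       kind = fit$kind,
       params = as.list(fit$params),
       perf0 = fit$perf0,
       n = fit$n,
       p = fit$p,
       rss = fit$rss,
       loglik = fit$loglik,
       aicc = aicc(fit),
       converged = fit$converged,
       n_starts = fit$n_starts,
       seed = fit$seed,
       perf_decay = fit$perf_decay,
       measurement_days = fit$measurement_days,
       fitted = fit$fitted,
       residuals = fit$residuals)
}

#' Serialize fits and selection tables to JSON
#'
#' JSON reports keep full numeric precision and carry the package version
#' and the resolved configuration (seed, starts, discretisation) for
#' provenance.
#'
#' @param fit an `ssm_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "ssm_fit"))
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @param tab a `selection_table` from [compare_models()].
#' @export
write_selection_json <- function(tab, path) {
  stopifnot(inherits(tab, "selection_table"))
  fits <- attr(tab, "fits")
  body <- list(package = "trainsignal",
               version = pkg_version(),
               models = lapply(seq_len(nrow(tab)), function(i) {
                 c(as.list(tab[i, , drop = FALSE]),
                   list(params = as.list(fits[[tab$kind[i]]]$params)))
               }),
               nested_tests = attr(tab, "nested_tests"))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Read model parameters from a JSON file
#'
#' Expects a flat object of parameter names to values, e.g.
#' `{"k_off": 0.0305, "k_s1": 0.292, "k_s2": 0.0074, "k_i": 0.0021}`.
#'
#' @param path path to the JSON file.
#' @param kind model kind the parameters must match.
#' @return validated named parameter vector.
#' @export
read_params_json <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$params)) obj <- obj$params   # accept fit JSON too
  p <- unlist(obj[names(obj) %in% model_param_names(kind)])
  do.call(model_params, c(list(kind = kind), as.list(p)))
}
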