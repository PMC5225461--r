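#' Goodness-of-fit statistics for a fitted model
#'
#' Computes the coefficient of determination `r2 = 1 - RSS/TSS` (TSS about
#' the mean of the measurements), the adjusted coefficient
#' `adj_r2 = 1 - (1 - r2) (n - 1)/(n - p - 1)`, the mean square error on
#' performance estimation `se = RSS/(n - p)` (watts squared) and the overall
#' significance of the fit from the regression analysis-of-variance F
#' statistic `[(TSS - RSS)/p] / [RSS/(n - p - 1)]` on `(p, n - p - 1)`
#' degrees of freedom.
#'
#' @param fit an `ssm_fit` from [fit_model()].
#' @return list with `r2`, `adj_r2`, `se`, `f_stat`, `overall_p`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "ssm_fit"))
  n <- fit$n
  p <- fit$p
  if (n <= p + 1L) stop("n must exceed p + 1", call. = FALSE)
  obs <- fit$observed
  tss <- sum((obs - mean(obs))^2)
  rss <- fit$rss
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f_stat <- ((tss - rss) / p) / (rss / (n - p - 1))
  list(r2 = r2,
       adj_r2 = adj_r2,
       se = rss / (n - p),
       f_stat = f_stat,
       overall_p = stats::pf(f_stat, p, n - p - 1, lower.tail = FALSE))
}

#' Bias-corrected Akaike information criterion
#'
#' `AICc = -2 ln(L) + 2p + 2p(p+1)/(n - p - 1)`, with the profiled Gaussian
#' log-likelihood of [negative_log_likelihood()] and `p` the kind's
#' parameter count (the profiled error variance is not counted).
#'
#' @param fit an `ssm_fit`, or a log-likelihood value if `n` and `p` are
#'   given.
#' @param n,p sample size and parameter count (only when `fit` is a bare
#'   log-likelihood).
#' @return the AICc value.
#' @export
aicc <- function(fit, n = NULL, p = NULL) {
  if (inherits(fit, "ssm_fit")) {
    loglik <- fit$loglik
    n <- fit$n
    p <- fit$p
  } else {
    loglik <- fit
    if (is.null(n) || is.null(p)) {
      stop("supply n and p with a bare log-likelihood", call. = FALSE)
    }
  }
  if (n <= p + 1L) {
    stop("AICc undefined: need n > p + 1", call. = FALSE)
  }
  -2 * loglik + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Akaike weights from a set of AICc values
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`. The weights are shift-invariant, sum to
#' one, and quantify the weight of evidence for each candidate model.
#'
#' @param aicc_values numeric vector (length >= 2) of AICc values.
#' @return numeric vector of weights, same order and names as the input.
#' @examples
#' akaike_weights(c(T = 328.04, TI = 291.07, TF = 332.74, TIF = 293.96))
#' @export
akaike_weights <- function(aicc_values) {
  x <- as.numeric(aicc_values)
  if (length(x) < 2L) stop("need at least 2 AICc values", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite AICc value", call. = FALSE)
  delta <- x - min(x)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  names(w) <- names(aicc_values)
  w
}

ssm_nestings <- list(c("T", "TI"), c("T", "TF"), c("TI", "TIF"),
                     c("TF", "TIF"))

#' F-ratio test between nested model fits
#'
#' Tests whether the decrease in RSS from the reduced to the full model is
#' larger than expected from the extra parameters:
#' `F = [(RSS_red - RSS_full)/(p_full - p_red)] / [RSS_full/(n - p_full)]`
#' on `(p_full - p_red, n - p_full)` degrees of freedom. The nested pairs
#' are T in TI, T in TF, TI in TIF and TF in TIF. A negative numerator
#' (possible only if the full fit failed to reach the reduced optimum)
#' clamps F to 0 and the p-value to 1.
#'
#' @param reduced,full `ssm_fit` objects on the same series.
#' @return list with `f_stat`, `df1`, `df2`, `p_value`.
#' @export
nested_f_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "ssm_fit"), inherits(full, "ssm_fit"))
  pair_ok <- any(vapply(ssm_nestings, function(pr) {
    identical(pr, c(reduced$kind, full$kind))
  }, logical(1)))
  if (!pair_ok) {
    stop("Model ", reduced$kind, " is not nested in Model ", full$kind,
         call. = FALSE)
  }
  if (reduced$n != full$n) {
    stop("fits compare different numbers of measurements", call. = FALSE)
  }
  n <- full$n
  df1 <- full$p - reduced$p
  df2 <- n - full$p
  num <- (reduced$rss - full$rss) / df1
  den <- full$rss / df2
  f_stat <- max(num / den, 0)
  list(f_stat = f_stat, df1 = df1, df2 = df2,
       p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE))
}

#' Fit and compare the four model kinds on one series
#'
#' Fits Models T, TI, TF and TIF and assembles the full model-selection
#' battery: per-model goodness of fit, AICc, AICc differences and Akaike
#' weights, plus the nested F-ratio tests. The optimum of Model T seeds the
#' TI and TF fits, and the TI/TF optima seed TIF, so the nesting inequality
#' RSS(full) <= RSS(reduced) holds at the returned optima.
#'
#' @inheritParams fit_model
#' @return a `selection_table`: a `data.frame` with one row per kind and
#'   columns `kind`, `n`, `p`, `rss`, `r2`, `adj_r2`, `se`, `loglik`,
#'   `aicc`, `delta_aicc`, `weight`, `overall_p`, `converged`; the fits are
#'   in `attr(, "fits")` and the nested tests in `attr(, "nested_tests")`.
#' @export
compare_models <- function(series, n_starts = 20L, seed = 1L,
                           bounds = default_bounds(),
                           perf_decay = c("euler", "exp")) {
  perf_decay <- match.arg(perf_decay)
  fits <- list()
  fits$T <- fit_model("T", series, n_starts = n_starts, seed = seed,
                      bounds = bounds, perf_decay = perf_decay)
  fits$TI <- fit_model("TI", series, n_starts = n_starts, seed = seed + 1L,
                       bounds = bounds, perf_decay = perf_decay,
                       extra_starts = list(fits$T$params))
  fits$TF <- fit_model("TF", series, n_starts = n_starts, seed = seed + 2L,
                       bounds = bounds, perf_decay = perf_decay,
                       extra_starts = list(fits$T$params))
  fits$TIF <- fit_model("TIF", series, n_starts = n_starts,
                        seed = seed + 3L, bounds = bounds,
                        perf_decay = perf_decay,
                        extra_starts = list(fits$TI$params, fits$TF$params))

  gofs <- lapply(fits, goodness_of_fit)
  aiccs <- vapply(fits, aicc, numeric(1))
  delta <- aiccs - min(aiccs)
  w <- akaike_weights(aiccs)

  tab <- data.frame(
    kind = names(fits),
    n = vapply(fits, `[[`, integer(1), "n"),
    p = vapply(fits, `[[`, integer(1), "p"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    r2 = vapply(gofs, `[[`, numeric(1), "r2"),
    adj_r2 = vapply(gofs, `[[`, numeric(1), "adj_r2"),
    se = vapply(gofs, `[[`, numeric(1), "se"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = aiccs,
    delta_aicc = delta,
    weight = w,
    overall_p = vapply(gofs, `[[`, numeric(1), "overall_p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)

  tests <- do.call(rbind, lapply(ssm_nestings, function(pr) {
    ft <- nested_f_test(fits[[pr[1]]], fits[[pr[2]]])
    data.frame(reduced = pr[1], full = pr[2], f_stat = ft$f_stat,
               df1 = ft$df1, df2 = ft$df2, p_value = ft$p_value)
  }))

  attr(tab, "fits") <- fits
  attr(tab, "nested_tests") <- tests
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' Render a selection table as aligned text
#'
#' Rows Adj.R2, AICc and w(AICc), one column per model, with numbers at the
#' conventional reporting precision (3, 2 and 3 decimals respectively).
#'
#' @param tab a `selection_table`.
#' @return character vector of lines.
#' @export
render_selection <- function(tab) {
  stopifnot(inherits(tab, "selection_table"))
  cols <- paste0("Model ", tab$kind)
  fmt_row <- function(label, values) {
    sprintf("%-10s %s", label,
            paste(sprintf("%10s", values), collapse = " "))
  }
  c(fmt_row("", cols),
    fmt_row("Adj.R2", sprintf("%.3f", tab$adj_r2)),
    fmt_row("AICc", sprintf("%.2f", tab$aicc)),
    fmt_row("w(AICc)", sprintf("%.3f", tab$weight)))
}

#' @export
print.selection_table <- function(x, ...) {
  cat(render_selection(x), sep = "\n")
  tests <- attr(x, "nested_tests")
  if (!is.null(tests)) {
    cat("\nNested F-ratio tests:\n")
    for (i in seq_len(nrow(tests))) {
      cat(sprintf("  %s -> %s: F(%d, %d) = %.2f, P = %.3g\n",
                  tests$reduced[i], tests$full[i], tests$df1[i],
                  tests$df2[i], tests$f_stat[i], tests$p_value[i]))
    }
  }
  invisible(x)
}
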