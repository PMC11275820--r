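# Pairwise Granger-causality core. Conditional OLS on lagged designs with no
# intercept (the autoregressive models are specified without one and all
# signals here are baseline-corrected / zero-mean), residual-variance
# log-ratio GC values, and nested-model F tests.

# Build the lagged design for rows P+1..n. Returns list(y, X).
lagged_design <- function(x, lag_order, extra = NULL) {
  n <- length(x)
  idx <- (lag_order + 1):n
  own <- vapply(seq_len(lag_order), function(p) x[idx - p], numeric(length(idx)))
  X <- own
  if (!is.null(extra)) {
    src <- vapply(seq_len(lag_order), function(p) extra[idx - p],
                  numeric(length(idx)))
    X <- cbind(own, src)
  }
  list(y = x[idx], X = matrix(X, nrow = length(idx)))
}

check_series <- function(x, lag_order, name) {
  if (length(x) <= 3 * lag_order) {
    abort(sprintf("`%s` too short: need length > 3 * lag_order.", name))
  }
  if (!all(is.finite(x))) abort(sprintf("`%s` contains non-finite values.", name))
  if (var(x) < 1e-12) {
    abort(sprintf("Degenerate input: `%s` is (near-)constant.", name))
  }
}

ols_fit <- function(y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("Degenerate input: rank-deficient lagged design.")
  }
  coef <- qr.coef(qx, y)
  resid <- y - X %*% coef
  list(coefficients = as.numeric(coef),
       residual_variance = mean(resid^2),
       rss = sum(resid^2), n_used = length(y))
}

#' Fit a univariate autoregressive model by least squares
#'
#' Through-the-origin OLS of `x_t` on its `lag_order` own lags, using rows
#' `lag_order + 1 .. n` (conditional likelihood, no pre-sample padding).
#'
#' @param x Numeric series.
#' @param lag_order Model order P; requires `length(x) > 3 * P`.
#' @return List with `coefficients` (length P), `residual_variance` (mean
#'   squared residual over the n - P usable rows), `rss`, `n_used`.
#' @export
fit_ar <- function(x, lag_order) {
  lag_order <- check_positive_int(lag_order, "lag_order")
  check_series(x, lag_order, "x")
  d <- lagged_design(x, lag_order)
  ols_fit(d$y, d$X)
}

#' Fit a bivariate autoregressive model by least squares
#'
#' As [fit_ar()] with the stacked design `[own lags | source lags]`: the
#' target is regressed on `lag_order` lags of itself and of the source.
#'
#' @param x_target,x_source Equal-length numeric series.
#' @inheritParams fit_ar
#' @return As [fit_ar()]; `coefficients` has length `2 * lag_order`
#'   (own lags first).
#' @export
fit_var2 <- function(x_target, x_source, lag_order) {
  lag_order <- check_positive_int(lag_order, "lag_order")
  if (length(x_target) != length(x_source)) {
    abort("`x_target` and `x_source` must have equal length.")
  }
  check_series(x_target, lag_order, "x_target")
  check_series(x_source, lag_order, "x_source")
  d <- lagged_design(x_target, lag_order, extra = x_source)
  ols_fit(d$y, d$X)
}

gc_one_direction <- function(target, source, lag_order, alpha,
                             source_name, target_name) {
  uni <- fit_ar(target, lag_order)
  bi <- fit_var2(target, source, lag_order)
  m <- uni$n_used
  df2 <- m - 2 * lag_order
  f_stat <- ((uni$rss - bi$rss) / lag_order) / (bi$rss / df2)
  p_value <- pf(f_stat, lag_order, df2, lower.tail = FALSE)
  tibble::tibble(
    source = source_name, target = target_name, lag_order = lag_order,
    var_uni = uni$residual_variance, var_bi = bi$residual_variance,
    gc_value = log(uni$residual_variance / bi$residual_variance),
    f_stat = f_stat, p_value = p_value,
    significant = p_value < alpha, degenerate = FALSE)
}

#' Granger-causality test for one ordered channel pair (both directions)
#'
#' Quantifies directed influence as the log ratio of the univariate to the
#' bivariate residual variance, `GC = ln(var_uni / var_bi)`, and gates
#' significance with the nested-OLS F test of "all source-lag coefficients are
#' zero" on `(P, n - 3P)` degrees of freedom.
#'
#' @param x_i,x_j Equal-length numeric series for channels i and j.
#' @param lag_order Lag order P of both fits.
#' @param alpha Significance level of the F test.
#' @param names Length-2 labels for (i, j) used in the output.
#' @return Tibble with two rows — influence `j -> i` first, then `i -> j` —
#'   and columns `source`, `target`, `lag_order`, `var_uni`, `var_bi`,
#'   `gc_value`, `f_stat`, `p_value`, `significant`, `degenerate`.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = 0.5), 300))
#' y <- 0.8 * dplyr::lag(x, 1, default = 0) + rnorm(300)
#' granger_pair(y, x, lag_order = 1)
#' @export
granger_pair <- function(x_i, x_j, lag_order = 2, alpha = 0.05,
                         names = c("i", "j")) {
  dplyr::bind_rows(
    gc_one_direction(x_i, x_j, lag_order, alpha, names[2], names[1]),
    gc_one_direction(x_j, x_i, lag_order, alpha, names[1], names[2]))
}

empty_gc_tibble <- function() {
  tibble::tibble(source = character(), target = character(),
                 lag_order = integer(), var_uni = double(), var_bi = double(),
                 gc_value = double(), f_stat = double(), p_value = double(),
                 significant = logical(), degenerate = logical())
}

degenerate_gc_row <- function(source, target, lag_order) {
  tibble::tibble(source = source, target = target, lag_order = lag_order,
                 var_uni = NA_real_, var_bi = NA_real_, gc_value = NA_real_,
                 f_stat = NA_real_, p_value = NA_real_,
                 significant = NA, degenerate = TRUE)
}

#' Granger-causality tests over all ordered channel pairs
#'
#' Runs [granger_pair()] for every ordered pair of columns of `X`. Degenerate
#' channels (constant series) are flagged in the `degenerate` column rather
#' than silently zeroed; their test statistics are `NA`.
#'
#' @param X Numeric matrix `[L x C]`, one column per channel.
#' @param lag_order Lag order P (`L > 3 * P` required).
#' @param alpha Significance level.
#' @param p_adjust Multiple-testing correction applied across the
#'   `C * (C - 1)` tests before gating significance; `"none"` (default,
#'   matching the framework's usage) or any method of [stats::p.adjust()].
#' @return Tidy tibble, one row per ordered (source, target) pair, with the
#'   columns of [granger_pair()].
#' @export
granger_matrix <- function(X, lag_order = 2, alpha = 0.05, p_adjust = "none") {
  X <- as.matrix(X)
  C <- ncol(X)
  if (C < 2) return(empty_gc_tibble())
  if (nrow(X) <= 3 * lag_order) abort("Need nrow(X) > 3 * lag_order.")
  labels <- colnames(X) %||% as.character(seq_len(C))
  degenerate <- vapply(seq_len(C), function(c) var(X[, c]) < 1e-12, logical(1))
  if (any(degenerate)) {
    warn(sprintf("Degenerate (constant) channels flagged: %s",
                 paste(labels[degenerate], collapse = ", ")))
  }
  rows <- list()
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      if (i == j) next
      rows[[length(rows) + 1]] <-
        if (degenerate[i] || degenerate[j]) {
          degenerate_gc_row(labels[j], labels[i], lag_order)
        } else {
          gc_one_direction(X[, i], X[, j], lag_order, alpha,
                           labels[j], labels[i])
        }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (p_adjust != "none") {
    ok <- !out$degenerate
    out$p_value[ok] <- stats::p.adjust(out$p_value[ok], method = p_adjust)
    out$significant[ok] <- out$p_value[ok] < alpha
  }
  out
}

#' Select an autoregressive lag order by BIC
#'
#' Scans univariate AR fits of order `1..p_max` and returns the order
#' minimising the Bayesian information criterion (Gaussian likelihood on the
#' common usable rows so orders are comparable).
#'
#' @param x Numeric series.
#' @param p_max Largest order scanned.
#' @return Integer lag order.
#' @export
select_lag_bic <- function(x, p_max = 6) {
  p_max <- check_positive_int(p_max, "p_max")
  n <- length(x)
  if (n <= 3 * p_max) abort("Series too short for `p_max`.")
  m <- n - p_max  # common estimation sample across candidate orders
  bic <- vapply(seq_len(p_max), function(p) {
    xx <- x[(p_max - p + 1):n]
    d <- lagged_design(xx, p)
    fit <- ols_fit(d$y, d$X)
    m * log(fit$rss / m) + p * log(m)
  }, numeric(1))
  which.min(bic)
}
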