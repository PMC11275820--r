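test_that("AR fits recover generating parameters", {
  set.seed(1)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 20000))
  fit <- fit_ar(x, 1)
  expect_gt(fit$coefficients[1], 0.75)
  expect_lt(fit$coefficients[1], 0.85)
  expect_equal(fit$residual_variance, 1, tolerance = 0.05)

  w <- rnorm(3000)
  fw <- fit_ar(w, 2)
  expect_equal(fw$residual_variance, var(w), tolerance = 0.05)

  expect_error(fit_ar(rep(1, 100), 2), "constant")
})

test_that("bivariate fits respect nesting and recover coupling", {
  set.seed(2)
  x <- rnorm(2000)
  y <- 0.9 * c(0, x[-2000]) + rnorm(2000)
  uni <- fit_ar(y, 1)
  bi <- fit_var2(y, x, 1)
  expect_lte(bi$residual_variance, uni$residual_variance + 1e-9)
  expect_equal(bi$residual_variance, 1, tolerance = 0.05)
  expect_lt(abs(bi$coefficients[1]), 0.1)   # own lag ~ 0
  expect_equal(bi$coefficients[2], 0.9, tolerance = 0.1)

  # identical source adds nothing but cannot hurt in-sample
  z <- as.numeric(stats::arima.sim(list(ar = 0.5), 500))
  expect_lte(fit_var2(z, z + rnorm(500, sd = 1e-6), 1)$residual_variance,
             fit_ar(z, 1)$residual_variance + 1e-6)

  a <- rnorm(2000)
  b <- rnorm(2000)
  expect_true(all(abs(fit_var2(a, b, 2)$coefficients) < 3 / sqrt(2000) * 1.5))
})

test_that("granger_pair matches the brute-force least-squares oracle", {
  set.seed(3)
  for (rep in 1:30) {
    P <- sample(1:3, 1)
    n <- sample(50:200, 1)
    x <- as.numeric(stats::arima.sim(list(ar = 0.4), n))
    y <- 0.3 * c(rep(0, P), x[seq_len(n - P)]) + rnorm(n)
    res <- granger_pair(y, x, lag_order = P)
    expect_equal(res$gc_value[1], oracle_gc_value(y, x, P), tolerance = 1e-8)
    expect_equal(res$gc_value[2], oracle_gc_value(x, y, P), tolerance = 1e-8)
  }
})

test_that("directed coupling is detected in the right direction", {
  detected <- vapply(1:100, function(s) {
    sp <- var_spec(2, 1, coupling = data.frame(source = 1, target = 2,
                                               lag = 1, coefficient = 0.9),
                   seed = s)
    x <- simulate_var(sp, 2000)
    res <- granger_pair(x[, 2], x[, 1], lag_order = 1,
                        names = c("y", "x"))
    res$significant[1] && !res$significant[2]
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("nesting invariant holds on random pairs", {
  set.seed(4)
  for (rep in 1:20) {
    x <- rnorm(100)
    y <- rnorm(100)
    res <- granger_pair(x, y, lag_order = 2)
    expect_true(all(res$var_bi <= res$var_uni + 1e-9))
    expect_true(all(res$gc_value >= -1e-9))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  }
})

test_that("granger_matrix covers all ordered pairs consistently", {
  set.seed(5)
  X <- matrix(rnorm(400), 100, 4)
  gm <- granger_matrix(X, lag_order = 2)
  expect_equal(nrow(gm), 12)
  pair <- granger_pair(X[, 1], X[, 3], lag_order = 2, names = c("1", "3"))
  row <- gm[gm$source == "3" & gm$target == "1", ]
  expect_equal(row$gc_value, pair$gc_value[1])
  expect_equal(row$f_stat, pair$f_stat[1])

  expect_equal(nrow(granger_matrix(X[, 1, drop = FALSE], 2)), 0)
})

test_that("degenerate channels are flagged, not silently zeroed", {
  X <- cbind(rnorm(100), rep(2, 100), rnorm(100))
  expect_warning(gm <- granger_matrix(X, lag_order = 1), "Degenerate")
  bad <- gm[gm$source == "2" | gm$target == "2", ]
  expect_true(all(bad$degenerate))
  expect_true(all(is.na(bad$gc_value)))
  good <- gm[!(gm$source == "2" | gm$target == "2"), ]
  expect_false(any(good$degenerate))
})

test_that("a planted two-edge network is recovered", {
  sp <- var_spec(4, 1, coupling = data.frame(source = c(1, 3),
                                             target = c(2, 4),
                                             lag = 1, coefficient = 0.6),
                 seed = 6)
  x <- simulate_var(sp, 2000)
  gm <- granger_matrix(x, lag_order = 1)
  sig <- gm[which(gm$significant), c("source", "target")]
  expect_true(all(c("1", "3") %in% sig$source))
  hits <- paste(sig$source, sig$target) %in% c("1 2", "3 4")
  expect_true(all(paste(c("1", "3"), c("2", "4")) %in%
                    paste(sig$source, sig$target)))
  expect_lte(sum(!hits), 1)
})

test_that("BIC lag scan finds a low true order", {
  set.seed(7)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), 1000))
  expect_equal(select_lag_bic(x, 5), 1)
})

test_that("Benjamini-Hochberg option reduces significant calls", {
  set.seed(8)
  X <- matrix(rnorm(1500), 250, 6)
  raw <- granger_matrix(X, lag_order = 1)
  adj <- granger_matrix(X, lag_order = 1, p_adjust = "BH")
  expect_lte(sum(adj$significant), sum(raw$significant))
})
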