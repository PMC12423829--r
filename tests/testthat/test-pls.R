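test_that("PLS at full rank reproduces ordinary least squares", {
  set.seed(41)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("v", 1:6)
  y <- as.numeric(X %*% c(1, -2, 0.5, 0, 3, -1) + 4 + rnorm(40, 0, 0.1))
  m <- fit_pls(X, y, n_lv = 6)
  ols <- stats::lm(y ~ X)
  expect_equal(unname(m$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-8)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-8)

  # exact linear response: R2 = 1, tiny residuals
  y2 <- as.numeric(X %*% rep(1, 6) + 2)
  m2 <- fit_pls(X, y2, n_lv = 6)
  st <- calibrate_stats(m2, X, y2)
  expect_equal(st$r2, 1, tolerance = 1e-10)
  expect_lt(max(abs(predict(m2, X) - y2)), 1e-8)

  # constant response: zero coefficients, intercept = mean
  m3 <- fit_pls(X, rep(5, 40), n_lv = 2)
  expect_equal(unname(m3$coefficients), rep(0, 6))
  expect_equal(m3$intercept, 5)

  expect_error(fit_pls(X, y, n_lv = 7), "rank")
})

test_that("calibration statistics follow their formulas on a hand set", {
  # 6-point dataset, 1 LV; spreadsheet-style oracle below
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9)
  m <- fit_pls(X, y, n_lv = 1)
  st <- calibrate_stats(m, X, y)
  fit <- stats::lm(y ~ X)
  sse <- sum(residuals(fit)^2)
  ssy <- sum((y - mean(y))^2)
  expect_equal(st$r2, 1 - sse / ssy, tolerance = 1e-12)
  expect_equal(st$rmsec, sqrt(sse / 6), tolerance = 1e-12)
  expect_equal(st$sec, sqrt(sse / (6 - 1 - 1)), tolerance = 1e-12)
  expect_equal(st$f_stat, ((ssy - sse) / 1) / (sse / 4), tolerance = 1e-12)

  # mean-only prediction gives R2 = 0
  m0 <- fit_pls(X, rep(c(2, 4), 3), n_lv = 1)
  st0 <- calibrate_stats(m0, matrix(rep(3.5, 6), ncol = 1),
                         rep(c(2, 4), 3))
  expect_equal(st0$r2, 0, tolerance = 1e-9)
})

test_that("LOO cross-validation equals the brute-force refit oracle", {
  set.seed(43)
  X <- matrix(rnorm(15 * 3), 15, 3)
  y <- as.numeric(X %*% c(1, 1, -1) + rnorm(15, 0, 0.4))
  cv <- loo_cv(X, y, n_lv = 2)
  # independent oracle: explicit per-compound refit
  pred <- vapply(1:15, function(i) {
    mi <- fit_pls(X[-i, ], y[-i], n_lv = 2)
    predict(mi, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cv$predictions, pred, tolerance = 1e-12)
  expect_equal(cv$press_cv, sum((y - pred)^2), tolerance = 1e-12)
  expect_equal(cv$q2, 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(cv$rmsecv, sqrt(cv$press_cv / 15), tolerance = 1e-12)

  # n = 3, 1 LV: three hand-enumerable leave-one-out residuals
  X3 <- matrix(c(0, 1, 2), ncol = 1)
  y3 <- c(0.1, 1.0, 2.2)
  cv3 <- loo_cv(X3, y3, n_lv = 1)
  press3 <- sum(vapply(1:3, function(i) {
    co <- stats::coef(stats::lm(y3[-i] ~ X3[-i, ]))
    (y3[i] - (co[1] + co[2] * X3[i, ]))^2
  }, numeric(1)))
  expect_equal(cv3$press_cv, press3, tolerance = 1e-10)
})

test_that("strong planted signal gives high Q2, permuted responses do not", {
  fx <- fx_field()
  pr <- prune_columns(fx$matrix, fx$planted$y)
  s <- pls_summary(pr, fx$planted$y)
  expect_gt(s$q2, 0.9)
  expect_lte(s$q2, s$r2 + 1e-9)
  yr <- y_randomization(pr[, 1:40], fx$planted$y, n_lv = 2, n_perm = 20,
                        seed = 5)
  expect_gte(mean(yr <= 0.2), 0.9)
})

test_that("external validation follows its formula", {
  set.seed(44)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- as.numeric(X %*% c(2, -1, 1) + 5)
  m <- fit_pls(X[1:24, ], y[1:24], n_lv = 3)
  # perfect prediction
  expect_equal(external_validation(m, X[25:30, ], y[25:30], mean(y[1:24])),
               1, tolerance = 1e-9)
  # 4-point arithmetic oracle
  yt <- c(1, 2, 3, 4); yh <- c(1.5, 2.5, 2.5, 4.5); ytr <- 2
  r2p <- 1 - sum((yt - yh)^2) / sum((yt - ytr)^2)
  mfake <- structure(list(coefficients = c(a = 1), intercept = 0,
                          n_lv = 1), class = "pls_model")
  expect_equal(external_validation(mfake, matrix(yh, ncol = 1,
                                                 dimnames = list(NULL, "a")),
                                   yt, ytr), r2p, tolerance = 1e-12)
  expect_error(external_validation(m, X[0, ], numeric(0), 2), "empty")
})

test_that("adding pure noise columns does not inflate LOO Q2", {
  set.seed(45)
  deltas <- vapply(1:20, function(s) {
    set.seed(500 + s)
    X <- matrix(rnorm(20 * 4), 20, 4)
    y <- as.numeric(X %*% c(1, -1, 0.5, 0) + rnorm(20, 0, 0.3))
    base <- loo_cv(X, y, 2)$q2
    noisy <- loo_cv(cbind(X, rnorm(20)), y, 2)$q2
    noisy - base
  }, numeric(1))
  expect_lte(stats::median(deltas), 0.02)
})

test_that("forward variable selection finds the causal column first", {
  set.seed(46)
  n <- 25
  causal <- rnorm(n)
  X <- cbind(causal = causal, matrix(rnorm(n * 20), n, 20))
  colnames(X)[-1] <- paste0("n", 1:20)
  y <- 2 * causal + rnorm(n, 0, 0.3)
  sel <- select_variables(X, y, n_lv = 1, window = 1)
  expect_equal(sel$columns[1], "causal")
  # duplicated causal column: only one of the pair selected
  X2 <- cbind(X, causal2 = causal)
  pr2 <- prune_columns(X2, y, variance_floor = 0)
  expect_equal(sum(c("causal", "causal2") %in% colnames(pr2)), 1)
  # pure noise never yields a confident model
  nulls <- vapply(1:20, function(s) {
    set.seed(600 + s)
    Xn <- matrix(rnorm(20 * 10), 20, 10)
    colnames(Xn) <- paste0("x", 1:10)
    yn <- rnorm(20)
    out <- tryCatch(select_variables(Xn, yn, n_lv = 1)$q2,
                    error = function(e) -Inf)
    out
  }, numeric(1))
  expect_gte(mean(nulls <= 0.2), 0.9)
})

test_that("coefficient maps re-index model weights onto the grid", {
  fx <- fx_field()
  pr <- prune_columns(fx$matrix, fx$planted$y)
  m <- fit_pls(pr, fx$planted$y, n_lv = 3)
  cmap <- coefficient_map(m, fx$grid)
  expect_true(all(cmap$type %in% c("LJ", "C")))
  expect_true(all(cmap$sign == ifelse(cmap$coefficient > 0, "positive",
                                      "negative")))
  pts <- grid_coordinates(fx$grid)
  i <- which(cmap$grid_index == cmap$grid_index[1] &
               cmap$type == cmap$type[1])[1]
  expect_equal(unlist(cmap[i, c("x", "y", "z")], use.names = FALSE),
               pts[cmap$grid_index[i], ])
  # round-trip through a cube export of the LJ coefficient field
  lj_field <- numeric(nrow(pts))
  lj <- cmap[cmap$type == "LJ", ]
  lj_field[lj$grid_index] <- lj$coefficient
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(lj_field, fx$grid, path)
  expect_equal(read_cube(path)$values, lj_field, tolerance = 1e-4)
})
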