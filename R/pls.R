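#' Fit a PLS regression by NIPALS
#'
#' Single-response partial least squares: X and y are centered (and
#' optionally autoscaled) internally, latent variables are extracted by
#' the NIPALS iteration (weights w, scores t, X-loadings p, y-loadings
#' q), and regression coefficients are folded back to the original
#' variable space so that `predict` is simply `X b + intercept`. With
#' `n_lv` equal to the rank of centered X the solution coincides with
#' ordinary least squares.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param n_lv number of latent variables (must not exceed the rank of
#'   centered X).
#' @param scale autoscale columns to unit variance (default FALSE:
#'   field columns share physical units).
#' @return object of class `pls_model` with coefficients, intercept,
#'   scores, loadings, weights and the centering/scaling parameters.
#' @export
fit_pls <- function(X, y, n_lv, scale = FALSE) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_lv >= 1)
  xm <- colMeans(X); ym <- mean(y)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(xs == 0)) stop("constant column(s) cannot be autoscaled")
  Xc <- sweep(sweep(X, 2, xm), 2, xs, "/")
  rk <- qr(Xc)$rank
  if (n_lv > rk)
    stop("n_lv = ", n_lv, " exceeds the rank of the centered predictor ",
         "matrix (", rk, ")")
  yc <- y - ym
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  Xd <- Xc; yd <- yc
  a_eff <- 0
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break   # residual response exhausted (e.g. constant y)
    w <- w / wn
    t <- Xd %*% w
    tt <- sum(t^2)
    pl <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pl)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
    a_eff <- a
  }
  # coefficients in (centered, scaled) space: B = W (P'W)^-1 q
  Bstar <- if (a_eff == 0) rep(0, p) else {
    Wa <- W[, seq_len(a_eff), drop = FALSE]
    Pa <- P[, seq_len(a_eff), drop = FALSE]
    Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a_eff)])
  }
  b <- as.numeric(Bstar) / xs
  intercept <- ym - sum(b * xm)
  structure(list(coefficients = stats::setNames(b, colnames(X)),
                 intercept = intercept, n_lv = n_lv, scale = scale,
                 x_mean = xm, x_sd = xs, y_mean = ym,
                 scores = Tm, loadings = P, weights = W, y_loadings = q),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d latent variables, %d predictors\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

#' Calibration statistics of a fitted PLS model
#'
#' With SSE the residual sum of squares and SSY the total sum of squares
#' about the mean: `R2 = 1 - SSE/SSY`, `RMSEC = sqrt(SSE/n)`,
#' `SEC = sqrt(SSE/(n - n_lv - 1))` and
#' `F = ((SSY - SSE)/n_lv) / (SSE/(n - n_lv - 1))` — latent variables
#' are counted as model degrees of freedom. SEC and F are reported as
#' `NA` when `n <= n_lv + 1`.
#'
#' @param model a `pls_model`.
#' @param X,y the calibration data.
#' @return list with `r2`, `rmsec`, `sec`, `f_stat`, `sse`, `ssy`, `n`.
#' @export
calibrate_stats <- function(model, X, y) {
  yhat <- predict(model, X)
  n <- length(y); a <- model$n_lv
  sse <- sum((y - yhat)^2)
  ssy <- sum((y - mean(y))^2)
  r2 <- 1 - sse / ssy
  rmsec <- sqrt(sse / n)
  if (n > a + 1) {
    sec <- sqrt(sse / (n - a - 1))
    f_stat <- ((ssy - sse) / a) / (sse / (n - a - 1))
  } else {
    sec <- NA_real_; f_stat <- NA_real_
  }
  list(r2 = r2, rmsec = rmsec, sec = sec, f_stat = f_stat,
       sse = sse, ssy = ssy, n = n)
}

#' Leave-one-out (or leave-N-out) cross-validation of a PLS model
#'
#' For each fold the model is refit without the held-out compounds and
#' they are predicted; `PRESS = sum (y_i - yhat_(i))^2`,
#' `Q2 = 1 - PRESS/SSY`, `RMSECV = sqrt(PRESS/n)`.
#'
#' @param X,y training data.
#' @param n_lv latent variables.
#' @param leave_out fold size (default 1 = LOO).
#' @param scale passed to [fit_pls()].
#' @return list with `press_cv`, `q2`, `rmsecv`, `predictions`.
#' @export
loo_cv <- function(X, y, n_lv, leave_out = 1, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(n >= n_lv + 2)
  folds <- split(seq_len(n), ceiling(seq_len(n) / leave_out))
  pred <- numeric(n)
  for (f in folds) {
    m <- tryCatch(
      fit_pls(X[-f, , drop = FALSE], y[-f], n_lv, scale = scale),
      error = function(e)
        stop("cross-validation refit failed for fold {",
             paste(f, collapse = ","), "}: ", conditionMessage(e)))
    pred[f] <- predict(m, X[f, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  ssy <- sum((y - mean(y))^2)
  list(press_cv = press, q2 = 1 - press / ssy, rmsecv = sqrt(press / n),
       predictions = pred)
}

#' External predictive R2
#'
#' `R2pred = 1 - sum((y_test - yhat)^2) / sum((y_test - mean(y_train))^2)`.
#'
#' @param model a `pls_model`.
#' @param X_test,y_test external set (disjoint from training).
#' @param y_train_mean training-set response mean.
#' @return R2pred.
#' @export
external_validation <- function(model, X_test, y_test, y_train_mean) {
  if (!length(y_test)) stop("empty external test set")
  yhat <- predict(model, X_test)
  1 - sum((y_test - yhat)^2) / sum((y_test - y_train_mean)^2)
}

#' y-randomization (chance correlation) check
#'
#' Refits the model on permuted responses and records the LOO Q2 of
#' each permutation; a real structure-activity model should leave the
#' permuted Q2 distribution far below its own.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param n_lv latent variables.
#' @param n_perm permutations (default 50).
#' @param seed RNG seed.
#' @return numeric vector of permuted-response Q2 values.
#' @export
y_randomization <- function(X, y, n_lv, n_perm = 50, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i)
    loo_cv(X, sample(y), n_lv)$q2, numeric(1))
}

#' Choose the number of latent variables by LOO Q2
#'
#' @param X,y training data.
#' @param max_lv cap on latent variables (default 10, limited by rank).
#' @param scale passed to [fit_pls()].
#' @return list with `n_lv` (the Q2 maximizer) and `q2_by_lv`.
#' @export
choose_n_lv <- function(X, y, max_lv = 10, scale = FALSE) {
  X <- as.matrix(X)
  rk <- qr(scale(X, scale = FALSE))$rank
  lvs <- seq_len(min(max_lv, rk, nrow(X) - 2))
  q2 <- vapply(lvs, function(a) loo_cv(X, y, a, scale = scale)$q2,
               numeric(1))
  list(n_lv = lvs[which.max(q2)], q2_by_lv = stats::setNames(q2, lvs))
}

#' Correlation-ranked forward variable selection scored by LOO Q2
#'
#' Columns are ordered by |correlation with y| and added in windows of
#' `window` columns; after each window the LOO Q2 of a model on the
#' current subset is evaluated and the window is kept only if Q2
#' improves. The best-seen subset is returned.
#'
#' @param X pruned field matrix.
#' @param y response.
#' @param n_lv latent variables for the scoring model (capped by subset
#'   rank automatically).
#' @param window columns added per step (default 5).
#' @param max_vars cap on selected columns (default 30).
#' @return list with `columns` (selected names), `q2`, and the
#'   selection `trace` (step, n_columns, q2, kept).
#' @export
select_variables <- function(X, y, n_lv = 2, window = 5, max_vars = 30) {
  X <- as.matrix(X)
  ry <- abs(suppressWarnings(stats::cor(X, y)))[, 1]
  ry[is.na(ry)] <- 0
  ord <- colnames(X)[order(ry, decreasing = TRUE)]
  ord <- utils::head(ord, max_vars)
  current <- character(0); best_q2 <- -Inf
  trace <- data.frame(step = integer(0), n_columns = integer(0),
                      q2 = numeric(0), kept = logical(0))
  step <- 0
  while (length(current) < length(ord)) {
    step <- step + 1
    cand <- ord[seq_len(min(length(current) + window, length(ord)))]
    Xs <- X[, cand, drop = FALSE]
    a <- min(n_lv, qr(scale(Xs, scale = FALSE))$rank, nrow(Xs) - 2)
    q2 <- tryCatch(loo_cv(Xs, y, a)$q2, error = function(e) -Inf)
    kept <- q2 > best_q2
    trace <- rbind(trace, data.frame(step = step,
                                     n_columns = length(cand),
                                     q2 = q2, kept = kept))
    if (kept) { current <- cand; best_q2 <- q2 }
    else break
  }
  if (!length(current))
    stop("no variable subset achieved a finite Q2; best seen: ", best_q2)
  list(columns = current, q2 = best_q2, trace = trace)
}

#' Map PLS coefficients back onto the energy grid
#'
#' Re-indexes the fitted coefficients of a field-descriptor model to
#' grid coordinates, split by energy type (LJ / C) and sign, for
#' contour-style visualization. Zero coefficients (columns absent from
#' the model) do not appear.
#'
#' @param model a `pls_model` fitted on field-descriptor columns named
#'   `LJ_<i>` / `C_<i>`.
#' @param grid the `energy_grid` the columns refer to.
#' @return data.frame: `type`, `grid_index`, `x`, `y`, `z`,
#'   `coefficient`, `sign`.
#' @export
coefficient_map <- function(model, grid) {
  cn <- names(model$coefficients)
  if (!all(grepl("^(LJ|C)_\\d+$", cn)))
    stop("model coefficients are not named field columns (LJ_i / C_i)")
  pts <- grid_coordinates(grid)
  idx <- as.integer(sub("^(LJ|C)_", "", cn))
  if (max(idx) > nrow(pts))
    stop("model refers to grid points beyond this grid")
  keep <- model$coefficients != 0
  data.frame(type = sub("_.*", "", cn)[keep], grid_index = idx[keep],
             x = pts[idx[keep], 1], y = pts[idx[keep], 2],
             z = pts[idx[keep], 3],
             coefficient = unname(model$coefficients[keep]),
             sign = ifelse(model$coefficients[keep] > 0, "positive",
                           "negative"),
             stringsAsFactors = FALSE)
}

#' Full PLS model summary (calibration + validation statistics)
#'
#' Convenience wrapper collecting the statistics suite for a training /
#' external-set pair into one record: n_lv, R2, RMSEC, SEC, F, PRESS,
#' Q2, RMSECV and R2pred.
#'
#' @param X,y training data.
#' @param n_lv latent variables (chosen by [choose_n_lv()] when NULL).
#' @param X_test,y_test optional external set.
#' @param scale passed to [fit_pls()].
#' @return list of class `pls_summary`.
#' @export
pls_summary <- function(X, y, n_lv = NULL, X_test = NULL, y_test = NULL,
                        scale = FALSE) {
  if (is.null(n_lv)) n_lv <- choose_n_lv(X, y, scale = scale)$n_lv
  model <- fit_pls(X, y, n_lv, scale = scale)
  cal <- calibrate_stats(model, X, y)
  cv <- loo_cv(X, y, n_lv, scale = scale)
  r2_pred <- if (!is.null(X_test))
    external_validation(model, X_test, y_test, mean(y)) else NA_real_
  structure(list(model = model, n_lv = n_lv, r2 = cal$r2,
                 rmsec = cal$rmsec, sec = cal$sec, f_stat = cal$f_stat,
                 press_cv = cv$press_cv, q2 = cv$q2, rmsecv = cv$rmsecv,
                 r2_pred = r2_pred),
            class = "pls_summary")
}

#' @export
print.pls_summary <- function(x, ...) {
  cat(sprintf(paste0("PLS summary: nLV = %d\n",
                     "  R2 = %.4f  RMSEC = %.3f  SEC = %.3f  F = %.3f\n",
                     "  Q2 = %.4f  RMSECV = %.3f  PRESS = %.3f\n"),
              x$n_lv, x$r2, x$rmsec, x$sec, x$f_stat, x$q2, x$rmsecv,
              x$press_cv))
  if (!is.na(x$r2_pred)) cat(sprintf("  R2pred = %.4f\n", x$r2_pred))
  invisible(x)
}
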