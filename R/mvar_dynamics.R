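## Sliding-window multivariate autoregressive modeling of ROI signals:
## ensemble Vieira-Morf lattice estimation, six-criterion order selection,
## and model validation (residual whiteness, percent consistency,
## stability).

#' Detrend and normalize ROI signals
#'
#' Per trial and channel: removes a linear trend and scales to unit
#' temporal variance; then across the trial ensemble: removes the
#' per-timepoint mean and scales to unit per-timepoint variance. The
#' result is approximately idempotent and centers the ensemble at every
#' timepoint, the preconditioning expected by the lattice estimator.
#'
#' @param roi a `roi_signals` object (or any list with a `[M x T x N]`
#'   `data` array).
#' @return The input with `data` replaced by its normalized version.
#' @export
detrend_normalize <- function(roi) {
  x <- roi$data
  d <- dim(x); M <- d[1]; Tn <- d[2]; N <- d[3]
  if (N < 2) stop("ensemble normalization needs at least 2 trials")
  tt <- seq_len(Tn)
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  for (n in seq_len(N)) {
    for (m in seq_len(M)) {
      y <- x[m, , n]
      if (var(y) < 1e-300)
        stop("zero-variance channel: ",
             if (!is.null(roi$roi_names)) roi$roi_names[m] else m)
      slope <- sum(tc * y) / denom
      y <- y - mean(y) - slope * tc
      s <- sqrt(sum(y^2) / (Tn - 1))
      # a trial that is exactly a linear trend detrends to zero; keep it
      x[m, , n] <- if (s < 1e-300) y else y / s
    }
  }
  ## ensemble statistics per (channel, timepoint)
  mu <- apply(x, c(1, 2), mean)
  sdev <- apply(x, c(1, 2), sd)
  sdev[sdev < 1e-12] <- 1
  for (n in seq_len(N)) x[, , n] <- (x[, , n] - mu) / sdev
  roi$data <- x
  roi
}

#' Sliding-window sample intervals
#'
#' Half-open 0-based sample intervals `[start, stop)` of length
#' `round(window_len_s * fs)` stepped by `round(window_step_s * fs)`;
#' `floor((T - w) / s) + 1` windows in total.
#'
#' @param T_samples epoch length in samples.
#' @param fs sampling rate in Hz.
#' @param window_len_s window length in seconds.
#' @param window_step_s step in seconds.
#' @return Data frame with `start`, `stop` (0-based, half-open) and
#'   `start_s` (seconds).
#' @export
sliding_windows <- function(T_samples, fs, window_len_s, window_step_s) {
  w <- round(window_len_s * fs)
  s <- round(window_step_s * fs)
  if (s < 1) stop("window step shorter than one sample")
  if (w > T_samples) stop("window longer than the epoch")
  n <- floor((T_samples - w) / s) + 1
  start <- (seq_len(n) - 1L) * s
  data.frame(start = start, stop = start + w, start_s = start / fs)
}

#' Ensemble Vieira-Morf VAR fit
#'
#' Order-recursive lattice estimation with geometric-mean (Vieira-Morf)
#' normalization of the reflection coefficients, accumulating the
#' forward/backward error covariances across the trial ensemble rather
#' than concatenating trials. Warns when the data-to-parameter ratio
#' `N w M / (p M^2)` falls below 10.
#'
#' @param x numeric array `[M x w x N]` (zero-mean window data).
#' @param p model order.
#' @return List with `A` (`[M x M x p]`, convention
#'   `x_t = sum_k A_k x_{t-k} + e_t`), `Sigma` (residual covariance),
#'   `order`.
#' @export
vieira_morf_fit <- function(x, p) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  d <- dim(x); M <- d[1]; w <- d[2]; N <- d[3]
  if (p <= 0) stop("model order must be positive")
  ratio <- (N * w * M) / (p * M^2)
  if (ratio < 10)
    warning(sprintf("data-to-parameter ratio %.1f below 10:1", ratio))
  fit <- cpp_vm_lattice(x, as.integer(p))
  list(A = fit$A[[p]], Sigma = fit$Sigma[[p]], order = p)
}

#' Model-order information criteria
#'
#' Six criteria evaluated for orders `1..p_max` from a single lattice
#' pass: AIC, corrected AIC, Schwarz-Bayes, Hannan-Quinn, the logarithm of
#' Akaike's final prediction error, and Rissanen's minimum description
#' length (which counts the innovation covariance parameters in addition
#' to the coefficients, hence a penalty constant different from SBC).
#' When window starts are supplied the curves are averaged across
#' windows.
#'
#' @param x array `[M x T x N]`.
#' @param p_max largest candidate order.
#' @param starts optional 0-based window starts (with `w`): evaluate per
#'   window and average the curves.
#' @param w window length in samples when `starts` is given.
#' @return An `order_criteria` object: matrix `[p_max x 6]` plus the
#'   per-criterion argmin.
#' @export
order_criteria <- function(x, p_max = 30, starts = NULL, w = NULL) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  d <- dim(x); M <- d[1]
  segs <- if (is.null(starts)) list(x) else
    lapply(starts, function(s) x[, (s + 1):(s + w), , drop = FALSE])
  crit_names <- c("AIC", "AICc", "SBC", "HQ", "logFPE", "Rissanen")
  acc <- matrix(0, p_max, 6, dimnames = list(NULL, crit_names))
  for (seg in segs) {
    ws <- dim(seg)[2]; N <- dim(seg)[3]
    n <- N * ws
    fit <- cpp_vm_lattice(seg, as.integer(p_max))
    for (p in seq_len(p_max)) {
      ld <- determinant(fit$Sigma[[p]], logarithm = TRUE)$modulus[1]
      k <- p * M^2
      kr <- k + M * (M + 1) / 2
      aic <- ld + 2 * k / n
      aicc <- if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n * (n - k - 1)) else Inf
      sbc <- ld + k * log(n) / n
      hq <- ld + 2 * k * log(log(n)) / n
      fpe <- if (n - M * p - 1 > 0)
        ld + M * log((n + M * p + 1) / (n - M * p - 1)) else Inf
      ris <- ld + kr * log(n) / n
      acc[p, ] <- acc[p, ] + c(aic, aicc, sbc, hq, fpe, ris)
    }
  }
  acc <- acc / length(segs)
  structure(list(criteria = acc, argmin = apply(acc, 2, which.min)),
            class = "order_criteria")
}

#' Select the model order from criterion curves
#'
#' The per-criterion optimal orders (curve minima) are averaged and the
#' result rounded down to the nearest integer.
#'
#' @param crit an [order_criteria()] object, or an integer vector of
#'   per-criterion argmins.
#' @return Integer model order.
#' @export
select_order <- function(crit) {
  am <- if (inherits(crit, "order_criteria")) crit$argmin else crit
  as.integer(floor(mean(am)))
}

#' Residual whiteness tests
#'
#' The autocorrelation-function check (fraction of residual auto- and
#' cross-correlations at lags `1..h` inside the `+-1.96/sqrt(n)` band)
#' and three multivariate portmanteau statistics (Box-Pierce, Ljung-Box,
#' Li-McLeod) referred to a chi-square with `M^2 (h - p)` degrees of
#' freedom.
#'
#' @param model a fit from [vieira_morf_fit()], or `NULL` to treat `x`
#'   itself as the residual series.
#' @param x array `[M x T x N]` of data (or residuals when
#'   `model = NULL`).
#' @param h number of lags (default `min(20, floor(T/4))`).
#' @return List with `acf_pass_fraction`, `acf_pass` and a `portmanteau`
#'   data frame (statistic, df, p for each test).
#' @export
whiteness_tests <- function(model, x, h = NULL) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  p <- if (is.null(model)) 0L else model$order
  E <- if (is.null(model)) x else cpp_var_residuals(x, model$A)
  d <- dim(E); M <- d[1]; Tn <- d[2]; N <- d[3]
  if (is.null(h)) h <- min(20L, floor(Tn / 4))
  if (h >= Tn) stop("lag count must be smaller than the sample count")
  ntot <- N * Tn
  C0 <- matrix(0, M, M)
  for (n in seq_len(N)) C0 <- C0 + tcrossprod(matrix(E[, , n], M))
  C0 <- C0 / ntot
  C0i <- solve(C0)
  bp <- lb <- 0
  acf_in <- 0L
  denom <- sqrt(diag(C0))
  for (k in seq_len(h)) {
    Ck <- matrix(0, M, M)
    for (n in seq_len(N)) {
      En <- matrix(E[, , n], M)
      Ck <- Ck + En[, (k + 1):Tn, drop = FALSE] %*%
        t(En[, 1:(Tn - k), drop = FALSE])
    }
    Ck <- Ck / ntot
    trk <- sum(diag(t(Ck) %*% C0i %*% Ck %*% C0i))
    bp <- bp + trk
    lb <- lb + trk / (ntot - k)
    Rk <- Ck / outer(denom, denom)
    acf_in <- acf_in + sum(abs(Rk) <= 1.96 / sqrt(ntot))
  }
  df <- M^2 * (h - p)
  if (df <= 0) stop("lag count must exceed the model order")
  Q_bp <- ntot * bp
  Q_lb <- ntot * (ntot + 2) * lb
  Q_lm <- ntot * bp + M^2 * h * (h + 1) / (2 * ntot)
  port <- data.frame(test = c("box_pierce", "ljung_box", "li_mcleod"),
                     statistic = c(Q_bp, Q_lb, Q_lm),
                     df = df,
                     p = pchisq(c(Q_bp, Q_lb, Q_lm), df, lower.tail = FALSE))
  frac <- acf_in / (h * M^2)
  list(acf_pass_fraction = frac, acf_pass = frac >= 0.95,
       portmanteau = port)
}

#' Percent consistency of a fitted VAR
#'
#' Simulates a matched ensemble (same trial count and length) from the
#' fitted model and compares the stacked auto/cross-correlation structure
#' with that of the data:
#' `PC = 100 (1 - ||r_sim - r_real|| / ||r_real||)`.
#'
#' @param model fit from [vieira_morf_fit()].
#' @param x array `[M x w x N]` the model was fitted to.
#' @param seed RNG seed for the simulated ensemble.
#' @param max_lag correlation lags compared (default the model order).
#' @return Percent consistency (a scalar `<= 100`).
#' @export
percent_consistency <- function(model, x, seed = 1L, max_lag = NULL) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  d <- dim(x); M <- d[1]; w <- d[2]; N <- d[3]
  p <- model$order
  if (stability_index(model$A) >= 0) stop("unstable model")
  if (is.null(max_lag)) max_lag <- p
  burn <- 10L * p
  set.seed(seed)
  ch <- chol((model$Sigma + t(model$Sigma)) / 2)
  innov <- array(t(ch) %*% matrix(rnorm(M * (w + burn) * N), M),
                 c(M, w + burn, N))
  Acoef <- array(matrix(model$A, M, M * p), c(M, M * p, 1))
  sim <- cpp_var_simulate(Acoef, p, integer(w), burn, innov)
  corr_stack <- function(y) {
    out <- NULL
    C0 <- matrix(0, M, M)
    for (n in seq_len(N)) C0 <- C0 + tcrossprod(matrix(y[, , n], M))
    C0 <- C0 / (N * w)
    s <- sqrt(diag(C0))
    for (k in 0:max_lag) {
      Ck <- matrix(0, M, M)
      for (n in seq_len(N)) {
        yn <- matrix(y[, , n], M)
        Ck <- Ck + yn[, (k + 1):w, drop = FALSE] %*%
          t(yn[, 1:(w - k), drop = FALSE])
      }
      Ck <- Ck / (N * (w - k))
      out <- c(out, as.vector(Ck / outer(s, s)))
    }
    out
  }
  r_real <- corr_stack(x)
  r_sim <- corr_stack(sim)
  100 * (1 - sqrt(sum((r_sim - r_real)^2)) / sqrt(sum(r_real^2)))
}

#' Stability index of VAR coefficients
#'
#' Natural logarithm of the spectral radius of the companion matrix;
#' negative values mean the process is stable (stationary).
#'
#' @param A coefficient array `[M x M x p]` (a matrix is taken as p = 1).
#' @return Log spectral radius.
#' @export
stability_index <- function(A) {
  if (is.matrix(A)) A <- array(A, c(nrow(A), ncol(A), 1L))
  M <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) C[1:M, ((k - 1) * M + 1):(k * M)] <- A[, , k]
  if (p > 1)
    C[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  log(max(Mod(eigen(C, only.values = TRUE)$values)))
}

#' Fit and validate sliding-window MVAR models
#'
#' Selects the model order once from criterion curves averaged over a
#' subsample of windows, fits a Vieira-Morf VAR in every sliding window,
#' and attaches a per-window validation report (whiteness, percent
#' consistency, stability index).
#'
#' @param roi `roi_signals` (already detrended/normalized).
#' @param window_len,window_step window length/step in seconds.
#' @param order `"auto"` (six-criterion selection) or a fixed integer.
#' @param order_range candidate orders for automatic selection.
#' @param order_windows number of windows used for the order-selection
#'   curves.
#' @param validate compute the per-window validation report.
#' @param seed seed for the consistency simulation.
#' @return A `windowed_mvar`: per-window coefficient/covariance lists,
#'   the order, window table and (optionally) the `validation` report.
#' @export
fit_windowed_mvar <- function(roi, window_len = 0.55, window_step = 0.01,
                              order = "auto", order_range = c(1, 30),
                              order_windows = 5, validate = TRUE,
                              seed = 1L) {
  x <- roi$data
  d <- dim(x); Tn <- d[2]
  wins <- sliding_windows(Tn, roi$fs, window_len, window_step)
  w <- wins$stop[1] - wins$start[1]
  if (identical(order, "auto")) {
    sub <- wins$start[unique(round(seq(1, nrow(wins),
                                       length.out = min(order_windows,
                                                        nrow(wins)))))]
    crit <- order_criteria(x, p_max = order_range[2], starts = sub, w = w)
    p <- max(order_range[1], select_order(crit))
  } else {
    p <- as.integer(order)
    crit <- NULL
  }
  A_list <- vector("list", nrow(wins))
  S_list <- vector("list", nrow(wins))
  report <- if (validate)
    data.frame(start_s = wins$start_s, stability = NA_real_,
               consistency = NA_real_, acf_pass = NA,
               ljung_box_p = NA_real_, box_pierce_p = NA_real_,
               li_mcleod_p = NA_real_) else NULL
  for (i in seq_len(nrow(wins))) {
    seg <- x[, (wins$start[i] + 1):wins$stop[i], , drop = FALSE]
    fit <- suppressWarnings(vieira_morf_fit(seg, p))
    A_list[[i]] <- fit$A; S_list[[i]] <- fit$Sigma
    if (validate) {
      report$stability[i] <- stability_index(fit$A)
      report$consistency[i] <- percent_consistency(fit, seg,
                                                   seed = seed + i)
      wt <- whiteness_tests(fit, seg)
      report$acf_pass[i] <- wt$acf_pass
      report$ljung_box_p[i] <- wt$portmanteau$p[2]
      report$box_pierce_p[i] <- wt$portmanteau$p[1]
      report$li_mcleod_p[i] <- wt$portmanteau$p[3]
    }
  }
  structure(list(windows = wins, A = A_list, Sigma = S_list, order = p,
                 fs = roi$fs, window_len_s = window_len,
                 window_step_s = window_step, criteria = crit,
                 validation = report, roi_names = roi$roi_names),
            class = "windowed_mvar")
}

#' @export
print.windowed_mvar <- function(x, ...) {
  cat(sprintf("<windowed_mvar> order %d, %d windows of %g s (step %g s)\n",
              x$order, nrow(x$windows), x$window_len_s, x$window_step_s))
  if (!is.null(x$validation))
    cat(sprintf("  stability < 0 in %d/%d windows; mean consistency %.1f%%\n",
                sum(x$validation$stability < 0), nrow(x$windows),
                mean(x$validation$consistency)))
  invisible(x)
}
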