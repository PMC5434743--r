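## Channel-space cleaning: zero-phase band-pass filtering, common-average
## re-referencing, kurtosis-based channel/trial rejection, Infomax ICA
## with equivalent-dipole screening of components, back-projection and
## anti-aliased downsampling.

## Zero-phase application of a symmetric (linear-phase) FIR kernel via FFT
## convolution with reflection padding and group-delay compensation.
fir_zerophase <- function(y, b) {
  L <- length(b)
  D <- (L - 1) / 2
  n <- length(y)
  pad <- min(D, n - 1)
  ypad <- c(rev(y[2:(pad + 1)]), y, rev(y[(n - pad):(n - 1)]))
  out <- convolve(ypad, rev(b), type = "open")
  out[(pad + D + 1):(pad + D + n)]
}

fir_bandpass_kernel <- function(fs, low, high, max_len = 4097, T_cap = Inf) {
  trans <- max(low, 1)                       # Hz, transition budget
  L <- round(3.3 * fs / trans)
  L <- min(L, max_len, T_cap - 1)
  L <- max(L, 33)
  if (L %% 2 == 0) L <- L + 1
  signal::fir1(L - 1, c(low, high) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter
#'
#' Linear-phase FIR band-pass (Hamming-windowed design) applied with
#' group-delay compensation, so the output is exactly zero-phase. The
#' kernel length adapts to the low edge (about `3.3 fs / low` taps,
#' capped by the epoch length).
#'
#' @param eeg an [epoched_eeg()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2`.
#' @return Filtered [epoched_eeg()].
#' @export
bandpass_filter <- function(eeg, low, high) {
  fs <- eeg$fs
  if (!(low > 0 && high > low)) stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  b <- fir_bandpass_kernel(fs, low, high, T_cap = n_samples(eeg))
  x <- eeg$data
  for (n in seq_len(dim(x)[3]))
    for (c in seq_len(dim(x)[1]))
      x[c, , n] <- fir_zerophase(x[c, , n], b)
  eeg$data <- x
  eeg
}

#' Common-average re-reference
#'
#' Subtracts the instantaneous channel mean; the per-sample mean of the
#' output is exactly zero and the operation is an idempotent projection.
#'
#' @param eeg an [epoched_eeg()].
#' @return Re-referenced [epoched_eeg()].
#' @export
rereference_average <- function(eeg) {
  x <- eeg$data
  for (n in seq_len(dim(x)[3]))
    x[, , n] <- sweep(x[, , n], 2, colMeans(x[, , n]))
  eeg$data <- x
  eeg
}

excess_kurtosis <- function(v) {
  v <- v - mean(v)
  m2 <- mean(v^2)
  if (m2 == 0) return(0)
  mean(v^4) / m2^2 - 3
}

#' Kurtosis-based channel and trial rejection
#'
#' Computes excess kurtosis per channel (over all trials concatenated)
#' and per trial (over all channels concatenated), Z-scores each
#' population, and flags entries with `|Z|` above the threshold. The
#' visual-inspection step of a manual workflow becomes an audit log plus
#' an override list.
#'
#' @param eeg an [epoched_eeg()].
#' @param z_threshold positive Z-score threshold (default 5).
#' @param keep_channels,keep_trials indices never removed (overrides).
#' @return List with `channel_flags`, `trial_flags` (logical), `report`
#'   (kurtosis and Z per entry) and `cleaned` (the reduced
#'   [epoched_eeg()]).
#' @export
kurtosis_reject <- function(eeg, z_threshold = 5, keep_channels = integer(),
                            keep_trials = integer()) {
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be positive")
  C <- n_channels(eeg); N <- n_trials(eeg)
  if (C < 3 || N < 3)
    stop("Z-scores need at least 3 channels and 3 trials")
  kc <- vapply(seq_len(C), function(c) excess_kurtosis(as.vector(eeg$data[c, , ])), 0)
  kt <- vapply(seq_len(N), function(n) excess_kurtosis(as.vector(eeg$data[, , n])), 0)
  zc <- if (sd(kc) > 0) (kc - mean(kc)) / sd(kc) else rep(0, C)
  zt <- if (sd(kt) > 0) (kt - mean(kt)) / sd(kt) else rep(0, N)
  cf <- abs(zc) > z_threshold
  tf <- abs(zt) > z_threshold
  cf[keep_channels] <- FALSE
  tf[keep_trials] <- FALSE
  if (all(cf) || all(tf)) stop("rejection would remove everything")
  cleaned <- eeg
  cleaned$data <- eeg$data[!cf, , !tf, drop = FALSE]
  cleaned$channel_names <- eeg$channel_names[!cf]
  if (!is.null(eeg$channel_pos))
    cleaned$channel_pos <- eeg$channel_pos[!cf, , drop = FALSE]
  cleaned$condition <- eeg$condition[!tf]
  report <- list(
    channels = data.frame(channel = eeg$channel_names, kurtosis = kc,
                          z = zc, flagged = abs(zc) > z_threshold,
                          removed = cf),
    trials = data.frame(trial = seq_len(N), kurtosis = kt, z = zt,
                        flagged = abs(zt) > z_threshold, removed = tf))
  list(channel_flags = cf, trial_flags = tf, report = report,
       cleaned = cleaned)
}

#' Infomax independent component analysis
#'
#' Natural-gradient Infomax with a logistic nonlinearity on sphered data:
#' stochastic block updates with learning-rate annealing driven by the
#' angle between successive weight changes. Deterministic for a fixed
#' seed.
#'
#' @param eeg an [epoched_eeg()] (band-passed, full-rank data).
#' @param seed RNG seed for the block permutations.
#' @param max_iter maximum number of passes through the data.
#' @param lrate initial learning rate (default `6.5e-4 / log(C)`).
#' @param tol weight-change stopping tolerance.
#' @return An `ica_decomposition`: `unmixing`, `mixing`, `activations`
#'   `[C x T x N]`, `converged`, `iterations`.
#' @export
infomax_ica <- function(eeg, seed = 1L, max_iter = 512L, lrate = NULL,
                        tol = 1e-6) {
  C <- n_channels(eeg); Tn <- n_samples(eeg); N <- n_trials(eeg)
  X <- matrix(eeg$data, C, Tn * N)
  X <- X - rowMeans(X)
  cv <- tcrossprod(X) / ncol(X)
  ev <- eigen(cv, symmetric = TRUE)
  if (min(ev$values) < 1e-10 * max(ev$values))
    stop("numerical error: rank-deficient data; reduce dimensionality ",
         "before ICA (e.g. drop a channel after average referencing)")
  sph <- 2 * ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  Xs <- sph %*% X
  n <- ncol(Xs)
  block <- max(8L, ceiling(min(5 * log(n), 0.3 * n)))
  if (is.null(lrate)) lrate <- 6.5e-4 / log(C)
  W <- diag(C)
  oldW <- W
  dW_prev <- NULL
  set.seed(seed)
  converged <- FALSE
  it <- 0L
  I_b <- diag(C) * block
  while (it < max_iter) {
    it <- it + 1L
    perm <- sample.int(n)
    blew_up <- FALSE
    for (s in seq(1, n - block + 1, by = block)) {
      u <- W %*% Xs[, perm[s:(s + block - 1)], drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * (I_b + (1 - 2 * y) %*% t(u)) %*% W
      if (max(abs(W)) > 1e8) { blew_up <- TRUE; break }
    }
    if (blew_up) {
      lrate <- lrate * 0.5
      W <- diag(C); oldW <- W; dW_prev <- NULL
      next
    }
    dW <- W - oldW
    change <- sum(dW^2)
    if (!is.null(dW_prev)) {
      angle <- sum(dW * dW_prev) /
        sqrt(max(sum(dW^2) * sum(dW_prev^2), 1e-300))
      if (angle < cos(60 * pi / 180)) lrate <- lrate * 0.98
    }
    dW_prev <- dW
    oldW <- W
    if (change < tol * C^2) { converged <- TRUE; break }
  }
  unmixing <- W %*% sph
  mixing <- solve(unmixing)
  act <- array(unmixing %*% X, c(C, Tn, N))
  structure(list(unmixing = unmixing, mixing = mixing, activations = act,
                 converged = converged, iterations = it,
                 center = rowMeans(matrix(eeg$data, C, Tn * N)),
                 fs = eeg$fs, condition = eeg$condition),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %s after %d iterations\n",
              nrow(x$unmixing),
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' Fit an equivalent current dipole to a scalp map
#'
#' Exhaustive scan over the mesh gridpoints with the forward model's
#' fixed (surface-normal) dipole orientation: at each gridpoint the
#' least-squares scalar moment is computed and the global minimum of the
#' residual variance `||map - K m||^2 / ||map||^2` returned, ties broken
#' to the lowest vertex index.
#'
#' @param scalp_map numeric vector of length `C`.
#' @param model a [build_head_model()] result (or list with `K`, `mesh`).
#' @return A `dipole_fit`: `gridpoint`, `location`, `moment`,
#'   `residual_variance`.
#' @export
fit_equivalent_dipole <- function(scalp_map, model) {
  map2 <- sum(scalp_map^2)
  if (map2 == 0) stop("zero-norm scalp map")
  num <- drop(crossprod(model$K, scalp_map))
  den <- colSums(model$K^2)
  rv <- 1 - num^2 / (den * map2)
  g <- which.min(rv)
  structure(list(gridpoint = g, location = model$mesh$vertices[g, ],
                 moment = num[g] / den[g],
                 residual_variance = max(0, rv[g])),
            class = "dipole_fit")
}

#' Select cortical independent components by dipole residual variance
#'
#' Each IC scalp map (column of the mixing matrix) is fitted with
#' [fit_equivalent_dipole()]; components at or below the residual
#' variance threshold are retained. The decision log records every IC's
#' fit.
#'
#' @param decomp an [infomax_ica()] decomposition.
#' @param model head model.
#' @param rv_threshold residual variance cutoff (default 0.15).
#' @return List with `retained` (indices) and `log` (per-IC data frame).
#' @export
select_cortical_ics <- function(decomp, model, rv_threshold = 0.15) {
  C <- ncol(decomp$mixing)
  fits <- lapply(seq_len(C), function(i)
    fit_equivalent_dipole(decomp$mixing[, i], model))
  rv <- vapply(fits, `[[`, 0, "residual_variance")
  log <- data.frame(ic = seq_len(C), residual_variance = rv,
                    gridpoint = vapply(fits, `[[`, 0L, "gridpoint"),
                    retained = rv <= rv_threshold)
  list(retained = which(rv <= rv_threshold), log = log, fits = fits)
}

#' Back-project retained independent components
#'
#' Reconstructs channel data from a subset of ICs:
#' `mixing[, retained] %*% activations[retained]`. Retaining every IC
#' reproduces the (mean-removed) input to numerical precision.
#'
#' @param decomp an [infomax_ica()] decomposition.
#' @param retained integer component indices to keep.
#' @return An [epoched_eeg()] of the cleaned channel data.
#' @export
backproject <- function(decomp, retained) {
  if (length(retained) == 0) stop("no components retained")
  C <- nrow(decomp$mixing)
  d <- dim(decomp$activations)
  act <- matrix(decomp$activations, d[1], d[2] * d[3])
  out <- decomp$mixing[, retained, drop = FALSE] %*%
    act[retained, , drop = FALSE]
  epoched_eeg(array(out, c(C, d[2], d[3])), decomp$fs,
              condition = decomp$condition)
}

#' Anti-aliased downsampling
#'
#' Zero-phase FIR low-pass (cutoff `0.42 * target_fs`, sharp transition)
#' followed by decimation. Only integer decimation factors are
#' supported.
#'
#' @param eeg an [epoched_eeg()].
#' @param target_fs target sampling rate in Hz (must divide `fs`).
#' @return Resampled [epoched_eeg()].
#' @export
resample_eeg <- function(eeg, target_fs) {
  if (!is.numeric(target_fs) || target_fs <= 0)
    stop("target sampling rate must be positive")
  q <- eeg$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("target_fs must divide the sampling rate (integer decimation)")
  q <- round(q)
  if (q == 1) return(eeg)
  Tn <- n_samples(eeg)
  L <- min(511, if (Tn %% 2 == 0) Tn - 1 else Tn - 2)
  b <- signal::fir1(L - 1, 0.42 * target_fs / (eeg$fs / 2))
  keep <- seq(1, Tn, by = q)
  x <- array(0, c(n_channels(eeg), length(keep), n_trials(eeg)))
  for (n in seq_len(n_trials(eeg)))
    for (c in seq_len(n_channels(eeg)))
      x[c, , n] <- fir_zerophase(eeg$data[c, , n], b)[keep]
  eeg$data <- x
  eeg$fs <- target_fs
  eeg
}

#' Full channel-space cleaning pass
#'
#' Fixed order: band-pass filter, average re-reference, kurtosis
#' rejection, (optionally) Infomax ICA with dipole-based component
#' selection and back-projection, then downsampling.
#'
#' @param eeg an [epoched_eeg()].
#' @param config a [pipeline_config()].
#' @param model head model (needed when `ica = TRUE`).
#' @param ica run the ICA artifact-removal stage.
#' @param rv_threshold dipole residual-variance cutoff for IC retention.
#' @return List with `eeg` (cleaned) and `log` (rejection/IC reports).
#' @export
preprocess <- function(eeg, config = pipeline_config(), model = NULL,
                       ica = FALSE, rv_threshold = 0.15) {
  out <- bandpass_filter(eeg, config$band[1], config$band[2])
  out <- rereference_average(out)
  rej <- kurtosis_reject(out, config$kurtosis_z)
  out <- rej$cleaned
  log <- list(rejection = rej$report)
  if (ica) {
    if (is.null(model)) stop("ICA-based cleaning needs a head model")
    dec <- infomax_ica(out, seed = config$seed)
    sel <- select_cortical_ics(dec, model, rv_threshold)
    out2 <- backproject(dec, sel$retained)
    out2$channel_names <- out$channel_names
    out2$channel_pos <- out$channel_pos
    out2$epoch_window <- out$epoch_window
    out <- out2
    log$ic_selection <- sel$log
  }
  if (config$resample_fs < out$fs) out <- resample_eeg(out, config$resample_fs)
  list(eeg = out, log = log)
}
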