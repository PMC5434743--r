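## Spectro-temporal causal connectivity from windowed VAR models:
## transfer function, cross-spectrum, partial coherence, and the
## short-time direct directed transfer function (SdDTF).

#' VAR transfer matrix on a frequency grid
#'
#' `H(f) = (I - sum_k A_k exp(-i 2 pi f k / fs))^-1`, evaluated per
#' frequency.
#'
#' @param A coefficient array `[M x M x p]`.
#' @param freqs frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return Complex array `[M x M x F]`.
#' @export
transfer_matrix <- function(A, freqs, fs) {
  if (is.matrix(A)) A <- array(A, c(nrow(A), ncol(A), 1L))
  M <- dim(A)[1]; p <- dim(A)[3]
  if (stability_index(A) >= 0)
    warning("transfer matrix of an unstable model")
  H <- array(complex(real = 0), c(M, M, length(freqs)))
  for (fi in seq_along(freqs)) {
    Abar <- diag(M) + 0i
    for (k in seq_len(p))
      Abar <- Abar - A[, , k] * exp(-2i * pi * freqs[fi] * k / fs)
    Hf <- tryCatch(solve(Abar), error = function(e)
      stop(sprintf("transfer matrix singular at %g Hz", freqs[fi])))
    H[, , fi] <- Hf
  }
  H
}

#' Cross-spectral matrix and partial coherence
#'
#' `S(f) = H(f) Sigma H(f)^H / fs`; the partial coherence comes from the
#' inverse spectral matrix `G = S^-1` as
#' `P_ij = G_ij / sqrt(G_ii G_jj)` (conditional frequency-domain
#' correlation of nodes i and j given all others).
#'
#' @param H transfer array `[M x M x F]` from [transfer_matrix()].
#' @param Sigma innovation covariance `[M x M]`.
#' @param fs sampling rate in Hz.
#' @return List with complex arrays `S` and `P` (`[M x M x F]`).
#' @export
spectral_and_partial_coherence <- function(H, Sigma, fs) {
  M <- dim(H)[1]; Fn <- dim(H)[3]
  S <- array(complex(real = 0), dim(H))
  P <- array(complex(real = 0), dim(H))
  for (fi in seq_len(Fn)) {
    Sf <- H[, , fi] %*% Sigma %*% Conj(t(H[, , fi])) / fs
    G <- tryCatch(solve(Sf), error = function(e) {
      jit <- 1e-10 * Re(sum(diag(Sf))) / M
      solve(Sf + jit * diag(M))
    })
    dn <- sqrt(abs(Re(diag(G))))
    P[, , fi] <- G / outer(dn, dn)
    S[, , fi] <- Sf
  }
  list(S = S, P = P)
}

#' SdDTF of one windowed model set
#'
#' For each window,
#' `eta2[i, j, f] = |H_ij(f)|^2 |P_ij(f)|^2 / sum_{f,k,l} |H_kl|^2 |P_kl|^2`
#' (the default squared-magnitude convention, which makes the values sum
#' to one over all pairs and frequencies within the window);
#' `convention = "literal"` uses `|H_ij||P_ij|` in the numerator with the
#' same denominator. The normalization sums over every node pair
#' including the diagonal; diagonal entries are masked only when the
#' tensor is written out.
#'
#' @param model a `windowed_mvar` from [fit_windowed_mvar()].
#' @param freqs frequency grid in Hz.
#' @param convention `"squared"` (default) or `"literal"`.
#' @return A [connectivity_tensor()] `[M x M x F x W]` (sink, source,
#'   frequency, window).
#' @export
sddtf <- function(model, freqs, convention = c("squared", "literal")) {
  convention <- match.arg(convention)
  W <- length(model$A)
  M <- dim(model$A[[1]])[1]
  eta <- array(0, c(M, M, length(freqs), W))
  for (wi in seq_len(W)) {
    out <- cpp_sddtf_model(model$A[[wi]], model$Sigma[[wi]],
                           as.numeric(freqs), model$fs,
                           convention == "squared", FALSE)
    eta[, , , wi] <- out$eta2
  }
  connectivity_tensor(eta, freqs, model$windows$start_s,
                      roi_names = model$roi_names,
                      meta = list(convention = convention,
                                  order = model$order))
}

#' SdDTF straight from an ensemble (fit-per-window driver)
#'
#' Fits a Vieira-Morf VAR of fixed order in every sliding window of the
#' ensemble and evaluates the SdDTF, all in compiled code; used by the
#' permutation stage where thousands of ensembles are scored.
#'
#' @param x array `[M x T x N]` (detrended/normalized).
#' @param fs sampling rate in Hz.
#' @param order VAR order.
#' @param window_len,window_step seconds.
#' @param freqs frequency grid in Hz.
#' @param convention SdDTF numerator convention.
#' @param roi_names optional node names.
#' @return A [connectivity_tensor()] with per-window stability indices in
#'   `meta$stability`.
#' @export
sddtf_ensemble <- function(x, fs, order, window_len = 0.55,
                           window_step = 0.01, freqs = seq(2, 50),
                           convention = c("squared", "literal"),
                           roi_names = NULL) {
  convention <- match.arg(convention)
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  wins <- sliding_windows(dim(x)[2], fs, window_len, window_step)
  out <- cpp_window_sddtf(x, as.integer(wins$start),
                          as.integer(wins$stop[1] - wins$start[1]),
                          as.integer(order), as.numeric(freqs), fs,
                          convention == "squared")
  connectivity_tensor(out$eta2, freqs, wins$start_s, roi_names = roi_names,
                      meta = list(convention = convention, order = order,
                                  stability = out$stability))
}

#' Integrate causal flow over a band and interval
#'
#' Mean SdDTF over the requested frequencies and window interval,
#' returning the `[sink x source]` flow matrix; node in-flow is the row
#' sum and out-flow the column sum (diagonal excluded).
#'
#' @param tensor a [connectivity_tensor()].
#' @param band length-2 Hz interval (inclusive).
#' @param interval length-2 seconds interval on window starts
#'   (inclusive); default all windows.
#' @return Matrix `[M x M]` with attributes `inflow` and `outflow`.
#' @export
integrate_flow <- function(tensor, band = NULL, interval = NULL) {
  if (is.null(band)) band <- range(tensor$freqs)
  if (is.null(interval)) interval <- range(tensor$window_starts)
  fi <- which(tensor$freqs >= band[1] & tensor$freqs <= band[2])
  wi <- which(tensor$window_starts >= interval[1] &
                tensor$window_starts <= interval[2])
  if (!length(fi)) stop("empty frequency band")
  if (!length(wi)) stop("empty window interval")
  m <- apply(tensor$eta2[, , fi, wi, drop = FALSE], c(1, 2), mean)
  dimnames(m) <- list(tensor$roi_names, tensor$roi_names)
  md <- m; diag(md) <- 0
  attr(m, "inflow") <- rowSums(md)
  attr(m, "outflow") <- colSums(md)
  m
}
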