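## Cortically constrained distributed inverse solution with
## Laplacian-weighted Tikhonov regularization, data-driven selection of
## the regularization parameter per epoch, and the max-power collapse of
## ROI current to one representative gridpoint signal.

#' cLORETA transformation matrix
#'
#' Solves the regularized normal equations
#' `T = (K'K + lambda^2 H'H)^-1 K'` by Cholesky factorization. This is the
#' reference (dense) path; the pipeline uses the spectral factorization in
#' [cloreta_operator()] which gives the same operator for all lambda at
#' once.
#'
#' @param K lead field `C x G`.
#' @param H_lap surface Laplacian `G x G` (the Tikhonov weighting).
#' @param lambda regularization scalar, `>= 0`.
#' @return `G x C` transformation matrix.
#' @export
cloreta_transform <- function(K, H_lap, lambda) {
  stopifnot(lambda >= 0, ncol(K) == nrow(H_lap))
  A <- crossprod(K) + lambda^2 * crossprod(H_lap)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    if (lambda == 0)
      stop("rank error: K'K singular at lambda = 0; use lambda > 0")
    stop("rank error: regularized system singular")
  }
  backsolve(ch, backsolve(ch, t(K), transpose = TRUE))
}

#' Precomputed inverse operator
#'
#' Factors the inverse problem once per head model so that the
#' transformation matrix, the GCV curve and the EM evidence are cheap for
#' any lambda. Uses the identity
#' `(K'K + lambda^2 L)^-1 K' = L^-1 K' (K L^-1 K' + lambda^2 I)^-1`
#' with `L = H'H + ridge * I` (the tiny ridge removes the constant null
#' vector of the Laplacian) and an eigendecomposition of the `C x C`
#' matrix `K L^-1 K'`.
#'
#' @param K lead field `C x G`.
#' @param H_lap surface Laplacian `G x G`.
#' @param ridge relative ridge added to `H'H`; scaled by the mean
#'   diagonal.
#' @param depth_weight normalize lead-field columns to unit gain before
#'   inversion (default). The electrode cap covers only part of the head,
#'   so unweighted minimum-norm solutions are biased toward high-gain
#'   gridpoints; gain normalization removes that bias from the max-power
#'   gridpoint selection. Source amplitudes are then in normalized units
#'   (`J_physical = J / gain`), which is immaterial downstream because
#'   ROI signals are re-standardized before modeling.
#' @return A `cloreta_operator` with fields `W` (`G x C`), `U`, `d`, `K`,
#'   `gain`.
#' @export
cloreta_operator <- function(K, H_lap, ridge = 1e-9, depth_weight = TRUE) {
  gain <- if (depth_weight) sqrt(colSums(K^2)) else rep(1, ncol(K))
  K <- sweep(K, 2, gain, "/")
  L <- crossprod(H_lap)
  eps <- ridge * mean(diag(L))
  diag(L) <- diag(L) + eps
  W <- solve(L, t(K))
  M <- K %*% W
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  structure(list(W = W, U = eig$vectors, d = pmax(eig$values, 0), K = K,
                 G = ncol(K), ridge = eps, gain = gain),
            class = "cloreta_operator")
}

#' Transformation matrix from a precomputed operator
#' @param op a [cloreta_operator()].
#' @param lambda regularization scalar.
#' @param rows optional gridpoint subset (rows of T to return).
#' @return `G x C` (or `length(rows) x C`) matrix.
#' @export
operator_transform <- function(op, lambda, rows = NULL) {
  Wl <- if (is.null(rows)) op$W else op$W[rows, , drop = FALSE]
  Wl %*% (op$U * rep(1 / (op$d + lambda^2), each = nrow(op$U))) %*% t(op$U)
}

#' Select lambda by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = ||(I - K T(lambda)) Phi||_F^2 /
#' trace(I - K T(lambda))^2` over a log-spaced grid. The default grid
#' spans the spectrum of `K L^-1 K'`, since GCV is invariant to the
#' overall scale of `Phi`.
#'
#' @param K lead field or a [cloreta_operator()] (then `H_lap` may be
#'   `NULL`).
#' @param H_lap surface Laplacian (ignored when `K` is an operator).
#' @param phi_epoch channel data `C x T` for one epoch.
#' @param grid optional lambda grid (log-spaced, >= 1 point).
#' @return List with `lambda`, `grid`, `gcv` (the curve).
#' @export
gcv_select_lambda <- function(K, H_lap = NULL, phi_epoch, grid = NULL) {
  op <- if (inherits(K, "cloreta_operator")) K else cloreta_operator(K, H_lap)
  if (all(phi_epoch == 0)) stop("degenerate epoch: all-zero data")
  if (is.null(grid)) grid <- default_lambda_grid(op)
  z <- crossprod(op$U, phi_epoch)
  s <- rowMeans(z^2)
  Tn <- ncol(phi_epoch)
  gcv <- vapply(grid, function(l) {
    shr <- l^2 / (op$d + l^2)
    num <- Tn * sum(shr^2 * s)
    den <- sum(shr)^2
    num / den
  }, 0)
  list(lambda = grid[which.min(gcv)], grid = grid, gcv = gcv)
}

default_lambda_grid <- function(op, n = 30) {
  dpos <- op$d[op$d > max(op$d) * 1e-12]
  exp(seq(log(sqrt(min(dpos)) * 1e-2), log(sqrt(max(op$d)) * 1e2),
          length.out = n))
}

#' Refine lambda by evidence (EM) iteration
#'
#' Treats the inverse problem as a two-variance-component hierarchical
#' Gaussian model (`Phi = K J + e`, `e ~ N(0, sigma2 I)`,
#' `J ~ N(0, tau2 L^-1)`) and runs the EM fixed point on
#' `(sigma2, tau2)`; the returned `lambda = sigma/tau` is the
#' evidence-optimal regularization for this epoch. The marginal
#' log-likelihood is non-decreasing across iterations.
#'
#' @param K lead field or a [cloreta_operator()].
#' @param H_lap surface Laplacian (ignored when `K` is an operator).
#' @param phi_epoch channel data `C x T`.
#' @param lambda0 starting value (typically the GCV pick).
#' @param tol relative-change stopping tolerance on lambda.
#' @param max_iter iteration cap.
#' @return List with `lambda`, `sigma2`, `tau2`, `evidence` (per
#'   iteration), `iterations`, `converged`.
#' @export
em_refine_lambda <- function(K, H_lap = NULL, phi_epoch, lambda0,
                             tol = 1e-4, max_iter = 50) {
  stopifnot(lambda0 > 0)
  op <- if (inherits(K, "cloreta_operator")) K else cloreta_operator(K, H_lap)
  C <- nrow(op$U); G <- op$G; Tn <- ncol(phi_epoch)
  z <- crossprod(op$U, phi_epoch)
  s <- rowMeans(z^2)
  lam <- lambda0
  shr <- lam^2 / (op$d + lam^2)
  sigma2 <- max(sum(shr^2 * s) / C, 1e-300)
  tau2 <- sigma2 / lam^2
  evidence <- function(sig2, ta2) {
    v <- ta2 * op$d + sig2
    -(Tn / 2) * sum(log(2 * pi * v) + s / v)
  }
  ev <- evidence(sigma2, tau2)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    lam2 <- sigma2 / tau2
    f <- op$d / (op$d + lam2)
    resid <- sum((lam2 / (op$d + lam2))^2 * s)
    sigma2_new <- (resid + sigma2 * sum(f)) / C
    quad <- sum(op$d * s / (op$d + lam2)^2)
    tau2_new <- (quad + tau2 * (G - sum(f))) / G
    sigma2 <- sigma2_new; tau2 <- tau2_new
    ev <- c(ev, evidence(sigma2, tau2))
    lam_new <- sqrt(sigma2 / tau2)
    if (abs(lam_new - lam) / lam < tol) {
      lam <- lam_new; converged <- TRUE; break
    }
    lam <- lam_new
  }
  if (!converged)
    warning("EM lambda refinement did not converge in ", max_iter,
            " iterations")
  list(lambda = lam, sigma2 = sigma2, tau2 = tau2, evidence = ev,
       iterations = it, converged = converged)
}

#' Localize one epoch
#'
#' Applies the transformation matrix: `J = T Phi`.
#'
#' @param T_mat transformation matrix `G x C`.
#' @param phi_epoch channel data `C x T`.
#' @param lambda the regularization used (stored for provenance).
#' @return A `source_activation`: list with `J` (`G x T`) and `lambda`.
#' @export
localize_epoch <- function(T_mat, phi_epoch, lambda = NA_real_) {
  if (ncol(T_mat) != nrow(phi_epoch)) stop("shape mismatch: T vs Phi")
  structure(list(J = T_mat %*% phi_epoch, lambda = lambda),
            class = "source_activation")
}

#' Localize every epoch of a recording
#'
#' Per-epoch regularization: GCV on a log-spaced grid, optionally followed
#' by the EM evidence refinement, then `J = T(lambda) Phi` restricted to
#' the requested gridpoints.
#'
#' @param op a [cloreta_operator()].
#' @param eeg an [epoched_eeg()].
#' @param rows gridpoint indices to retain (default all).
#' @param method `"gcv"` or `"gcv+em"`.
#' @param grid optional lambda grid.
#' @return List with `J` (`length(rows) x T x N`), `gridpoints`, `lambda`
#'   (per epoch), `fs`, `condition`.
#' @export
localize_epochs <- function(op, eeg, rows = NULL, method = c("gcv", "gcv+em"),
                            grid = NULL) {
  method <- match.arg(method)
  if (is.null(rows)) rows <- seq_len(op$G)
  if (is.null(grid)) grid <- default_lambda_grid(op)
  N <- n_trials(eeg); Tn <- n_samples(eeg)
  J <- array(0, c(length(rows), Tn, N))
  lambdas <- numeric(N)
  for (n in seq_len(N)) {
    phi <- eeg$data[, , n]
    lam <- gcv_select_lambda(op, phi_epoch = phi, grid = grid)$lambda
    if (method == "gcv+em")
      lam <- em_refine_lambda(op, phi_epoch = phi, lambda0 = lam)$lambda
    J[, , n] <- operator_transform(op, lam, rows) %*% phi
    lambdas[n] <- lam
  }
  list(J = J, gridpoints = rows, lambda = lambdas, fs = eeg$fs,
       condition = eeg$condition)
}

#' Collapse ROI current to representative signals by maximum power
#'
#' Within each ROI the gridpoint with the greatest mean squared current is
#' selected (aggregated over all epochs with `scope = "per_subject"`, or
#' separately per epoch with `scope = "per_epoch"`); ties break to the
#' lowest vertex index. Its current time series becomes the ROI signal.
#'
#' @param act localization result from [localize_epochs()] (or a list with
#'   `J` `[G x T x N]`, `gridpoints`, `fs`, `condition`).
#' @param roi_map named list of gridpoint index sets.
#' @param scope `"per_subject"` (default) or `"per_epoch"`.
#' @return A `roi_signals`: `data` `[M x T x N]`, `roi_names`,
#'   `chosen_gridpoint`, `fs`, `condition`.
#' @export
maxpower_roi_signals <- function(act, roi_map, scope = c("per_subject",
                                                         "per_epoch")) {
  scope <- match.arg(scope)
  if (any(lengths(roi_map) == 0)) stop("empty ROI in roi_map")
  d <- dim(act$J); Tn <- d[2]; N <- d[3]
  M <- length(roi_map)
  out <- array(0, c(M, Tn, N))
  chosen <- integer(M)
  for (m in seq_len(M)) {
    rows <- match(roi_map[[m]], act$gridpoints)
    if (anyNA(rows))
      stop("ROI ", names(roi_map)[m], " has gridpoints missing from the ",
           "localization result")
    if (scope == "per_subject") {
      pw <- apply(act$J[rows, , , drop = FALSE], 1, function(x) mean(x^2))
      g <- rows[which.max(pw)] # which.max: lowest index on ties
      out[m, , ] <- act$J[g, , ]
      chosen[m] <- act$gridpoints[g]
    } else {
      gs <- integer(N)
      for (n in seq_len(N)) {
        pw <- rowMeans(act$J[rows, , n, drop = FALSE]^2)
        g <- rows[which.max(pw)]
        out[m, , n] <- act$J[g, , n]
        gs[n] <- act$gridpoints[g]
      }
      chosen[m] <- gs[1]
    }
  }
  structure(list(data = out, roi_names = names(roi_map),
                 chosen_gridpoint = stats::setNames(chosen, names(roi_map)),
                 fs = act$fs, condition = act$condition),
            class = "roi_signals")
}

#' @export
print.roi_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<roi_signals> %d ROIs x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}
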