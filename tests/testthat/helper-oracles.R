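# Independent oracles and small fixtures used across the suite.

# Permutation/scale-invariant distance between estimated unmixing and true
# mixing; 0 for perfect recovery.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1) / (n * (n - 1))
  cc <- sum(colSums(P / apply(P, 2, max)) - 1) / (n * (n - 1))
  (r + cc) / 2
}

# Stationary covariance of a VAR(1): solves the discrete Lyapunov equation
# S = A S A' + Q by the Kronecker-product linear system.
lyapunov_cov <- function(A, Q) {
  n <- nrow(A)
  vecS <- solve(diag(n^2) - kronecker(A, A), as.vector(Q))
  matrix(vecS, n, n)
}

# Plain-R simulation of a constant-coefficient VAR (independent of the
# compiled simulator).
simulate_var_r <- function(A, Sigma, T, N, burn = 100, seed = 1) {
  set.seed(seed)
  if (is.matrix(A)) A <- array(A, c(nrow(A), ncol(A), 1))
  M <- dim(A)[1]; p <- dim(A)[3]
  ch <- chol(Sigma)
  out <- array(0, c(M, T, N))
  for (n in seq_len(N)) {
    x <- matrix(0, M, T + burn)
    v <- t(ch) %*% matrix(rnorm(M * (T + burn)), M)
    for (t in seq_len(T + burn)) {
      s <- v[, t]
      for (k in seq_len(min(p, t - 1))) s <- s + A[, , k] %*% x[, t - k]
      x[, t] <- s
    }
    out[, , n] <- x[, (burn + 1):(burn + T)]
  }
  out
}

# Least-squares VAR fit (independent of the lattice implementation).
ols_var_fit <- function(x, p) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  M <- nrow(x); Tn <- ncol(x)
  Y <- x[, (p + 1):Tn, drop = FALSE]
  Z <- do.call(rbind, lapply(seq_len(p), function(k)
    x[, (p + 1 - k):(Tn - k), drop = FALSE]))
  B <- Y %*% t(Z) %*% solve(Z %*% t(Z))
  array(B, c(M, M, p))
}

# Closed-form surface potential of a radial unit dipole in a homogeneous
# conducting sphere with insulated boundary (electrode at angle gamma from
# the dipole axis, dipole at radius b, sphere radius R).
single_sphere_potential <- function(cosg, b, R, sigma) {
  x <- b / R
  rho <- sqrt(1 - 2 * x * cosg + x^2)
  (2 * x * (cosg - x) / rho^3 + 1 / rho - 1) / (4 * pi * sigma * R^2 * x)
}

# Small head model shared by several test files (built once per run).
test_head_model <- local({
  hm <- NULL
  function(subdivisions = 2) {
    if (is.null(hm)) hm <<- build_head_model(subdivisions)
    hm
  }
})
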