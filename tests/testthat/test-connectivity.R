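test_that("transfer matrix matches closed forms and structure", {
  H <- transfer_matrix(array(0.5, c(1, 1, 1)), freqs = 0, fs = 128)
  expect_equal(Re(H[1, 1, 1]), 2, tolerance = 1e-12)
  H0 <- transfer_matrix(array(0, c(3, 3, 1)), freqs = c(1, 10, 30), fs = 128)
  for (f in 1:3) expect_equal(H0[, , f], diag(3) + 0i)
  # lower-triangular coefficients: the upper off-diagonal entry stays 0
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(0.5, 0.4, 0, 0.3), 2)
  A[, , 2] <- matrix(c(-0.2, 0.1, 0, -0.1), 2)
  Ht <- transfer_matrix(A, freqs = seq(1, 60, by = 1), fs = 128)
  expect_lt(max(abs(Ht[1, 2, ])), 1e-12)
  expect_warning(transfer_matrix(matrix(1.05), freqs = 1, fs = 128),
                 "unstable")
})

test_that("partial coherence has unit diagonal, vanishes for independent
          channels, and suppresses indirect paths", {
  A <- array(0, c(3, 3, 1))
  diag(A[, , 1]) <- c(0.5, 0.4, 0.3)
  Hd <- transfer_matrix(A, freqs = c(5, 10), fs = 128)
  sp <- spectral_and_partial_coherence(Hd, diag(3), 128)
  for (f in 1:2) {
    expect_equal(abs(diag(sp$P[, , f])), rep(1, 3), tolerance = 1e-10)
    off <- abs(sp$P[, , f]); diag(off) <- 0
    expect_lt(max(off), 1e-10)
    # Hermitian magnitude symmetry
    expect_equal(abs(sp$P[, , f]), t(abs(sp$P[, , f])), tolerance = 1e-10)
  }
  # chain 1 -> 2 -> 3: partial coherence of (1,3) much below ordinary
  # coherence at the coupling frequencies
  Ac <- array(0, c(3, 3, 1))
  diag(Ac[, , 1]) <- 0.5
  Ac[2, 1, 1] <- 0.6; Ac[3, 2, 1] <- 0.6
  Hc <- transfer_matrix(Ac, freqs = seq(2, 20), fs = 128)
  spc <- spectral_and_partial_coherence(Hc, diag(3), 128)
  ordinary <- sapply(seq_len(dim(Hc)[3]), function(f)
    abs(spc$S[1, 3, f]) / sqrt(abs(spc$S[1, 1, f]) * abs(spc$S[3, 3, f])))
  partial <- sapply(seq_len(dim(Hc)[3]), function(f) abs(spc$P[1, 3, f]))
  expect_lt(mean(partial), mean(ordinary) / 5)
})

fit_two_node <- function(seed = 1, a21 = 0.4) {
  A <- matrix(c(0.5, a21, 0, 0.5), 2, 2)
  x <- simulate_var_r(A, diag(2), T = 128, N = 40, seed = seed)
  structure(list(data = x, roi_names = c("n1", "n2"), fs = 128,
                 condition = rep("test", 40)),
            class = "roi_signals")
}

test_that("SdDTF normalizes exactly and respects planted direction", {
  roi <- detrend_normalize(fit_two_node(seed = 2))
  wm <- fit_windowed_mvar(roi, window_len = 0.55, window_step = 0.1,
                          order = 1, validate = FALSE)
  ten <- sddtf(wm, freqs = seq(2, 50))
  for (w in seq_len(dim(ten$eta2)[4]))
    expect_equal(sum(ten$eta2[, , , w]), 1, tolerance = 1e-10)
  expect_true(all(ten$eta2 >= 0))
  fwd <- mean(ten$eta2[2, 1, , ])   # 1 -> 2 (sink 2, source 1)
  bwd <- mean(ten$eta2[1, 2, , ])
  expect_gte(fwd / bwd, 5)
  # literal convention: same denominator, unsquared numerator, so the
  # ratio literal^2 / squared is one constant (1/denominator) everywhere
  tlit <- sddtf(wm, freqs = seq(2, 50), convention = "literal")
  ratio <- tlit$eta2[, , , 1]^2 / ten$eta2[, , , 1]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
  expect_gt(abs(sum(tlit$eta2[, , , 1]) - 1), 1e-3) # no exact normalization
  expect_equal(tlit$meta$convention, "literal")
})

test_that("the ensemble driver agrees with the stepwise path", {
  roi <- detrend_normalize(fit_two_node(seed = 3))
  wm <- fit_windowed_mvar(roi, window_len = 0.55, window_step = 0.1,
                          order = 1, validate = FALSE)
  t1 <- sddtf(wm, freqs = seq(2, 20))
  t2 <- sddtf_ensemble(roi$data, roi$fs, order = 1, window_len = 0.55,
                       window_step = 0.1, freqs = seq(2, 20),
                       roi_names = roi$roi_names)
  expect_equal(t1$eta2, t2$eta2, tolerance = 1e-10)
  expect_true(all(t2$meta$stability < 0))
})

test_that("partial-coherence weighting suppresses the indirect chain edge
          relative to plain DTF", {
  set.seed(4)
  Ac <- array(0, c(3, 3, 1))
  diag(Ac[, , 1]) <- 0.5
  Ac[2, 1, 1] <- 0.6; Ac[3, 2, 1] <- 0.6
  x <- simulate_var_r(Ac, diag(3), T = 400, N = 20, seed = 4)
  fit <- vieira_morf_fit(x, 1)
  freqs <- seq(2, 50)
  out <- cortconn:::cpp_sddtf_model(fit$A, fit$Sigma, freqs, 128, TRUE, TRUE)
  eta <- out$eta2
  # plain DTF with the same normalization but no partial-coherence factor
  H2 <- abs(out$H)^2
  dtf <- H2 / sum(H2)
  indirect_sddtf <- sum(eta[3, 1, ]) / sum(eta)
  indirect_dtf <- sum(dtf[3, 1, ]) / sum(dtf)
  expect_gte(indirect_dtf / indirect_sddtf, 3)
})

test_that("coupling through a resonant lag pattern localizes in
          frequency", {
  # driver node resonant near 16 Hz at fs 128
  fs <- 128; f0 <- 16; r <- 0.9
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 2 * r * cos(2 * pi * f0 / fs); A[1, 1, 2] <- -r^2
  A[2, 2, 1] <- 0.3
  A[2, 1, 1] <- 0.5
  x <- simulate_var_r(A, diag(2), T = 256, N = 30, seed = 5)
  fit <- vieira_morf_fit(x, 2)
  freqs <- seq(2, 50)
  out <- cortconn:::cpp_sddtf_model(fit$A, fit$Sigma, freqs, fs, TRUE, FALSE)
  peak_f <- freqs[which.max(out$eta2[2, 1, ])]
  expect_lte(abs(peak_f - f0), 2)
})

test_that("switched-off coupling shows up as a drop across windows", {
  net <- truth_network(2, order = 1, self = 0.4,
                       coupling = data.frame(from = 1, to = 2, lag = 1,
                                             coef_r1 = 0.6, coef_r2 = 0),
                       regime_bounds_s = 1)
  x <- simulate_var_sources(net, T = 256, N = 40, fs = 128, seed = 6)
  roi <- detrend_normalize(
    structure(list(data = x, roi_names = c("a", "b"), fs = 128,
                   condition = rep("test", 40)), class = "roi_signals"))
  ten <- sddtf_ensemble(roi$data, 128, order = 1, window_len = 0.55,
                        window_step = 0.05, freqs = seq(2, 40, by = 2))
  edge <- apply(ten$eta2[2, 1, , , drop = FALSE], 4, mean)
  early <- mean(edge[ten$window_starts <= 0.2])
  late <- mean(edge[ten$window_starts >= 1.0]) # windows fully post-switch
  expect_lt(late, 0.5 * early)
})

test_that("integrated flow slices and aggregates correctly", {
  set.seed(7)
  eta <- array(runif(3 * 3 * 4 * 5), c(3, 3, 4, 5))
  # normalize per window over all pairs/freqs (as the squared convention)
  for (w in 1:5) eta[, , , w] <- eta[, , , w] / sum(eta[, , , w])
  ten <- connectivity_tensor(eta, freqs = c(2, 4, 6, 8),
                             window_starts = (0:4) / 10)
  full <- integrate_flow(ten)
  expect_lte(sum(full) - sum(diag(full)), 1)  # off-diagonal mass <= 1
  one <- integrate_flow(ten, band = c(4, 4), interval = c(0.2, 0.2))
  expect_equal(unname(one[2, 3]), eta[2, 3, 2, 3])
  inf <- attr(full, "inflow"); outf <- attr(full, "outflow")
  md <- full; diag(md) <- 0
  expect_equal(unname(inf), unname(rowSums(md)))
  expect_equal(unname(outf), unname(colSums(md)))
  expect_error(integrate_flow(ten, band = c(100, 120)), "empty")
})
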