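test_that("cloreta_transform solves the regularized normal equations", {
  set.seed(1)
  # square invertible K, identity penalty, lambda = 0: exact inverse
  K <- matrix(rnorm(16), 4, 4)
  expect_equal(cloreta_transform(K, diag(4), 0), solve(K),
               tolerance = 1e-8)
  # dense-inverse oracle on an underdetermined system with a graph penalty
  mesh <- build_source_mesh(0)
  H <- surface_laplacian(mesh)
  K2 <- matrix(rnorm(8 * 12), 8, 12)
  T1 <- cloreta_transform(K2, H, 0.1)
  T2 <- solve(crossprod(K2) + 0.01 * crossprod(H)) %*% t(K2)
  expect_lt(max(abs(T1 - T2)), 1e-8)
  # lambda = 0 with G > C must fail with guidance
  expect_error(cloreta_transform(K2, H, 0), "lambda > 0")
  # shrinkage: operator norm decreases for large lambda
  norms <- sapply(c(1, 10, 100, 1000), function(l)
    norm(cloreta_transform(K2, H, l), "F"))
  expect_true(all(diff(norms) < 0))
})

test_that("the factored operator reproduces the dense transform", {
  set.seed(2)
  mesh <- build_source_mesh(1)
  H <- surface_laplacian(mesh)
  K <- matrix(rnorm(16 * 42), 16, 42)
  op <- cloreta_operator(K, H, depth_weight = FALSE)
  lam <- 0.5
  Tfast <- operator_transform(op, lam)
  L <- crossprod(H); diag(L) <- diag(L) + op$ridge
  Tdense <- solve(crossprod(K) + lam^2 * L) %*% t(K)
  expect_lt(max(abs(Tfast - Tdense)), 1e-7 * max(abs(Tdense)))
})

test_that("GCV selects sensible regularization", {
  set.seed(3)
  hm <- test_head_model()
  op <- cloreta_operator(hm$K, hm$H_lap)
  phi <- hm$K[, 30, drop = FALSE] %*% matrix(rnorm(64), 1)
  # single-point grid returns that point
  expect_equal(gcv_select_lambda(op, phi_epoch = phi, grid = 3)$lambda, 3)
  expect_error(gcv_select_lambda(op, phi_epoch = phi * 0), "degenerate")
  # more sensor noise leads to larger selected lambda (monotone trend)
  lams <- sapply(c(0.01, 10), function(sn) {
    median(replicate(10, {
      noise <- matrix(rnorm(length(phi)), nrow(phi)) * sn * sd(phi)
      gcv_select_lambda(op, phi_epoch = phi + noise)$lambda
    }))
  })
  expect_gt(lams[2], lams[1])
  # noise-free data from the model: selected lambda gives near-minimal
  # reconstruction error over the grid
  g <- 25
  phi0 <- hm$K[, g, drop = FALSE] %*% matrix(rnorm(64), 1)
  sel <- gcv_select_lambda(op, phi_epoch = phi0)
  errs <- sapply(sel$grid, function(l) {
    J <- operator_transform(op, l) %*% phi0
    1 - max(rowMeans(J^2)) / sum(rowMeans(J^2))
  })
  expect_lte(which(sel$grid == sel$lambda), which.min(errs) + 8)
})

test_that("EM refinement maximizes evidence and recovers the variance
          ratio", {
  set.seed(4)
  hm <- build_head_model(1)
  op <- cloreta_operator(hm$K, hm$H_lap, depth_weight = FALSE)
  L <- crossprod(hm$H_lap); diag(L) <- diag(L) + op$ridge
  Le <- eigen(L, symmetric = TRUE)
  G <- ncol(hm$K); C <- nrow(hm$K)
  tau <- 2; sigma <- 3
  ratios <- replicate(30, {
    J <- Le$vectors %*% (matrix(rnorm(G * 40), G) * tau / sqrt(Le$values))
    phi <- hm$K %*% J + sigma * matrix(rnorm(C * 40), C)
    lam0 <- gcv_select_lambda(op, phi_epoch = phi)$lambda
    em <- em_refine_lambda(op, phi_epoch = phi, lambda0 = lam0)
    em$lambda^2 / (sigma^2 / tau^2)
  })
  expect_lt(abs(median(ratios) - 1), 0.25)
  # evidence is non-decreasing along the iteration
  J <- Le$vectors %*% (matrix(rnorm(G * 40), G) * tau / sqrt(Le$values))
  phi <- hm$K %*% J + sigma * matrix(rnorm(C * 40), C)
  em <- em_refine_lambda(op, phi_epoch = phi, lambda0 = 1)
  expect_true(all(diff(em$evidence) > -1e-6 * abs(em$evidence[1])))
  # huge tolerance: single iteration
  em1 <- em_refine_lambda(op, phi_epoch = phi, lambda0 = 1, tol = 1e6)
  expect_equal(em1$iterations, 1)
})

test_that("localization is linear and finds a planted dipole", {
  set.seed(5)
  hm <- test_head_model()
  op <- cloreta_operator(hm$K, hm$H_lap)
  Tm <- operator_transform(op, 1)
  expect_equal(localize_epoch(Tm, matrix(0, 64, 10))$J,
               matrix(0, ncol(hm$K), 10))
  phi1 <- hm$K[, 3, drop = FALSE] %*% matrix(rnorm(20), 1)
  phi2 <- hm$K[, 80, drop = FALSE] %*% matrix(rnorm(20), 1)
  expect_equal(localize_epoch(Tm, phi1 + phi2)$J,
               localize_epoch(Tm, phi1)$J + localize_epoch(Tm, phi2)$J)
  expect_error(localize_epoch(Tm, matrix(0, 5, 4)), "shape")
  g <- which(hm$mesh$vertices[, 3] > 0)[10]
  phi <- hm$K[, g, drop = FALSE] %*% matrix(rnorm(128), 1)
  lam <- gcv_select_lambda(op, phi_epoch = phi)$lambda
  J <- localize_epoch(operator_transform(op, lam), phi)$J
  expect_equal(which.max(rowMeans(J^2)), g)
})

test_that("max-power ROI collapse picks the right gridpoint with
          deterministic tie-breaks", {
  act <- list(J = array(0, c(4, 10, 3)), gridpoints = 1:4, fs = 128,
              condition = rep("test", 3))
  act$J[2, , ] <- 2    # power 4
  act$J[3, , ] <- 1    # power 1
  roi_map <- list(A = c(2, 3), B = c(1, 4))
  rs <- maxpower_roi_signals(act, roi_map)
  expect_equal(unname(rs$chosen_gridpoint["A"]), 2)
  expect_equal(rs$data[1, , ], act$J[2, , ])
  # exact tie: lowest index wins
  act$J[3, , ] <- -2
  rs2 <- maxpower_roi_signals(act, roi_map)
  expect_equal(unname(rs2$chosen_gridpoint["A"]), 2)
  expect_error(maxpower_roi_signals(act, list(A = integer())), "empty")
  # per-epoch scope agrees with per-subject majority on stationary data
  set.seed(6)
  act3 <- list(J = array(rnorm(4 * 50 * 9), c(4, 50, 9)),
               gridpoints = 1:4, fs = 128, condition = rep("test", 9))
  act3$J[2, , ] <- act3$J[2, , ] * 3
  ps <- maxpower_roi_signals(act3, list(A = 1:4), scope = "per_subject")
  pe <- maxpower_roi_signals(act3, list(A = 1:4), scope = "per_epoch")
  expect_equal(unname(ps$chosen_gridpoint["A"]), 2)
  expect_equal(unname(pe$chosen_gridpoint["A"]), 2)
})

test_that("per-epoch lambda does not degrade reconstruction on
          heteroscedastic epochs", {
  set.seed(7)
  hm <- test_head_model()
  op <- cloreta_operator(hm$K, hm$H_lap)
  top <- which(hm$mesh$vertices[, 3] > 0)
  g <- top[5]
  noise_sds <- rep(c(0.05, 2), each = 6)
  err_per <- err_global <- numeric(12)
  phis <- list(); truths <- list()
  for (e in 1:12) {
    s <- matrix(rnorm(64), 1)
    phi0 <- hm$K[, g, drop = FALSE] %*% s
    phis[[e]] <- phi0 + noise_sds[e] * sd(phi0) *
      matrix(rnorm(length(phi0)), nrow(phi0))
    truths[[e]] <- phi0
  }
  lam_each <- sapply(phis, function(p)
    gcv_select_lambda(op, phi_epoch = p)$lambda)
  lam_global <- gcv_select_lambda(op, phi_epoch = do.call(cbind, phis))$lambda
  recon_err <- function(phi, lam, truth) {
    J <- operator_transform(op, lam) %*% phi
    phihat <- op$K %*% J
    truth_n <- truth / sd(truth)
    sum((phihat / sd(truth) - truth_n)^2)
  }
  for (e in 1:12) {
    err_per[e] <- recon_err(phis[[e]], lam_each[e], truths[[e]])
    err_global[e] <- recon_err(phis[[e]], lam_global, truths[[e]])
  }
  expect_lte(mean(err_per), mean(err_global) * 1.05)
})
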