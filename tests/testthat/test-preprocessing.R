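make_tone_eeg <- function(freqs_hz, fs = 512, T = 2048, C = 2) {
  t <- seq_len(T) / fs
  x <- array(0, c(C, T, 1))
  for (c in seq_len(C))
    x[c, , 1] <- rowSums(sapply(freqs_hz, function(f) sin(2 * pi * f * t)))
  epoched_eeg(x, fs)
}

rms_mid <- function(v) {
  n <- length(v)
  sqrt(mean(v[round(n / 4):round(3 * n / 4)]^2))
}

test_that("band-pass keeps the passband, kills stopband and DC", {
  eeg10 <- make_tone_eeg(10)
  f10 <- bandpass_filter(eeg10, 1, 55)
  expect_lt(abs(rms_mid(f10$data[1, , 1]) / rms_mid(eeg10$data[1, , 1]) - 1),
            0.05)
  eeg100 <- make_tone_eeg(100)
  f100 <- bandpass_filter(eeg100, 1, 55)
  expect_lt(rms_mid(f100$data[1, , 1]) / rms_mid(eeg100$data[1, , 1]), 0.1)
  dc <- make_tone_eeg(10)
  dc$data <- dc$data + 50
  fdc <- bandpass_filter(dc, 1, 55)
  expect_lt(abs(mean(fdc$data[1, , 1])), 1)
  expect_error(bandpass_filter(eeg10, 1, 400), "Nyquist")
})

test_that("zero-phase filtering does not shift a passband tone", {
  eeg <- make_tone_eeg(10)
  f <- bandpass_filter(eeg, 1, 55)
  mid <- 513:1536
  lagcor <- sapply(-3:3, function(l)
    cor(eeg$data[1, mid, 1], f$data[1, mid + l, 1]))
  expect_equal(which.max(lagcor), 4L)     # zero lag maximizes correlation
})

test_that("average re-reference zeroes the channel mean and is a
          projection", {
  x <- array(c(1, 3, 1, 3), c(2, 2, 1))
  e <- epoched_eeg(x, 10)
  r <- rereference_average(e)
  expect_equal(r$data[, , 1], matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(rereference_average(r)$data, r$data)  # idempotent
  set.seed(1)
  big <- epoched_eeg(array(rnorm(6 * 50), c(6, 50, 1)), 10)
  rb <- rereference_average(big)
  expect_equal(max(abs(colMeans(rb$data[, , 1]))), 0, tolerance = 1e-12)
  expect_lte(qr(rb$data[, , 1])$rank, 5)  # rank <= C - 1
})

test_that("kurtosis rejection flags only the contaminated channel", {
  set.seed(6)
  x <- array(rnorm(32 * 200 * 5), c(32, 200, 5))
  spikes <- runif(200 * 5) < 0.05
  x[7, , ][spikes] <- x[7, , ][spikes] + 12
  e <- epoched_eeg(x, 128)
  kr <- kurtosis_reject(e, 5)
  expect_true(kr$channel_flags[7])
  expect_equal(sum(kr$channel_flags), 1)
  expect_equal(dim(kr$cleaned$data)[1], 31)
  # homogeneous data: no flags
  clean <- epoched_eeg(array(rnorm(8 * 100 * 4), c(8, 100, 4)), 128)
  kr2 <- kurtosis_reject(clean, 5)
  expect_false(any(kr2$channel_flags))
  expect_false(any(kr2$trial_flags))
  expect_error(kurtosis_reject(e, 0), "positive")
  tiny <- epoched_eeg(array(rnorm(2 * 10 * 2), c(2, 10, 2)), 10)
  expect_error(kurtosis_reject(tiny, 5), "at least 3")
})

test_that("Infomax ICA recovers mixed Laplacian sources and is
          deterministic", {
  set.seed(7)
  S <- matrix(rexp(2 * 8000) * sample(c(-1, 1), 2 * 8000, TRUE), 2)
  Amix <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  eeg <- epoched_eeg(array(Amix %*% S, c(2, 8000, 1)), 128)
  dec <- infomax_ica(eeg, seed = 1)
  expect_lt(amari_index(dec$unmixing %*% Amix), 0.1)
  expect_equal(dec$mixing %*% dec$unmixing, diag(2), tolerance = 1e-6)
  dec2 <- infomax_ica(eeg, seed = 1)
  expect_identical(dec$unmixing, dec2$unmixing)
  # already-unmixed orthogonal sources: unmixing ~ scaled permutation
  eeg0 <- epoched_eeg(array(S, c(2, 8000, 1)), 128)
  dec0 <- infomax_ica(eeg0, seed = 1)
  expect_lt(amari_index(dec0$unmixing), 0.1)
  # rank-deficient input is refused with guidance
  bad <- eeg
  bad$data[2, , ] <- bad$data[1, , ]
  expect_error(infomax_ica(bad, seed = 1), "rank-deficient")
})

test_that("equivalent-dipole fitting finds the generating gridpoint", {
  hm <- test_head_model()
  g <- 40
  fit <- fit_equivalent_dipole(hm$K[, g], hm)
  expect_equal(fit$gridpoint, g)
  expect_lt(fit$residual_variance, 1e-10)
  set.seed(8)
  noisy <- hm$K[, g] + rnorm(nrow(hm$K)) * sd(hm$K[, g]) / 10 # SNR 20 dB
  fit2 <- fit_equivalent_dipole(noisy, hm)
  expect_equal(fit2$gridpoint, g)
  # map orthogonal to the lead-field column space has RV ~ 1
  sv <- svd(hm$K)
  resid_dir <- sv$u[, ncol(sv$u)]         # weakest direction
  proj <- resid_dir - hm$K %*% (MASS::ginv(hm$K) %*% resid_dir)
  if (sqrt(sum(proj^2)) > 1e-8) {
    fit3 <- fit_equivalent_dipole(as.vector(proj), hm)
    expect_gt(fit3$residual_variance, 0.9)
  }
  expect_error(fit_equivalent_dipole(rep(0, nrow(hm$K)), hm), "zero-norm")
})

test_that("IC selection keeps dipolar maps and drops noise maps", {
  hm <- test_head_model()
  set.seed(9)
  C <- nrow(hm$K)
  mixing <- cbind(hm$K[, 10], hm$K[, 50], rnorm(C), rnorm(C))
  dec <- structure(list(mixing = mixing,
                        unmixing = MASS::ginv(mixing),
                        activations = array(rnorm(4 * 50 * 2), c(4, 50, 2)),
                        fs = 128, condition = rep("test", 2)),
                   class = "ica_decomposition")
  sel <- select_cortical_ics(dec, hm, rv_threshold = 0.15)
  expect_true(all(c(1, 2) %in% sel$retained))
  expect_false(any(c(3, 4) %in% sel$retained))
  sel_all <- select_cortical_ics(dec, hm, rv_threshold = 1)
  expect_equal(sel_all$retained, 1:4)
})

test_that("back-projection reconstructs and filters components", {
  set.seed(10)
  eeg <- epoched_eeg(array(rnorm(4 * 1000), c(4, 1000, 1)), 128)
  dec <- infomax_ica(eeg, seed = 2)
  full <- backproject(dec, 1:4)
  centered <- eeg$data - rowMeans(matrix(eeg$data, 4))
  expect_lt(max(abs(full$data - array(centered, dim(eeg$data)))), 1e-8)
  one <- backproject(dec, 2)
  expect_lte(qr(matrix(one$data, 4))$rank, 1)
  expect_error(backproject(dec, integer()), "retained")
})

test_that("removing the blink component lowers frontal variance", {
  hm <- build_head_model(1, electrodes = standard_electrodes(16))
  net <- truth_network(4, self = c(0.5, -0.3))
  src <- simulate_var_sources(net, 256, 8, 128, seed = 11)
  rois <- names(hm$roi_map)[c(1, 2, 5, 6)]
  clean <- project_to_channels(src, hm, rois, snr_db = 30, seed = 11)
  dirty <- add_artifact_components(clean, "blink", rate = 4, seed = 12)
  dec <- infomax_ica(dirty, seed = 3, max_iter = 150)
  blink_topo <- pmax(hm$electrodes$y, 0)
  blink_ic <- which.max(abs(cor(dec$mixing, blink_topo)))
  cleaned <- backproject(dec, setdiff(seq_len(nrow(dec$mixing)), blink_ic))
  frontal <- which(hm$electrodes$y > 0.05)
  v_dirty <- mean(dirty$data[frontal, , ]^2)
  v_clean <- mean(cleaned$data[frontal, , ]^2)
  expect_lt(v_clean, 0.5 * v_dirty)
})

test_that("resampling preserves duration and passband, removes
          out-of-band content", {
  eeg <- make_tone_eeg(10, fs = 512, T = 2048)
  r <- resample_eeg(eeg, 128)
  expect_equal(dim(r$data)[2], 512)       # T / 4
  expect_equal(r$fs, 128)
  expect_lt(abs(rms_mid(r$data[1, , 1]) / rms_mid(eeg$data[1, , 1]) - 1),
            0.05)
  hi <- make_tone_eeg(60, fs = 512, T = 2048)
  rh <- resample_eeg(hi, 128)
  expect_lt(rms_mid(rh$data[1, , 1]) / rms_mid(hi$data[1, , 1]), 0.1)
  expect_error(resample_eeg(eeg, -10), "positive")
  expect_error(resample_eeg(eeg, 100), "integer")
})
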