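## Multi-subject, two-condition synthetic EEG with known directed source
## coupling: stable VAR dynamics among ROI-anchored cortical nodes with
## piecewise-constant (planning vs execution) coefficient schedules,
## projected to the scalp through the spherical lead field, plus sensor
## noise and optional stereotyped artifacts.

#' Ground-truth directed source network
#'
#' A VAR(p) network over `n_nodes` with piecewise-constant coefficient
#' regimes: each coupling entry carries one coefficient per regime, and
#' the regime boundary (default 0.5 s) mirrors a planning/execution
#' split within the epoch.
#'
#' @param n_nodes number of nodes.
#' @param order VAR order.
#' @param self numeric vector of self-coefficients per lag (recycled to
#'   all nodes).
#' @param coupling data frame with columns `from`, `to`, `lag` and one
#'   `coef_r<k>` column per regime (a single `coef` column means the same
#'   value in every regime).
#' @param regime_bounds_s regime switch times in seconds (within-epoch).
#' @param noise_cov innovation covariance (default identity).
#' @return A `truth_network`; construction fails if any regime's
#'   companion matrix has spectral radius `>= 1`.
#' @export
truth_network <- function(n_nodes, order = 2,
                          self = c(0.5, -0.3),
                          coupling = NULL,
                          regime_bounds_s = 0.5,
                          noise_cov = NULL) {
  M <- n_nodes
  p <- order
  if (is.null(noise_cov)) noise_cov <- diag(M)
  stopifnot(nrow(noise_cov) == M, isSymmetric(unname(noise_cov)))
  if (is.null(coupling))
    coupling <- data.frame(from = integer(), to = integer(),
                           lag = integer(), coef = numeric())
  cc <- grep("^coef", names(coupling), value = TRUE)
  n_regimes <- max(1L, length(cc), length(regime_bounds_s) + 1L)
  A <- array(0, c(M, M * p, n_regimes))
  for (r in seq_len(n_regimes)) {
    for (k in seq_len(p)) {
      if (k <= length(self))
        for (m in seq_len(M)) A[m, (k - 1) * M + m, r] <- self[k]
    }
    if (nrow(coupling)) {
      cols <- if (length(cc) >= n_regimes) cc[r] else cc[1]
      for (i in seq_len(nrow(coupling))) {
        k <- coupling$lag[i]
        A[coupling$to[i], (k - 1) * M + coupling$from[i], r] <-
          coupling[[cols]][i]
      }
    }
  }
  net <- structure(list(n_nodes = M, order = p, A = A,
                        self = self, coupling = coupling,
                        regime_bounds_s = regime_bounds_s,
                        noise_cov = noise_cov),
                   class = "truth_network")
  si <- network_stability(net)
  if (any(si >= 0))
    stop("stability error: regime(s) ", paste(which(si >= 0), collapse = ","),
         " have spectral radius >= 1")
  net
}

#' Log spectral radius of each regime of a truth network
#' @param net a [truth_network()].
#' @return Numeric vector, one log-spectral-radius per regime.
#' @export
network_stability <- function(net) {
  vapply(seq_len(dim(net$A)[3]), function(r)
    stability_index(array(net$A[, , r], c(net$n_nodes, net$n_nodes,
                                          net$order))),
    0)
}

regime_per_sample <- function(net, T, fs) {
  bounds <- round(net$regime_bounds_s * fs)
  reg <- integer(T)
  for (b in bounds) reg[seq_len(T) > b] <- reg[seq_len(T) > b] + 1L
  pmin(reg, dim(net$A)[3] - 1L)
}

#' Simulate source signals from a truth network
#'
#' Independent trial realizations of the (time-varying) VAR process with
#' Gaussian innovations; a burn-in of `10 * order` samples under the
#' first regime is discarded per trial.
#'
#' @param net a [truth_network()].
#' @param T samples per trial.
#' @param N trials.
#' @param fs sampling rate in Hz (locates the regime boundaries).
#' @param seed RNG seed.
#' @return Array `[M x T x N]`.
#' @export
simulate_var_sources <- function(net, T, N, fs, seed = 1L) {
  si <- network_stability(net)
  if (any(si >= 0)) stop("stability error: unstable network")
  if (T <= 10 * net$order) stop("T must exceed 10 * order")
  M <- net$n_nodes
  burn <- 10L * net$order
  set.seed(seed)
  ch <- chol(net$noise_cov)
  innov <- array(t(ch) %*% matrix(rnorm(M * (T + burn) * N), M),
                 c(M, T + burn, N))
  cpp_var_simulate(net$A, net$order, regime_per_sample(net, T, fs),
                   burn, innov)
}

roi_representative_vertex <- function(model, roi) {
  idx <- model$roi_map[[roi]]
  if (is.null(idx)) stop("index error: unknown ROI ", roi)
  v <- model$mesh$vertices[idx, , drop = FALSE]
  ctr <- colMeans(v)
  idx[which.min(sqrt(rowSums((v - rep(ctr, each = nrow(v)))^2)))]
}

#' Project source signals to the scalp
#'
#' Channel data are the lead-field mixture of the node signals (each
#' node placed at a deterministic representative gridpoint inside its
#' ROI) plus white Gaussian sensor noise at the requested SNR (total
#' signal power over total noise power, in dB).
#'
#' @param sources array `[M x T x N]`.
#' @param model head model.
#' @param roi_assignment character vector: ROI name per node.
#' @param snr_db signal-to-noise ratio in dB (`Inf` for noise-free).
#' @param seed RNG seed for the noise.
#' @param fs sampling rate in Hz.
#' @param condition per-trial labels.
#' @return An [epoched_eeg()]; the chosen gridpoints are attached as
#'   attribute `"gridpoints"`.
#' @export
project_to_channels <- function(sources, model, roi_assignment, snr_db = 10,
                                seed = 1L, fs = 128,
                                condition = NULL) {
  d <- dim(sources); M <- d[1]; Tn <- d[2]; N <- d[3]
  stopifnot(length(roi_assignment) == M)
  gp <- vapply(roi_assignment, roi_representative_vertex, 0L, model = model)
  Ks <- model$K[, gp, drop = FALSE]
  C <- nrow(Ks)
  sig <- array(Ks %*% matrix(sources, M), c(C, Tn, N))
  if (is.finite(snr_db)) {
    set.seed(seed)
    noise <- array(rnorm(C * Tn * N), c(C, Tn, N))
    psig <- mean(sig^2)
    pn <- psig / 10^(snr_db / 10)
    sig <- sig + noise * sqrt(pn)
  }
  out <- epoched_eeg(sig, fs,
                     channel_names = as.character(model$electrodes$name),
                     channel_pos = as.matrix(model$electrodes[, c("x", "y", "z")]),
                     condition = condition)
  attr(out, "gridpoints") <- gp
  out
}

#' Add stereotyped artifact components
#'
#' `kind = "blink"`: a shared frontal-weighted transient (rank-1
#' topography over channels, raised-cosine time course) occurring at the
#' given rate per second. `kind = "impulse-channel"`: sparse heavy-tailed
#' spikes on a single channel at the given rate per sample, the classic
#' signature that kurtosis-based rejection flags.
#'
#' @param eeg an [epoched_eeg()].
#' @param kind `"blink"` or `"impulse-channel"`.
#' @param rate events per second (blink) or spike probability per sample
#'   (impulse-channel).
#' @param seed RNG seed.
#' @param channel target channel for `"impulse-channel"` (default 1).
#' @param amplitude artifact amplitude as a multiple of the data's
#'   standard deviation.
#' @return The contaminated [epoched_eeg()].
#' @export
add_artifact_components <- function(eeg, kind = c("blink", "impulse-channel"),
                                    rate, seed = 1L, channel = 1L,
                                    amplitude = NULL) {
  kind <- match.arg(kind)
  stopifnot(rate >= 0)
  if (rate == 0) return(eeg)
  set.seed(seed)
  C <- n_channels(eeg); Tn <- n_samples(eeg); N <- n_trials(eeg)
  s0 <- sd(eeg$data)
  if (kind == "blink") {
    if (is.null(amplitude)) amplitude <- 8
    ## frontal weighting from electrode geometry when available
    topo <- if (!is.null(eeg$channel_pos)) {
      w <- pmax(eeg$channel_pos[, 2], 0)    # anterior (y > 0) channels
      if (all(w == 0)) w <- rep(1, C)
      w / max(w)
    } else exp(-(seq_len(C) - 1) / (C / 4))
    wl <- max(3L, round(0.3 * eeg$fs))
    wave <- (1 - cos(2 * pi * seq_len(wl) / (wl + 1))) / 2
    dur <- Tn / eeg$fs
    for (n in seq_len(N)) {
      k <- rpois(1, rate * dur)
      if (k == 0) next
      centers <- sample.int(max(Tn - wl, 1), k, replace = TRUE)
      tr <- numeric(Tn)
      for (cs in centers)
        tr[cs:(cs + wl - 1)] <- tr[cs:(cs + wl - 1)] + wave
      eeg$data[, , n] <- eeg$data[, , n] +
        amplitude * s0 * topo %o% tr
    }
  } else {
    if (is.null(amplitude)) amplitude <- 10
    for (n in seq_len(N)) {
      hits <- which(runif(Tn) < rate)
      if (length(hits))
        eeg$data[channel, hits, n] <- eeg$data[channel, hits, n] +
          amplitude * s0 * sample(c(-1, 1), length(hits), replace = TRUE)
    }
  }
  eeg
}

#' Default control/test truth networks over the nine standard ROIs
#'
#' Both conditions share the node set and a sparse baseline of directed
#' edges; the test network adds one condition-specific edge (anterior
#' cingulate to left motor cortex, coupling 0.4) active only during the
#' planning regime (before 0.5 s). This is the planted contrast the
#' group statistics should recover.
#'
#' @param planted_coef planning-regime coupling of the planted edge.
#' @return List with `control`, `test` ([truth_network()]s),
#'   `roi_assignment` and `planted` (from/to/regime of the planted
#'   edge).
#' @export
default_truth_networks <- function(planted_coef = 0.4) {
  rois <- c("L_Occ", "R_Occ", "L_Par", "R_Par", "L_Mot", "R_Mot",
            "ACC", "SMA", "Prec")
  base <- data.frame(
    from = c(1, 2, 3, 9, 8),
    to   = c(3, 4, 5, 4, 7),
    lag  = c(1, 1, 1, 2, 1),
    coef_r1 = c(0.30, 0.30, 0.25, 0.25, 0.20),
    coef_r2 = c(0.30, 0.30, 0.25, 0.25, 0.20))
  test_coupling <- rbind(base,
                         data.frame(from = 7, to = 5, lag = 1,
                                    coef_r1 = planted_coef, coef_r2 = 0))
  list(control = truth_network(9, coupling = base),
       test = truth_network(9, coupling = test_coupling),
       roi_assignment = rois,
       planted = list(from = 7L, to = 5L, regime = 1L,
                      roi_from = "ACC", roi_to = "L_Mot"))
}

## Jitter the coupling coefficients of the two condition networks with a
## shared per-edge multiplier (edges keyed by from/to/lag), so that edges
## common to both conditions stay identical within a subject and only the
## condition-specific structure differs. Unstable draws are rejected and
## resampled.
jitter_network_pair <- function(net_c, net_t, jitter, seed,
                                max_tries = 20) {
  if (jitter == 0) return(list(control = net_c, test = net_t))
  key <- function(cp) paste(cp$from, cp$to, cp$lag)
  keys <- unique(c(key(net_c$coupling), key(net_t$coupling)))
  set.seed(seed)
  rebuild <- function(net, mult) {
    cp <- net$coupling
    if (nrow(cp) == 0) return(net)
    m <- mult[key(cp)]
    for (col in grep("^coef", names(cp), value = TRUE))
      cp[[col]] <- cp[[col]] * m
    truth_network(net$n_nodes, net$order, self = net$self, coupling = cp,
                  regime_bounds_s = net$regime_bounds_s,
                  noise_cov = net$noise_cov)
  }
  for (try in seq_len(max_tries)) {
    mult <- setNames(1 + jitter * runif(length(keys), -1, 1), keys)
    out <- tryCatch(list(control = rebuild(net_c, mult),
                         test = rebuild(net_t, mult)),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  warning("jittered networks unstable after ", max_tries,
          " tries; using unjittered coefficients")
  list(control = net_c, test = net_t)
}

#' Generate a synthetic multi-subject cohort
#'
#' Each subject gets condition-specific trial ensembles simulated from
#' (per-subject jittered) control and test networks, projected to the
#' scalp at the requested SNR. Per-subject seeds derive deterministically
#' from the master seed, so cohort regeneration is bit-identical.
#'
#' @param n_subjects number of subjects (default 10).
#' @param nets networks as from [default_truth_networks()].
#' @param model head model.
#' @param jitter fractional coupling jitter across subjects.
#' @param seed master seed.
#' @param n_control,n_test trials per condition (defaults 96 / 192).
#' @param T_s epoch length in seconds.
#' @param fs sampling rate in Hz.
#' @param snr_db sensor SNR in dB.
#' @return List of subjects, each with `eeg`, `true_sources` (list per
#'   condition), `roi_assignment`, `gridpoints`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 10, nets = default_truth_networks(),
                            model, jitter = 0.1, seed = 1L,
                            n_control = 96, n_test = 192, T_s = 1,
                            fs = 128, snr_db = 10) {
  Tn <- round(T_s * fs)
  lapply(seq_len(n_subjects), function(i) {
    si <- seed + 7919L * i
    jt <- jitter_network_pair(nets$control, nets$test, jitter, si)
    net_c <- jt$control
    net_t <- jt$test
    src_c <- simulate_var_sources(net_c, Tn, n_control, fs, seed = si + 2L)
    src_t <- simulate_var_sources(net_t, Tn, n_test, fs, seed = si + 3L)
    src <- array(0, c(dim(src_c)[1], Tn, n_control + n_test))
    src[, , seq_len(n_control)] <- src_c
    src[, , n_control + seq_len(n_test)] <- src_t
    cond <- c(rep("control", n_control), rep("test", n_test))
    eeg <- project_to_channels(src, model, nets$roi_assignment,
                               snr_db = snr_db, seed = si + 4L, fs = fs,
                               condition = cond)
    list(eeg = eeg, true_sources = src,
         roi_assignment = nets$roi_assignment,
         gridpoints = attr(eeg, "gridpoints"), seed = si)
  })
}
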