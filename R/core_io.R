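## Data model and file plumbing shared by every pipeline stage.
##
## Conventions: time in seconds, epochs referenced to event onset, sample
## indices 0-based with half-open intervals [start, end) wherever windows
## are expressed in samples.

#' Epoched multichannel EEG
#'
#' The basic container moved through the pipeline: a `channels x samples x
#' trials` array of microvolt data with sampling rate, channel metadata and
#' a two-level condition factor per trial.
#'
#' @param data numeric array `[C x T x N]` (channels x samples x trials),
#'   in microvolts. A `C x T` matrix is promoted to a single trial.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `C`.
#' @param channel_pos optional `C x 3` matrix of electrode positions in
#'   meters.
#' @param condition per-trial labels; must take at most two levels, coded
#'   `"control"` / `"test"` in the standard cohort.
#' @param epoch_window length-2 numeric, epoch start/end in seconds
#'   relative to the event.
#' @return An object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, fs, channel_names = NULL, channel_pos = NULL,
                        condition = NULL, epoch_window = NULL) {
  if (is.matrix(data)) data <- array(data, c(nrow(data), ncol(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  C <- dim(data)[1]; T <- dim(data)[2]; N <- dim(data)[3]
  if (C < 2L) stop("epoched_eeg needs at least 2 channels")
  if (T < 2L) stop("epoched_eeg needs at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(C))
  if (length(channel_names) != C) stop("channel_names length mismatch")
  if (!is.null(channel_pos)) {
    channel_pos <- as.matrix(channel_pos)
    if (nrow(channel_pos) != C || ncol(channel_pos) != 3L)
      stop("channel_pos must be a C x 3 matrix")
    if (!all(is.finite(channel_pos))) stop("channel_pos must be finite")
  }
  if (is.null(condition)) condition <- rep("test", N)
  condition <- as.character(condition)
  if (length(condition) != N) stop("condition must have one entry per trial")
  if (length(unique(condition)) > 2L)
    stop("condition is restricted to a two-level factor")
  if (is.null(epoch_window)) epoch_window <- c(0, T / fs)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 channel_pos = channel_pos, condition = condition,
                 epoch_window = as.numeric(epoch_window)),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  epoch window [%g, %g] s; conditions: %s\n",
              x$epoch_window[1], x$epoch_window[2],
              paste(sprintf("%s(%d)", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

n_channels <- function(eeg) dim(eeg$data)[1]
n_samples  <- function(eeg) dim(eeg$data)[2]
n_trials   <- function(eeg) dim(eeg$data)[3]

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the full pipeline with their default
#' values: 1-55 Hz analysis band, kurtosis rejection threshold Z = 5,
#' downsampling to 128 Hz, K = 14 clusters on 10 principal dimensions,
#' 550 ms sliding windows stepped by 10 ms, candidate model orders 1-30,
#' 300 condition-mixing permutations at alpha = 0.05, and a 2-50 Hz
#' connectivity frequency grid.
#'
#' @param band band-pass edges `(low, high)` in Hz.
#' @param kurtosis_z rejection threshold on the kurtosis Z-score.
#' @param resample_fs target sampling rate in Hz after cleaning.
#' @param n_clusters number of K-means clusters for IC grouping.
#' @param pca_dims feature-vector dimensionality after PCA.
#' @param window_len,window_step sliding-window length/step in seconds.
#' @param order_range candidate MVAR orders `(min, max)`.
#' @param n_permutations surrogate permutation count per subject.
#' @param alpha significance level for FDR thresholding.
#' @param freq_range connectivity frequency range `(low, high)` in Hz.
#' @param freq_step frequency grid spacing in Hz.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band = c(1, 55), kurtosis_z = 5,
                            resample_fs = 128, n_clusters = 14,
                            pca_dims = 10, window_len = 0.55,
                            window_step = 0.01, order_range = c(1, 30),
                            n_permutations = 300, alpha = 0.05,
                            freq_range = c(2, 50), freq_step = 1,
                            seed = 1L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1])
  if (band[2] >= resample_fs) # filtered before resampling; checked again there
    stopifnot(band[2] > 0)
  stopifnot(window_len > window_step, window_step > 0)
  stopifnot(order_range[1] >= 1, order_range[2] <= 30,
            order_range[1] <= order_range[2])
  stopifnot(alpha > 0, alpha < 1)
  stopifnot(freq_range[1] < freq_range[2], freq_step > 0)
  structure(list(band = as.numeric(band), kurtosis_z = kurtosis_z,
                 resample_fs = resample_fs, n_clusters = n_clusters,
                 pca_dims = pca_dims, window_len = window_len,
                 window_step = window_step,
                 order_range = as.integer(order_range),
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 freq_range = as.numeric(freq_range), freq_step = freq_step,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## ---- raw EEG readers/writers -------------------------------------------

#' Read electrode positions
#'
#' Whitespace-delimited text with four columns: name, x, y, z (meters).
#'
#' @param path file path.
#' @return data frame with columns `name`, `x`, `y`, `z`.
#' @export
read_electrode_positions <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("name", "x", "y", "z"))
  if (!all(vapply(tab[, 2:4], is.numeric, TRUE)))
    stop("electrode position columns x, y, z must be numeric")
  tab
}

#' Write electrode positions
#' @param pos data frame with columns `name`, `x`, `y`, `z`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_electrode_positions <- function(pos, path) {
  write.table(pos, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read raw EEG and epoch it
#'
#' Accepts either the package's plain-text dialect (tab-separated sample x
#' channel matrix with a header row of channel names, plus a JSON sidecar
#' `<path>.json` holding at least `fs`) or a 16-bit EDF file written by
#' [write_eeg()]. The continuous recording is cut into fixed-length epochs
#' around the supplied event latencies.
#'
#' @param path file path (`.tsv`/`.txt` or `.edf`).
#' @param events list with `latency` (event samples, 0-based),
#'   `condition` (per-event labels) and `window` (length-2 seconds relative
#'   to the event, half-open in samples).
#' @param channel_pos optional electrode positions (`C x 3` matrix or a
#'   data frame from [read_electrode_positions()]).
#' @return An [epoched_eeg()].
#' @export
read_eeg <- function(path, events, channel_pos = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    raw <- read_edf(path)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("format error: missing JSON sidecar ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("format error: sidecar lacks 'fs'")
    tab <- tryCatch(read.delim(path, check.names = FALSE),
                    error = function(e) stop("format error: ", conditionMessage(e)))
    raw <- list(data = t(as.matrix(tab)), fs = meta$fs,
                channel_names = colnames(tab))
  }
  if (is.data.frame(channel_pos)) channel_pos <- as.matrix(channel_pos[, c("x", "y", "z")])
  epoch_continuous(raw$data, raw$fs, events, raw$channel_names, channel_pos)
}

epoch_continuous <- function(data, fs, events, channel_names,
                             channel_pos = NULL) {
  stopifnot(is.matrix(data))
  win <- round(events$window * fs)
  len <- win[2] - win[1]
  lat <- as.integer(events$latency)
  if (any(lat + win[1] < 0) || any(lat + win[2] > ncol(data)))
    stop("bounds error: event window extends beyond the recording")
  epochs <- array(0, c(nrow(data), len, length(lat)))
  for (i in seq_along(lat))
    epochs[, , i] <- data[, (lat[i] + win[1] + 1):(lat[i] + win[2]), drop = FALSE]
  epoched_eeg(epochs, fs, channel_names, channel_pos,
              condition = events$condition, epoch_window = events$window)
}

#' Write raw EEG
#'
#' Serializes a continuous (single-trial) or trial-concatenated recording.
#' The TSV dialect is lossless; EDF stores 16-bit integers scaled to the
#' per-channel physical range, so round-trips are exact only up to that
#' quantization.
#'
#' @param eeg an [epoched_eeg()]; trials are concatenated along time.
#' @param path destination (`.tsv` or `.edf` decides the format).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(eeg, path) {
  flat <- matrix(aperm(eeg$data, c(1, 2, 3)), nrow = n_channels(eeg))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(flat, eeg$fs, eeg$channel_names, path)
  } else {
    tab <- as.data.frame(t(flat))
    colnames(tab) <- eeg$channel_names
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(fs = eeg$fs, n_trials = n_trials(eeg),
                              epoch_window = eeg$epoch_window,
                              condition = eeg$condition),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

## Minimal EDF writer/reader: one data record holding the full recording,
## 16-bit little-endian samples scaled to each channel's physical range.
write_edf <- function(data, fs, channel_names, path) {
  C <- nrow(data); T <- ncol(data)
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  span <- pmax - pmin
  pmin[span == 0] <- pmin[span == 0] - 1; pmax[span == 0] <- pmax[span == 0] + 1
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(x, n) {
    out <- sprintf(paste0("%-", n, "s"), substr(x, 1, n))
    writeChar(out, con, nchars = nchar(out), eos = NULL)
  }
  pad("0", 8); pad("synthetic", 80); pad("synthetic", 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(as.character(256 + 256 * C), 8); pad("", 44); pad("1", 8)
  pad(format(T / fs, digits = 10), 8); pad(as.character(C), 4)
  for (ch in channel_names) pad(ch, 16)
  for (i in seq_len(C)) pad("", 80)        # transducer
  for (i in seq_len(C)) pad("uV", 8)
  for (i in seq_len(C)) pad(format(pmin[i], digits = 7), 8)
  for (i in seq_len(C)) pad(format(pmax[i], digits = 7), 8)
  for (i in seq_len(C)) pad("-32768", 8)
  for (i in seq_len(C)) pad("32767", 8)
  for (i in seq_len(C)) pad("", 80)        # prefilter
  for (i in seq_len(C)) pad(as.character(T), 8)
  for (i in seq_len(C)) pad("", 32)
  for (i in seq_len(C)) {
    dig <- round((data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * 65535) - 32768
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                     # header bytes
  rd(44); n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  nm <- trimws(vapply(seq_len(C), function(i) rd(16), ""))
  for (i in seq_len(C)) rd(80)
  for (i in seq_len(C)) rd(8)
  pmin <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(C), function(i) rd(8), ""))
  for (i in seq_len(C)) rd(80)
  ns <- as.integer(vapply(seq_len(C), function(i) rd(8), ""))
  for (i in seq_len(C)) rd(32)
  if (n_rec != 1L) stop("format error: only single-record EDF files supported")
  fs <- ns[1] / dur
  if (abs(fs - round(fs)) < 1e-3 * fs) fs <- round(fs)  # header precision
  data <- matrix(0, C, ns[1])
  for (i in seq_len(C)) {
    dig <- readBin(con, "integer", n = ns[i], size = 2, endian = "little")
    data[i, ] <- pmin[i] + (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
  }
  list(data = data, fs = fs, channel_names = nm)
}

## ---- connectivity tensor I/O -------------------------------------------

#' Construct a connectivity tensor
#'
#' SdDTF values indexed as `[sink, source, frequency, window]`. Diagonal
#' entries are retained internally (the per-window normalization sums over
#' every pair) but masked when written out, since self-flow carries no
#' physical meaning for network analysis.
#'
#' @param eta2 numeric array `[M x M x F x W]`, non-negative.
#' @param freqs frequency axis in Hz (length `F`).
#' @param window_starts window start times in seconds (length `W`).
#' @param roi_names node names (length `M`).
#' @param pvals,mask optional arrays of matching shape.
#' @param meta free-form metadata list (config, seed, convention).
#' @return A `connectivity_tensor`.
#' @export
connectivity_tensor <- function(eta2, freqs, window_starts, roi_names = NULL,
                                pvals = NULL, mask = NULL, meta = list()) {
  d <- dim(eta2)
  stopifnot(length(d) == 4L, d[1] == d[2], d[3] == length(freqs),
            d[4] == length(window_starts))
  if (is.null(roi_names)) roi_names <- sprintf("roi%02d", seq_len(d[1]))
  if (length(roi_names) != d[1]) stop("consistency error: roi_names length")
  for (extra in list(pvals, mask))
    if (!is.null(extra) && !identical(dim(extra), d))
      stop("consistency error: auxiliary array shape mismatch")
  structure(list(eta2 = eta2, freqs = as.numeric(freqs),
                 window_starts = as.numeric(window_starts),
                 roi_names = roi_names, pvals = pvals, mask = mask,
                 meta = meta),
            class = "connectivity_tensor")
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  d <- dim(x$eta2)
  cat(sprintf("<connectivity_tensor> %d nodes, %d freqs (%g-%g Hz), %d windows\n",
              d[1], d[3], min(x$freqs), max(x$freqs), d[4]))
  if (!is.null(x$mask))
    cat(sprintf("  significant cells: %d\n", sum(x$mask, na.rm = TRUE)))
  invisible(x)
}

#' Write a connectivity tensor
#'
#' Long-format TSV with columns `sink`, `source`, `freq_Hz`, `window_s`,
#' `value`, `p`, `significant` (diagonal omitted), plus a JSON metadata
#' sidecar `<path>.json` carrying axes, node names, configuration and seed
#' so the tensor can be reconstructed exactly.
#'
#' @param tensor a [connectivity_tensor()].
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(tensor, path) {
  stopifnot(inherits(tensor, "connectivity_tensor"))
  d <- dim(tensor$eta2); M <- d[1]
  idx <- expand.grid(sink = seq_len(M), source = seq_len(M),
                     fi = seq_len(d[3]), wi = seq_len(d[4]))
  idx <- idx[idx$sink != idx$source, ]
  flat <- function(a) if (is.null(a)) rep(NA, nrow(idx)) else
    a[cbind(idx$sink, idx$source, idx$fi, idx$wi)]
  p <- flat(tensor$pvals)
  tab <- data.frame(sink = tensor$roi_names[idx$sink],
                    source = tensor$roi_names[idx$source],
                    freq_Hz = tensor$freqs[idx$fi],
                    window_s = tensor$window_starts[idx$wi],
                    value = flat(tensor$eta2),
                    p = p,
                    significant = flat(tensor$mask))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  meta <- c(tensor$meta,
            list(roi_names = tensor$roi_names, freqs = tensor$freqs,
                 window_starts = tensor$window_starts,
                 has_pvals = !is.null(tensor$pvals),
                 has_mask = !is.null(tensor$mask),
                 diagonal = "omitted"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a connectivity tensor written by [write_connectivity()]
#' @param path TSV path (expects the `<path>.json` sidecar alongside).
#' @return A [connectivity_tensor()]; diagonal entries are `NA`.
#' @export
read_connectivity <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- read.delim(path, na.strings = "")
  M <- length(meta$roi_names); Fn <- length(meta$freqs)
  W <- length(meta$window_starts)
  shape <- c(M, M, Fn, W)
  si <- match(tab$sink, meta$roi_names)
  so <- match(tab$source, meta$roi_names)
  fi <- match(tab$freq_Hz, meta$freqs)
  wi <- match(round(tab$window_s, 9), round(meta$window_starts, 9))
  fill <- function(vals) {
    a <- array(NA_real_, shape)
    a[cbind(si, so, fi, wi)] <- vals
    a
  }
  eta2 <- fill(tab$value)
  pv <- if (isTRUE(meta$has_pvals)) fill(tab$p) else NULL
  mk <- if (isTRUE(meta$has_mask)) {
    m <- fill(as.numeric(tab$significant)); storage.mode(m) <- "logical"; m
  } else NULL
  keep <- setdiff(names(meta), c("roi_names", "freqs", "window_starts",
                                 "has_pvals", "has_mask", "diagonal"))
  connectivity_tensor(eta2, meta$freqs, meta$window_starts, meta$roi_names,
                      pvals = pv, mask = mk, meta = meta[keep])
}
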