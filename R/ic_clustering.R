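## Per-IC feature extraction (scalp map, ERP, spectrum, ERSP, ITC,
## ERP-image, dipole location), PCA reduction, cross-subject K-means
## clustering and centroid-to-ROI assignment.

#' Event-related potential of a component
#' @param activations matrix `[T x N]` (time x trials).
#' @return Length-`T` trial-mean time course.
#' @export
compute_erp <- function(activations) {
  activations <- as.matrix(activations)
  rowMeans(activations)
}

stft_power_phase <- function(activations, fs, window_len, step) {
  Tn <- nrow(activations); N <- ncol(activations)
  if (window_len > Tn) stop("STFT window longer than the epoch")
  starts <- seq(1, Tn - window_len + 1, by = step)
  h <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_len) / (window_len + 1))
  nf <- floor(window_len / 2) + 1
  pow <- array(0, c(nf, length(starts)))
  itc <- array(0 + 0i, c(nf, length(starts)))
  for (wi in seq_along(starts)) {
    seg <- activations[starts[wi]:(starts[wi] + window_len - 1), ,
                       drop = FALSE] * h
    Z <- mvfft(seg)[1:nf, , drop = FALSE]
    pow[, wi] <- rowMeans(abs(Z)^2)
    mag <- abs(Z); mag[mag == 0] <- 1
    itc[, wi] <- rowMeans(Z / mag)
  }
  list(power = pow, itc = abs(itc),
       freqs = (seq_len(nf) - 1) * fs / window_len,
       times = (starts - 1 + window_len / 2) / fs)
}

#' Event-related spectral perturbation
#'
#' Short-time Fourier power averaged over trials, in dB relative to the
#' per-frequency mean power over the baseline windows (all windows by
#' default, i.e. a full-epoch gain baseline).
#'
#' @param activations matrix `[T x N]`.
#' @param fs sampling rate in Hz.
#' @param window_len,step STFT window length/step in samples.
#' @param baseline_windows indices of windows forming the baseline
#'   (default all).
#' @return List with `ersp` (`[F x W]`, dB), `freqs`, `times`.
#' @export
compute_ersp <- function(activations, fs, window_len, step,
                         baseline_windows = NULL) {
  st <- stft_power_phase(as.matrix(activations), fs, window_len, step)
  W <- ncol(st$power)
  if (is.null(baseline_windows)) baseline_windows <- seq_len(W)
  if (length(baseline_windows) == 0) stop("empty baseline window")
  base <- rowMeans(st$power[, baseline_windows, drop = FALSE])
  base[base == 0] <- .Machine$double.xmin
  list(ersp = 10 * log10(st$power / base), freqs = st$freqs,
       times = st$times)
}

#' Inter-trial coherence
#'
#' Magnitude of the trial-average of unit-magnitude spectral phasors from
#' the same short-time Fourier transform; values lie in `[0, 1]`, with 1
#' meaning perfectly phase-locked trials.
#'
#' @inheritParams compute_ersp
#' @return List with `itc` (`[F x W]`), `freqs`, `times`.
#' @export
compute_itc <- function(activations, fs, window_len, step) {
  activations <- as.matrix(activations)
  if (ncol(activations) < 2) stop("ITC needs at least 2 trials")
  st <- stft_power_phase(activations, fs, window_len, step)
  list(itc = st$itc, freqs = st$freqs, times = st$times)
}

resample_vec <- function(v, len) {
  if (length(v) == len) return(as.numeric(v))
  approx(seq_along(v), v, n = len)$y
}

ic_feature_blocks <- function(ic, fs, stft_len, stft_step) {
  act <- as.matrix(ic$activations)
  erp <- resample_vec(compute_erp(act), 64)
  spec <- rowMeans(abs(mvfft(act))^2)[seq_len(floor(nrow(act) / 2))]
  spec <- resample_vec(log10(spec + .Machine$double.xmin), 64)
  er <- compute_ersp(act, fs, stft_len, stft_step)
  itc <- compute_itc(act, fs, stft_len, stft_step)
  img <- t(act) # trials x time
  img <- apply(img, 2, resample_vec, len = 16)   # 16 trial bins
  img <- t(apply(img, 1, resample_vec, len = 32)) # 32 time bins
  list(scalp_map = as.numeric(ic$scalp_map),
       erp = erp, spectrum = spec,
       ersp = as.numeric(er$ersp), itc = as.numeric(itc$itc),
       erp_image = as.numeric(img),
       dipole_xyz = as.numeric(ic$dipole_xyz))
}

pca_reduce <- function(mat, dims) {
  dims <- min(dims, ncol(mat), nrow(mat) - 1)
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(dims), drop = FALSE]
  list(scores = scores, sdev = pc$sdev, dims = dims)
}

#' Build reduced feature vectors for a pooled IC set
#'
#' For every IC (pooled across subjects): seven feature blocks (scalp
#' map, ERP, power spectrum, ERSP, ITC, ERP-image, dipole location), each
#' reduced by PCA fitted on the pooled set, z-scored to unit total
#' variance, concatenated, and reduced once more to `pca_dims`
#' dimensions.
#'
#' @param ics list of ICs, each a list with `subject`, `component`,
#'   `scalp_map` (length `C`), `activations` (`[T x N]`),
#'   `dipole_xyz` (length 3), and `fs`.
#' @param pca_dims final dimensionality (default 10).
#' @param stft_len,stft_step STFT parameters in samples for the ERSP/ITC
#'   blocks.
#' @return An `ic_features` object: `reduced` (`n x pca_dims` matrix),
#'   `ids` (subject/component), `dipole_xyz` (`n x 3`).
#' @export
build_feature_vectors <- function(ics, pca_dims = 10, stft_len = 32,
                                  stft_step = 8) {
  n <- length(ics)
  if (n <= pca_dims)
    stop("fewer pooled ICs (", n, ") than pca_dims (", pca_dims,
         "); reduce pca_dims")
  fs <- ics[[1]]$fs
  blocks <- lapply(ics, ic_feature_blocks, fs = fs, stft_len = stft_len,
                   stft_step = stft_step)
  block_names <- names(blocks[[1]])
  reduced_blocks <- lapply(block_names, function(bn) {
    mat <- do.call(rbind, lapply(blocks, function(b) b[[bn]]))
    red <- pca_reduce(mat, pca_dims)$scores
    tv <- sum(apply(red, 2, var))
    if (tv > 0) red <- red / sqrt(tv) # unit total variance per block
    red
  })
  concat <- do.call(cbind, reduced_blocks)
  final <- pca_reduce(concat, pca_dims)
  ids <- data.frame(
    subject = vapply(ics, function(i) as.character(i$subject), ""),
    component = vapply(ics, function(i) as.integer(i$component), 0L))
  structure(list(reduced = final$scores, ids = ids,
                 dipole_xyz = do.call(rbind, lapply(ics, `[[`, "dipole_xyz")),
                 eigenvalues = final$sdev^2),
            class = "ic_features")
}

kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- numeric(K)
  centers[1] <- sample.int(n, 1)
  d2 <- colSums((t(x) - x[centers[1], ])^2)
  if (K >= 2) for (k in 2:K) {
    pr <- d2 / sum(d2)
    centers[k] <- sample.int(n, 1, prob = pr)
    d2 <- pmin(d2, colSums((t(x) - x[centers[k], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of IC feature vectors
#'
#' Lloyd's algorithm from k-means++ seeds, best of `n_restarts` by
#' within-cluster sum of squares; deterministic given the seed.
#'
#' @param features an [build_feature_vectors()] result, or a plain
#'   matrix.
#' @param K number of clusters (default 14).
#' @param seed RNG seed.
#' @param n_restarts restarts (default 20).
#' @param dipole_xyz `n x 3` dipole locations (taken from `features`
#'   when it is an `ic_features`).
#' @return A `cluster_result`: `assignments`, `centroids`,
#'   `centroid_xyz`, `withinss`, `ids`.
#' @export
kmeans_cluster <- function(features, K = 14, seed = 1L, n_restarts = 20,
                           dipole_xyz = NULL) {
  if (K <= 0) stop("K must be positive")
  x <- if (inherits(features, "ic_features")) features$reduced else
    as.matrix(features)
  if (nrow(x) < K) stop("need at least K feature vectors")
  if (is.null(dipole_xyz) && inherits(features, "ic_features"))
    dipole_xyz <- features$dipole_xyz
  ids <- if (inherits(features, "ic_features")) features$ids else NULL
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      suppressWarnings(kmeans(x, centers = kmeanspp_centers(x, K),
                              iter.max = 100, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  cx <- if (!is.null(dipole_xyz)) {
    t(vapply(seq_len(K), function(k) {
      m <- dipole_xyz[best$cluster == k, , drop = FALSE]
      if (nrow(m) == 0) rep(NA_real_, 3) else colMeans(m)
    }, numeric(3)))
  } else NULL
  structure(list(assignments = best$cluster, centroids = best$centers,
                 centroid_xyz = cx, withinss = best$tot.withinss,
                 sizes = best$size, ids = ids,
                 dipole_xyz = dipole_xyz),
            class = "cluster_result")
}

#' Assign clusters to named cortical regions
#'
#' Each cluster centroid is labeled with the region whose seed is
#' nearest (Euclidean). Clusters whose member dipoles split
#' substantially across a bilateral region pair receive both labels
#' (one-to-many); midline regions with merged left/right gridpoint sets
#' produce a single label by construction.
#'
#' @param cluster a [kmeans_cluster()] result.
#' @param roi_specs region specification as in [default_roi_specs()].
#' @param mesh_radius radius to which seed directions are scaled.
#' @param span_fraction minimum member fraction for a secondary
#'   bilateral label (default 0.25).
#' @return Named list: cluster index -> character vector of region
#'   names.
#' @export
assign_rois <- function(cluster, roi_specs, mesh_radius = 0.082,
                        span_fraction = 0.25) {
  seeds <- lapply(roi_specs, function(s) s$seeds * mesh_radius)
  nms <- vapply(roi_specs, `[[`, "", "name")
  nearest_spec <- function(p) {
    d <- vapply(seeds, function(s) min(sqrt(rowSums((s - rep(p, each = nrow(s)))^2))), 0)
    which.min(d)
  }
  K <- nrow(cluster$centroids)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    p <- cluster$centroid_xyz[k, ]
    if (anyNA(p)) { out[[k]] <- character(); next }
    if (sqrt(sum(p^2)) > 1.5 * mesh_radius)
      warning("cluster ", k, " centroid outside the mesh volume; ",
              "assigning to nearest region")
    primary <- nearest_spec(p)
    labels <- nms[primary]
    members <- cluster$dipole_xyz[cluster$assignments == k, , drop = FALSE]
    if (nrow(members) > 1) {
      memb_spec <- apply(members, 1, nearest_spec)
      tab <- table(memb_spec) / length(memb_spec)
      nm <- nms[primary]
      mirror <- if (startsWith(nm, "L_")) sub("^L_", "R_", nm)
                else if (startsWith(nm, "R_")) sub("^R_", "L_", nm)
                else NA_character_
      mi <- match(mirror, nms)
      if (!is.na(mi) && mi != primary &&
          !is.na(tab[as.character(mi)]) &&
          tab[as.character(mi)] >= span_fraction)
        labels <- c(labels, nms[mi])
    }
    out[[k]] <- labels
  }
  names(out) <- paste0("cluster", seq_len(K))
  out
}
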