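## End-to-end orchestration: per-subject preprocessing, source
## localization, ROI collapse, MVAR order selection and SdDTF; group-level
## surrogate statistics and condition-difference maps.

#' Run the per-subject pipeline
#'
#' Channel cleaning (optional), per-epoch cLORETA localization restricted
#' to the ROI gridpoints, max-power ROI collapse, detrend/normalize, and
#' independent six-criterion order selection plus SdDTF for each
#' condition.
#'
#' @param eeg the subject's [epoched_eeg()] (both conditions).
#' @param model head model.
#' @param config a [pipeline_config()].
#' @param preprocess_channels run the channel-cleaning stage (off for
#'   already-clean synthetic data).
#' @param ica run ICA-based artifact removal inside preprocessing.
#' @param lambda_method `"gcv"` or `"gcv+em"`.
#' @param order `"auto"` or a fixed integer.
#' @return A `subject_result`: per-condition `roi` signals, selected
#'   `order`, observed `tensor`, `lambda` per epoch, and a validation
#'   summary.
#' @export
run_subject <- function(eeg, model, config = pipeline_config(),
                        preprocess_channels = FALSE, ica = FALSE,
                        lambda_method = "gcv", order = "auto") {
  log <- list()
  if (preprocess_channels) {
    pp <- preprocess(eeg, config, model = model, ica = ica)
    eeg <- pp$eeg
    log <- pp$log
  }
  if (!any(eeg$condition == "control") || !any(eeg$condition == "test"))
    stop("subject needs trials in both conditions")
  op <- cloreta_operator(model$K, model$H_lap)
  rows <- sort(unique(unlist(model$roi_map)))
  act <- localize_epochs(op, eeg, rows = rows, method = lambda_method)
  roi <- maxpower_roi_signals(act, model$roi_map)
  roi <- detrend_normalize(roi)
  freqs <- seq(config$freq_range[1], config$freq_range[2],
               by = config$freq_step)
  out <- list(roi = roi, lambda = act$lambda,
              chosen_gridpoint = roi$chosen_gridpoint, log = log)
  for (cond in c("control", "test")) {
    sel <- which(roi$condition == cond)
    x <- roi$data[, , sel, drop = FALSE]
    wins <- sliding_windows(dim(x)[2], roi$fs, config$window_len,
                            config$window_step)
    p <- if (identical(order, "auto")) {
      sub <- wins$start[unique(round(seq(1, nrow(wins), length.out =
                                           min(5, nrow(wins)))))]
      crit <- order_criteria(x, p_max = config$order_range[2], starts = sub,
                             w = wins$stop[1] - wins$start[1])
      max(config$order_range[1], select_order(crit))
    } else as.integer(order)
    tens <- sddtf_ensemble(x, roi$fs, p, config$window_len,
                           config$window_step, freqs,
                           roi_names = roi$roi_names)
    tens$meta$condition <- cond
    tens$meta$seed <- config$seed
    out[[cond]] <- list(order = p, tensor = tens, n_trials = length(sel))
  }
  class(out) <- "subject_result"
  out
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> orders: control %d, test %d; %d ROIs\n",
              x$control$order, x$test$order, dim(x$roi$data)[1]))
  invisible(x)
}

#' Run the group-level statistics
#'
#' For each condition: cross-subject mean of the per-subject SdDTF
#' tensors as the observed statistic, a per-subject permutation surrogate
#' stack averaged across subjects, rank p-values, and BH-FDR
#' thresholding; finally the test-minus-control difference of the
#' significance-masked tensors, plus a validation/order summary table.
#'
#' @param subjects list of [run_subject()] results.
#' @param config a [pipeline_config()].
#' @param R permutation count (default `config$n_permutations`).
#' @param tail p-value sidedness.
#' @param scope BH pooling scope, see [fdr_bh()].
#' @return A `group_result` with `control`, `test`
#'   ([significance_test()] results), `difference`, `tensor_axes`, and
#'   `summary`.
#' @export
run_group <- function(subjects, config = pipeline_config(), R = NULL,
                      tail = "two", scope = "global") {
  if (length(subjects) < 2) stop("group analysis needs at least 2 subjects")
  if (is.null(R)) R <- config$n_permutations
  freqs <- seq(config$freq_range[1], config$freq_range[2],
               by = config$freq_step)
  d1 <- dim(subjects[[1]]$control$tensor$eta2)
  for (s in subjects)
    if (!identical(dim(s$control$tensor$eta2), d1))
      stop("heterogeneous tensor axes across subjects")
  out <- list()
  for (cond in c("control", "test")) {
    obs <- Reduce(`+`, lapply(subjects, function(s) s[[cond]]$tensor$eta2)) /
      length(subjects)
    per_subj <- lapply(seq_along(subjects), function(i) {
      s <- subjects[[i]]
      subject_surrogate(s$roi, s[[cond]]$order, size = cond, R = R,
                        seed = config$seed + 977L * i,
                        window_len = config$window_len,
                        window_step = config$window_step, freqs = freqs)
    })
    sur <- build_surrogate(per_subj)
    out[[cond]] <- significance_test(obs, sur, alpha = config$alpha,
                                     tail = tail, scope = scope)
  }
  out$difference <- condition_difference(out$test, out$control)
  axes <- subjects[[1]]$control$tensor
  out$tensor_axes <- list(freqs = axes$freqs,
                          window_starts = axes$window_starts,
                          roi_names = axes$roi_names)
  orders <- sapply(c("control", "test"), function(cond)
    sapply(subjects, function(s) s[[cond]]$order))
  out$summary <- data.frame(
    condition = c("control", "test"),
    order_mean = colMeans(orders),
    order_sd = apply(orders, 2, sd))
  out$R <- R
  class(out) <- "group_result"
  out
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> R = %d permutations\n", x$R))
  print(x$summary)
  cat(sprintf("  significant cells: control %d, test %d\n",
              sum(x$control$mask, na.rm = TRUE),
              sum(x$test$mask, na.rm = TRUE)))
  invisible(x)
}

#' Convert a group result into connectivity tensors
#'
#' Packages the per-condition observed tensors (with p-values and masks)
#' and the condition difference as [connectivity_tensor()]s ready for
#' [write_connectivity()].
#'
#' @param group a [run_group()] result.
#' @param config the configuration used (stored as provenance metadata).
#' @return Named list of [connectivity_tensor()]s (`control`, `test`,
#'   `difference`).
#' @export
group_tensors <- function(group, config = NULL) {
  ax <- group$tensor_axes
  meta <- list(config = unclass(config), R = group$R)
  out <- list()
  for (cond in c("control", "test"))
    out[[cond]] <- connectivity_tensor(group[[cond]]$observed, ax$freqs,
                                       ax$window_starts, ax$roi_names,
                                       pvals = group[[cond]]$pvals,
                                       mask = group[[cond]]$mask,
                                       meta = c(meta, condition = cond))
  out$difference <- connectivity_tensor(group$difference, ax$freqs,
                                        ax$window_starts, ax$roi_names,
                                        meta = c(meta,
                                                 condition = "test-control"))
  out
}
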