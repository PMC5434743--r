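## Nonparametric significance for SdDTF tensors: condition-mixing
## permutations per subject, cross-subject averaged surrogate
## distribution, rank p-values, Benjamini-Hochberg FDR, and
## condition-difference maps.

#' Condition-mixing permutation ensembles
#'
#' Each replicate draws, without replacement, a trial ensemble of the
#' evaluated condition's size containing equal numbers of control and
#' test trials (for odd sizes the extra draw alternates between the two
#' conditions across replicates). Draws are deterministic per
#' `(seed, replicate)`.
#'
#' @param n_control,n_test available trial counts per condition.
#' @param size ensemble size, `"control"`, `"test"`, or an integer.
#' @param R number of replicates.
#' @param seed RNG seed.
#' @return List of `R` lists with `control` and `test` trial indices
#'   (indices within each condition).
#' @export
permute_conditions <- function(n_control, n_test, size = "test", R,
                               seed = 1L) {
  if (n_control < 1 || n_test < 1) stop("both conditions must be non-empty")
  sz <- if (identical(size, "control")) n_control else
    if (identical(size, "test")) n_test else as.integer(size)
  half <- sz %/% 2
  lapply(seq_len(R), function(r) {
    extra_to_control <- (sz %% 2 == 1) && (r %% 2 == 1)
    nc <- half + as.integer((sz %% 2 == 1) && extra_to_control)
    nt <- sz - nc
    if (nc > n_control || nt > n_test)
      stop("requested ensemble size exceeds the available epochs")
    set.seed(seed + 131L * r)
    list(control = sample.int(n_control, nc),
         test = sample.int(n_test, nt))
  })
}

#' Per-subject surrogate SdDTF stack
#'
#' Recomputes the sliding-window SdDTF on `R` condition-mixed trial
#' ensembles of one subject's normalized ROI signals.
#'
#' @param roi `roi_signals` with a two-level `condition` field.
#' @param order VAR order to fit in every window.
#' @param size evaluated condition (`"control"`/`"test"`), fixing the
#'   ensemble size.
#' @param R replicates.
#' @param seed RNG seed.
#' @param window_len,window_step,freqs,convention as in
#'   [sddtf_ensemble()].
#' @return Array `[M x M x F x W x R]`.
#' @export
subject_surrogate <- function(roi, order, size = "test", R = 300,
                              seed = 1L, window_len = 0.55,
                              window_step = 0.01, freqs = seq(2, 50),
                              convention = "squared") {
  idx_c <- which(roi$condition == "control")
  idx_t <- which(roi$condition == "test")
  perms <- permute_conditions(length(idx_c), length(idx_t), size, R, seed)
  out <- NULL
  for (r in seq_len(R)) {
    sel <- c(idx_c[perms[[r]]$control], idx_t[perms[[r]]$test])
    tens <- sddtf_ensemble(roi$data[, , sel, drop = FALSE], roi$fs, order,
                           window_len, window_step, freqs, convention,
                           roi_names = roi$roi_names)
    if (is.null(out)) out <- array(0, c(dim(tens$eta2), R))
    out[, , , , r] <- tens$eta2
  }
  out
}

#' Cross-subject averaged surrogate distribution
#'
#' Replicate `r` of every subject is averaged position-wise across
#' subjects (replicate pairing by index, exchangeable under the null),
#' then the `R` averaged values at each spectro-temporal position are
#' sorted ascending.
#'
#' @param per_subject list of `[M x M x F x W x R]` arrays.
#' @return A `surrogate_distribution`: sorted array of the same shape
#'   plus `R` and `subject_count`.
#' @export
build_surrogate <- function(per_subject) {
  d <- dim(per_subject[[1]])
  for (s in per_subject)
    if (!identical(dim(s), d)) stop("axis mismatch across subjects")
  avg <- Reduce(`+`, per_subject) / length(per_subject)
  sorted <- apply(avg, seq_len(length(d) - 1), sort)
  ## apply puts the replicate axis first; move it back to the end
  sorted <- aperm(sorted, c(seq_len(length(d) - 1) + 1, 1))
  structure(list(values = sorted, R = d[length(d)],
                 subject_count = length(per_subject)),
            class = "surrogate_distribution")
}

#' Rank-based empirical p-values
#'
#' Position-wise rank of the observed (cross-subject mean) value within
#' the sorted surrogate values:
#' `p = 2 min(r_hi, r_lo) / (R + 1)` (two-sided, capped at 1) with
#' `r_hi = 1 + #(surrogate >= observed)` and
#' `r_lo = 1 + #(surrogate <= observed)`; one-sided mode uses
#' `r_hi / (R + 1)`.
#'
#' @param observed array `[M x M x F x W]` (cross-subject mean).
#' @param surrogate a [build_surrogate()] result (or a bare array with a
#'   trailing replicate axis).
#' @param tail `"two"` or `"one"` (one-sided: larger than surrogate).
#' @return Array of p-values matching `observed`.
#' @export
empirical_pvalues <- function(observed, surrogate, tail = c("two", "one")) {
  tail <- match.arg(tail)
  vals <- if (inherits(surrogate, "surrogate_distribution"))
    surrogate$values else surrogate
  R <- dim(vals)[length(dim(vals))]
  if (is.null(R) || R == 0) stop("empty surrogate distribution")
  d <- dim(observed)
  sv <- matrix(vals, prod(d), R)
  ob <- as.vector(observed)
  r_hi <- 1 + rowSums(sv >= ob)
  r_lo <- 1 + rowSums(sv <= ob)
  p <- if (tail == "two") pmin(1, 2 * pmin(r_hi, r_lo) / (R + 1)) else
    pmin(1, r_hi / (R + 1))
  array(p, d)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `alpha`, pooled over all finite p-values
#' (by default every off-diagonal spectro-temporal position of one
#' condition's tensor).
#'
#' @param pvals numeric array of p-values (`NA` positions are ignored
#'   and never significant).
#' @param alpha FDR level.
#' @param scope `"global"` pools every finite position of the tensor in
#'   one step-up pass; `"per_pair"` corrects within each (sink, source)
#'   slice separately (useful when the permutation count caps the
#'   attainable p-value well above `alpha / n_positions`).
#' @return Logical array: `TRUE` where the BH-adjusted p-value is at or
#'   below `alpha`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05, scope = c("global", "per_pair")) {
  stopifnot(alpha > 0, alpha < 1)
  scope <- match.arg(scope)
  bh <- function(p) {
    ok <- is.finite(p)
    adj <- rep(NA_real_, length(p))
    adj[ok] <- p.adjust(p[ok], method = "BH")
    !is.na(adj) & adj <= alpha
  }
  if (scope == "global" || is.null(dim(pvals)) || length(dim(pvals)) != 4)
    return(array(bh(as.vector(pvals)), dim(pvals)))
  d <- dim(pvals)
  mask <- array(FALSE, d)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      mask[i, j, , ] <- array(bh(as.vector(pvals[i, j, , ])), d[3:4])
  mask
}

mask_diagonal <- function(a) {
  M <- dim(a)[1]
  for (m in seq_len(M)) a[m, m, , ] <- NA
  a
}

#' Significance of one condition's group tensor
#'
#' Convenience wrapper: p-values against the averaged surrogate, diagonal
#' masked out, BH-FDR thresholding.
#'
#' @param observed group-mean tensor array `[M x M x F x W]`.
#' @param surrogate a [build_surrogate()] result.
#' @param alpha FDR level.
#' @param tail p-value sidedness.
#' @param scope BH pooling scope, see [fdr_bh()].
#' @return A `significance_result`: `observed`, `pvals`, `mask`,
#'   `alpha`.
#' @export
significance_test <- function(observed, surrogate, alpha = 0.05,
                              tail = "two", scope = "global") {
  pv <- mask_diagonal(empirical_pvalues(observed, surrogate, tail))
  mask <- fdr_bh(pv, alpha, scope)
  structure(list(observed = observed, pvals = pv, mask = mask,
                 alpha = alpha, tail = tail),
            class = "significance_result")
}

#' Difference of significance-masked condition tensors
#'
#' `masked(test) - masked(control)`, where entries that are not
#' FDR-significant contribute zero; positive values mean stronger
#' connectivity in the test condition.
#'
#' @param sig_test,sig_control [significance_test()] results on shared
#'   axes.
#' @return Difference array `[M x M x F x W]`.
#' @export
condition_difference <- function(sig_test, sig_control) {
  if (!identical(dim(sig_test$observed), dim(sig_control$observed)))
    stop("axis mismatch between conditions")
  mt <- ifelse(sig_test$mask, sig_test$observed, 0)
  mc <- ifelse(sig_control$mask, sig_control$observed, 0)
  mt - mc
}
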