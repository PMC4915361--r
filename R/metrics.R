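#' Precision, recall and false positive rate across support thresholds
#'
#' For each threshold s, branches with support >= s are called positive;
#' precision is the fraction of called branches that are in the reference
#' tree, recall the fraction of true branches called, and FPR the fraction
#' of false branches called. Empty denominators give `NA`.
#'
#' @param support Numeric vector of per-branch support values.
#' @param is_true Logical vector: is the branch's bipartition in the
#'   reference tree?
#' @param thresholds Numeric vector of thresholds.
#' @return Data frame with columns `threshold`, `precision`, `recall`,
#'   `fpr`.
#' @export
support_pr_fpr <- function(support, is_true,
                           thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(length(support) == length(is_true), is.logical(is_true))
  n_true <- sum(is_true)
  n_false <- sum(!is_true)
  rows <- lapply(thresholds, function(s) {
    called <- support >= s
    tp <- sum(called & is_true)
    fp <- sum(called & !is_true)
    data.frame(
      threshold = s,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (n_true > 0) tp / n_true else NA_real_,
      fpr = if (n_false > 0) fp / n_false else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Mean absolute log10 branch-length error
#'
#' `mean(|log10(w) - log10(w_hat)|)` over branches; an error of 0.10 means
#' branches are on average within a factor of 10^0.10 (about 25%) of the
#' truth. True lengths must be positive; estimates that are zero or `NA`
#' (e.g. MAP estimates at or below the positivity threshold) are excluded,
#' with the exclusion count attached as attribute `"excluded"`.
#'
#' @param w True branch lengths (all > 0).
#' @param w_hat Estimated branch lengths.
#' @return The mean absolute log10 error, with attribute `"excluded"`.
#' @export
length_log_error <- function(w, w_hat) {
  stopifnot(length(w) == length(w_hat))
  if (any(is.na(w)) || any(w <= 0)) {
    stop("true branch lengths must be positive", call. = FALSE)
  }
  use <- !is.na(w_hat) & w_hat > 0
  err <- mean(abs(log10(w[use]) - log10(w_hat[use])))
  attr(err, "excluded") <- sum(!use)
  err
}

#' Root-mean-square branch-length error
#'
#' `sqrt(mean((w - w_hat)^2))`; zero estimates are included.
#'
#' @param w True branch lengths.
#' @param w_hat Estimated branch lengths (same length as `w`).
#' @return The RMSE.
#' @export
length_rmse <- function(w, w_hat) {
  if (length(w) != length(w_hat)) stop("length mismatch", call. = FALSE)
  sqrt(mean((w - w_hat)^2))
}
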