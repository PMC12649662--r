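#' Cronbach's alpha
#'
#' `alpha = k / (k - 1) * (1 - sum of item variances / variance of item
#' sums)`, with sample variances (denominator `n - 1`). Items are rows of
#' `items`; observations are columns.
#'
#' @param items A `k x n` matrix: `k >= 2` items measured on `n >= 2`
#'   observations.
#' @return Alpha (a scalar, at most 1; can be arbitrarily negative).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- nrow(items)
  n <- ncol(items)
  if (k < 2) stop("need at least 2 items")
  if (n < 2) stop("need at least 2 observations per item")
  total_var <- stats::var(colSums(items))
  if (total_var == 0)
    stop("undefined alpha: total score variance is zero")
  item_var <- sum(apply(items, 1, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Within-subject sHRF reliability
#'
#' Cronbach's alpha with the subject's two runs as the `k = 2` items and the
#' FIR time points as observations.
#'
#' @param run1,run2 `hrf_curve`s (or numeric vectors) with equal length,
#'   typically the 12 FIR time points of each run.
#' @return Alpha.
#' @export
within_subject_reliability <- function(run1, run2) {
  a1 <- if (inherits(run1, "hrf_curve")) run1$amplitudes else as.numeric(run1)
  a2 <- if (inherits(run2, "hrf_curve")) run2$amplitudes else as.numeric(run2)
  if (length(a1) != length(a2))
    stop("the two runs must have the same number of time points")
  cronbach_alpha(rbind(a1, a2))
}

#' Cross-subject sHRF reliability
#'
#' For every ordered pair of distinct subjects `(i, j)`, the alpha between
#' subject `i`'s run-1 curve and subject `j`'s run-2 curve. High values mean
#' HRF shape is shared across people; within-subject alphas exceeding these
#' indicate subject-unique shape information.
#'
#' @param curves_run1,curves_run2 Lists of `hrf_curve`s (or numeric
#'   vectors), one per subject, in the same subject order.
#' @return Data frame with columns `i`, `j`, `alpha`.
#' @export
cross_subject_reliability <- function(curves_run1, curves_run2) {
  n <- length(curves_run1)
  if (length(curves_run2) != n)
    stop("run lists must have the same number of subjects")
  if (n < 2) stop("need at least 2 subjects")
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  pairs$alpha <- mapply(function(i, j)
    within_subject_reliability(curves_run1[[i]], curves_run2[[j]]),
    pairs$i, pairs$j)
  rownames(pairs) <- NULL
  pairs
}

#' Compare within- and cross-subject reliability
#'
#' Welch's two-sample t-test of the within-subject alphas against the
#' cross-subject pair alphas. A significantly higher within-subject mean
#' indicates the estimated sHRF carries subject-unique information.
#'
#' @param within Numeric vector of within-subject alphas (n >= 2).
#' @param cross Numeric vector of cross-subject pair alphas (n >= 2).
#' @return A list of class `reliability_result`: `within_alphas`,
#'   `cross_alphas`, `mean_within`, `mean_cross`, `t_stat`, `dof`,
#'   `p_value`.
#' @export
compare_reliability <- function(within, cross) {
  if (length(within) < 2 || length(cross) < 2)
    stop("need at least 2 alphas per group for Welch's t-test")
  tt <- stats::t.test(within, cross, var.equal = FALSE)
  structure(list(within_alphas = within, cross_alphas = cross,
                 mean_within = mean(within), mean_cross = mean(cross),
                 t_stat = unname(tt$statistic), dof = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf(paste0("<reliability: mean within-alpha %.3f (n=%d), ",
                     "mean cross-alpha %.3f (n=%d), t=%.2f, p=%.3g>\n"),
              x$mean_within, length(x$within_alphas),
              x$mean_cross, length(x$cross_alphas), x$t_stat, x$p_value))
  invisible(x)
}
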