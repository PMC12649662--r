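#' Regress an HRF metric on age, risk, and their interaction
#'
#' OLS of the per-subject metric on centered age, centered risk-factor
#' score, and their product. Simple slopes of risk at specified ages (e.g.
#' group-typical ages) are available via `simple_slope_ages`.
#'
#' @param metric Numeric per-subject outcome (e.g. HRF peak amplitude).
#' @param age Ages in years.
#' @param risk Risk-factor scores.
#' @param simple_slope_ages Optional ages at which to evaluate the simple
#'   slope of risk.
#' @return A list of class `group_stats_result`: `terms` (data frame with
#'   `term`, `b`, `se`, `statistic`, `p`), `n`, and optionally
#'   `simple_slopes`.
#' @export
regress_metric <- function(metric, age, risk, simple_slope_ages = NULL) {
  n <- length(metric)
  if (n < 4) stop("need at least 4 subjects")
  if (length(age) != n || length(risk) != n)
    stop("metric, age and risk must have equal length")
  if (anyNA(metric) || anyNA(age) || anyNA(risk))
    stop("missing values are not allowed")
  age_c <- age - mean(age)
  risk_c <- risk - mean(risk)
  fit <- stats::lm(metric ~ age_c * risk_c)
  if (any(is.na(stats::coef(fit))))
    stop("collinear predictors: coefficients not estimable")
  sm <- summary(fit)$coefficients
  terms <- data.frame(
    term = c("intercept", "age", "risk", "age:risk"),
    b = sm[, 1], se = sm[, 2], statistic = sm[, 3], p = sm[, 4],
    row.names = NULL
  )
  out <- list(terms = terms, n = n)
  if (!is.null(simple_slope_ages)) {
    V <- stats::vcov(fit)
    b <- stats::coef(fit)
    out$simple_slopes <- do.call(rbind, lapply(simple_slope_ages, function(a) {
      ac <- a - mean(age)
      slope <- b["risk_c"] + b["age_c:risk_c"] * ac
      se <- sqrt(V["risk_c", "risk_c"] + ac^2 * V["age_c:risk_c", "age_c:risk_c"] +
                   2 * ac * V["risk_c", "age_c:risk_c"])
      t <- slope / se
      data.frame(age = a, slope = slope, se = se, statistic = t,
                 p = 2 * stats::pt(abs(t), fit$df.residual, lower.tail = FALSE))
    }))
  }
  class(out) <- "group_stats_result"
  out
}

#' Mixed ANCOVA: analysis type (within) by age and risk (between)
#'
#' Exactly two within-subject measurements per subject (canonical-HRF and
#' sHRF parameter estimates). Implemented through the mean/difference
#' decomposition: between-subject effects are tested on the subject means,
#' within-subject effects (analysis type and its interactions) on the
#' canonical-minus-sHRF differences, each with centered age, risk, and
#' age-by-risk as covariates. F, MSE, and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) are reported per term.
#'
#' @param estimates n x 2 matrix (columns: canonical, sHRF), or a data
#'   frame with two columns.
#' @param age,risk Optional between-subject covariates (both or neither).
#' @return A `group_stats_result` whose `terms` include `analysis_type`,
#'   the between effects, and the type-by-covariate interactions, with
#'   columns `F`, `mse`, `p`, `partial_eta_sq`, `df1`, `df2`.
#' @export
mixed_ancova <- function(estimates, age = NULL, risk = NULL) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != 2)
    stop("exactly 2 analysis-type measurements per subject are required")
  if (anyNA(estimates)) stop("missing cell in the estimates matrix")
  n <- nrow(estimates)
  m <- rowMeans(estimates)
  d <- estimates[, 1] - estimates[, 2]
  has_cov <- !is.null(age)
  if (has_cov && is.null(risk)) stop("supply both age and risk, or neither")
  if (has_cov) {
    age_c <- age - mean(age)
    risk_c <- risk - mean(risk)
    Xb <- stats::model.matrix(~ age_c * risk_c)
  } else {
    Xb <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  term_row <- function(label, est, se, dof, mse) {
    f <- if (se > 0) (est / se)^2 else if (abs(est) < 1e-12) 0 else Inf
    data.frame(term = label, b = est, se = se, F = f, df1 = 1, df2 = dof,
               mse = mse, p = stats::pf(f, 1, dof, lower.tail = FALSE),
               partial_eta_sq = f / (f + dof))
  }
  rows <- list()

  # within-subject stratum: model the differences
  fit_d <- stats::lm.fit(Xb, d)
  dof_w <- n - ncol(Xb)
  rss_d <- sum(fit_d$residuals^2)
  # var(d) = 2 * within-cell variance, so the within-stratum MSE is RSS/2/dof
  mse_w <- rss_d / 2 / dof_w
  se_d <- sqrt(diag(chol2inv(qr.R(fit_d$qr))) * rss_d / dof_w)
  lab_w <- c("analysis_type",
             if (has_cov) c("analysis_type:age", "analysis_type:risk",
                            "analysis_type:age:risk"))
  for (j in seq_len(ncol(Xb)))
    rows[[length(rows) + 1L]] <-
      term_row(lab_w[j], fit_d$coefficients[j], se_d[j], dof_w, mse_w)

  # between-subject stratum: model the subject means
  if (has_cov) {
    fit_m <- stats::lm.fit(Xb, m)
    rss_m <- sum(fit_m$residuals^2)
    dof_b <- n - ncol(Xb)
    mse_b <- 2 * rss_m / dof_b
    se_m <- sqrt(diag(chol2inv(qr.R(fit_m$qr))) * rss_m / dof_b)
    lab_b <- c("(between intercept)", "age", "risk", "age:risk")
    for (j in 2:ncol(Xb))
      rows[[length(rows) + 1L]] <-
        term_row(lab_b[j], fit_m$coefficients[j], se_m[j], dof_b, mse_b)
  }
  structure(list(terms = do.call(rbind, rows), n = n),
            class = "group_stats_result")
}

#' @export
print.group_stats_result <- function(x, ...) {
  cat(sprintf("<group_stats_result: n = %d>\n", x$n))
  if (!is.null(x$terms)) print(x$terms, digits = 4)
  else print(utils::str(x[setdiff(names(x), "n")]))
  invisible(x)
}

#' Voxel-wise paired t-test between two analyses
#'
#' Per-voxel paired t over subjects (dof `n - 1`) between two subject x
#' voxel matrices on the same grid.
#'
#' @param map_a,map_b Subject x voxel matrices (same dimensions).
#' @return List with `t` (per-voxel), `mean_diff`, `dof`, `n`.
#' @export
paired_t_map <- function(map_a, map_b) {
  map_a <- as.matrix(map_a); map_b <- as.matrix(map_b)
  if (!all(dim(map_a) == dim(map_b)))
    stop("both map sets must share subjects and voxel grid")
  n <- nrow(map_a)
  if (n < 2) stop("need at least 2 subjects")
  d <- map_a - map_b
  md <- colMeans(d)
  sd_d <- apply(d, 2, stats::sd)
  t <- ifelse(sd_d > 0, md / (sd_d / sqrt(n)), 0)
  list(t = t, mean_diff = md, dof = n - 1, n = n)
}

# 3D connected-component labeling; queue-based breadth-first search
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3)
  dims <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  labels <- array(0L, dims)
  current <- 0L
  idx_all <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    v <- idx_all[r, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    current <- current + 1L
    queue <- matrix(v, 1, 3)
    labels[v[1], v[2], v[3]] <- current
    while (nrow(queue) > 0) {
      head <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(off, 2, head, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      keep <- mask[nb] & labels[nb] == 0L
      if (any(keep)) {
        nb <- nb[keep, , drop = FALSE]
        labels[nb] <- current
        queue <- rbind(queue, nb)
      }
    }
  }
  labels
}

#' Cluster-extent thresholding of a statistic map
#'
#' Thresholds a 3D t map at the value corresponding to the voxel-level
#' `p_threshold` (one-sided, upper tail), labels connected supra-threshold
#' components, and discards clusters smaller than `min_extent` voxels.
#' Negate the map to find negative clusters.
#'
#' @param stat_map 3D array of t statistics.
#' @param p_threshold Voxel-level p (default 0.001).
#' @param min_extent Minimum cluster size in voxels (default 100).
#' @param dof Degrees of freedom of the t statistics.
#' @param connectivity 26 (default) or 6.
#' @return A list of class `cluster_table`: `clusters` (data frame with
#'   `label`, `size`, `peak_stat`, `peak_x`, `peak_y`, `peak_z`),
#'   `threshold_stat`, `p_threshold`, `min_extent`.
#' @export
cluster_threshold <- function(stat_map, p_threshold = 0.001,
                              min_extent = 100, dof, connectivity = 26) {
  if (length(dim(stat_map)) != 3) stop("stat_map must be a 3D array")
  if (min_extent < 1) stop("min_extent must be at least 1")
  thr <- stats::qt(p_threshold, dof, lower.tail = FALSE)
  mask <- stat_map > thr
  labels <- label_components(mask, connectivity)
  ids <- setdiff(unique(as.integer(labels)), 0L)
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    if (length(vox) < min_extent) return(NULL)
    peak <- vox[which.max(stat_map[vox])]
    pc <- arrayInd(peak, dim(stat_map))
    data.frame(label = id, size = length(vox),
               peak_stat = stat_map[peak],
               peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(label = integer(0), size = integer(0),
                       peak_stat = numeric(0), peak_x = integer(0),
                       peak_y = integer(0), peak_z = integer(0))
  structure(list(clusters = rows, threshold_stat = thr,
                 p_threshold = p_threshold, min_extent = min_extent,
                 labels = labels),
            class = "cluster_table")
}

#' Chi-square test of association for a contingency table
#'
#' Pearson chi-square without continuity correction,
#' `dof = (rows - 1)(cols - 1)`.
#'
#' @param table Matrix of non-negative integer counts (e.g. affected /
#'   unaffected by age group).
#' @return A `group_stats_result` with `statistic`, `dof`, `p`, `n`.
#' @export
chi_square_association <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("undefined: zero marginal in the contingency table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 dof = unname(ct$parameter), p = ct$p.value,
                 n = sum(table)),
            class = "group_stats_result")
}

#' Brain-behavior correlation
#'
#' Pearson correlation with a two-sided p value between per-subject brain
#' parameter estimates and a behavioral measure.
#'
#' @param estimates,behavior Paired numeric vectors (n >= 3).
#' @return A `group_stats_result` with `r`, `statistic`, `dof`, `p`, `n`.
#' @export
brain_behavior_correlation <- function(estimates, behavior) {
  n <- length(estimates)
  if (length(behavior) != n) stop("inputs must be paired")
  if (n < 3) stop("need at least 3 subjects")
  if (stats::sd(estimates) == 0 || stats::sd(behavior) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(estimates, behavior, method = "pearson")
  structure(list(r = unname(ct$estimate), statistic = unname(ct$statistic),
                 dof = unname(ct$parameter), p = ct$p.value, n = n),
            class = "group_stats_result")
}
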