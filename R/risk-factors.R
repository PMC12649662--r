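#' Horn's parallel analysis
#'
#' Compares the eigenvalues of the observed correlation matrix with
#' eigenvalues of correlation matrices computed from independent standard
#' normal data of the same shape. Components are retained while the observed
#' eigenvalue exceeds the reference simulated eigenvalue, counting
#' consecutively from the first.
#'
#' The default reference is the 95th percentile of the simulated
#' eigenvalues: with the mean reference, noise-only data retains a spurious
#' first factor about half the time (the observed and simulated first
#' eigenvalues are draws from the same distribution), so the percentile
#' reference is used for a calibrated retention decision; `reference =
#' "mean"` gives the classical comparison against the average random
#' eigenvalue.
#'
#' @param data Subject x indicator matrix (standardized internally).
#' @param n_iterations Number of random matrices (default 1000).
#' @param seed Integer RNG seed.
#' @param reference `"p95"` (default) or `"mean"`.
#' @return Number of retained factors (integer >= 0).
#' @export
parallel_analysis <- function(data, n_iterations = 1000, seed = 1,
                              reference = c("p95", "mean")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  if (n < 2) stop("need at least 2 subjects")
  obs <- eigen(stats::cor(data), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sim <- matrix(0, n_iterations, p)
  for (it in seq_len(n_iterations)) {
    r <- stats::cor(matrix(stats::rnorm(n * p), n, p))
    sim[it, ] <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  }
  ref <- if (reference == "mean") colMeans(sim)
         else apply(sim, 2, stats::quantile, probs = 0.95)
  keep <- obs > ref
  if (!keep[1]) return(0L)
  as.integer(which.min(c(keep, FALSE)) - 1L)
}

#' Exploratory factor analysis with direct oblimin rotation
#'
#' Principal-axis factoring (iterated communalities starting from squared
#' multiple correlations) followed by direct oblimin rotation with
#' `gamma = 0` (quartimin), fitted by gradient projection. Indicators are
#' standardized internally via the correlation matrix.
#'
#' @param data Subject x indicator matrix.
#' @param n_factors Number of factors to extract (>= 1, <= indicators).
#' @param max_iter Maximum PAF / rotation iterations (defaults 200 / 1000).
#' @param tol Convergence tolerance on communalities (default 1e-7).
#' @return A list of class `factor_solution`: `loadings` (indicator x
#'   factor, rotated pattern matrix), `factor_correlations`, `communalities`,
#'   `eigenvalues` (of the correlation matrix), `n_factors`,
#'   `proportion_variance` (cumulative proportion of total variance
#'   explained by the retained factors), `unrotated`.
#' @export
efa_oblimin <- function(data, n_factors, max_iter = 200, tol = 1e-7) {
  data <- as.matrix(data)
  p <- ncol(data)
  if (n_factors < 1 || n_factors > p)
    stop("n_factors must lie in [1, number of indicators]")
  R <- stats::cor(data)
  eig_all <- eigen(R, symmetric = TRUE, only.values = TRUE)$values

  # principal-axis extraction with iterated communalities
  inv_ok <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(inv_ok)) rep(0.5, p) else 1 - 1 / diag(inv_ok)
  A <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(n_factors)], 0)
    A <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev), n_factors)
    h2_new <- pmin(rowSums(A^2), 1)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; converged <- TRUE; break }
    h2 <- h2_new
  }
  if (!converged)
    stop("principal-axis extraction did not converge after ", max_iter,
         " iterations (max communality change ", format(max(abs(h2))), ")")

  if (n_factors == 1L) {
    L <- A
    phi <- matrix(1, 1, 1)
  } else {
    rot <- oblimin_rotate(A, max_iter = 1000)
    if (!rot$converged)
      stop("oblimin rotation did not converge; gradient norm ",
           format(rot$grad_norm))
    L <- rot$loadings
    phi <- rot$phi
  }
  dimnames(L) <- list(colnames(data), paste0("F", seq_len(n_factors)))
  dimnames(phi) <- list(colnames(L), colnames(L))
  structure(list(loadings = L, factor_correlations = phi,
                 communalities = stats::setNames(h2, colnames(data)),
                 eigenvalues = eig_all, n_factors = as.integer(n_factors),
                 proportion_variance = sum(h2) / p,
                 unrotated = A),
            class = "factor_solution")
}

# Direct oblimin (gamma = 0, quartimin) by oblique gradient projection.
oblimin_rotate <- function(A, max_iter = 1000, eps = 1e-6) {
  k <- ncol(A)
  vgQ <- function(L) {
    L2 <- L^2
    N <- matrix(1, k, k) - diag(k)
    X <- L2 %*% N
    list(f = sum(L2 * X) / 4, Gq = L * X)
  }
  Tm <- diag(k)
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  v <- vgQ(L)
  f <- v$f
  G <- -t(t(L) %*% v$Gq %*% Ti)
  al <- 1
  s <- Inf
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 1:25) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)))
      Ti_t <- solve(Tt)
      Lt <- A %*% t(Ti_t)
      vt <- vgQ(Lt)
      if (vt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; Ti <- Ti_t; L <- Lt; f <- vt$f
    G <- -t(t(L) %*% vt$Gq %*% Ti)
  }
  list(loadings = L, phi = t(Tm) %*% Tm, converged = s < eps, grad_norm = s)
}

#' Weighted-average factor scores
#'
#' For each factor, the score is the loading-weighted average of the
#' standardized indicators: `sum(loading * z) / sum(|loading|)`. Negative
#' loadings contribute with their sign, so protective indicators lower a
#' risk score.
#'
#' @param solution A `factor_solution`.
#' @param data Subject x indicator matrix on the raw scale (standardized
#'   internally; columns must match the loading rows).
#' @return Subject x factor matrix of scores.
#' @export
factor_scores <- function(solution, data) {
  stopifnot(inherits(solution, "factor_solution"))
  data <- as.matrix(data)
  L <- solution$loadings
  if (ncol(data) != nrow(L))
    stop("data columns must match the indicators in the solution")
  z <- scale(data)
  denom <- colSums(abs(L))
  if (any(denom == 0)) stop("undefined scores: a factor has zero loading sum")
  sweep(z %*% L, 2, denom, "/")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution: %d factors, %.1f%% of variance>\n",
              x$n_factors, 100 * x$proportion_variance))
  print(round(x$loadings, 3))
  cat("factor correlations:\n")
  print(round(x$factor_correlations, 3))
  invisible(x)
}
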