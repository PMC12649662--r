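# Shared fixtures and small independent oracles for the test suite.

# default ground-truth HRF parameters used across tests
test_hrf_params <- function(peak_amplitude = 0.8, peak_time = 5.5,
                            width_scale = 1, undershoot_ratio = 6) {
  list(peak_amplitude = peak_amplitude, peak_time = peak_time,
       width_scale = width_scale, undershoot_ratio = undershoot_ratio)
}

noiseless <- function() bold_noise_config(sd = 0, drift_amplitude = 0,
                                          spike_prob = 0)

# raw double-gamma evaluated independently of the package internals
oracle_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                                ratio = 6) {
  ifelse(t > 0,
         dgamma(t, shape = peak_delay, scale = 1) -
           dgamma(t, shape = undershoot_delay, scale = 1) / ratio,
         0)
}

# align an estimated loading matrix to a target: greedy column matching by
# absolute cross-product, then sign flip
align_loadings <- function(L, target) {
  k <- ncol(target)
  cp <- abs(crossprod(L, target))
  perm <- integer(k)
  used <- rep(FALSE, ncol(L))
  for (j in order(-apply(cp, 2, max))) {
    i <- which.max(ifelse(used, -Inf, cp[, j]))
    perm[j] <- i
    used[i] <- TRUE
  }
  out <- L[, perm, drop = FALSE]
  for (j in seq_len(k))
    if (sum(out[, j] * target[, j]) < 0) out[, j] <- -out[, j]
  out
}

# sample data from a factor model: n subjects, loadings Lambda (p x k),
# factor correlation Phi; uniquenesses fill variances to 1
sample_factor_data <- function(n, Lambda, Phi = diag(ncol(Lambda)), seed = 1) {
  set.seed(seed)
  k <- ncol(Lambda)
  p <- nrow(Lambda)
  f <- matrix(rnorm(n * k), n, k) %*% chol(Phi)
  communality <- rowSums((Lambda %*% Phi) * Lambda)
  stopifnot(all(communality < 1))
  e <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(1 - communality))
  list(data = f %*% t(Lambda) + e, factors = f)
}

# recursive flood fill: independent oracle for connected-component labeling
oracle_flood_fill <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  labels <- array(0L, dims)
  cur <- 0L
  fill <- function(v, lab) {
    stack <- list(v)
    while (length(stack) > 0) {
      x <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (labels[x[1], x[2], x[3]] != 0L || !mask[x[1], x[2], x[3]]) next
      labels[x[1], x[2], x[3]] <<- lab
      for (r in seq_len(nrow(off))) {
        nb <- x + off[r, ]
        if (all(nb >= 1) && all(nb <= dims) &&
            mask[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L)
          stack[[length(stack) + 1L]] <- nb
      }
    }
  }
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3]))
      if (mask[i, j, k] && labels[i, j, k] == 0L) {
        cur <- cur + 1L
        fill(c(i, j, k), cur)
      }
  labels
}

# multiset of component sizes, for comparing labelings up to relabeling
component_sizes <- function(labels) sort(tabulate(labels[labels > 0]))
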