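# Convergence diagnostics: split-R-hat and effective sample size for the
# posterior mean, computed from an [iterations, chains, 1] draw array.

split_draw_matrix <- function(draws) {
  draws <- draws[, , 1, drop = TRUE]
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  n <- nrow(draws)
  h <- floor(n / 2)
  # split each chain in half to detect within-chain trends
  do.call(cbind, lapply(seq_len(ncol(draws)), function(ch) {
    cbind(draws[seq_len(h), ch], draws[(n - h + 1):n, ch])
  }))
}

split_rhat <- function(draws) {
  m <- split_draw_matrix(draws)
  n <- nrow(m)
  w <- mean(apply(m, 2, var))
  if (!is.finite(w) || w == 0) {
    return(1)
  }
  b <- n * var(colMeans(m))
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

ess_mean <- function(draws) {
  m <- split_draw_matrix(draws)
  n <- nrow(m)
  n_chain <- ncol(m)
  w <- mean(apply(m, 2, var))
  if (!is.finite(w) || w == 0) {
    return(n * n_chain)
  }
  b <- n * var(colMeans(m))
  var_plus <- (n - 1) / n * w + b / n
  max_lag <- min(n - 2, 500)
  acov <- vapply(seq_len(n_chain), function(ch) {
    a <- acf(m[, ch], lag.max = max_lag, type = "covariance", plot = FALSE,
      demean = TRUE
    )$acf[, 1, 1]
    a
  }, numeric(max_lag + 1))
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence on paired sums
  n_pairs <- floor((length(rho) - 1) / 2)
  tail_sum <- 0
  prev <- Inf
  for (k in seq_len(n_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    tail_sum <- tail_sum + pair
    prev <- pair
  }
  ess <- n * n_chain / (1 + 2 * tail_sum)
  min(ess, n * n_chain)
}
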