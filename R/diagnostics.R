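# MCMC convergence diagnostics: split-Rhat and effective sample size
# (Geyer initial-monotone autocovariance summation, averaged over split
# chains), following standard practice for reporting Bayesian fits.

split_chains <- function(x) {
  # x: iterations x chains -> iterations/2 x (2*chains)
  n <- nrow(x) %/% 2L
  do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(n), j], x[n + seq_len(n), j])
  }))
}

#' Split-chain potential scale reduction factor
#'
#' @param x Matrix of draws, iterations by chains.
#' @return Split-Rhat; `NA` for (near-)constant quantities.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) return(NA_real_)
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W < 1e-300 * max(1, abs(mean(means)))) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of MCMC draws
#'
#' @param x Matrix of draws, iterations by chains.
#' @return Estimated effective sample size across all chains.
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 4L) return(NA_real_)
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  means <- colMeans(x)
  var_plus <- (n - 1) / n * W + stats::var(means)

  # chain-averaged autocovariances via FFT
  acov <- matrix(0, n, m)
  for (j in seq_len(m)) {
    y <- x[, j] - means[j]
    np <- stats::nextn(2L * n)
    f <- stats::fft(c(y, rep(0, np - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / np
    acov[, j] <- ac / n  # biased autocovariance at lags 0..n-1
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- 0; t <- 1L
  prev <- Inf
  while (t + 1L < n) {
    pair <- rho[t + 1L] + ifelse(t + 2L <= n, rho[t + 2L], 0)
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n * 10)
}
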