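# Shared MCMC machinery: adaptive random-walk Metropolis blocks, categorical
# Gibbs draws via the Gumbel-max trick, and split-Rhat / effective-sample-size
# convergence diagnostics. All samplers in the package are built from these.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix
row_log_sum_exp <- function(X) {
  m <- do.call(pmax, c(as.data.frame(X), list(na.rm = FALSE)))
  m + log(rowSums(exp(X - m)))
}

# one categorical draw per row of a log-weight matrix (Gumbel-max trick)
rcategorical_log <- function(logw) {
  g <- -log(-log(matrix(runif(length(logw)), nrow(logw), ncol(logw))))
  max.col(logw + g, ties.method = "first")
}

# half-normal log density (x > 0)
dhalfnorm_log <- function(x, scale) {
  ifelse(x > 0, log(2) + dnorm(x, 0, scale, log = TRUE), -Inf)
}

# Robbins-Monro step for a proposal log-scale during adaptation
adapt_scale <- function(log_s, accepted, iter, target = 0.3) {
  log_s + (accepted - target) / sqrt(iter)
}

# Split-chain potential scale reduction (split-Rhat). `draws` is an
# iterations x chains matrix of post-warmup draws.
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  x <- cbind(draws[seq_len(half), , drop = FALSE],
             draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(x)
  n2 <- nrow(x)
  chain_means <- colMeans(x)
  chain_vars <- apply(x, 2, var)
  b <- n2 * var(chain_means)
  w <- mean(chain_vars)
  if (w <= 0) return(1)
  sqrt(((n2 - 1) / n2 * w + b / n2) / w)
}

# Effective sample size via the initial positive sequence of autocovariances
# pooled across chains (Geyer-style truncation).
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  rho <- matrix(0, n - 1, m)
  for (j in seq_len(m)) {
    a <- acf(draws[, j], lag.max = n - 1, plot = FALSE,
             demean = TRUE)$acf[-1]
    rho[seq_along(a), j] <- a
  }
  rho_bar <- rowMeans(rho)
  # truncate at first negative pair sum
  s <- 0
  k <- 1
  while (k + 1 <= length(rho_bar)) {
    pair <- rho_bar[k] + rho_bar[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}

# Evenly-spaced indices selecting `k` of `n` draws
thin_index <- function(n, k) {
  if (k >= n) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}
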