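# Independent oracles used to check the implementation. These deliberately
# re-derive each quantity from first principles (explicit inverses, direct
# sums) rather than calling the package's own code paths.

# Textbook relevance-vector regression by evidence maximization:
# Sigma = (A + beta X'X)^{-1}, mu = beta Sigma X'y, gamma_i = 1 - a_i Sigma_ii,
# a_i <- gamma_i / mu_i^2, beta <- (p - sum(gamma)) / ||y - X mu||^2.
rvm_oracle <- function(y, x, a_init = 1, beta_init = NULL, max_iter = 200,
                       tol = 1e-6, a_max = 1e12) {
  p <- nrow(x); n <- ncol(x)
  a <- rep(a_init, n)
  beta <- if (is.null(beta_init)) {
    v <- stats::var(y); if (!is.finite(v) || v == 0) 1 else 10 / v
  } else beta_init
  mu_prev <- rep(0, n)
  for (it in seq_len(max_iter)) {
    Sigma <- solve(diag(a, n) + beta * t(x) %*% x)
    mu <- drop(beta * Sigma %*% t(x) %*% y)
    gamma <- 1 - a * diag(Sigma)
    a <- ifelse(mu^2 < 1e-24, a_max, gamma / mu^2)
    a <- pmin(pmax(a, 1e-12), a_max)
    rss <- sum((y - drop(x %*% mu))^2)
    beta <- if (rss == 0) 1e12 else min(max((p - sum(gamma)) / rss, 1e-12), 1e12)
    if (sqrt(sum((mu - mu_prev)^2)) / max(sqrt(sum(mu_prev^2)), 1e-12) < tol) break
    mu_prev <- mu
  }
  list(mu = mu, a = a, beta = beta, n_iter = it)
}

# ridge closed form: (a I + beta X'X)^{-1} beta X'y
ridge_oracle <- function(y, x, a, beta) {
  n <- ncol(x)
  drop(solve(diag(a, n) + beta * t(x) %*% x, beta * t(x) %*% y))
}

# Laplacian quadratic form by direct summation over edges
laplacian_quadform_oracle <- function(V, z) {
  s <- 0
  p <- nrow(V)
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    s <- s + V[i, j] * (z[i] - z[j])^2
  s
}

# soft threshold, for the orthonormal-design lasso solution
soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

# random regression instance with unit-norm dictionary columns
random_instance <- function(p, n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(p * n), p, n)
  x <- sweep(x, 2, sqrt(colSums(x^2)), "/")
  k <- sample(n, 1)
  w <- numeric(n); w[k] <- runif(1, 1, 3) * sample(c(-1, 1), 1)
  list(x = x, w_true = w, support = k)
}

# add white noise at a given SNR (dB) relative to the signal power
add_noise_snr <- function(signal, snr_db) {
  ps <- mean(signal^2)
  sd_n <- sqrt(ps / 10^(snr_db / 10))
  signal + rnorm(length(signal), sd = sd_n)
}

# naive maximum lagged Pearson correlation (per-lag cor() calls)
naive_max_lagged_cor <- function(x, y, max_lag) {
  best <- -Inf
  for (l in (-max_lag):max_lag) {
    if (l >= 0) { xs <- x[1:(length(x) - l)]; ys <- y[(1 + l):length(y)] }
    else { xs <- x[(1 - l):length(x)]; ys <- y[1:(length(y) + l)] }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    best <- max(best, stats::cor(xs, ys))
  }
  best
}
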