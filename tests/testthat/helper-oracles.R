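# Independent oracles used to cross-check the package's likelihood code.
# These deliberately avoid the package's own computational path.

# Brute-force Gaussian log-likelihood: per-observation densities evaluated
# one at a time from the density formula, then summed.
oracle_gaussian_nll <- function(y, mu, sigma) {
  total <- 0
  for (i in seq_along(y)) {
    total <- total - (-0.5 * log(2 * pi) - log(sigma) -
                        (y[i] - mu[i])^2 / (2 * sigma^2))
  }
  total
}

# Gompertz mean evaluated from its differential-equation solution written
# out directly (no shared helper with the package).
oracle_gompertz <- function(t, S0, gamma, alpha) {
  S0 * exp((gamma / alpha) * (1 - exp(-alpha * t)))
}

# Closed-form marginal log-likelihood of the Gaussian random-intercept
# model y = X beta + Z b + e, b ~ N(0, sigma_b^2 I), e ~ N(0, sigma^2 I),
# via the full multivariate normal density with V = sigma^2 I +
# sigma_b^2 Z Z'.
oracle_lmm_loglik <- function(y, X, group, beta, sigma_b, sigma) {
  Z <- stats::model.matrix(~ 0 + factor(group))
  V <- diag(sigma^2, length(y)) + sigma_b^2 * tcrossprod(Z)
  r <- y - drop(X %*% beta)
  ch <- chol(V)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Central finite differences for gradient checks.
oracle_num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Brute-force column count of the treatment coding for a structure label:
# counts the distinct coefficients implied by dummy-coding the factors,
# computed from first principles via qr rank on the 12 cells.
oracle_column_count <- function(formula) {
  cells <- expand.grid(
    location = factor(c("coastal", "inland")),
    salinity = factor(c("fresh", "salt4ppt")),
    density = factor(c("2", "4", "8"))
  )
  qr(stats::model.matrix(formula, cells))$rank
}
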