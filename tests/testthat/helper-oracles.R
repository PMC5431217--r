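# Independent AICc oracle: explicit Gaussian likelihood at the MLE,
# evaluated observation by observation with dnorm; k counts slopes +
# intercept + residual variance.
aicc_oracle <- function(y, X_cols, data) {
  n <- length(y)
  fit <- if (length(X_cols) == 0) stats::lm(y ~ 1) else
    stats::lm(stats::reformulate(X_cols, response = "y"),
              data = cbind(data.frame(y = y), data))
  mu <- stats::fitted(fit)
  sigma2 <- sum((y - mu)^2) / n
  ll <- sum(stats::dnorm(y, mu, sqrt(sigma2), log = TRUE))
  k <- length(X_cols) + 2
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}
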