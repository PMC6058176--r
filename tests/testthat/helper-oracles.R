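# Independent oracles, deliberately written against the formulas rather than
# the package's code paths.

# largest-remainder apportionment: hand out units one at a time to the
# category whose running allocation is furthest below its exact quota
apportion_oracle <- function(weights, total) {
  if (sum(weights) == 0) return(integer(length(weights)))
  quota <- weights * total / sum(weights)
  out <- floor(quota)
  for (u in seq_len(total - sum(out))) {
    deficit <- quota - out
    out[which.max(deficit)] <- out[which.max(deficit)] + 1
  }
  as.integer(out)
}

# BCa from a replicate stream: bias correction, jackknife acceleration and
# normal-scale interpolated order-statistic quantiles
bca_oracle <- function(t0, t, jack, level = 0.95) {
  B <- length(t)
  z0 <- qnorm(sum(t < t0) / B)
  u <- mean(jack) - jack
  a <- sum(u^3) / (6 * sum(u^2)^(3 / 2))
  zq <- qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ts <- sort(t)
  ends <- vapply(adj, function(p) {
    k <- (B + 1) * p
    k1 <- floor(k)
    if (k1 < 1) return(ts[1])
    if (k1 >= B) return(ts[B])
    g <- (qnorm(k / (B + 1)) - qnorm(k1 / (B + 1))) /
      (qnorm((k1 + 1) / (B + 1)) - qnorm(k1 / (B + 1)))
    ts[k1] * (1 - g) + g * ts[k1 + 1]
  }, numeric(1))
  list(z0 = z0, a = a, low = ends[1], high = ends[2])
}
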