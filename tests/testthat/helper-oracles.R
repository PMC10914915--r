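# Independent oracles, kept free of the implementation code paths they
# check.

# bent-cable transfer written out directly (scalar-safe)
qBendOracle <- function(t, tau, gamma) {
  sapply(t, function(x) {
    if (x <= tau - gamma) 0
    else if (x >= tau + gamma) x - tau
    else (x - tau + gamma)^2 / (4 * gamma)
  })
}

# exhaustive lattice minimiser of the bent-cable RSS by plain OLS at
# every (tau, gamma) node
bruteForceBentCable <- function(times, values, tauStep = 4) {
  taus <- seq(min(times) + tauStep, max(times) - tauStep, by = tauStep)
  gammas <- exp(seq(log(1), log(diff(range(times)) / 2), length.out = 12))
  best <- list(rss = Inf)
  for (tau in taus) for (gamma in gammas) {
    q <- qBendOracle(times, tau, gamma)
    fit <- stats::.lm.fit(cbind(1, times, q), values)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss) best <- list(tau = tau, gamma = gamma, rss = rss)
  }
  best
}

# closed-form triangle curve: rises 0 -> peak on [0, tPeak], falls back to
# 0 at tEnd
triangleCurve <- function(grid, peak = 4, tPeak = 600, tEnd = 1200) {
  up <- pmin(pmax(grid, 0), tPeak) / tPeak * peak
  down <- ifelse(grid > tPeak,
                 peak * pmax(tEnd - grid, 0) / (tEnd - tPeak), Inf)
  pmin(up, down)
}
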