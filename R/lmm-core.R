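## Shared single-variance-ratio REML machinery.
##
## Model: y = X b + u + e, u ~ N(0, sigma_g^2 K), e ~ N(0, sigma_e^2 I).
## With K = U D U' and delta = sigma_e^2 / sigma_g^2, the rotated model has
## independent errors with variance sigma_g^2 (D_i + delta); the REML
## criterion in delta is profiled over b and sigma_g^2 and minimised by
## one-dimensional search on log10(delta) in [-5, 5].

remlCriterion <- function(log10delta, yt, Xt, D) {
  delta <- 10^log10delta
  w <- 1 / (D + delta)
  sw <- sqrt(w)
  Xw <- Xt * sw
  yw <- yt * sw
  fit <- stats::lm.fit(Xw, yw)
  p <- fit$rank
  n <- length(yt)
  rss <- sum(fit$residuals^2)
  XtWX <- crossprod(Xw[, seq_len(ncol(Xw)), drop = FALSE])
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  (n - p) * log(rss) - sum(log(w)) + as.numeric(ld)
}

## returns delta, variance components and the REML criterion value
remlEigen <- function(yt, Xt, D, interval = c(-5, 5)) {
  opt <- stats::optimize(remlCriterion, interval = interval,
                         yt = yt, Xt = Xt, D = D, tol = 1e-6)
  delta <- 10^opt$minimum
  w <- 1 / (D + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  n <- length(yt); p <- fit$rank
  sigmaG2 <- sum(fit$residuals^2) / (n - p)
  list(delta = delta, sigmaG2 = sigmaG2, sigmaE2 = sigmaG2 * delta,
       criterion = opt$objective, beta = fit$coefficients)
}

## Maximum (profile) log-likelihood of the rotated model at fixed delta,
## sigma^2 profiled by ML; used for per-marker likelihood-ratio tests.
mlLoglik <- function(yt, Xt, D, delta) {
  w <- 1 / (D + delta)
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  n <- length(yt)
  rss <- sum(fit$residuals^2)
  -0.5 * (n * log(2 * pi * rss / n) + n - sum(log(w)))
}
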