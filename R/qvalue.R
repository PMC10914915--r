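#' Storey q-values with smoother pi0 estimate
#'
#' Estimates the null proportion `pi0` by evaluating
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` on
#' `lambda = 0.05, 0.10, ..., 0.95`, smoothing with a natural cubic
#' smoothing spline and taking the value at `lambda = 0.95` (clipped to
#' `(0, 1]`). The q-value of a test is the minimum over all tests with
#' larger p of `pi0 * m * p / rank(p)`, which makes q non-decreasing in p.
#' With fewer than 100 tests the smoother is unstable and `pi0` is fixed
#' at 1 (a warning is issued).
#'
#' @param p vector of p-values in `(0, 1]`.
#' @return numeric q-values with attribute `pi0`.
#' @export
storeyQvalues <- function(p) {
  stopifnot(all(is.finite(p)), all(p > 0), all(p <= 1))
  m <- length(p)
  if (m < 100) {
    warning("fewer than 100 p-values; pi0 fixed at 1")
    pi0 <- 1
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    sp <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(sp, x = 0.95)$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  rankOfP <- rank(p, ties.method = "max")
  q[ord] <- cummin(pi0 * m * p[ord] / rankOfP[ord])
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}
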