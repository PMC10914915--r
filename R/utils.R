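#' Derive a reproducible child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed and a stage tag, so stages can be re-run independently and the whole
#' pipeline is bit-reproducible under one integer.
#'
#' @param seed Master seed (integer).
#' @param tag Character stage tag, e.g. `"genotypes"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  val <- ((abs(seed) %% 1e6) * 2017 + h * 7919) %% (2^31 - 2)
  as.integer(val) + 1L
}

#' AR1 correlation matrix
#'
#' @param n Dimension.
#' @param rho Autocorrelation in `[0, 1)`.
#' @return `n` x `n` matrix with entries `rho^|i-j|`.
#' @keywords internal
ar1Matrix <- function(n, rho) {
  stopifnot(n >= 1, rho > -1, rho < 1)
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

## trapezoidal integral of a gridded curve over [a, b]; fractional bounds
## are handled by linear interpolation so that adjacent windows tile
## exactly (AUC additivity holds to numerical precision)
trapezoid <- function(times, values, a, b) {
  a <- max(a, times[1L]); b <- min(b, times[length(times)])
  if (b <= a) return(0)
  keep <- times > a & times < b
  t2 <- c(a, times[keep], b)
  v2 <- c(stats::approx(times, values, xout = a)$y, values[keep],
          stats::approx(times, values, xout = b)$y)
  sum((v2[-1] + v2[-length(v2)]) / 2 * diff(t2))
}

## half-open interval overlap, 1-based bp coordinates
intervalsOverlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}
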