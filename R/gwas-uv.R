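#' Univariate mixed-model association scan
#'
#' For one trait in one environment, fits `y = mu + x beta + u + e` with a
#' polygenic term `u ~ N(0, sigma_g^2 K)` per marker, where `x` is the
#' B73-allele-carrier indicator and, for markers on chromosome `c`, `K` is
#' the leave-one-chromosome-out kinship `K^(-c)` (or the global kinship).
#' Per chromosome, the kinship is eigendecomposed once and the variance
#' ratio `delta = sigma_e^2 / sigma_g^2` is estimated by REML under the
#' no-marker null; each marker is then tested by a likelihood-ratio test
#' (chi-square, 1 df) with `delta` reused from the null, or re-optimised
#' per marker when `exact = TRUE`.
#'
#' Monomorphic markers are reported with `p = 1` and flagged.
#'
#' @param y named numeric vector of genotype adjusted means (names are line
#'   ids matching `colnames(panel)`).
#' @param panel a [MagicPanel-class].
#' @param kinships from [kinshipSet()].
#' @param trait,environment labels copied to the output rows.
#' @param loco use LOCO kinships (default) or the global matrix.
#' @param exact re-optimise `delta` per marker.
#' @param chromosomes optional subset of chromosomes to scan.
#' @return data.frame, one row per marker: `trait`, `environment`,
#'   `marker`, `chrom`, `pos_bp`, `method` (`"UV"`), `beta` (B73-allele
#'   effect), `se`, `statistic`, `p`, `flag`.
#' @export
gwasUnivariate <- function(y, panel, kinships, trait = "trait",
                           environment = "env", loco = TRUE,
                           exact = FALSE, chromosomes = NULL) {
  lines <- colnames(panel)
  stopifnot(!is.null(names(y)), all(lines %in% names(y)))
  y <- y[lines]
  ok <- is.finite(y)
  map <- markerMap(panel)
  B <- b73Dosage(panel)[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  chroms <- unique(map$chrom)
  if (!is.null(chromosomes)) chroms <- intersect(chroms, chromosomes)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    c <- chroms[ci]
    K <- if (loco) kinships$loco[[c]] else kinships$global
    K <- K[ok, ok, drop = FALSE]
    eig <- eigen(K, symmetric = TRUE)
    D <- pmax(eig$values, 0)
    U <- eig$vectors
    yt <- as.vector(crossprod(U, y))
    onet <- as.vector(crossprod(U, rep(1, n)))
    null <- remlEigen(yt, cbind(onet), D)
    delta <- null$delta
    w <- 1 / (D + delta)
    sw <- sqrt(w)
    ywS <- yt * sw
    oneS <- onet * sw
    ll0 <- mlLoglik(yt, cbind(onet), D, delta)
    mIdx <- which(map$chrom == c)
    Xc <- crossprod(U, B[, mIdx, drop = FALSE]) * sw  # rotated, weighted
    res <- matrix(NA_real_, length(mIdx), 4,
                  dimnames = list(NULL, c("beta", "se", "stat", "p")))
    flag <- rep(NA_character_, length(mIdx))
    ## null pieces for fast per-marker GLS
    a11 <- sum(oneS^2); a1y <- sum(oneS * ywS); yy <- sum(ywS^2)
    for (j in seq_along(mIdx)) {
      xo <- B[, mIdx[j]]
      if (stats::var(xo) == 0) {
        res[j, ] <- c(0, NA, 0, 1)
        flag[j] <- "monomorphic"
        next
      }
      if (exact) {
        xt <- as.vector(crossprod(U, xo))
        fitAlt <- remlEigen(yt, cbind(onet, xt), D)
        dA <- fitAlt$delta
        llA <- mlLoglik(yt, cbind(onet, xt), D, dA)
        wA <- 1 / (D + dA); swA <- sqrt(wA)
        XA <- cbind(onet, xt) * swA
        fit <- stats::lm.fit(XA, yt * swA)
        s2 <- sum(fit$residuals^2) / (n - 2)
        vcv <- s2 * solve(crossprod(XA))
        res[j, ] <- c(fit$coefficients[2], sqrt(vcv[2, 2]),
                      max(0, 2 * (llA - ll0)), NA)
      } else {
        xs <- Xc[, j]
        a12 <- sum(oneS * xs); a22 <- sum(xs^2); a2y <- sum(xs * ywS)
        det <- a11 * a22 - a12^2
        if (det <= 1e-12) {
          res[j, ] <- c(0, NA, 0, 1); flag[j] <- "collinear"; next
        }
        beta <- (a11 * a2y - a12 * a1y) / det
        mu <- (a22 * a1y - a12 * a2y) / det
        rss1 <- yy - mu * a1y - beta * a2y
        rss0 <- yy - a1y^2 / a11
        stat <- max(0, n * (log(rss0) - log(rss1)))
        s2 <- rss1 / (n - 2)
        res[j, ] <- c(beta, sqrt(s2 * a11 / det), stat, NA)
      }
      res[j, "p"] <- stats::pchisq(res[j, "stat"], df = 1,
                                   lower.tail = FALSE)
    }
    out[[ci]] <- data.frame(
      trait = trait, environment = environment, marker = map$marker[mIdx],
      chrom = c, pos_bp = map$pos_bp[mIdx], method = "UV",
      beta = res[, "beta"], se = res[, "se"], statistic = res[, "stat"],
      p = pmin(pmax(res[, "p"], .Machine$double.xmin), 1),
      flag = flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  attr(out, "delta") <- NULL
  out
}

#' Genomic inflation factor
#'
#' Median association chi-square statistic divided by the null median.
#'
#' @param p vector of p-values (1 df tests).
#' @return `lambda_GC`.
#' @export
genomicInflation <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
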