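#' Genotype adjusted means with spatially autocorrelated plot errors
#'
#' Fits, for one trait in one environment, the field-trial model
#' `value = mean + genotype + block + e` with fixed genotype and block
#' effects (sum-to-zero coding) and residual covariance
#' `sigma^2 AR1(rho_row) x AR1(rho_col)` over the plot grid, by generalized
#' least squares. The spatial correlations are chosen by profiling the REML
#' criterion over a discrete grid (default `{0, 0.1, ..., 0.9}^2`); the
#' adjusted mean of a genotype is the overall mean plus its effect.
#'
#' @param plotTable data.frame with `genotype`, `environment`, `block`,
#'   `row`, `col` and the trait column.
#' @param trait trait column name.
#' @param environment environment to fit.
#' @param rhoGrid candidate AR1 correlations for rows and columns.
#' @return data.frame `genotype`, `value` (NA with a `reason` for genotypes
#'   absent from the environment), with attribute `fit` recording the
#'   selected `rho`, `sigma2` and REML criterion.
#' @export
adjustedMeans <- function(plotTable, trait, environment,
                          rhoGrid = seq(0, 0.9, by = 0.1)) {
  d <- plotTable[plotTable$environment == environment, ]
  d <- d[is.finite(d[[trait]]), ]
  if (nrow(d) < 3L) stop("not enough plots in environment ", environment)
  allGeno <- sort(unique(plotTable$genotype))
  d$genotype <- factor(d$genotype)
  d$block <- factor(d$block)
  y <- d[[trait]]
  n <- length(y)

  useBlock <- nlevels(d$block) > 1L
  form <- if (useBlock) ~genotype + block else ~genotype
  ctr <- c(list(genotype = "contr.sum"),
           if (useBlock) list(block = "contr.sum"))
  X <- stats::model.matrix(form, d, contrasts.arg = ctr)

  dr <- abs(outer(d$row, d$row, "-"))
  dc <- abs(outer(d$col, d$col, "-"))
  evalRho <- function(rr, rc) {
    R <- (if (rr == 0) (dr == 0) * 1 else rr^dr) *
         (if (rc == 0) (dc == 0) * 1 else rc^dc)
    L <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(L)) return(list(crit = Inf))
    Xw <- backsolve(L, X, transpose = TRUE)
    yw <- backsolve(L, y, transpose = TRUE)
    fit <- stats::lm.fit(Xw, yw)
    p <- fit$rank
    rss <- sum(fit$residuals^2)
    XtX <- crossprod(Xw)
    ldX <- determinant(XtX, logarithm = TRUE)$modulus
    crit <- (n - p) * log(rss / (n - p)) + 2 * sum(log(diag(L))) +
      as.numeric(ldX)
    list(crit = crit, fit = fit, sigma2 = rss / (n - p))
  }
  grid <- expand.grid(rr = rhoGrid, rc = rhoGrid)
  best <- NULL; bestCrit <- Inf; bestRho <- c(0, 0)
  for (k in seq_len(nrow(grid))) {
    res <- evalRho(grid$rr[k], grid$rc[k])
    if (res$crit < bestCrit) {
      bestCrit <- res$crit; best <- res
      bestRho <- c(grid$rr[k], grid$rc[k])
    }
  }
  cf <- best$fit$coefficients
  names(cf) <- colnames(X)
  cf[is.na(cf)] <- 0
  mu <- cf[["(Intercept)"]]
  lev <- levels(d$genotype)
  gIdx <- grep("^genotype", names(cf))
  gEff <- c(cf[gIdx], -sum(cf[gIdx]))
  names(gEff) <- lev
  out <- data.frame(genotype = allGeno,
                    value = unname(mu + gEff[allGeno]),
                    stringsAsFactors = FALSE)
  out$reason <- ifelse(is.na(out$value), "genotype absent in environment",
                       NA_character_)
  attr(out, "fit") <- list(rho = stats::setNames(bestRho, c("row", "col")),
                           sigma2 = best$sigma2, criterion = bestCrit,
                           n = n, trait = trait, environment = environment)
  out
}

#' Generalized (Cullis) heritability
#'
#' `H2 = 1 - vBar / (2 sigma_g^2)`, where `vBar` is the mean prediction
#' error variance of pairwise genotype BLUP differences. Within one
#' environment the model is `value = block + genotype(random) + e` with an
#' optional AR1 x AR1 residual (the spatial correlations of the adjusted
#' means fit can be supplied); across the network it is
#' `value = environment + genotype(random) + genotype:environment(random)
#' + e` fitted by REML, with `vBar` from the genotype BLUPs of that model.
#' All genotype pairs are used up to 400 genotypes, beyond which 10,000
#' random pairs are sampled.
#'
#' @inheritParams adjustedMeans
#' @param environment one environment name, or NULL for the network model.
#' @param rho AR1 residual correlations `c(row, col)` (single-environment
#'   model only).
#' @param maxPairGenotypes,pairSample pair enumeration cutover and sample
#'   size.
#' @return `H2` in `[0, 1]` with attribute `components`.
#' @export
generalizedHeritability <- function(plotTable, trait, environment = NULL,
                                    rho = c(0, 0),
                                    maxPairGenotypes = 400,
                                    pairSample = 10000) {
  if (!is.null(environment)) {
    d <- plotTable[plotTable$environment == environment, ]
    d <- d[is.finite(d[[trait]]), ]
    d$genotype <- factor(d$genotype)
    d$block <- factor(d$block)
    y <- d[[trait]]
    X <- if (nlevels(d$block) > 1L)
      stats::model.matrix(~block, d,
                          contrasts.arg = list(block = "contr.sum"))
    else matrix(1, length(y), 1)
    Z <- stats::model.matrix(~0 + genotype, d)
    if (any(rho != 0)) {
      R <- (if (rho[1] == 0) diag(nrow(d))
            else rho[1]^abs(outer(d$row, d$row, "-"))) *
           (if (rho[2] == 0) 1 else rho[2]^abs(outer(d$col, d$col, "-")))
      L <- chol(R)
      y <- backsolve(L, y, transpose = TRUE)
      X <- backsolve(L, X, transpose = TRUE)
      Z <- backsolve(L, Z, transpose = TRUE)
    }
    K <- tcrossprod(Z)
    eig <- eigen(K, symmetric = TRUE)
    yt <- crossprod(eig$vectors, y)
    Xt <- crossprod(eig$vectors, X)
    rem <- remlEigen(yt, Xt, pmax(eig$values, 0))
    sigmaG2 <- rem$sigmaG2; sigmaE2 <- rem$sigmaE2
    delta <- rem$delta
    nG <- ncol(Z)
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + delta * diag(nG)))
    Ci <- solve(C)
    pevIdx <- ncol(X) + seq_len(nG)
    PEV <- sigmaE2 * Ci[pevIdx, pevIdx]
  } else {
    d <- plotTable[is.finite(plotTable[[trait]]), ]
    d$genotype <- factor(d$genotype)
    d$environment <- factor(d$environment)
    fit <- lme4::lmer(
      stats::reformulate(c("environment", "(1 | genotype)",
                           "(1 | genotype:environment)"),
                         response = trait),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigmaG2 <- vc$vcov[vc$grp == "genotype"]
    sigmaGE2 <- vc$vcov[vc$grp == "genotype:environment"]
    sigmaE2 <- vc$vcov[vc$grp == "Residual"]
    ## mixed-model equations for the genotype PEV block
    X <- stats::model.matrix(~environment, d)
    Z1 <- stats::model.matrix(~0 + genotype, d)
    Z2 <- stats::model.matrix(~0 + genotype:environment, d)
    d1 <- sigmaE2 / max(sigmaG2, 1e-10)
    d2 <- sigmaE2 / max(sigmaGE2, 1e-10)
    nG <- ncol(Z1); nGE <- ncol(Z2)
    C <- rbind(
      cbind(crossprod(X), crossprod(X, Z1), crossprod(X, Z2)),
      cbind(crossprod(Z1, X), crossprod(Z1) + d1 * diag(nG),
            crossprod(Z1, Z2)),
      cbind(crossprod(Z2, X), crossprod(Z2, Z1),
            crossprod(Z2) + d2 * diag(nGE)))
    Ci <- tryCatch(solve(C), error = function(e) MASS_ginv(C))
    pevIdx <- ncol(X) + seq_len(nG)
    PEV <- sigmaE2 * Ci[pevIdx, pevIdx]
  }
  if (sigmaG2 <= 1e-12) {
    warning("estimated genetic variance is zero; H2 = 0 by definition")
    return(structure(0, components = list(sigmaG2 = sigmaG2,
                                          sigmaE2 = sigmaE2)))
  }
  nG <- nrow(PEV)
  if (nG <= maxPairGenotypes) {
    pr <- utils::combn(nG, 2)
  } else {
    pr <- replicate(pairSample, sample.int(nG, 2))
  }
  vDelta <- PEV[cbind(pr[1, ], pr[1, ])] + PEV[cbind(pr[2, ], pr[2, ])] -
    2 * PEV[cbind(pr[1, ], pr[2, ])]
  h2 <- 1 - mean(vDelta) / (2 * sigmaG2)
  structure(min(max(h2, 0), 1),
            components = list(sigmaG2 = sigmaG2, sigmaE2 = sigmaE2,
                              vBarDelta = mean(vDelta)))
}

## pseudo-inverse fallback for near-singular mixed-model equations
MASS_ginv <- function(M) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-10
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
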