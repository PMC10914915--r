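## Multivariate (multi-trait) mixed-model association.
##
## Matrix-variate model for t traits: Y = X B + G + E with rows of
## G ~ MN(0, K, Vg) and E ~ MN(0, I, Ve). In the eigenbasis of K the rows
## become independent with covariance S_i = lambda_i Vg + Ve. All
## computations additionally exploit the simultaneous diagonalization
## Q' Ve Q = I, Q' Vg Q = diag(phi): in the Q-basis every S_i is diagonal,
## so the EM variance-component updates and the per-marker generalized
## least squares reduce to elementwise operations.

## generalized eigendecomposition: returns Q with Q'VeQ = I, Q'VgQ = diag
simDiag <- function(Vg, Ve) {
  ee <- eigen(Ve, symmetric = TRUE)
  iSqrt <- ee$vectors %*% (t(ee$vectors) / sqrt(pmax(ee$values, 1e-10)))
  A <- iSqrt %*% Vg %*% iSqrt
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  Q <- iSqrt %*% ea$vectors
  list(Q = Q, Qi = solve(Q), phi = pmax(ea$values, 0))
}

fixPsd <- function(V, floor = 1e-8) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(e$values) < floor)
    V <- e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
  (V + t(V)) / 2
}

## EM fit of (Vg, Ve) in the kinship eigenbasis; Xt is the rotated fixed
## design (n x p), Yt the rotated responses (n x t), D the kinship
## eigenvalues.
mvLmmFit <- function(Yt, Xt, D, tol = 1e-6, maxIter = 1000) {
  t <- ncol(Yt); n <- nrow(Yt); p <- ncol(Xt)
  V0 <- stats::cov(Yt)
  Vg <- fixPsd(V0 / 2); Ve <- fixPsd(V0 / 2)
  ll0 <- -Inf; ll <- NA_real_; iter <- 0
  repeat {
    iter <- iter + 1
    sd <- simDiag(Vg, Ve)
    U <- Yt %*% sd$Q                       # n x t, transformed responses
    Wm <- 1 / (outer(D, sd$phi) + 1)       # n x t weights (diag of S^-1)
    ## GLS fixed effects per transformed trait column
    Bt <- matrix(0, p, t)
    for (k in seq_len(t)) {
      w <- Wm[, k]
      Xw <- Xt * sqrt(w)
      Bt[, k] <- stats::lm.fit(Xw, U[, k] * sqrt(w))$coefficients
    }
    Rm <- U - Xt %*% Bt                    # transformed residuals
    ## log-likelihood (up to constant): det(S_i) in original coords
    ldQ <- as.numeric(determinant(crossprod(sd$Q),
                                  logarithm = TRUE)$modulus)
    ll <- -0.5 * (sum(log(outer(D, sd$phi) + 1)) - n * ldQ +
                    sum(Wm * Rm^2))
    ## E-step in the diagonal basis, then map back
    WR <- Wm * Rm
    phiM <- matrix(sd$phi, n, t, byrow = TRUE)
    DM <- matrix(D, n, t)
    Ea <- sqrt(DM) * phiM * WR
    Va <- colMeans(phiM - DM * phiM^2 * Wm)
    VgT <- crossprod(Ea) / n + diag(Va, t)
    Ee <- WR
    VeT <- crossprod(Ee) / n + diag(colMeans(1 - Wm), t)
    Vg <- fixPsd(t(sd$Qi) %*% VgT %*% sd$Qi)
    Ve <- fixPsd(t(sd$Qi) %*% VeT %*% sd$Qi)
    if (is.finite(ll0) && abs(ll - ll0) < tol * max(1, abs(ll0))) break
    if (iter >= maxIter) {
      warning("multivariate variance-component EM hit iteration limit")
      break
    }
    ll0 <- ll
  }
  list(Vg = Vg, Ve = Ve, rg = stats::cov2cor(Vg), loglik = ll,
       iterations = iter)
}

#' Multivariate mixed-model association scan
#'
#' Jointly tests each marker against `t` traits in one environment with a
#' Wald test (chi-square, `t` df) of the null that all `t` marker effects
#' are zero, under a matrix-variate mixed model with between-trait genetic
#' covariance `Vg` (scaled by kinship between lines) and residual
#' covariance `Ve`. `(Vg, Ve)` are estimated once per chromosome in the
#' eigenbasis of the LOCO kinship by an EM algorithm (relative
#' log-likelihood change `< 1e-6` or 1000 iterations; non-positive-definite
#' updates are projected to the nearest PSD matrix with an eigenvalue floor
#' of 1e-8); markers are then scored by generalized least squares. Rows
#' with any missing trait are dropped (listwise deletion). Effects use
#' B73-allele-carrier coding.
#'
#' @param Y genotype x trait matrix of adjusted means (rownames are line
#'   ids).
#' @param panel a [MagicPanel-class].
#' @param kinships from [kinshipSet()].
#' @param environment label copied to the output.
#' @param loco use LOCO kinships (default).
#' @param chromosomes optional subset of chromosomes to scan.
#' @return list with `associations` (one row per marker: joint `statistic`,
#'   `p`, plus per-trait `beta_*` and `se_*` columns) and `nullFit`
#'   (per-chromosome `Vg`, `Ve`, genetic correlations `rg`, log-likelihood,
#'   iterations).
#' @export
gwasMultivariate <- function(Y, panel, kinships, environment = "env",
                             loco = TRUE, chromosomes = NULL) {
  stopifnot(is.matrix(Y) || is.data.frame(Y))
  Y <- as.matrix(Y)
  lines <- colnames(panel)
  stopifnot(!is.null(rownames(Y)), all(lines %in% rownames(Y)))
  Y <- Y[lines, , drop = FALSE]
  keep <- stats::complete.cases(Y)
  Y <- Y[keep, , drop = FALSE]
  t <- ncol(Y)
  if (t > 10) stop("multivariate scan supports at most 10 traits")
  n <- nrow(Y)
  map <- markerMap(panel)
  B <- b73Dosage(panel)[keep, , drop = FALSE]
  chroms <- unique(map$chrom)
  if (!is.null(chromosomes)) chroms <- intersect(chroms, chromosomes)
  nullFits <- list()
  rows <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    c <- chroms[ci]
    K <- if (loco) kinships$loco[[c]] else kinships$global
    K <- K[keep, keep, drop = FALSE]
    eig <- eigen(K, symmetric = TRUE)
    D <- pmax(eig$values, 0)
    U <- eig$vectors
    Yt <- crossprod(U, Y)
    onet <- as.vector(crossprod(U, rep(1, n)))
    nf <- mvLmmFit(Yt, cbind(onet), D)
    nullFits[[c]] <- nf
    sd <- simDiag(nf$Vg, nf$Ve)
    Ut <- Yt %*% sd$Q                     # n x t
    Wm <- 1 / (outer(D, sd$phi) + 1)      # n x t
    mIdx <- which(map$chrom == c)
    Xc <- crossprod(U, B[, mIdx, drop = FALSE])  # rotated markers, n x m
    ## per-(marker, transformed-trait) GLS: independent 2x2 systems
    a11 <- colSums(onet^2 * Wm)           # t
    b1 <- colSums(onet * Wm * Ut)         # t
    A12 <- crossprod(Xc, onet * Wm)       # m x t : sum c x w
    A22 <- crossprod(Xc^2, Wm)            # m x t : sum x^2 w
    B2 <- sapply(seq_len(t), function(k)
      colSums(Xc * (Wm[, k] * Ut[, k])))  # m x t : sum x w u
    A11 <- matrix(a11, nrow(A12), t, byrow = TRUE)
    B1 <- matrix(b1, nrow(A12), t, byrow = TRUE)
    det <- A11 * A22 - A12^2
    betaT <- (A11 * B2 - A12 * B1) / det  # m x t, transformed effects
    varT <- A11 / det                     # m x t, Var(betaT_k)
    stat <- rowSums(betaT^2 / varT)
    ## back-transform: beta = t(Qi) betaT ; Var(beta) = t(Qi) diag(varT) Qi
    beta <- betaT %*% sd$Qi
    se <- sqrt(varT %*% (sd$Qi^2))
    mono <- apply(B[, mIdx, drop = FALSE], 2, stats::var) == 0 |
      !is.finite(stat)
    stat[mono] <- 0
    pv <- stats::pchisq(stat, df = t, lower.tail = FALSE)
    pv[mono] <- 1
    res <- data.frame(
      environment = environment, marker = map$marker[mIdx], chrom = c,
      pos_bp = map$pos_bp[mIdx], method = "MV", statistic = stat,
      p = pmin(pmax(pv, .Machine$double.xmin), 1),
      stringsAsFactors = FALSE)
    colnames(beta) <- paste0("beta_", colnames(Y))
    colnames(se) <- paste0("se_", colnames(Y))
    res <- cbind(res, beta, se)
    res$flag <- ifelse(mono, "monomorphic", NA_character_)
    rows[[ci]] <- res
  }
  list(associations = do.call(rbind, rows), nullFit = nullFits)
}

#' A-posteriori trait assignment of multivariate hits
#'
#' A marker that passes the joint multivariate screen is assigned to trait
#' `j` when its per-trait Wald statistic `(beta_j / se_j)^2` exceeds the
#' chi-square(1) quantile at `1 - alpha`. Markers with no assignable trait
#' are flagged `unassigned`.
#'
#' @param mvRows significant rows of [gwasMultivariate()] associations.
#' @param traits trait names (matching the `beta_*`/`se_*` columns).
#' @param alpha per-trait test level (default 0.01).
#' @return `mvRows` with list-column `assigned` and logical `unassigned`.
#' @export
assignMvTraits <- function(mvRows, traits, alpha = 0.01) {
  thr <- stats::qchisq(1 - alpha, df = 1)
  assigned <- lapply(seq_len(nrow(mvRows)), function(i) {
    w <- vapply(traits, function(tr) {
      b <- mvRows[[paste0("beta_", tr)]][i]
      s <- mvRows[[paste0("se_", tr)]][i]
      if (!is.finite(b) || !is.finite(s) || s <= 0) 0 else (b / s)^2
    }, numeric(1))
    traits[w > thr]
  })
  mvRows$assigned <- assigned
  mvRows$unassigned <- lengths(assigned) == 0L
  mvRows
}
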