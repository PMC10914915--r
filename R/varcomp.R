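#' Multi-environment variance decomposition
#'
#' REML fit of `value = environment (fixed) + genotype (random) +
#' genotype:environment (random) + residual` across environments, with each
#' random term tested by a restricted likelihood-ratio test against the
#' model without it. The boundary null is handled with the
#' `0.5 chi2_0 + 0.5 chi2_1` mixture. `CV_g = 100 sigma_g / mu` expresses
#' the genetic standard deviation as a percentage of the trait mean.
#'
#' @param plotTable plot- or genotype-level table with `genotype`,
#'   `environment` and the trait column (replicates within environment are
#'   required to separate G x E from residual variance).
#' @param trait trait column name.
#' @return list of class `glaiVarComp`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `cv_g` (percent), `geOverG`, and `rlrt` (term, statistic,
#'   p-value).
#' @export
varianceDecomposition <- function(plotTable, trait) {
  d <- plotTable[is.finite(plotTable[[trait]]), ]
  if (length(unique(d$environment)) < 2L)
    stop("variance decomposition needs at least 2 environments")
  d$genotype <- factor(d$genotype)
  d$environment <- factor(d$environment)
  ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                           calc.derivs = FALSE)
  full <- lme4::lmer(
    stats::reformulate(c("environment", "(1 | genotype)",
                         "(1 | genotype:environment)"), response = trait),
    data = d, REML = TRUE, control = ctl)
  noG <- lme4::lmer(
    stats::reformulate(c("environment", "(1 | genotype:environment)"),
                       response = trait), data = d, REML = TRUE,
    control = ctl)
  noGE <- lme4::lmer(
    stats::reformulate(c("environment", "(1 | genotype)"),
                       response = trait), data = d, REML = TRUE,
    control = ctl)
  vc <- as.data.frame(lme4::VarCorr(full))
  s2g <- vc$vcov[vc$grp == "genotype"]
  s2ge <- vc$vcov[vc$grp == "genotype:environment"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  rlrtP <- function(fullFit, redFit) {
    stat <- max(0, 2 * (as.numeric(stats::logLik(fullFit)) -
                          as.numeric(stats::logLik(redFit))))
    p <- if (stat <= 0) 1 else
      0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
    c(statistic = stat, p = p)
  }
  rlrt <- rbind(genotype = rlrtP(full, noG), gxe = rlrtP(full, noGE))
  mu <- mean(d[[trait]])
  structure(list(sigma2_g = s2g, sigma2_ge = s2ge, sigma2_e = s2e,
                 cv_g = 100 * sqrt(s2g) / mu,
                 geOverG = if (s2g > 0) s2ge / s2g else NA_real_,
                 rlrt = data.frame(term = rownames(rlrt), rlrt,
                                   row.names = NULL),
                 mu = mu, fit = full),
            class = "glaiVarComp")
}

#' @export
print.glaiVarComp <- function(x, ...) {
  cat(sprintf(
    "variance components: g %.4g | gxe %.4g | e %.4g  (CV_g = %.1f%%)\n",
    x$sigma2_g, x$sigma2_ge, x$sigma2_e, x$cv_g))
  print(x$rlrt)
  invisible(x)
}

#' Trait PCA and pairwise Pearson correlations
#'
#' Standardized principal component analysis of adjusted means (rows are
#' genotype-in-environment observations after listwise deletion; columns
#' are unit-variance traits), with per-axis explained variance fractions
#' and trait-axis correlations, plus pairwise Pearson correlations with
#' two-sided t-test p-values per environment.
#'
#' @param means wide data.frame with `genotype`, `environment` and trait
#'   columns.
#' @param traits trait column names (default: all numeric columns).
#' @return list with `pca` (`sdev`, `explained`, `loadings`,
#'   `traitAxisCor`, `scores`, `dropped`) and `correlations` (long
#'   data.frame `environment`, `trait1`, `trait2`, `r`, `p`).
#' @export
traitPcaCorrelations <- function(means, traits = NULL) {
  if (is.null(traits))
    traits <- setdiff(names(means)[vapply(means, is.numeric, TRUE)],
                      c("genotype", "environment"))
  M <- means[, traits, drop = FALSE]
  keep <- stats::complete.cases(M)
  M <- M[keep, , drop = FALSE]
  constant <- vapply(M, function(v) stats::sd(v) < 1e-12, TRUE)
  if (any(constant)) {
    warning("excluding constant trait column(s): ",
            paste(traits[constant], collapse = ", "))
    M <- M[, !constant, drop = FALSE]
  }
  pca <- stats::prcomp(M, center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  axisCor <- stats::cor(M, pca$x)
  envs <- unique(means$environment)
  cors <- do.call(rbind, lapply(envs, function(e) {
    Me <- means[means$environment == e, colnames(M), drop = FALSE]
    Me <- Me[stats::complete.cases(Me), , drop = FALSE]
    prs <- utils::combn(colnames(M), 2)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      ct <- stats::cor.test(Me[[prs[1, k]]], Me[[prs[2, k]]])
      data.frame(environment = e, trait1 = prs[1, k], trait2 = prs[2, k],
                 r = unname(ct$estimate), p = ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(pca = list(sdev = pca$sdev, explained = expl,
                  loadings = pca$rotation, traitAxisCor = axisCor,
                  scores = pca$x, dropped = traits[constant]),
       correlations = cors)
}
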