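test_that("IBS kinship matches direct allele-sharing enumeration", {
  d <- rbind(c(0, 0, 2, 2),
             c(0, 2, 2, 0),
             c(0, 0, 2, 2))
  p <- toyPanel(d, chrom = rep("1", 4), pos = c(10, 20, 30, 40))
  K <- ibsKinship(p)
  expect_equal(unname(K[1, 2]), 2 / 4)  # shares loci 1 and 3
  expect_equal(unname(K[1, 3]), 1)      # identical lines
  expect_equal(unname(diag(K)), rep(1, 3))
  d2 <- rbind(c(0, 0, 0), c(2, 2, 2))
  p2 <- toyPanel(d2, chrom = rep("1", 3), pos = c(1, 2, 3))
  expect_equal(unname(ibsKinship(p2)[1, 2]), 0)  # opposite homozygotes
})

test_that("LOCO kinship never uses the excluded chromosome", {
  # markers on chromosome 1 make lines identical; on chromosome 2 they
  # differ, so K^(-1) must differ from the global matrix
  d <- rbind(c(2, 2, 0, 2),
             c(2, 2, 2, 0))
  p <- toyPanel(d, chrom = c("1", "1", "2", "2"), pos = c(1, 2, 1, 2))
  ks <- kinshipSet(p)
  expect_equal(unname(ks$loco[["1"]][1, 2]), 0)  # chrom-2 markers only
  expect_equal(unname(ks$loco[["2"]][1, 2]), 1)  # chrom-1 markers only
  expect_equal(unname(ks$global[1, 2]), 0.5)
  expect_error(ibsKinship(toyPanel(d[, 1:2, drop = FALSE],
                                   chrom = c("1", "1"), pos = 1:2),
                          excludeChrom = "1"), "no markers")
})

test_that("with an identity kinship the scan degenerates to ordinary least squares", {
  set.seed(41)
  p <- fixturePanel()
  kid <- identityKinships(p)
  B <- b73Dosage(p)
  y <- 0.5 * B[, 10] + rnorm(ncol(p))
  names(y) <- colnames(p)
  res <- gwasUnivariate(y, p, kid)
  n <- length(y)
  for (j in c(5, 10, 50)) {
    x <- B[, res$marker[j]]
    fit0 <- lm(y ~ 1); fit1 <- lm(y ~ x)
    lrt <- n * (log(sum(resid(fit0)^2)) - log(sum(resid(fit1)^2)))
    pOls <- pchisq(lrt, 1, lower.tail = FALSE)
    expect_equal(res$beta[j], unname(coef(fit1)[2]), tolerance = 1e-6)
    expect_equal(res$p[j], pOls, tolerance = 1e-6)
  }
})

test_that("monomorphic markers are reported with p = 1 and flagged", {
  d <- cbind(c(2, 2, 2, 2, 2, 0), rep(2, 6), c(0, 2, 0, 2, 0, 2))
  p <- toyPanel(d, chrom = rep("1", 3), pos = c(1, 5, 9))
  y <- rnorm(6); names(y) <- colnames(p)
  res <- gwasUnivariate(y, p, identityKinships(p))
  expect_equal(res$p[res$marker == "M02"], 1)
  expect_equal(res$flag[res$marker == "M02"], "monomorphic")
})

test_that("the univariate scan holds its size and inflation on a null chromosome", {
  # polygenic background on the other chromosomes; scanned chromosome null
  set.seed(43)
  p <- simulateMagicGenotypes(nLines = 200, nChrom = 3,
                              markersPerChrom = c(400, 120, 120),
                              seed = 19)
  kin <- kinshipSet(p)
  off <- markerMap(p)$chrom != "1"
  Z <- scale(dosage(p)[, off])
  pv <- unlist(lapply(1:10, function(r) {
    u <- as.vector(Z %*% rnorm(ncol(Z))); u <- u / sd(u)
    y <- u + rnorm(200); names(y) <- colnames(p)
    gwasUnivariate(y, p, kin, chromosomes = "1")$p
  }))
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.015)
  expect_lt(abs(genomicInflation(pv) - 1), 0.12)
})

test_that("LRT power matches the noncentral chi-square oracle for a 10% QTL", {
  set.seed(44)
  p <- fixturePanel()
  kid <- identityKinships(p)
  B <- b73Dosage(p)
  mk <- names(sort(markerMaf(p), decreasing = TRUE))[1]
  n <- ncol(p)
  x <- B[, mk]
  stats <- sapply(1:10, function(s) {
    set.seed(s * 7)
    beta <- sqrt(0.1 / 0.9 / var(x))
    y <- beta * x + rnorm(n)
    names(y) <- colnames(p)
    res <- gwasUnivariate(y, p, kid)
    res$statistic[res$marker == mk]
  })
  ncp <- n * 0.10 / 0.90
  theor <- qchisq(0.5, df = 1, ncp = ncp)
  expect_equal(median(stats), theor, tolerance = 0.25 * theor)
})

test_that("with independent traits the multivariate betas match the univariate ones", {
  set.seed(45)
  p <- fixturePanel()
  kid <- identityKinships(p)
  B <- b73Dosage(p)
  n <- ncol(p)
  Y <- cbind(0.6 * B[, 3] + rnorm(n), rnorm(n), rnorm(n))
  rownames(Y) <- colnames(p); colnames(Y) <- c("a", "b", "c")
  mv <- suppressWarnings(gwasMultivariate(Y, p, kid))
  for (tr in colnames(Y)) {
    y <- Y[, tr]; names(y) <- rownames(Y)
    uv <- gwasUnivariate(y, p, kid)
    m <- match(uv$marker, mv$associations$marker)
    expect_equal(mv$associations[[paste0("beta_", tr)]][m], uv$beta,
                 tolerance = 1e-3)
  }
})

test_that("the joint Wald statistic has mean t under the null", {
  set.seed(46)
  p <- simulateMagicGenotypes(nLines = 200, nChrom = 3,
                              markersPerChrom = c(400, 120, 120), seed = 19)
  kin <- kinshipSet(p)
  off <- markerMap(p)$chrom != "1"
  Z <- scale(dosage(p)[, off])
  t <- 4
  G <- scale(Z %*% matrix(rnorm(ncol(Z) * t), ncol = t)) %*%
    chol(0.5 + 0.5 * diag(t))
  Y <- G + matrix(rnorm(200 * t), ncol = t) %*% chol(0.3 + 0.7 * diag(t))
  rownames(Y) <- colnames(p); colnames(Y) <- paste0("T", 1:t)
  mv <- suppressWarnings(gwasMultivariate(Y, p, kin, chromosomes = "1"))
  expect_equal(mean(mv$associations$statistic), t, tolerance = 0.5)
  # genetic correlation of a trait with itself is exactly 1
  expect_equal(unname(diag(mv$nullFit[["1"]]$rg)), rep(1, t))
})

test_that("univariate and multivariate tests agree in the single-trait limit", {
  set.seed(47)
  p <- simulateMagicGenotypes(nLines = 200, nChrom = 3,
                              markersPerChrom = 80, seed = 42)
  kin <- kinshipSet(p)
  B <- b73Dosage(p)
  L <- chol(kin$global + 1e-8 * diag(200))
  u <- as.vector(t(L) %*% rnorm(200)); u <- u / sd(u)
  y <- 0.4 * B[, 7] + u + rnorm(200)
  names(y) <- colnames(p)
  uv <- gwasUnivariate(y, p, kin, loco = FALSE)
  Y <- matrix(y, ncol = 1, dimnames = list(names(y), "t1"))
  mv <- suppressWarnings(gwasMultivariate(Y, p, kin, loco = FALSE))
  m <- match(uv$marker, mv$associations$marker)
  ok <- uv$flag %in% NA
  expect_gt(cor(rank(uv$p[ok]), rank(mv$associations$p[m][ok])), 0.999)
})

test_that("Storey q-values behave as a step-up FDR procedure", {
  expect_warning(q1 <- storeyQvalues(0.03), "fewer than 100")
  expect_equal(as.numeric(q1), 0.03)
  set.seed(48)
  pUnif <- runif(10000)
  q <- storeyQvalues(pUnif)
  expect_equal(attr(q, "pi0"), 1, tolerance = 0.05)
  ord <- order(pUnif)
  expect_true(all(diff(q[ord]) >= -1e-12))
  ## independent step-up construction on a mixed sample
  pMix <- c(runif(300), rbeta(60, 0.2, 5))
  qm <- storeyQvalues(pMix)
  pi0 <- attr(qm, "pi0")
  m <- length(pMix)
  direct <- vapply(pMix, function(pi)
    min(pi0 * m * pMix[pMix >= pi] /
          rank(pMix, ties.method = "max")[pMix >= pi], 1), numeric(1))
  expect_equal(as.numeric(qm), direct, tolerance = 1e-12)
})

test_that("a-posteriori trait assignment follows the per-trait Wald rule", {
  rows <- data.frame(marker = c("m1", "m2"),
                     beta_a = c(10, 0.5), se_a = c(1, 1),
                     beta_b = c(0.1, 0.6), se_b = c(1, 1))
  out <- assignMvTraits(rows, c("a", "b"), alpha = 0.01)
  expect_equal(out$assigned[[1]], "a")
  expect_true(out$unassigned[2])
})
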