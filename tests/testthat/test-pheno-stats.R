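test_that("with no spatial correlation adjusted means reduce to raw genotype means", {
  set.seed(21)
  d <- balancedPlotTable(40)
  am <- adjustedMeans(d, "y", "E1", rhoGrid = 0)
  raw <- tapply(d$y, d$genotype, mean)
  expect_equal(am$value, as.numeric(raw[am$genotype]), tolerance = 1e-8)
})

test_that("planted block offsets are removed exactly in a balanced design", {
  set.seed(22)
  b <- c(-1.5, 1.5)
  d <- balancedPlotTable(30, blockEff = b)
  am <- adjustedMeans(d, "y", "E1", rhoGrid = 0)
  corrected <- tapply(d$y - b[d$block], d$genotype, mean)
  expect_equal(am$value, as.numeric(corrected[am$genotype]),
               tolerance = 1e-6)
})

test_that("spatial adjustment beats raw means under a planted AR1 field", {
  set.seed(23)
  rmses <- sapply(1:8, function(s) {
    set.seed(s)
    d <- balancedPlotTable(36, sdE = 0.4)
    g <- attr(d, "trueG")
    nr <- max(d$row); nc <- max(d$col)
    Lr <- chol(0.7^abs(outer(1:nr, 1:nr, "-")))
    Lc <- chol(0.7^abs(outer(1:nc, 1:nc, "-")))
    field <- 1.0 * (t(Lr) %*% matrix(rnorm(nr * nc), nr, nc) %*% Lc)
    d$y <- d$y + field[cbind(d$row, d$col)]
    am <- adjustedMeans(d, "y", "E1", rhoGrid = c(0, 0.3, 0.5, 0.7))
    raw <- tapply(d$y, d$genotype, mean)
    truth <- g[as.integer(factor(am$genotype))]
    rmse <- function(v) sqrt(mean((v - mean(v) - (truth - mean(truth)))^2))
    c(adj = rmse(am$value), raw = rmse(as.numeric(raw[am$genotype])))
  })
  expect_lte(mean(rmses["adj", ]), mean(rmses["raw", ]))
})

test_that("heritability matches the balanced-design closed form", {
  # sigma_g^2 = sigma_e^2 = 1, r = 2 reps: H2 = 1 / (1 + 1/2) = 2/3
  set.seed(24)
  h2 <- sapply(1:6, function(s) {
    set.seed(s * 13)
    generalizedHeritability(balancedPlotTable(150), "y", "E1")
  })
  expect_equal(mean(h2), 2 / 3, tolerance = 0.05)
})

test_that("heritability approaches its limits", {
  set.seed(25)
  dHi <- balancedPlotTable(60, sdG = 1, sdE = 0.01)
  expect_gt(generalizedHeritability(dHi, "y", "E1"), 0.99)
  # response driven by block alone: essentially no genetic variance
  dNo <- balancedPlotTable(60, sdG = 0, sdE = 0.05,
                           blockEff = c(-1, 1))
  expect_lt(generalizedHeritability(dNo, "y", "E1"), 0.1)
})

test_that("multi-environment variance components are recovered", {
  set.seed(26)
  make <- function(seed) {
    set.seed(seed)
    g <- rnorm(200, 0, 2)
    ge <- matrix(rnorm(200 * 4), 200)
    d <- expand.grid(genotype = sprintf("g%03d", 1:200),
                     environment = paste0("E", 1:4), rep = 1:2,
                     stringsAsFactors = FALSE)
    gi <- as.integer(factor(d$genotype))
    ei <- as.integer(factor(d$environment))
    d$y <- 10 + ei + g[gi] + ge[cbind(gi, ei)] + rnorm(nrow(d))
    d
  }
  est <- sapply(1:4, function(s) {
    vc <- varianceDecomposition(make(s), "y")
    c(vc$sigma2_g, vc$sigma2_ge, vc$sigma2_e)
  })
  expect_lt(max(abs(rowMeans(est) - c(4, 1, 1)) / c(4, 1, 1)), 0.15)
  vc <- varianceDecomposition(make(1), "y")
  expect_lt(vc$rlrt$p[vc$rlrt$term == "genotype"], 1e-6)
  # CV_g is the genetic SD as a percentage of the mean, by construction
  expect_equal(vc$cv_g, 100 * sqrt(vc$sigma2_g) / vc$mu)
})

test_that("the G x E likelihood-ratio test holds its size under a null G x E", {
  set.seed(27)
  rej <- sapply(1:60, function(s) {
    set.seed(s + 500)
    g <- rnorm(60)
    d <- expand.grid(genotype = sprintf("g%02d", 1:60),
                     environment = c("A", "B"), rep = 1:2,
                     stringsAsFactors = FALSE)
    d$y <- g[as.integer(factor(d$genotype))] + rnorm(nrow(d))
    vc <- varianceDecomposition(d, "y")
    vc$rlrt$p[vc$rlrt$term == "gxe"] <= 0.05
  })
  expect_lt(mean(rej), 0.14)  # near the nominal 5%
})

test_that("PCA explained variance matches a direct eigendecomposition", {
  set.seed(28)
  n <- 150
  base <- rnorm(n)
  m <- data.frame(genotype = sprintf("g%03d", 1:n), environment = "E1",
                  t1 = base, t2 = base, t3 = rnorm(n), t4 = rnorm(n))
  res <- traitPcaCorrelations(m, c("t1", "t2", "t3", "t4"))
  ev <- eigen(cor(m[, c("t1", "t2", "t3", "t4")]))$values
  expect_equal(res$pca$explained, ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(res$pca$explained), 1, tolerance = 1e-12)
})

test_that("a planted trait correlation of 0.4 is estimated at n = 324", {
  set.seed(29)
  n <- 324
  x <- rnorm(n)
  m <- data.frame(genotype = sprintf("g%03d", 1:n), environment = "E1",
                  a = x, b = 0.4 * x + sqrt(1 - 0.16) * rnorm(n))
  res <- traitPcaCorrelations(m, c("a", "b"))
  expect_lt(abs(res$correlations$r[1] - 0.4), 0.1)
})

test_that("constant trait columns are excluded with a warning", {
  m <- data.frame(genotype = sprintf("g%02d", 1:30), environment = "E1",
                  a = rnorm(30), b = rnorm(30), c = 1)
  expect_warning(res <- traitPcaCorrelations(m, c("a", "b", "c")),
                 "constant")
  expect_false("c" %in% colnames(res$pca$loadings))
})
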