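test_that("doubled-haploid dosages are 0/2 and mosaics tile chromosomes", {
  p <- fixturePanel()
  expect_true(all(dosage(p) %in% c(0, 2)))
  fm <- founderMosaic(p)
  for (ln in unique(fm$line)[1:5]) {
    for (ch in unique(fm$chrom)) {
      seg <- fm[fm$line == ln & fm$chrom == ch, ]
      expect_equal(seg$start[1], 1)
      if (nrow(seg) > 1)
        expect_equal(seg$start[-1], head(seg$end, -1))
      expect_true(all(seg$founder %in% 1:16))
    }
  }
})

test_that("zero recombination gives one founder segment per chromosome", {
  p <- simulateMagicGenotypes(nLines = 20, nChrom = 2,
                              markersPerChrom = 30, recombRate = 0,
                              seed = 7)
  fm <- founderMosaic(p)
  segs <- aggregate(start ~ line + chrom, fm, length)
  expect_true(all(segs$start == 1))
})

test_that("generation is bit-identical under a fixed seed", {
  p1 <- simulateMagicGenotypes(nLines = 25, nChrom = 2,
                               markersPerChrom = 40, seed = 11)
  p2 <- simulateMagicGenotypes(nLines = 25, nChrom = 2,
                               markersPerChrom = 40, seed = 11)
  expect_identical(dosage(p1), dosage(p2))
  expect_identical(markerMap(p1), markerMap(p2))
})

test_that("MAF filter enforces its threshold and can empty the panel", {
  p <- fixturePanel()
  expect_true(min(markerMaf(p)) >= 0.035)
  # 3 lines: every possible frequency is below 0.49, so nothing survives
  expect_error(
    simulateMagicGenotypes(nLines = 3, nChrom = 1, markersPerChrom = 10,
                           mafThreshold = 0.49, seed = 13),
    "MAF")
})

test_that("degenerate generator yields identical true curves per environment", {
  p <- simulateMagicGenotypes(nLines = 12, nChrom = 2,
                              markersPerChrom = 30, seed = 3)
  des <- makeTrialDesign(p, referenceEnvironments()[1, ], seed = 1)
  zeroSd <- function(x) stats::setNames(rep(0, length(x)), names(x))
  tc <- truthConfig(geneticSd = zeroSd(truthConfig()$geneticSd),
                    gxeSd = zeroSd(truthConfig()$gxeSd))
  sim <- simulateTrialPhenotypes(p, des, tc, seed = 5)
  tt <- sim$truth$trueTraits
  expect_true(all(apply(tt[, glaiTraitNames()], 2,
                        function(v) diff(range(v))) < 1e-9))
})

test_that("a planted QTL on a filtered-out marker fails loudly", {
  p <- fixturePanel()
  des <- makeTrialDesign(p, referenceEnvironments()[1:2, ], seed = 1)
  bad <- truthConfig(qtls = data.frame(marker = "NOT_A_MARKER",
                                       param = "glai_max", effect = 0.3))
  expect_error(simulateTrialPhenotypes(p, des, bad, seed = 1),
               "not retained")
})

test_that("planted GLAI_M effect is recovered as the allele-class mean difference", {
  p <- fixturePanel()
  des <- makeTrialDesign(p, referenceEnvironments()[1, ], seed = 1)
  qm <- names(sort(markerMaf(p), decreasing = TRUE))[1]
  diffs <- sapply(1:6, function(s) {
    sim <- simulateTrialPhenotypes(
      p, des, truthConfig(qtls = data.frame(marker = qm,
                                            param = "glai_max",
                                            effect = 0.3)), seed = s)
    tt <- sim$truth$trueTraits
    b <- b73Dosage(p)[tt$genotype, qm]
    mean(tt$GLAI_M[b == 1]) - mean(tt$GLAI_M[b == 0])
  })
  expect_equal(mean(diffs), 0.3, tolerance = 0.15)
})

test_that("the water-deficit multiplier shrinks GLAI_M by its configured ratio", {
  p <- simulateMagicGenotypes(nLines = 40, nChrom = 2,
                              markersPerChrom = 40, seed = 5)
  des <- makeTrialDesign(p, referenceEnvironments()[1:2, ], seed = 1)
  ratios <- sapply(1:5, function(s) {
    sim <- simulateTrialPhenotypes(p, des, truthConfig(wdGlaiMult = 0.8),
                                   seed = s)
    tt <- sim$truth$trueTraits
    mean(tt$GLAI_M[tt$environment == "16WD"]) /
      mean(tt$GLAI_M[tt$environment == "16WW"])
  })
  expect_equal(mean(ratios), 0.8, tolerance = 0.03)
})

test_that("yield correlates positively with the true senescence area", {
  p <- fixturePanel()
  des <- makeTrialDesign(p, referenceEnvironments()[1, ], seed = 2)
  sim <- simulateTrialPhenotypes(p, des, truthConfig(), seed = 9)
  m <- merge(sim$agronomic,
             sim$truth$trueTraits[, c("genotype", "environment", "AUC_S")],
             by = c("genotype", "environment"))
  expect_gt(cor(m$GY, m$AUC_S), 0)
})

test_that("funnel families show elevated within-family kinship", {
  p <- fixturePanel()
  K <- ibsKinship(p)
  fam <- SummarizedExperiment::colData(p)$family
  same <- outer(fam, fam, "==")
  diag(same) <- NA
  expect_gt(mean(K[which(same)]), mean(K[which(!same)]))
})

test_that("extraction on noise-free curves matches the analytic truth", {
  # cross-module oracle: planted parameters -> analytic traits vs grid
  # extraction of the same curve, within 2 GDD6 / 1% AUC
  set.seed(77)
  for (i in 1:5) {
    pars <- randomCurveParams()
    g <- 0:2000
    v <- glaiCurve(pars, g)
    tr <- extractTraits(g, v)
    tt <- trueGlaiTraits(pars)
    durations <- grep("^D_", glaiTraitNames(), value = TRUE)
    expect_true(all(abs(tr[durations] - tt[durations]) <= 2.5),
                label = paste("durations, curve", i))
    aucs <- grep("^AUC_", glaiTraitNames(), value = TRUE)
    expect_true(all(abs(tr[aucs] - tt[aucs]) <=
                      0.01 * pmax(tt[aucs], 1)),
                label = paste("AUCs, curve", i))
    expect_equal(unname(tr["GLAI_M"]), unname(tt["GLAI_M"]),
                 tolerance = 1e-6)
  }
})
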