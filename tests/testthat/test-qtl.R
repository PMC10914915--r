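makeHits <- function(panel, markers, p = NULL) {
  map <- markerMap(panel)
  i <- match(markers, map$marker)
  data.frame(trait = "t", environment = "e", marker = markers,
             chrom = map$chrom[i], pos_bp = map$pos_bp[i],
             p = if (is.null(p)) seq(1e-8, 1e-6,
                                     length.out = length(markers)) else p,
             stringsAsFactors = FALSE)
}

test_that("markers in complete LD form one cluster, unlinked markers two", {
  d <- cbind(c(0, 0, 2, 2, 0, 2), c(0, 0, 2, 2, 0, 2),
             c(2, 0, 0, 2, 2, 0))
  p <- toyPanel(d, chrom = rep("1", 3), pos = c(100, 200, 5000))
  S4Vectors::metadata(p)$chromLengthBp <- c("1" = 1e6)
  cl <- clusterSnps(makeHits(p, c("M01", "M02")), p)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_snps, 2L)
  cl2 <- clusterSnps(makeHits(p, c("M01", "M03")), p)
  expect_equal(nrow(cl2), 2L)
  expect_equal(nrow(clusterSnps(NULL, p)), 0L)
})

test_that("clusters longer than 30% of the chromosome are discarded as span artifacts", {
  d <- cbind(c(0, 0, 2, 2, 0, 2), c(0, 0, 2, 2, 0, 2))
  p <- toyPanel(d, chrom = rep("1", 2), pos = c(100, 360000))
  S4Vectors::metadata(p)$chromLengthBp <- c("1" = 1e6)
  cl <- clusterSnps(makeHits(p, c("M01", "M02")), p)  # spans 35.99%
  expect_true(all(cl$discarded))
  expect_equal(unique(cl$reason), "span")
  p2 <- toyPanel(d, chrom = rep("1", 2), pos = c(100, 250000))
  S4Vectors::metadata(p2)$chromLengthBp <- c("1" = 1e6)
  cl2 <- clusterSnps(makeHits(p2, c("M01", "M02")), p2)  # 24.99%
  expect_false(any(cl2$discarded))
})

test_that("clustering partitions the significant markers of each chromosome", {
  set.seed(61)
  p <- fixturePanel()
  for (i in 1:5) {
    mks <- sample(rownames(p), 25)
    hits <- makeHits(p, mks, p = runif(25, 1e-10, 1e-4))
    cl <- clusterSnps(hits, p)
    members <- unlist(cl$members)
    expect_setequal(members, mks)
    expect_equal(anyDuplicated(members), 0L)
    expect_true(all(cl$peak %in% mks))
    # peak is the smallest p of its members
    for (k in seq_len(nrow(cl))) {
      mp <- hits$p[match(cl$members[[k]], hits$marker)]
      expect_equal(hits$p[hits$marker == cl$peak[k]], min(mp))
    }
  }
})

test_that("interval extension follows the farthest qualifying marker", {
  # M1-M2 clustered; M3 50 kb beyond in complete LD; M4 unlinked
  v <- c(0, 0, 2, 2, 0, 2, 0, 2)
  d <- cbind(v, v, v, c(2, 0, 0, 2, 2, 0, 2, 0))
  p <- toyPanel(d, chrom = rep("1", 4),
                pos = c(100000, 120000, 170000, 300000))
  S4Vectors::metadata(p)$chromLengthBp <- c("1" = 1e7)
  cl <- clusterSnps(makeHits(p, c("M01", "M02")), p)
  ext <- extendInterval(cl[1, ], p, window = 1e6)
  expect_equal(unname(ext["start"]), 100000)
  expect_equal(unname(ext["end"]), 170001)  # extended to M3, not M4
  extNone <- extendInterval(cl[1, ], p, window = 1e4)
  expect_equal(unname(extNone["end"]), cl$end[1])  # M3 outside window
})

test_that("interval extension agrees with a brute-force scan", {
  set.seed(62)
  p <- fixturePanel()
  map <- markerMap(p)
  D <- dosage(p)
  for (i in 1:20) {
    mks <- sample(rownames(p), 4)
    hits <- makeHits(p, mks, p = runif(4, 1e-9, 1e-5))
    cl <- clusterSnps(hits, p)
    cl <- cl[!cl$discarded, ]
    if (!nrow(cl)) next
    k <- sample(nrow(cl), 1)
    ext <- extendInterval(cl[k, ], p, window = 5e6)
    # oracle: plain loop over all markers of the chromosome
    onC <- map[map$chrom == cl$chrom[k], ]
    mem <- cl$members[[k]]
    mpos <- onC$pos_bp[match(mem, onC$marker)]
    lm0 <- mem[which.min(mpos)]; rm0 <- mem[which.max(mpos)]
    s <- cl$start[k]; e <- cl$end[k]
    for (j in seq_len(nrow(onC))) {
      r2 <- suppressWarnings(cor(D[, lm0], D[, onC$marker[j]])^2)
      if (!is.na(r2) && r2 >= 0.6 && onC$pos_bp[j] < cl$start[k] &&
          onC$pos_bp[j] >= cl$start[k] - 5e6)
        s <- min(s, onC$pos_bp[j])
      r2 <- suppressWarnings(cor(D[, rm0], D[, onC$marker[j]])^2)
      if (!is.na(r2) && r2 >= 0.6 && onC$pos_bp[j] >= cl$end[k] &&
          onC$pos_bp[j] <= cl$end[k] - 1 + 5e6)
        e <- max(e, onC$pos_bp[j] + 1)
    }
    expect_equal(unname(ext), c(s, e))
  }
})

test_that("backward elimination keeps a planted QTL and little else", {
  set.seed(63)
  p <- fixturePanel()
  B <- b73Dosage(p)
  map <- markerMap(p)
  common <- names(which(markerMaf(p) >= 0.25))
  planted <- common[1]
  # decoys from other chromosomes, unlinked to the planted marker
  pool <- common[map$chrom[match(common, map$marker)] !=
                   map$chrom[match(planted, map$marker)]]
  keepRate <- decoyCount <- 0
  nSeeds <- 10
  for (s in 1:nSeeds) {
    set.seed(s + 70)
    decoys <- sample(pool, 5)
    d <- expand.grid(genotype = colnames(p),
                     environment = paste0("E", 1:4),
                     stringsAsFactors = FALSE)
    g <- rnorm(ncol(p)); names(g) <- colnames(p)
    # 0.8 SD effect: sized for this reduced 120-line fixture; the
    # 0.5-SD operating characteristics at full panel size are exercised
    # in the acceptance suite
    sdP <- sqrt(0.36 + 0.64)
    d$value <- 0.8 * sdP * B[d$genotype, planted] +
      0.6 * g[d$genotype] + 0.8 * rnorm(nrow(d))
    sel <- backwardSelectQtls(
      data.frame(id = c("planted", paste0("d", 1:5)),
                 marker = c(planted, decoys)), d, p, alpha = 0.01)
    keepRate <- keepRate + ("planted" %in% sel$selected)
    decoyCount <- decoyCount + sum(sel$selected != "planted")
  }
  expect_gte(keepRate, nSeeds - 1)
  expect_lte(decoyCount / nSeeds, 0.3)
  expect_equal(length(backwardSelectQtls(NULL, NULL, p)$selected), 0L)
})

test_that("backward elimination is invariant to candidate order", {
  set.seed(64)
  p <- fixturePanel()
  B <- b73Dosage(p)
  common <- names(which(markerMaf(p) >= 0.25))
  mks <- common[c(1, 8, 20, 30)]
  d <- expand.grid(genotype = colnames(p), environment = c("A", "B"),
                   stringsAsFactors = FALSE)
  d$value <- 0.6 * B[d$genotype, mks[1]] + 0.5 * B[d$genotype, mks[3]] +
    rnorm(nrow(d))
  cand <- data.frame(id = paste0("c", 1:4), marker = mks)
  s1 <- backwardSelectQtls(cand, d, p, alpha = 0.01)
  s2 <- backwardSelectQtls(cand[4:1, ], d, p, alpha = 0.01)
  expect_setequal(s1$selected, s2$selected)
})

test_that("an environment-specific effect is declared only where planted", {
  set.seed(65)
  p <- fixturePanel()
  B <- b73Dosage(p)
  mk <- names(which(markerMaf(p) >= 0.3))[1]
  hitsE1 <- sapply(1:8, function(s) {
    set.seed(s + 90)
    d <- expand.grid(genotype = colnames(p),
                     environment = paste0("E", 1:3),
                     stringsAsFactors = FALSE)
    d$value <- rnorm(nrow(d), sd = 0.6)
    e1 <- d$environment == "E1"
    d$value[e1] <- d$value[e1] + 1.0 * B[d$genotype[e1], mk]
    sel <- backwardSelectQtls(data.frame(id = "q", marker = mk), d, p,
                              alpha = 0.01)
    eff <- sel$effects
    isTRUE(eff$significant[eff$environment == "E1"]) &&
      sum(eff$significant, na.rm = TRUE) <= 2
  })
  expect_gte(mean(hitsE1), 0.8)
})

test_that("colocalization uses half-open interval overlap and effect signs", {
  qtls <- data.frame(qtl_id = c("a", "b", "c"),
                     trait = c("t1", "t2", "t3"),
                     chrom = "1",
                     ext_start = c(100, 150, 200),
                     ext_end = c(200, 300, 320))
  eff <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                    environment = rep(c("E1", "E2"), 3),
                    beta = c(1, 1, 2, 2, -1, -1),
                    significant = TRUE)
  co <- colocalizeQtls(qtls, eff)
  pairs <- paste(co$qtl1, co$qtl2)
  expect_true("a b" %in% pairs)
  expect_false("a c" %in% pairs)  # [100,200) vs [200,320) do not overlap
  expect_equal(co$direction[co$qtl1 == "a" & co$qtl2 == "b"], "same")
  expect_equal(co$direction[co$qtl1 == "b" & co$qtl2 == "c"], "opposite")
})

test_that("a pleiotropic marker colocalizes with concordant direction", {
  set.seed(66)
  p <- fixturePanel()
  B <- b73Dosage(p)
  mk <- names(which(markerMaf(p) >= 0.3))[2]
  wins <- sapply(1:6, function(s) {
    set.seed(s + 200)
    d1 <- expand.grid(genotype = colnames(p), environment = c("A", "B"),
                      stringsAsFactors = FALSE)
    d2 <- d1
    d1$value <- 0.8 * B[d1$genotype, mk] + rnorm(nrow(d1), sd = 0.5)
    d2$value <- 0.8 * B[d2$genotype, mk] + rnorm(nrow(d2), sd = 0.5)
    s1 <- backwardSelectQtls(data.frame(id = "q1", marker = mk), d1, p)
    s2 <- backwardSelectQtls(data.frame(id = "q2", marker = mk), d2, p)
    if (!length(s1$selected) || !length(s2$selected)) return(FALSE)
    pos <- markerMap(p)$pos_bp[match(mk, markerMap(p)$marker)]
    qtls <- data.frame(qtl_id = c("q1", "q2"), trait = c("t1", "t2"),
                       chrom = markerMap(p)$chrom[
                         match(mk, markerMap(p)$marker)],
                       ext_start = pos, ext_end = pos + 1)
    co <- colocalizeQtls(qtls, rbind(s1$effects, s2$effects))
    nrow(co) == 1 && co$direction == "same"
  })
  expect_gte(mean(wins), 0.9)
})

test_that("variance explained spans its trivial and null regimes", {
  set.seed(67)
  p <- fixturePanel()
  B <- b73Dosage(p)
  mk <- names(which(markerMaf(p) >= 0.3))[1]
  d <- data.frame(genotype = colnames(p), environment = "E1",
                  value = 2 + 1.5 * B[, mk])
  ve <- varianceExplained(mk, d, p, scope = "per-environment")
  expect_gt(ve$r2, 1 - 1e-10)
  nullHigh <- sapply(1:10, function(s) {
    set.seed(s + 300)
    d$value <- rnorm(ncol(p))
    mks <- sample(names(which(markerMaf(p) >= 0.2)), 5)
    varianceExplained(mks, d, p, scope = "network")$r2
  })
  # null expectation ~ 5/119 at this fixture size
  expect_gte(mean(nullHigh <= 0.12), 0.9)
})
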