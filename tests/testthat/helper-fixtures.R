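# Shared fixtures, built once per test run. Sizes are kept small; the
# full-scale study conditions live in test-acceptance.R.

fixturePanel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateMagicGenotypes(nLines = 120, nChrom = 3,
                                       markersPerChrom = 80, seed = 42)
    cache
  }
})

# hand-built two-chromosome panel with known dosages
toyPanel <- function(dosage, chrom, pos, b73 = NULL) {
  # dosage: lines x markers
  d <- t(dosage)
  rownames(d) <- sprintf("M%02d", seq_len(nrow(d)))
  colnames(d) <- sprintf("L%02d", seq_len(ncol(d)))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  names(gr) <- rownames(d)
  S4Vectors::mcols(gr)$ref <- "A"
  S4Vectors::mcols(gr)$alt <- "T"
  S4Vectors::mcols(gr)$b73Allele <-
    if (is.null(b73)) rep(1L, nrow(d)) else b73
  MagicPanel(d, gr)
}

# identity-kinship set matching a panel (degenerate LMM = OLS)
identityKinships <- function(panel) {
  n <- ncol(panel)
  K <- diag(n)
  dimnames(K) <- list(colnames(panel), colnames(panel))
  chroms <- unique(as.character(
    GenomicRanges::seqnames(SummarizedExperiment::rowRanges(panel))))
  list(global = K,
       loco = stats::setNames(rep(list(K), length(chroms)), chroms))
}

# random but valid curve parameters for property-style loops
randomCurveParams <- function() {
  p <- glaiCurveParams()
  p[["t_e"]] <- runif(1, 30, 90)
  p[["tau_v"]] <- p[["t_e"]] + runif(1, 150, 350)
  p[["t_M"]] <- p[["tau_v"]] + runif(1, 200, 500)
  p[["glai_max"]] <- runif(1, 2, 6)
  p[["t_o"]] <- p[["t_M"]] + runif(1, 120, 400)
  p[["tau_s"]] <- p[["t_o"]] + runif(1, 150, 450)
  p[["t_z"]] <- p[["tau_s"]] + runif(1, 150, 400)
  p
}

# balanced single-environment plot table with iid errors
balancedPlotTable <- function(nGeno, nRep = 2, sdG = 1, sdE = 1,
                              blockEff = rep(0, nRep), envName = "E1") {
  g <- rnorm(nGeno, 0, sdG)
  d <- expand.grid(genotype = sprintf("g%03d", seq_len(nGeno)),
                   block = seq_len(nRep), stringsAsFactors = FALSE)
  d$environment <- envName
  nCols <- ceiling(sqrt(nGeno))
  idx <- stats::ave(seq_len(nrow(d)), d$block, FUN = seq_along)
  d$row <- (d$block - 1) * ceiling(nGeno / nCols) +
    (idx - 1) %/% nCols + 1
  d$col <- (idx - 1) %% nCols + 1
  d$y <- g[as.integer(factor(d$genotype))] + blockEff[d$block] +
    rnorm(nrow(d), 0, sdE)
  attr(d, "trueG") <- g
  d
}
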