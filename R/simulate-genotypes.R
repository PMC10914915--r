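#' Simulate a 16-founder MAGIC doubled-haploid genotype panel
#'
#' Generates a panel of fully homozygous lines whose chromosomes are Markov
#' mosaics of founder haplotypes, mimicking a funnel cross of 16 historical
#' founders followed by doubled-haploid production. Founder haplotypes are
#' drawn per marker from per-marker allele frequencies; each line chromosome
#' is a sequence of founder segments with breakpoints at a configurable
#' expected rate; dosages follow from the mosaic; markers failing the minor
#' allele frequency filter are removed.
#'
#' Funnel family structure is approximated by grouping lines into
#' `nFamilies` families that share a founder-preference prior, which induces
#' the within- vs between-family kinship contrast expected of a funnel.
#'
#' @param nLines number of doubled-haploid lines (default 324).
#' @param nChrom number of chromosomes (default 10).
#' @param markersPerChrom markers simulated per chromosome before
#'   filtering (recycled over chromosomes, so marker density may vary).
#' @param chromLengthBp physical chromosome length in bp (recycled).
#' @param recombRate expected founder-switch breakpoints per chromosome per
#'   line (the funnel compresses several meioses into one mosaic; default 6).
#' @param mafThreshold minor allele frequency filter (default 0.035).
#' @param nFounders number of founders (default 16; founder 1 is B73).
#' @param nFamilies number of funnel families sharing a mosaic prior.
#' @param founderFreqRange range of per-marker founder allele frequencies.
#' @param seed integer seed; runs are bit-identical under a fixed seed.
#' @return A [MagicPanel-class] with founder-mosaic truth attached.
#' @examples
#' p <- simulateMagicGenotypes(nLines = 40, nChrom = 2,
#'                             markersPerChrom = 50, seed = 1)
#' dim(dosage(p))
#' @export
simulateMagicGenotypes <- function(nLines = 324,
                                   nChrom = 10,
                                   markersPerChrom = 60,
                                   chromLengthBp = 2e8,
                                   recombRate = 6,
                                   mafThreshold = 0.035,
                                   nFounders = 16,
                                   nFamilies = 8,
                                   founderFreqRange = c(0.1, 0.9),
                                   seed = 1L) {
  stopifnot(nLines >= 2, recombRate >= 0, nFounders >= 2,
            mafThreshold >= 0, mafThreshold < 0.5)
  set.seed(childSeed(seed, "magic-genotypes"))
  chromLengthBp <- rep_len(chromLengthBp, nChrom)
  markersPerChrom <- rep_len(markersPerChrom, nChrom)
  chroms <- as.character(seq_len(nChrom))
  lines <- sprintf("L%03d", seq_len(nLines))

  ## marker positions (sorted uniform) and founder haplotypes
  posList <- lapply(seq_len(nChrom), function(c) {
    sort(sample.int(chromLengthBp[c] - 1L, markersPerChrom[c])) + 1L
  })
  nMarkers <- sum(markersPerChrom)
  pAlt <- runif(nMarkers, founderFreqRange[1], founderFreqRange[2])
  ## founders x markers, 0 = ref, 1 = alt
  founderHap <- matrix(rbinom(nFounders * nMarkers, 1L,
                              rep(pAlt, each = nFounders)),
                       nrow = nFounders)

  ## family-specific founder weights (skewed Dirichlet draws)
  famOf <- rep_len(seq_len(nFamilies), nLines)
  famW <- matrix(rgamma(nFamilies * nFounders, shape = 0.8), nFamilies)
  famW <- famW / rowSums(famW)

  markerChrom <- rep(seq_len(nChrom), times = markersPerChrom)
  dosage <- matrix(0L, nrow = nMarkers, ncol = nLines)
  mosaic <- vector("list", nLines * nChrom)
  k <- 0L
  for (i in seq_len(nLines)) {
    w <- famW[famOf[i], ]
    for (c in seq_len(nChrom)) {
      nb <- rpois(1L, recombRate)
      brk <- if (nb > 0) sort(sample.int(chromLengthBp[c] - 2L, nb) + 1L)
             else integer()
      starts <- c(1L, brk)
      ends <- c(brk, chromLengthBp[c] + 1L)
      founders <- integer(length(starts))
      founders[1] <- sample.int(nFounders, 1L, prob = w)
      if (length(starts) > 1L) {
        for (s in 2L:length(starts)) {
          repeat {
            f <- sample.int(nFounders, 1L, prob = w)
            if (f != founders[s - 1L]) break
          }
          founders[s] <- f
        }
      }
      k <- k + 1L
      mosaic[[k]] <- data.frame(line = lines[i], chrom = chroms[c],
                                start = starts, end = ends,
                                founder = founders)
      ## founder carried at each marker of this chromosome
      idx <- which(markerChrom == c)
      seg <- findInterval(posList[[c]], starts)
      dosage[idx, i] <- 2L * founderHap[cbind(founders[seg], idx)]
    }
  }
  mosaic <- do.call(rbind, mosaic)

  markerNames <- unlist(lapply(seq_len(nChrom), function(c)
    sprintf("C%d_%d", c, posList[[c]])))
  rownames(dosage) <- markerNames
  colnames(dosage) <- lines

  bases <- c("A", "C", "G", "T")
  refA <- sample(bases, nMarkers, replace = TRUE)
  altA <- vapply(refA, function(b) sample(setdiff(bases, b), 1L), "")
  b73Allele <- founderHap[1L, ]  # founder 1 is B73

  gr <- GRanges(seqnames = chroms[markerChrom],
                ranges = IRanges(start = unlist(posList), width = 1L))
  names(gr) <- markerNames
  mcols(gr)$ref <- refA
  mcols(gr)$alt <- altA
  mcols(gr)$b73Allele <- as.integer(b73Allele)

  ## MAF filter
  f <- rowMeans(dosage) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= mafThreshold & maf > 0
  if (sum(keep) < 2L)
    stop("fewer than 2 polymorphic markers survive the MAF filter (",
         "threshold ", mafThreshold, ")")
  gr <- gr[keep]
  mcols(gr)$maf <- maf[keep]
  panel <- MagicPanel(dosage[keep, , drop = FALSE], gr,
                      founderMosaic = mosaic)
  colData(panel)$family <- famOf
  metadata(panel)$mafThreshold <- mafThreshold
  metadata(panel)$chromLengthBp <- stats::setNames(chromLengthBp, chroms)
  metadata(panel)$seed <- seed
  validObject(panel)
  panel
}
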