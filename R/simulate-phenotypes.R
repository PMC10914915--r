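#' Build a multi-environment alpha-lattice-like trial design
#'
#' Lays every line of the panel out in `nBlocks` replicate blocks per
#' environment on a rectangular row x column grid (blocks are contiguous
#' row bands, genotypes randomised within block), the layout the spatial
#' adjustment model assumes.
#'
#' @param panel a [MagicPanel-class] (or character vector of line names).
#' @param environments `data.frame` with columns `name`, `year`,
#'   `treatment` (`"WW"`/`"WD"`) and optionally `stress_start`,
#'   `stress_end` (GDD6). See [referenceEnvironments()].
#' @param nBlocks replicate blocks per environment (default 2).
#' @param nCols columns of the field grid (default: near-square).
#' @param seed integer seed for the within-block randomisation.
#' @return list with `environments` and a `plots` data.frame
#'   (`plot_id`, `environment`, `genotype`, `block`, `row`, `col`).
#' @export
makeTrialDesign <- function(panel, environments = referenceEnvironments(),
                            nBlocks = 2, nCols = NULL, seed = 1L) {
  lines <- if (is.character(panel)) panel else colnames(panel)
  n <- length(lines)
  stopifnot(n >= 2, nBlocks >= 1)
  set.seed(childSeed(seed, "trial-design"))
  if (is.null(nCols)) nCols <- ceiling(sqrt(n))
  rowsPerBlock <- ceiling(n / nCols)
  plots <- do.call(rbind, lapply(seq_len(nrow(environments)), function(e) {
    env <- environments$name[e]
    do.call(rbind, lapply(seq_len(nBlocks), function(b) {
      geno <- sample(lines)
      idx <- seq_len(n)
      data.frame(
        plot_id = sprintf("%s_B%d_P%03d", env, b, idx),
        environment = env, genotype = geno, block = b,
        row = (b - 1L) * rowsPerBlock + (idx - 1L) %/% nCols + 1L,
        col = (idx - 1L) %% nCols + 1L,
        stringsAsFactors = FALSE)
    }))
  }))
  stopifnot(!anyDuplicated(plots[, c("environment", "row", "col")]))
  list(environments = environments, plots = plots)
}

#' The four reference environments (2 years x 2 water treatments)
#'
#' @return `data.frame` of environment descriptors with GDD6 stress windows
#'   for the water-deficit (WD) treatments.
#' @export
referenceEnvironments <- function() {
  data.frame(
    name = c("16WW", "16WD", "17WW", "17WD"),
    year = c(2016, 2016, 2017, 2017),
    treatment = c("WW", "WD", "WW", "WD"),
    stress_start = c(NA, 900, NA, 650),
    stress_end = c(NA, 1700, NA, 1500),
    stringsAsFactors = FALSE)
}

#' Ground-truth configuration for the phenotype generator
#'
#' Collects every knob of the synthetic trial: per-environment baseline curve
#' parameters, genetic and genotype-by-environment standard deviations on
#' each curve parameter, planted QTL effects, the observation (UAV flight)
#' schedule, plot noise structure (block, separable AR1 x AR1 spatial field,
#' independent residual) and the weights tying agronomic traits to the true
#' curve.
#'
#' Water-deficit environments shrink the curve amplitude (`glai_max` times
#' `wdGlaiMult`) and advance senescence (`wdSenescenceShift` GDD6 on `t_o`,
#' `tau_s`, `t_z`), the stress phenomenology of a pre-flowering drought.
#'
#' @param qtls `data.frame` with columns `marker`, `param` (a curve
#'   parameter name, or `"GY"`/`"FF"` for direct agronomic effects),
#'   `effect` (B73-allele effect in trait units) and optionally
#'   `environment` (NA = all environments).
#' @param geneticSd,gxeSd named numeric: SDs of genotype main effects and of
#'   genotype-by-environment deviations per curve parameter.
#' @param flightTimes GDD6 observation times (default 10 flights, evenly
#'   spaced between 150 and 1800).
#' @param obsNoiseSd independent GLAI observation noise SD (m2/m2).
#' @param blockSd,spatialSd,spatialRho block effect SD, spatial field SD and
#'   AR1 correlations (row, col) of plot-level GLAI deviations.
#' @param wdGlaiMult,wdSenescenceShift WD stress multipliers (see above).
#' @param gyAucWeights weights `w1` (AUC_F) and `w2` (AUC_S) in the yield
#'   model, q/ha per (m2/m2 * GDD6).
#' @param gyEnvMean,gyGxeSd,gyNoiseSd grain-yield environment means, G x E
#'   SD and plot residual SD (q/ha).
#' @param ffPerDv flowering response to vegetative duration (GDD6/GDD6).
#' @return a list of class `glaiTruthConfig`.
#' @export
truthConfig <- function(qtls = NULL,
                        geneticSd = c(t_e = 4, tau_v = 12, t_M = 15,
                                      glai_max = 0.30, t_o = 18,
                                      tau_s = 25, t_z = 25),
                        gxeSd = c(t_e = 2, tau_v = 5, t_M = 6,
                                  glai_max = 0.10, t_o = 8,
                                  tau_s = 10, t_z = 10),
                        flightTimes = round(seq(150, 1800, length.out = 10)),
                        obsNoiseSd = 0.20,
                        blockSd = 0.10,
                        spatialSd = 0.15,
                        spatialRho = c(row = 0.4, col = 0.4),
                        wdGlaiMult = 0.8,
                        wdSenescenceShift = -60,
                        gyAucWeights = c(w1 = 0.012, w2 = 0.012),
                        gyEnvMean = NULL,
                        gyGxeSd = 2.0,
                        gyNoiseSd = 3.0,
                        ffPerDv = 0.6) {
  structure(list(
    base = glaiCurveParams(), qtls = qtls,
    geneticSd = geneticSd, gxeSd = gxeSd,
    flightTimes = flightTimes, obsNoiseSd = obsNoiseSd,
    blockSd = blockSd, spatialSd = spatialSd, spatialRho = spatialRho,
    wdGlaiMult = wdGlaiMult, wdSenescenceShift = wdSenescenceShift,
    gyAucWeights = gyAucWeights, gyEnvMean = gyEnvMean,
    gyGxeSd = gyGxeSd, gyNoiseSd = gyNoiseSd, ffPerDv = ffPerDv),
    class = "glaiTruthConfig")
}

## per-environment baseline curve parameters under the stress model
envBaseline <- function(cfg, envRow) {
  p <- cfg$base
  if (identical(envRow$treatment, "WD")) {
    p[["glai_max"]] <- p[["glai_max"]] * cfg$wdGlaiMult
    sh <- cfg$wdSenescenceShift
    p[["t_o"]] <- p[["t_o"]] + sh
    p[["tau_s"]] <- p[["tau_s"]] + sh
    p[["t_z"]] <- p[["t_z"]] + sh
  }
  p
}

## keep a perturbed parameter vector geometrically valid
orderParams <- function(p) {
  eps <- 5
  p[["t_e"]] <- max(p[["t_e"]], 1)
  p[["tau_v"]] <- max(p[["tau_v"]], p[["t_e"]] + eps)
  p[["t_M"]] <- max(p[["t_M"]], p[["tau_v"]] + eps)
  p[["t_o"]] <- max(p[["t_o"]], p[["t_M"]] + eps)
  p[["tau_s"]] <- max(p[["tau_s"]], p[["t_o"]] + eps)
  p[["t_z"]] <- max(p[["t_z"]], p[["tau_s"]] + eps)
  p[["glai_max"]] <- max(p[["glai_max"]], 0.2)
  p
}

#' Simulate plot-level GLAI observations and agronomic traits
#'
#' For every genotype x environment a true curve is built from the
#' environment baseline perturbed by genotype main effects, G x E deviations
#' and planted QTL effects (B73-allele indicator coding). Each plot observes
#' its genotype's true curve at the flight times plus a block effect, a
#' spatially AR1 x AR1 correlated plot deviation, and independent noise.
#' Grain yield is environment mean + weighted true areas under the curve
#' during grain filling and senescence + direct QTL effects + G x E + plot
#' noise; female flowering follows the true vegetative duration; kernel
#' number, kernel weight and anthesis-silking interval are correlated
#' derivatives.
#'
#' @param panel a [MagicPanel-class].
#' @param design from [makeTrialDesign()].
#' @param truth a [truthConfig()].
#' @param seed integer seed.
#' @return list with `glaiObs` (long `plot_id`, `gdd6`, `glai`), `agronomic`
#'   (plot-level GY, KN, TKW, FF, ASI), and `truth` (planted QTLs, true
#'   curve parameters, analytic true traits per genotype x environment, and
#'   the variance components used).
#' @export
simulateTrialPhenotypes <- function(panel, design, truth = truthConfig(),
                                    seed = 1L) {
  stopifnot(inherits(truth, "glaiTruthConfig"))
  set.seed(childSeed(seed, "trial-phenotypes"))
  lines <- colnames(panel)
  envs <- design$environments
  plots <- design$plots
  stopifnot(all(plots$genotype %in% lines))
  parNames <- names(truth$geneticSd)

  qtls <- truth$qtls
  if (!is.null(qtls) && nrow(qtls)) {
    missing <- setdiff(qtls$marker, rownames(panel))
    if (length(missing))
      stop("planted QTL marker(s) not retained in the panel (MAF filter?): ",
           paste(missing, collapse = ", "))
    if (is.null(qtls$environment)) qtls$environment <- NA_character_
  }
  bMat <- b73Dosage(panel)  # lines x markers 0/1

  ## genotype main effects and G x E deviations on curve parameters
  genEff <- sapply(parNames, function(p)
    stats::rnorm(length(lines), 0, truth$geneticSd[[p]]))
  rownames(genEff) <- lines
  gxe <- array(stats::rnorm(length(lines) * nrow(envs) * length(parNames)),
               dim = c(length(lines), nrow(envs), length(parNames)),
               dimnames = list(lines, envs$name, parNames))
  for (p in seq_along(parNames))
    gxe[, , p] <- gxe[, , p] * truth$gxeSd[[parNames[p]]]

  ## true parameters and analytic traits per genotype x environment
  paramList <- list(); trueTraitList <- list()
  for (e in seq_len(nrow(envs))) {
    base <- envBaseline(truth, envs[e, ])
    for (i in seq_along(lines)) {
      p <- base
      p[parNames] <- p[parNames] + genEff[i, parNames] +
        gxe[i, e, parNames]
      if (!is.null(qtls) && nrow(qtls)) {
        for (q in seq_len(nrow(qtls))) {
          if (!is.na(qtls$environment[q]) &&
              qtls$environment[q] != envs$name[e]) next
          if (qtls$param[q] %in% parNames)
            p[[qtls$param[q]]] <- p[[qtls$param[q]]] +
              bMat[i, qtls$marker[q]] * qtls$effect[q]
        }
      }
      p <- orderParams(p)
      key <- paste(lines[i], envs$name[e], sep = ".")
      paramList[[key]] <- p
      trueTraitList[[key]] <- trueGlaiTraits(p)
    }
  }
  trueTraits <- do.call(rbind, trueTraitList)
  info <- do.call(rbind, strsplit(rownames(trueTraits), ".", fixed = TRUE))
  trueTraits <- data.frame(genotype = info[, 1], environment = info[, 2],
                           trueTraits, row.names = NULL,
                           stringsAsFactors = FALSE)

  ## plot-level deviations: block + AR1xAR1 spatial + obs noise
  plots$dev <- 0
  for (e in envs$name) {
    sel <- plots$environment == e
    nb <- max(plots$block[sel])
    blockEff <- stats::rnorm(nb, 0, truth$blockSd)
    nr <- max(plots$row[sel]); nc <- max(plots$col[sel])
    Lr <- chol(ar1Matrix(nr, truth$spatialRho[["row"]]))
    Lc <- chol(ar1Matrix(nc, truth$spatialRho[["col"]]))
    field <- truth$spatialSd *
      (t(Lr) %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% Lc)
    plots$dev[sel] <- blockEff[plots$block[sel]] +
      field[cbind(plots$row[sel], plots$col[sel])]
  }

  ## GLAI observations at flight times
  ft <- truth$flightTimes
  key <- paste(plots$genotype, plots$environment, sep = ".")
  glaiObs <- do.call(rbind, lapply(seq_len(nrow(plots)), function(j) {
    tv <- glaiCurve(paramList[[key[j]]], ft)
    data.frame(plot_id = plots$plot_id[j], gdd6 = ft,
               glai = pmax(tv + plots$dev[j] +
                             stats::rnorm(length(ft), 0, truth$obsNoiseSd),
                           0),
               stringsAsFactors = FALSE)
  }))

  ## agronomic traits (plot level)
  gyMean <- truth$gyEnvMean
  if (is.null(gyMean)) {
    gyMean <- stats::setNames(
      ifelse(envs$treatment == "WD", 62, 85), envs$name)
  }
  tt <- trueTraits[match(key, paste(trueTraits$genotype,
                                    trueTraits$environment, sep = ".")), ]
  w <- truth$gyAucWeights
  gyGxe <- matrix(stats::rnorm(length(lines) * nrow(envs), 0, truth$gyGxeSd),
                  length(lines), dimnames = list(lines, envs$name))
  gy <- gyMean[plots$environment] +
    w[["w1"]] * (tt$AUC_F - mean(tt$AUC_F)) +
    w[["w2"]] * (tt$AUC_S - mean(tt$AUC_S)) +
    gyGxe[cbind(plots$genotype, plots$environment)] +
    plots$dev * 2 + stats::rnorm(nrow(plots), 0, truth$gyNoiseSd)
  if (!is.null(qtls) && nrow(qtls)) {
    for (q in which(qtls$param == "GY")) {
      sel <- if (is.na(qtls$environment[q])) rep(TRUE, nrow(plots))
             else plots$environment == qtls$environment[q]
      gy[sel] <- gy[sel] +
        bMat[cbind(plots$genotype[sel],
                   rep(qtls$marker[q], sum(sel)))] * qtls$effect[q]
    }
  }
  ff <- 850 + truth$ffPerDv * (tt$D_V - mean(tt$D_V)) +
    stats::rnorm(nrow(plots), 0, 8)
  if (!is.null(qtls) && nrow(qtls)) {
    for (q in which(qtls$param == "FF")) {
      sel <- if (is.na(qtls$environment[q])) rep(TRUE, nrow(plots))
             else plots$environment == qtls$environment[q]
      ff[sel] <- ff[sel] +
        bMat[cbind(plots$genotype[sel],
                   rep(qtls$marker[q], sum(sel)))] * qtls$effect[q]
    }
  }
  agronomic <- data.frame(
    plots[, c("plot_id", "environment", "genotype", "block", "row", "col")],
    GY = gy,
    KN = 2800 + 25 * (gy - mean(gy)) + stats::rnorm(nrow(plots), 0, 120),
    TKW = 300 + 0.9 * (gy - mean(gy)) + stats::rnorm(nrow(plots), 0, 12),
    FF = ff,
    ASI = 25 + 0.05 * (ff - mean(ff)) + stats::rnorm(nrow(plots), 0, 6),
    stringsAsFactors = FALSE)

  trueParams <- data.frame(
    genotype = info[, 1], environment = info[, 2],
    do.call(rbind, paramList), row.names = NULL, stringsAsFactors = FALSE)

  list(glaiObs = glaiObs, agronomic = agronomic,
       truth = list(qtls = qtls, trueParams = trueParams,
                    trueTraits = trueTraits,
                    varComponents = list(
                      geneticSd = truth$geneticSd, gxeSd = truth$gxeSd,
                      obsNoiseSd = truth$obsNoiseSd,
                      blockSd = truth$blockSd,
                      spatialSd = truth$spatialSd,
                      spatialRho = truth$spatialRho,
                      gyGxeSd = truth$gyGxeSd,
                      gyNoiseSd = truth$gyNoiseSd),
                    seed = seed))
}

#' Simulate a multi-environment drought yield network
#'
#' Generates genotype-level grain-yield adjusted means across `nEnv`
#' water-deficit environments in which a planted set of (GLAI) QTL markers
#' carries direct yield effects. Effect sizes are calibrated so that the
#' planted QTL set explains a target fraction `targetR2` of the
#' environment-centred phenotypic variance; environments differ in mean,
#' effect scaling and noise (heterogeneous stress), and a subset of markers
#' can flip effect sign across environments.
#'
#' @param panel a [MagicPanel-class].
#' @param qtlMarkers marker names carrying yield effects.
#' @param nEnv number of network environments (default 11).
#' @param targetR2 planted network-level QTL r2 (default 0.18).
#' @param relEffects relative effect sizes per marker (recycled).
#' @param signFlip logical per marker: effect sign flips in half of the
#'   environments (default none).
#' @param polygenicFrac fraction of the non-QTL variance that is a genotype
#'   main effect rather than environment-specific noise.
#' @param envMeanRange range of environment yield means (q/ha).
#' @param seed integer seed.
#' @return list with `gyMeans` (`genotype`, `environment`, `value`) and
#'   `truth` (effect matrix, variance components, expected r2).
#' @export
simulateGyNetwork <- function(panel, qtlMarkers, nEnv = 11,
                              targetR2 = 0.18, relEffects = 1,
                              signFlip = FALSE, polygenicFrac = 0.5,
                              envMeanRange = c(53, 89), seed = 1L) {
  stopifnot(all(qtlMarkers %in% rownames(panel)),
            targetR2 >= 0, targetR2 < 1)
  set.seed(childSeed(seed, "gy-network"))
  lines <- colnames(panel)
  n <- length(lines); q <- length(qtlMarkers)
  envNames <- sprintf("WD%02d", seq_len(nEnv))
  B <- b73Dosage(panel)[, qtlMarkers, drop = FALSE]
  relEffects <- rep_len(relEffects, q)
  signFlip <- rep_len(signFlip, q)
  ## per-environment effect scaling (heterogeneous stress) and sign pattern
  envScale <- stats::rnorm(nEnv, 1, 0.25)
  beta <- outer(relEffects, envScale)  # q x nEnv
  if (any(signFlip)) {
    flipEnv <- seq_len(nEnv) > nEnv / 2
    beta[signFlip, flipEnv] <- -beta[signFlip, flipEnv]
  }
  if (targetR2 == 0) beta[] <- 0
  signal <- B %*% beta  # n x nEnv
  sigCentered <- scale(signal, center = TRUE, scale = FALSE)
  varSig <- mean(sigCentered^2)
  if (targetR2 > 0 && varSig > 0) {
    varNoise <- varSig * (1 - targetR2) / targetR2
  } else {
    varNoise <- 1
    if (targetR2 > 0) warning("planted signal variance is zero")
  }
  sdG <- sqrt(varNoise * polygenicFrac)
  sdE <- sqrt(varNoise * (1 - polygenicFrac))
  gEff <- stats::rnorm(n, 0, sdG)
  envMean <- stats::runif(nEnv, envMeanRange[1], envMeanRange[2])
  y <- sweep(signal, 2, envMean, "+") + gEff +
    matrix(stats::rnorm(n * nEnv, 0, sdE), n)
  gyMeans <- data.frame(
    genotype = rep(lines, nEnv),
    environment = rep(envNames, each = n),
    value = as.vector(y), stringsAsFactors = FALSE)
  list(gyMeans = gyMeans,
       truth = list(markers = qtlMarkers,
                    beta = matrix(beta, q, nEnv,
                                  dimnames = list(qtlMarkers, envNames)),
                    sdG = sdG, sdE = sdE, envMean = envMean,
                    expectedR2 = varSig / (varSig + varNoise)))
}
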