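#' Pipeline configuration
#'
#' Assembles (and validates) every stage parameter of the end-to-end
#' driver. Unknown keys are rejected. The default multivariate trait list
#' holds the six retained GLAI traits (`D_V`, `D_S`, `GLAI_M`, `AUC_V`,
#' `AUC_F`, `AUC_S`) plus grain yield and female flowering, giving the
#' joint test its default 8 degrees of freedom.
#'
#' @param ... overrides of the default keys (see the function body or the
#'   methods vignette for the full list).
#' @return list of class `glaiPipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    seed = 1L,
    nLines = 324L, nChrom = 10L, markersPerChrom = 60L,
    chromLengthBp = 2e8, recombRate = 6, mafThreshold = 0.035,
    nBlocks = 2L,
    environments = referenceEnvironments(),
    truthQtls = data.frame(param = c("glai_max", "tau_s", "GY"),
                           effect = c(0.3, 40, 3),
                           stringsAsFactors = FALSE),
    obsNoiseSd = 0.20,
    uvTraits = c("D_V", "D_S", "GLAI_M", "AUC_V", "AUC_F", "AUC_S",
                 "GY", "FF"),
    mvTraits = c("D_V", "D_S", "GLAI_M", "AUC_V", "AUC_F", "AUC_S",
                 "GY", "FF"),
    rhoGrid = seq(0, 0.9, by = 0.1),
    qvalueAlpha = 0.05,
    r2Threshold = 0.6, maxSpanFrac = 0.30,
    clusterMethod = "peak", ldWindow = 1e6,
    qtlAlpha = 0.01,
    gyAlpha = 0.05, gyNetworkEnvs = 11L, gyTargetR2 = 0.18)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (k in names(over)) cfg[[k]] <- over[[k]]
  stopifnot(cfg$mafThreshold >= 0, cfg$mafThreshold < 0.5,
            cfg$r2Threshold > 0, cfg$r2Threshold <= 1,
            cfg$maxSpanFrac > 0, cfg$maxSpanFrac <= 1,
            cfg$qtlAlpha > 0, cfg$qtlAlpha < 1,
            cfg$gyAlpha > 0, cfg$gyAlpha < 1,
            cfg$gyTargetR2 >= 0, cfg$gyTargetR2 < 1)
  class(cfg) <- "glaiPipelineConfig"
  cfg
}

#' A small configuration for smoke runs
#'
#' 120 lines, 3 chromosomes, 200 markers per chromosome, 2 environments
#' and a coarse spatial-correlation grid: completes end to end in well
#' under a minute while exercising every stage.
#'
#' @param ... further overrides passed to [pipelineConfig()].
#' @return a `glaiPipelineConfig`.
#' @export
smallPipelineConfig <- function(...) {
  pipelineConfig(
    nLines = 120L, nChrom = 3L, markersPerChrom = 200L,
    environments = referenceEnvironments()[c(2, 3), ],
    rhoGrid = c(0, 0.4), gyNetworkEnvs = 5L,
    uvTraits = c("GLAI_M", "AUC_S", "GY"),
    mvTraits = c("D_V", "GLAI_M", "AUC_V", "AUC_S", "GY", "FF"),
    ...)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipelineConfig()] (data.frame keys
#'   like `environments` may be given as lists of columns).
#' @return a `glaiPipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  for (k in c("environments", "truthQtls"))
    if (!is.null(raw[[k]]))
      raw[[k]] <- as.data.frame(raw[[k]], stringsAsFactors = FALSE)
  do.call(pipelineConfig, raw)
}

## deterministically pick planted QTL markers: common markers spread evenly
## across the genome
pickQtlMarkers <- function(panel, n, minMaf = 0.2) {
  if (n == 0L) return(character())
  map <- markerMap(panel)
  maf <- markerMaf(panel)
  common <- which(maf >= minMaf)
  if (length(common) < n) common <- order(maf, decreasing = TRUE)[seq_len(n)]
  picks <- common[unique(round(seq(1, length(common), length.out = n)))]
  map$marker[picks]
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> trait extraction -> spatial adjustment ->
#' variance decomposition / PCA -> univariate and multivariate GWAS ->
#' q-values -> LD clustering -> backward QTL selection -> interval
#' extension -> colocalization -> yield-network prediction, writing every
#' stage artifact plus a manifest into `outDir`. A rerun with an identical
#' configuration is bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  stopifnot(inherits(config, "glaiPipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## 1. genotypes ----------------------------------------------------------
  panel <- stage("genotypes", simulateMagicGenotypes(
    nLines = config$nLines, nChrom = config$nChrom,
    markersPerChrom = config$markersPerChrom,
    chromLengthBp = config$chromLengthBp, recombRate = config$recombRate,
    mafThreshold = config$mafThreshold, seed = config$seed))
  genoFiles <- writeGenotypes(panel, outDir)

  ## 2. design + phenotypes ------------------------------------------------
  design <- stage("design", makeTrialDesign(
    panel, environments = config$environments, nBlocks = config$nBlocks,
    seed = config$seed))
  writeTable(design$plots, file.path(outDir, "design.csv"))

  qtls <- NULL
  if (nrow(config$truthQtls)) {
    qtls <- config$truthQtls
    qtls$marker <- pickQtlMarkers(panel, nrow(qtls))
  }
  sim <- stage("phenotypes", simulateTrialPhenotypes(
    panel, design, truth = truthConfig(qtls = qtls,
                                       obsNoiseSd = config$obsNoiseSd),
    seed = config$seed))
  writeTable(sim$glaiObs, file.path(outDir, "glai_observations.csv"))
  writeTable(sim$agronomic, file.path(outDir, "agronomic.csv"))
  jsonlite::write_json(
    list(qtls = sim$truth$qtls, varComponents = sim$truth$varComponents),
    file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  ## 3. trait extraction ---------------------------------------------------
  traits <- stage("extract-traits", extractTraitsTable(sim$glaiObs))
  plotTraits <- merge(sim$agronomic, traits, by = "plot_id")
  writeTable(plotTraits, file.path(outDir, "plot_traits.csv"))

  ## 4. adjusted means -----------------------------------------------------
  envNames <- config$environments$name
  adjTraits <- union(config$uvTraits, config$mvTraits)
  means <- stage("adjust", do.call(rbind, lapply(adjTraits, function(tr) {
    do.call(rbind, lapply(envNames, function(e) {
      am <- adjustedMeans(plotTraits, tr, e, rhoGrid = config$rhoGrid)
      data.frame(trait = tr, environment = e, genotype = am$genotype,
                 value = am$value, stringsAsFactors = FALSE)
    }))
  })))
  writeTable(means, file.path(outDir, "adjusted_means.csv"))

  ## 5. variance decomposition + PCA --------------------------------------
  varcomp <- NULL
  if (length(envNames) >= 2L)
    varcomp <- stage("varcomp", do.call(rbind, lapply(adjTraits,
      function(tr) {
        vc <- varianceDecomposition(plotTraits, tr)
        data.frame(trait = tr, sigma2_g = vc$sigma2_g,
                   sigma2_ge = vc$sigma2_ge, sigma2_e = vc$sigma2_e,
                   cv_g = vc$cv_g, ge_over_g = vc$geOverG,
                   p_g = vc$rlrt$p[1], p_ge = vc$rlrt$p[2])
      })))
  if (!is.null(varcomp))
    writeTable(varcomp, file.path(outDir, "variance_components.csv"))

  wide <- stats::reshape(means, idvar = c("genotype", "environment"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  pca <- stage("pca", traitPcaCorrelations(wide, adjTraits))
  writeTable(data.frame(axis = seq_along(pca$pca$explained),
                        explained = pca$pca$explained),
             file.path(outDir, "pca_explained.csv"))
  writeTable(pca$correlations, file.path(outDir, "trait_correlations.csv"))

  ## 6. GWAS ---------------------------------------------------------------
  kin <- stage("kinship", kinshipSet(panel))
  meansOf <- function(tr, e) {
    m <- means[means$trait == tr & means$environment == e, ]
    stats::setNames(m$value, m$genotype)
  }
  uv <- stage("gwas-uv", do.call(rbind, lapply(config$uvTraits,
    function(tr) do.call(rbind, lapply(envNames, function(e) {
      rows <- gwasUnivariate(meansOf(tr, e), panel, kin, trait = tr,
                             environment = e)
      q <- storeyQvalues(rows$p)
      rows$q <- as.numeric(q)
      rows$significant <- rows$q <= config$qvalueAlpha
      rows
    })))))
  writeTable(uv, file.path(outDir, "gwas_uv.tsv"))

  mvAll <- stage("gwas-mv", lapply(envNames, function(e) {
    Y <- sapply(config$mvTraits, function(tr) meansOf(tr, e))
    rownames(Y) <- colnames(panel)
    res <- gwasMultivariate(Y, panel, kin, environment = e)
    rows <- res$associations
    q <- storeyQvalues(rows$p)
    rows$q <- as.numeric(q)
    rows$significant <- rows$q <= config$qvalueAlpha
    rows <- assignMvTraits(rows, config$mvTraits)
    list(rows = rows, nullFit = res$nullFit)
  }))
  names(mvAll) <- envNames
  mv <- do.call(rbind, lapply(mvAll, `[[`, "rows"))
  writeTable(mv[, setdiff(names(mv), "assigned")],
             file.path(outDir, "gwas_mv.tsv"))

  ## 7. clustering + QTL selection per trait -------------------------------
  map <- markerMap(panel)
  clusters <- list(); qtlRows <- list(); effectRows <- list()
  r2Report <- list()
  for (tr in config$uvTraits) {
    candList <- list()
    for (e in envNames) {
      uvSig <- uv[uv$trait == tr & uv$environment == e & uv$significant, ]
      mvRows <- mvAll[[e]]$rows
      mvSig <- mvRows[mvRows$significant &
                        vapply(mvRows$assigned, function(a) tr %in% a,
                               TRUE), ]
      hitMarkers <- union(uvSig$marker, mvSig$marker)
      if (!length(hitMarkers)) next
      pBest <- pmin(
        uvSig$p[match(hitMarkers, uvSig$marker)],
        mvSig$p[match(hitMarkers, mvSig$marker)], na.rm = TRUE)
      hits <- data.frame(trait = tr, environment = e,
                         marker = hitMarkers,
                         chrom = map$chrom[match(hitMarkers, map$marker)],
                         pos_bp = map$pos_bp[match(hitMarkers,
                                                   map$marker)],
                         p = pBest, stringsAsFactors = FALSE)
      cl <- clusterSnps(hits, panel, r2Threshold = config$r2Threshold,
                        maxSpanFrac = config$maxSpanFrac,
                        method = config$clusterMethod, source = "M_ALL")
      clusters[[paste(tr, e)]] <- cl
      candList[[e]] <- cl[!cl$discarded, , drop = FALSE]
    }
    cand <- do.call(rbind, candList)
    if (is.null(cand) || !nrow(cand)) next
    cand <- cand[!duplicated(cand$peak), , drop = FALSE]
    trMeans <- means[means$trait == tr, c("genotype", "environment",
                                          "value")]
    sel <- stage("select-qtl", backwardSelectQtls(
      data.frame(id = cand$cluster_id, marker = cand$peak,
                 stringsAsFactors = FALSE),
      trMeans, panel, alpha = config$qtlAlpha))
    if (!length(sel$selected)) next
    kept <- cand[match(sel$selected, cand$cluster_id), , drop = FALSE]
    ext <- t(vapply(seq_len(nrow(kept)), function(i)
      extendInterval(kept[i, , drop = FALSE], panel,
                     r2Threshold = config$r2Threshold,
                     window = config$ldWindow), numeric(2)))
    qtlRows[[tr]] <- data.frame(
      qtl_id = kept$cluster_id, trait = tr, chrom = kept$chrom,
      start = kept$start, end = kept$end,
      ext_start = ext[, 1], ext_end = ext[, 2],
      peak = kept$peak, peak_p = kept$peak_p,
      joint_p = sel$joint$p[match(kept$cluster_id, sel$joint$id)],
      stringsAsFactors = FALSE)
    effectRows[[tr]] <- cbind(trait = tr, sel$effects)
    r2Report[[tr]] <- list(
      network = varianceExplained(kept$peak, trMeans, panel,
                                  scope = "network")$r2,
      perEnvironment = varianceExplained(kept$peak, trMeans, panel,
                                         scope = "per-environment"))
  }
  clustersTab <- if (length(clusters)) do.call(rbind, clusters)
                 else emptyClusterTable()
  writeTable(clustersTab, file.path(outDir, "clusters.tsv"))
  qtlTab <- if (length(qtlRows)) do.call(rbind, qtlRows) else NULL
  effTab <- if (length(effectRows)) do.call(rbind, effectRows) else NULL
  if (!is.null(qtlTab)) {
    rownames(qtlTab) <- NULL
    writeTable(qtlTab, file.path(outDir, "qtls.tsv"))
    writeTable(effTab, file.path(outDir, "qtl_effects.tsv"))
  }
  jsonlite::write_json(r2Report, file.path(outDir, "variance_explained.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## 8. colocalization -----------------------------------------------------
  coloc <- if (!is.null(qtlTab)) colocalizeQtls(qtlTab, effTab)
           else emptyColocTable()
  writeTable(coloc, file.path(outDir, "colocalizations.tsv"))

  ## 9. grain-yield drought network ----------------------------------------
  glaiQtls <- if (!is.null(qtlTab))
    qtlTab[qtlTab$trait != "GY", , drop = FALSE] else NULL
  netMarkers <- if (!is.null(sim$truth$qtls)) sim$truth$qtls$marker
                else pickQtlMarkers(panel, 3)
  gyNet <- stage("gy-network", simulateGyNetwork(
    panel, netMarkers, nEnv = config$gyNetworkEnvs,
    targetR2 = config$gyTargetR2, seed = config$seed))
  writeTable(gyNet$gyMeans, file.path(outDir, "gy_network_means.csv"))
  gyPred <- if (!is.null(glaiQtls) && nrow(glaiQtls))
    stage("predict-gy", predictGyFromGlaiQtls(glaiQtls, gyNet$gyMeans,
                                              panel,
                                              alpha = config$gyAlpha))
    else NULL
  if (!is.null(gyPred))
    jsonlite::write_json(
      list(selected = gyPred$selected, networkR2 = gyPred$networkR2,
           perEnvR2 = gyPred$perEnvR2, perEnvCounts = gyPred$perEnvCounts),
      file.path(outDir, "gy_prediction.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)

  ## manifest --------------------------------------------------------------
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "glaiQTL",
    version = as.character(utils::packageVersion("glaiQTL")),
    config = unclass(config),
    files = data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(outDir, files)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(panel = panel, design = design, sim = sim,
                 plotTraits = plotTraits, means = means,
                 varcomp = varcomp, pca = pca, uv = uv, mv = mvAll,
                 clusters = clustersTab, qtls = qtlTab, effects = effTab,
                 coloc = coloc, gyNetwork = gyNet, gyPrediction = gyPred,
                 manifest = manifest))
}
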