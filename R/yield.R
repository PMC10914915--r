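#' Merge GLAI QTLs into unique genomic regions
#'
#' Connected components of the interval-overlap graph over the extended
#' QTL intervals (per chromosome); each region is represented by the peak
#' marker with the overall smallest peak p among its member QTLs.
#'
#' @param qtls data.frame with `qtl_id`, `chrom`, `ext_start`, `ext_end`,
#'   `peak`, `peak_p`.
#' @return data.frame `id`, `marker`, `chrom`, `start`, `end`,
#'   `n_qtls`, `member_qtls` (list).
#' @export
uniqueQtlRegions <- function(qtls) {
  stopifnot(nrow(qtls) >= 1)
  out <- list()
  for (c in unique(qtls$chrom)) {
    q <- qtls[qtls$chrom == c, ]
    q <- q[order(q$ext_start, q$ext_end), ]
    comp <- integer(nrow(q)); g <- 0L; curEnd <- -Inf
    for (i in seq_len(nrow(q))) {
      if (q$ext_start[i] < curEnd) {
        comp[i] <- g
        curEnd <- max(curEnd, q$ext_end[i])
      } else {
        g <- g + 1L
        comp[i] <- g
        curEnd <- q$ext_end[i]
      }
    }
    for (k in unique(comp)) {
      m <- q[comp == k, ]
      best <- which.min(m$peak_p)
      out[[length(out) + 1L]] <- data.frame(
        id = sprintf("region_%s_%d", c, k), marker = m$peak[best],
        chrom = c, start = min(m$ext_start), end = max(m$ext_end),
        n_qtls = nrow(m), stringsAsFactors = FALSE)
      out[[length(out)]]$member_qtls <- I(list(m$qtl_id))
    }
  }
  do.call(rbind, out)
}

#' Grain-yield variance explained by GLAI QTLs across a drought network
#'
#' Reduces the GLAI QTLs to unique genomic regions, then runs the
#' multi-environment backward elimination on grain-yield adjusted means
#' over the network at the less conservative `alpha = 0.05`, and reports
#' the proportion of (environment-centred) yield variance the selected
#' QTLs explain at the network scale and per environment, together with
#' per-environment signed B73-allele effects and counts of significant
#' QTLs (a-posteriori Wald at `alpha`).
#'
#' @param qtls GLAI QTL table (`qtl_id`, `chrom`, `ext_start`, `ext_end`,
#'   `peak`, `peak_p`), or NULL with `regions` supplied directly.
#' @param gyMeans data.frame `genotype`, `environment`, `value` of yield
#'   adjusted means over the network environments.
#' @param panel a [MagicPanel-class].
#' @param alpha selection and per-environment test level (default 0.05).
#' @param regions optional precomputed [uniqueQtlRegions()] table.
#' @return list of class `gyNetworkResult`: `selected`, `networkR2`,
#'   `perEnvR2`, `perEnvCounts` (significant QTLs per environment),
#'   `effects`, `selection` (the full [backwardSelectQtls()] object),
#'   `regions`.
#' @export
predictGyFromGlaiQtls <- function(qtls, gyMeans, panel, alpha = 0.05,
                                  regions = NULL) {
  if (is.null(regions)) {
    if (is.null(qtls) || !nrow(qtls))
      return(structure(list(selected = character(), networkR2 = 0,
                            perEnvR2 = NULL, perEnvCounts = NULL,
                            effects = NULL, selection = NULL,
                            regions = NULL),
                       class = "gyNetworkResult"))
    regions <- uniqueQtlRegions(qtls)
  }
  sel <- backwardSelectQtls(regions[, c("id", "marker")], gyMeans, panel,
                            alpha = alpha, effectAlpha = alpha)
  if (!length(sel$selected))
    return(structure(list(selected = character(), networkR2 = 0,
                          perEnvR2 = NULL, perEnvCounts = NULL,
                          effects = sel$effects, selection = sel,
                          regions = regions),
                     class = "gyNetworkResult"))
  selMarkers <- sel$joint$marker
  net <- varianceExplained(selMarkers, gyMeans, panel, scope = "network")
  perEnv <- varianceExplained(selMarkers, gyMeans, panel,
                              scope = "per-environment")
  counts <- stats::aggregate(significant ~ environment, data = sel$effects,
                             FUN = function(x) sum(x, na.rm = TRUE))
  names(counts)[2] <- "n_significant"
  structure(list(selected = sel$selected, networkR2 = net$r2,
                 partialR2 = net$partial, perEnvR2 = perEnv,
                 perEnvCounts = counts, effects = sel$effects,
                 selection = sel, regions = regions),
            class = "gyNetworkResult")
}

#' @export
print.gyNetworkResult <- function(x, ...) {
  cat(sprintf(
    "GLAI QTLs vs grain yield: %d region(s) selected, network r2 = %.3f\n",
    length(x$selected), x$networkR2))
  if (!is.null(x$perEnvR2)) {
    cat("per-environment r2:\n")
    print(x$perEnvR2)
  }
  invisible(x)
}
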