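#' Pairwise linkage disequilibrium (r2) between markers
#'
#' Squared Pearson correlation of allele dosages, the natural LD measure
#' for fully homozygous lines.
#'
#' @param panel a [MagicPanel-class].
#' @param markers1,markers2 marker name vectors.
#' @return matrix of r2 values, `markers1` x `markers2`.
#' @export
ldR2 <- function(panel, markers1, markers2 = markers1) {
  d <- dosage(panel)
  suppressWarnings(
    stats::cor(d[, markers1, drop = FALSE],
               d[, markers2, drop = FALSE])^2)
}

#' Cluster significant SNPs by linkage disequilibrium
#'
#' Within each chromosome of one trait-environment combination, repeatedly
#' seeds a cluster at the most significant unassigned SNP and assigns to it
#' every unassigned significant SNP with `r2 >=` the LD threshold against
#' the seed; clusters whose physical intervals overlap are then aggregated.
#' Clusters spanning more than `maxSpanFrac` of their chromosome are
#' discarded as artifacts. Each cluster is described by its peak SNP
#' (smallest p, ties to the smaller position) and the half-open interval
#' covering its members. A single-linkage chaining variant is available via
#' `method = "chain"`.
#'
#' @param hits data.frame of significant markers for one trait-environment:
#'   columns `marker`, `chrom`, `pos_bp`, `p` (plus `trait`,
#'   `environment` if available).
#' @param panel a [MagicPanel-class].
#' @param r2Threshold LD threshold (default 0.6).
#' @param maxSpanFrac span filter as a fraction of chromosome length
#'   (default 0.30).
#' @param method `"peak"` (greedy peak-seeded, default) or `"chain"`
#'   (single-linkage components of the LD graph).
#' @param source label (`"M_UV"`, `"M_MV"`, `"M_ALL"`).
#' @return data.frame, one row per cluster: `cluster_id`, `trait`,
#'   `environment`, `source`, `chrom`, `start`, `end` (half-open bp),
#'   `peak`, `peak_p`, `n_snps`, `members` (list), `discarded`, `reason`.
#' @export
clusterSnps <- function(hits, panel, r2Threshold = 0.6,
                        maxSpanFrac = 0.30,
                        method = c("peak", "chain"), source = "M_UV") {
  method <- match.arg(method)
  if (is.null(hits) || !nrow(hits)) return(emptyClusterTable())
  stopifnot(all(c("marker", "chrom", "pos_bp", "p") %in% names(hits)))
  chromLen <- metadata(panel)$chromLengthBp
  trait <- if ("trait" %in% names(hits)) hits$trait[1] else NA_character_
  env <- if ("environment" %in% names(hits)) hits$environment[1]
         else NA_character_
  out <- list()
  for (c in unique(hits$chrom)) {
    h <- hits[hits$chrom == c, ]
    h <- h[order(h$p, h$pos_bp), ]
    r2 <- ldR2(panel, h$marker)
    groups <- integer(nrow(h))
    if (method == "peak") {
      g <- 0L
      while (any(groups == 0L)) {
        g <- g + 1L
        seed <- which(groups == 0L)[1L]  # most significant unassigned
        take <- groups == 0L & r2[seed, ] >= r2Threshold
        take[seed] <- TRUE
        groups[take] <- g
      }
    } else {
      adj <- r2 >= r2Threshold
      g <- 0L
      for (i in seq_len(nrow(h))) {
        if (groups[i] > 0L) next
        g <- g + 1L
        frontier <- i
        groups[i] <- g
        while (length(frontier)) {
          nxt <- which(groups == 0L &
                         colSums(adj[frontier, , drop = FALSE]) > 0)
          groups[nxt] <- g
          frontier <- nxt
        }
      }
    }
    cl <- lapply(split(seq_len(nrow(h)), groups), function(ix) {
      list(start = min(h$pos_bp[ix]), end = max(h$pos_bp[ix]) + 1L,
           members = h$marker[ix], p = h$p[ix], pos = h$pos_bp[ix])
    })
    ## aggregate overlapping clusters until stable
    repeat {
      merged <- FALSE
      if (length(cl) > 1L) {
        for (i in seq_len(length(cl) - 1L)) {
          for (j in (i + 1L):length(cl)) {
            if (intervalsOverlap(cl[[i]]$start, cl[[i]]$end,
                                 cl[[j]]$start, cl[[j]]$end)) {
              cl[[i]] <- list(
                start = min(cl[[i]]$start, cl[[j]]$start),
                end = max(cl[[i]]$end, cl[[j]]$end),
                members = c(cl[[i]]$members, cl[[j]]$members),
                p = c(cl[[i]]$p, cl[[j]]$p),
                pos = c(cl[[i]]$pos, cl[[j]]$pos))
              cl[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      if (!merged) break
    }
    len <- if (!is.null(chromLen) && c %in% names(chromLen))
      chromLen[[c]] else max(hits$pos_bp[hits$chrom == c])
    for (k in seq_along(cl)) {
      x <- cl[[k]]
      span <- max(x$pos) - min(x$pos)
      pk <- order(x$p, x$pos)[1L]
      discard <- span > maxSpanFrac * len
      out[[length(out) + 1L]] <- data.frame(
        trait = trait, environment = env, source = source, chrom = c,
        start = x$start, end = x$end, peak = x$members[pk],
        peak_p = x$p[pk], n_snps = length(x$members),
        discarded = discard,
        reason = if (discard) "span" else NA_character_,
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(x$members))
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  res$cluster_id <- sprintf("%s_%s_%s_c%02d", trait, env, res$chrom,
                            stats::ave(seq_len(nrow(res)), res$chrom,
                                       FUN = seq_along))
  rownames(res) <- NULL
  res[, c("cluster_id", "trait", "environment", "source", "chrom",
          "start", "end", "peak", "peak_p", "n_snps", "members",
          "discarded", "reason")]
}

emptyClusterTable <- function() {
  data.frame(cluster_id = character(), trait = character(),
             environment = character(), source = character(),
             chrom = character(), start = integer(), end = integer(),
             peak = character(), peak_p = numeric(), n_snps = integer(),
             members = I(list()), discarded = logical(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Extend a cluster interval by the local LD extent
#'
#' At each extremity of a (non-discarded) cluster interval, markers within
#' `window` bp outward are scanned and the interval is extended to the most
#' distant one in linkage disequilibrium (`r2 >=` threshold) with the
#' extremity member; with no qualifying marker that side is unchanged.
#'
#' @param cluster one row of [clusterSnps()] output.
#' @param panel a [MagicPanel-class].
#' @param r2Threshold LD threshold (default 0.6).
#' @param window scan window in bp (default 1 Mb).
#' @return numeric `c(start, end)` of the extended half-open interval.
#' @export
extendInterval <- function(cluster, panel, r2Threshold = 0.6,
                           window = 1e6) {
  stopifnot(nrow(cluster) == 1L, !isTRUE(cluster$discarded))
  map <- markerMap(panel)
  onChrom <- map[map$chrom == cluster$chrom, ]
  members <- cluster$members[[1L]]
  mpos <- onChrom$pos_bp[match(members, onChrom$marker)]
  leftM <- members[which.min(mpos)]
  rightM <- members[which.max(mpos)]
  start <- cluster$start; end <- cluster$end
  lo <- onChrom[onChrom$pos_bp < start &
                  onChrom$pos_bp >= start - window, , drop = FALSE]
  if (nrow(lo)) {
    r2 <- ldR2(panel, leftM, lo$marker)[1, ]
    qual <- which(r2 >= r2Threshold)
    if (length(qual)) start <- min(lo$pos_bp[qual])
  }
  hi <- onChrom[onChrom$pos_bp >= end &
                  onChrom$pos_bp <= (end - 1) + window, , drop = FALSE]
  if (nrow(hi)) {
    r2 <- ldR2(panel, rightM, hi$marker)[1, ]
    qual <- which(r2 >= r2Threshold)
    if (length(qual)) end <- max(hi$pos_bp[qual]) + 1L
  }
  c(start = start, end = end)
}
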