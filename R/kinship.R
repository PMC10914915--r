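#' Identity-by-state kinship of homozygous lines
#'
#' `K[i, j]` is the fraction of included markers at which lines `i` and `j`
#' carry identical genotypes. For fully homozygous lines each marker
#' contributes 0 or 1, the diagonal is 1, and all entries lie in `[0, 1]`.
#' Missing genotypes are excluded pairwise.
#'
#' @param panel a [MagicPanel-class].
#' @param excludeChrom chromosome (character) whose markers are left out,
#'   for leave-one-chromosome-out kinships; NULL for the global matrix.
#' @return symmetric n x n kinship matrix.
#' @export
ibsKinship <- function(panel, excludeChrom = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(rowRanges(panel)))
  keep <- if (is.null(excludeChrom)) rep(TRUE, nrow(panel))
          else chrom != excludeChrom
  if (!any(keep))
    stop("no markers left after excluding chromosome ", excludeChrom)
  d <- dosage(panel)[, keep, drop = FALSE]  # lines x markers
  if (anyNA(d)) {
    obs <- !is.na(d)
    d0 <- d; d0[!obs] <- 0
    same <- tcrossprod(d0 == 2) + tcrossprod(obs & d0 == 0)
    denom <- tcrossprod(obs * 1)
    K <- same / pmax(denom, 1)
  } else {
    K <- (tcrossprod(d == 2) + tcrossprod(d == 0)) / ncol(d)
  }
  dimnames(K) <- list(rownames(d), rownames(d))
  K
}

#' Global and leave-one-chromosome-out kinship set
#'
#' @param panel a [MagicPanel-class].
#' @return list with `global` and `loco` (one matrix per chromosome, each
#'   computed from all markers *not* on that chromosome, the construction
#'   that avoids proximal contamination in mixed-model association scans).
#' @export
kinshipSet <- function(panel) {
  chroms <- unique(as.character(GenomicRanges::seqnames(rowRanges(panel))))
  list(global = ibsKinship(panel),
       loco = stats::setNames(
         lapply(chroms, function(c) ibsKinship(panel, excludeChrom = c)),
         chroms))
}
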