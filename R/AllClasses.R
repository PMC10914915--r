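#' @importFrom methods setClass setValidity setMethod new validObject is callNextMethod
#' @import SummarizedExperiment
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' MagicPanel: genotypes of a multi-parent doubled-haploid panel
#'
#' An S4 container for a homozygous-line allele-dosage matrix with its marker
#' map and, when simulated, the founder-mosaic ground truth. It extends
#' [SummarizedExperiment::RangedSummarizedExperiment]: rows are markers
#' (a `GRanges` with `ref`, `alt`, `b73Allele` and `maf` metadata columns),
#' columns are lines, and the single assay `"dosage"` holds alternate-allele
#' dosages. Doubled haploids are fully homozygous, so every dosage is 0 or 2.
#'
#' The `b73Allele` column flags which allele (0 = ref, 1 = alt) is carried by
#' the reference founder B73; QTL and GWAS effects are reported on the
#' B73-allele scale, i.e. for the indicator "line carries the B73 allele".
#'
#' @slot founderMosaic a `data.frame` (or NULL) with columns `line`, `chrom`,
#'   `start`, `end`, `founder` giving, per line and chromosome, the ordered
#'   founder segments (half-open `[start, end)`, 1-based bp).
#'
#' @seealso [simulateMagicGenotypes()], [dosage()], [markerMap()]
#' @export
setClass("MagicPanel",
  contains = "RangedSummarizedExperiment",
  slots = c(founderMosaic = "ANY")
)

setValidity("MagicPanel", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (!all(d %in% c(0, 2)))
      msg <- c(msg, "dosages of doubled-haploid lines must all be 0 or 2")
  }
  need <- c("ref", "alt", "b73Allele")
  if (!all(need %in% colnames(S4Vectors::mcols(rowRanges(object)))))
    msg <- c(msg, "marker ranges need metadata columns ref, alt, b73Allele")
  if (length(msg)) msg else TRUE
})

#' Construct a MagicPanel
#'
#' @param dosage numeric matrix of alternate-allele dosages in \{0, 2\},
#'   markers in rows, lines in columns.
#' @param markers `GRanges` of marker positions (width-1 ranges) with
#'   metadata columns `ref`, `alt`, `b73Allele` (0/1 flag: B73 carries the
#'   alt allele).
#' @param founderMosaic optional founder-segment truth `data.frame`.
#' @return A [MagicPanel-class] object.
#' @export
MagicPanel <- function(dosage, markers, founderMosaic = NULL) {
  stopifnot(nrow(dosage) == length(markers))
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = markers)
  new("MagicPanel", se, founderMosaic = founderMosaic)
}

#' @describeIn MagicPanel-class display a compact summary
#' @param object a `MagicPanel`
#' @export
setMethod("show", "MagicPanel", function(object) {
  cat("MagicPanel:", ncol(object), "doubled-haploid lines x",
      nrow(object), "markers on",
      length(unique(as.character(seqnames(rowRanges(object))))),
      "chromosomes\n")
  m <- markerMaf(object)
  cat(sprintf("  MAF range: %.3f-%.3f\n", min(m), max(m)))
  if (!is.null(object@founderMosaic))
    cat("  founder-mosaic truth: yes (",
        length(unique(object@founderMosaic$founder)), "founders )\n")
  invisible(NULL)
})

#' Accessors for MagicPanel
#'
#' `dosage()` returns the lines x markers dosage matrix (transposed from the
#' internal markers x lines assay, which is the natural orientation for the
#' statistical code). `markerMap()` returns the marker map as a data.frame,
#' `markerMaf()` the per-marker minor allele frequencies, `founderMosaic()`
#' the founder-segment truth, and `b73Dosage()` the 0/1 B73-allele-carrier
#' indicator matrix used for effect estimation.
#'
#' @param panel a [MagicPanel-class].
#' @return see Description.
#' @export
dosage <- function(panel) {
  t(assay(panel, "dosage"))
}

#' @rdname dosage
#' @export
markerMap <- function(panel) {
  rr <- rowRanges(panel)
  data.frame(
    marker = names(rr),
    chrom = as.character(seqnames(rr)),
    pos_bp = start(rr),
    ref = mcols(rr)$ref,
    alt = mcols(rr)$alt,
    is_b73_allele = mcols(rr)$b73Allele,
    stringsAsFactors = FALSE
  )
}

#' @rdname dosage
#' @export
markerMaf <- function(panel) {
  d <- assay(panel, "dosage")
  f <- rowMeans(d) / 2
  pmin(f, 1 - f)
}

#' @rdname dosage
#' @export
founderMosaic <- function(panel) panel@founderMosaic

#' @rdname dosage
#' @export
b73Dosage <- function(panel) {
  d <- dosage(panel)  # lines x markers, alt dosage
  b73alt <- mcols(rowRanges(panel))$b73Allele
  ## carrier of B73 allele: dosage == 2 where B73 carries alt, == 0 otherwise
  ind <- sweep(d == 2, 2, b73alt == 1, "==")
  storage.mode(ind) <- "integer"
  dimnames(ind) <- dimnames(d)
  ind
}
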