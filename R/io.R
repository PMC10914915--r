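#' Write a MagicPanel to disk
#'
#' Emits a minimal VCF (homozygous `0/0` / `1/1` GT calls), a dosage TSV
#' (lines x markers) and a marker-map TSV (`marker`, `chrom`, `pos_bp`,
#' `ref`, `alt`, `is_b73_allele`). Positions are 1-based.
#'
#' @param panel a [MagicPanel-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the written file paths.
#' @export
writeGenotypes <- function(panel, dir, prefix = "panel") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- markerMap(panel)
  d <- assay(panel, "dosage")  # markers x lines
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=glaiQTL",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(d)),
                     collapse = "\t")), con)
  gt <- matrix(ifelse(d == 2, "1/1", "0/0"), nrow = nrow(d))
  body <- paste(map$chrom, map$pos_bp, map$marker, map$ref, map$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  close(con)
  dos <- file.path(dir, paste0(prefix, "_dosage.tsv"))
  utils::write.table(
    data.frame(line = colnames(d), t(d), check.names = FALSE),
    dos, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- file.path(dir, paste0(prefix, "_markers.tsv"))
  utils::write.table(map, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf, dosage = dos, markers = mp))
}

#' Read a dosage TSV + marker map back into a MagicPanel
#'
#' @param dosageFile TSV written by [writeGenotypes()] (`line` column then
#'   one column per marker).
#' @param markerFile marker-map TSV.
#' @return a [MagicPanel-class] (without founder-mosaic truth).
#' @export
readGenotypes <- function(dosageFile, markerFile) {
  dos <- utils::read.delim(dosageFile, check.names = FALSE)
  map <- utils::read.delim(markerFile,
                           colClasses = c(chrom = "character"))
  d <- t(as.matrix(dos[, -1, drop = FALSE]))
  colnames(d) <- dos$line
  stopifnot(identical(rownames(d), map$marker))
  gr <- GRanges(seqnames = map$chrom,
                ranges = IRanges(start = map$pos_bp, width = 1L))
  names(gr) <- map$marker
  mcols(gr)$ref <- map$ref
  mcols(gr)$alt <- map$alt
  mcols(gr)$b73Allele <- map$is_b73_allele
  f <- rowMeans(d) / 2
  mcols(gr)$maf <- pmin(f, 1 - f)
  MagicPanel(d, gr)
}

#' Write/read pipeline tables
#'
#' Thin CSV wrappers fixing the conventions used throughout: UTF-8, header
#' row, no row names.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `readTable` returns a data.frame; `writeTable` the path,
#'   invisibly.
#' @export
writeTable <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  listCols <- vapply(x, is.list, TRUE)
  if (any(listCols))
    for (cc in names(x)[listCols])
      x[[cc]] <- vapply(x[[cc]], paste, "", collapse = ";")
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8")
}
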