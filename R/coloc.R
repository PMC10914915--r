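#' QTL colocalization
#'
#' Two QTLs colocalize when their (extended) half-open intervals overlap on
#' the same chromosome, whatever their traits or environments. For each
#' colocalized pair the direction concordance compares the signs of the
#' B73-allele effects in the environments where both QTLs are significant:
#' `"same"`, `"opposite"`, `"mixed"`, or NA when they share no environment
#' of joint significance.
#'
#' @param qtls data.frame with one row per QTL: `qtl_id`, `trait`,
#'   `chrom`, `ext_start`, `ext_end`.
#' @param effects data.frame `id`, `environment`, `beta`, `significant`
#'   (from [backwardSelectQtls()]), `id` matching `qtl_id`.
#' @return data.frame of colocalized pairs: `qtl1`, `qtl2`, `trait1`,
#'   `trait2`, `chrom`, `overlap_start`, `overlap_end`, `direction`.
#' @export
colocalizeQtls <- function(qtls, effects = NULL) {
  res <- list()
  if (is.null(qtls) || nrow(qtls) < 2L) return(emptyColocTable())
  for (i in seq_len(nrow(qtls) - 1L)) {
    for (j in (i + 1L):nrow(qtls)) {
      if (qtls$chrom[i] != qtls$chrom[j]) next
      if (!intervalsOverlap(qtls$ext_start[i], qtls$ext_end[i],
                            qtls$ext_start[j], qtls$ext_end[j])) next
      dir <- NA_character_
      if (!is.null(effects)) {
        e1 <- effects[effects$id == qtls$qtl_id[i] &
                        isTRUE2(effects$significant), ]
        e2 <- effects[effects$id == qtls$qtl_id[j] &
                        isTRUE2(effects$significant), ]
        common <- intersect(e1$environment, e2$environment)
        if (length(common)) {
          s1 <- sign(e1$beta[match(common, e1$environment)])
          s2 <- sign(e2$beta[match(common, e2$environment)])
          agree <- s1 == s2
          dir <- if (all(agree)) "same"
                 else if (all(!agree)) "opposite" else "mixed"
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        qtl1 = qtls$qtl_id[i], qtl2 = qtls$qtl_id[j],
        trait1 = qtls$trait[i], trait2 = qtls$trait[j],
        chrom = qtls$chrom[i],
        overlap_start = max(qtls$ext_start[i], qtls$ext_start[j]),
        overlap_end = min(qtls$ext_end[i], qtls$ext_end[j]),
        direction = dir, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(emptyColocTable())
  do.call(rbind, res)
}

isTRUE2 <- function(x) !is.na(x) & x

emptyColocTable <- function() {
  data.frame(qtl1 = character(), qtl2 = character(),
             trait1 = character(), trait2 = character(),
             chrom = character(), overlap_start = numeric(),
             overlap_end = numeric(), direction = character(),
             stringsAsFactors = FALSE)
}
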