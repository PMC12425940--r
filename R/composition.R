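#' Per-gene nucleotide composition indices
#'
#' Computes, from codon counts, the composition indices classically reported
#' for codon-usage studies: overall GC of the (stop-stripped) CDS, GC at each
#' codon position (GC1, GC2, GC3 over all sense codons), their first-two
#' position mean GC12, GC at synonymous third positions (GC3s: codons of amino
#' acids with degeneracy >= 2; Met, Trp and stops excluded), and the
#' third-position base frequencies A3s/T3s/G3s/C3s.
#'
#' Two dialects exist for the X3s denominator. The default, \code{"codonw"},
#' divides the number of synonymous codons ending in base x by the number of
#' synonymous codons belonging to amino acids that possess at least one
#' synonymous codon ending in x (so e.g. Phe codons never enter the A3s
#' denominator). The alternative \code{"strict"} divides by all synonymous
#' codons, so the four frequencies sum to 1.
#'
#' GC3 and GC3s are deliberately kept distinct: GC3 (used on the neutrality
#' plot x-axis) includes Met and Trp third positions, GC3s (used on the
#' ENC-plot x-axis) does not.
#'
#' @param x a [CodonCounts-class] object.
#' @param x3s_dialect \code{"codonw"} (default) or \code{"strict"}.
#' @return A data.frame with one row per gene and columns \code{gene_id},
#'   \code{a3s}, \code{t3s}, \code{g3s}, \code{c3s}, \code{gc}, \code{gc1},
#'   \code{gc2}, \code{gc3}, \code{gc12}, \code{gc3s}, \code{n_codons},
#'   \code{qc_ok}. Genes with no usable codons get NA indices and
#'   \code{qc_ok = FALSE}.
#' @examples
#' cc <- countCodons(list(g1 = c("GGG", "GGG")))
#' compositionProfile(cc)$gc3s  # 1
#' @export
compositionProfile <- function(x, x3s_dialect = c("codonw", "strict")) {
  x3s_dialect <- match.arg(x3s_dialect)
  stopifnot(is(x, "CodonCounts"))
  code <- .code()
  cnt <- codonCounts(x)[code$sense_codons, , drop = FALSE]
  cods <- code$sense_codons
  b1 <- substr(cods, 1, 1); b2 <- substr(cods, 2, 2); b3 <- substr(cods, 3, 3)
  is_gc <- function(b) b %in% c("G", "C")
  ngc <- (b1 %in% c("G","C")) + (b2 %in% c("G","C")) + (b3 %in% c("G","C"))
  aa <- code$aa[match(cods, code$codons)]
  deg <- code$degeneracy[match(cods, code$codons)]
  syn <- deg >= 2L                      # synonymous codons (Ile included)

  # per-base denominator sets for the CodonW dialect: synonymous codons whose
  # amino acid can end in that base
  denom_mask <- lapply(c("A", "T", "G", "C"), function(b) {
    aa_can <- unique(aa[syn & b3 == b])
    syn & aa %in% aa_can
  })
  names(denom_mask) <- c("A", "T", "G", "C")

  res <- lapply(seq_len(ncol(cnt)), function(j) {
    n <- cnt[, j]
    tot <- sum(n)
    if (tot == 0L) {
      return(data.frame(gene_id = colnames(cnt)[j], a3s = NA_real_,
                        t3s = NA_real_, g3s = NA_real_, c3s = NA_real_,
                        gc = NA_real_, gc1 = NA_real_, gc2 = NA_real_,
                        gc3 = NA_real_, gc12 = NA_real_, gc3s = NA_real_,
                        n_codons = 0L, qc_ok = FALSE))
    }
    gc1 <- sum(n[is_gc(b1)]) / tot
    gc2 <- sum(n[is_gc(b2)]) / tot
    gc3 <- sum(n[is_gc(b3)]) / tot
    gc <- sum(n * ngc) / (3 * tot)
    nsyn <- sum(n[syn])
    gc3s <- if (nsyn > 0) sum(n[syn & is_gc(b3)]) / nsyn else NA_real_
    x3s <- vapply(c("A", "T", "G", "C"), function(b) {
      num <- sum(n[syn & b3 == b])
      den <- if (x3s_dialect == "codonw") sum(n[denom_mask[[b]]]) else nsyn
      if (den > 0) num / den else NA_real_
    }, numeric(1))
    data.frame(gene_id = colnames(cnt)[j],
               a3s = x3s[["A"]], t3s = x3s[["T"]],
               g3s = x3s[["G"]], c3s = x3s[["C"]],
               gc = gc, gc1 = gc1, gc2 = gc2, gc3 = gc3,
               gc12 = (gc1 + gc2) / 2, gc3s = gc3s,
               n_codons = tot, qc_ok = TRUE)
  })
  do.call(rbind, c(res, make.row.names = FALSE))
}
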