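#' Select extreme ENC groups
#'
#' Sorts genes ascending by ENC (ties broken by gene id, so membership is
#' deterministic) and takes the lowest-ENC fraction as the putative
#' high-expression group and the highest-ENC fraction as the low-expression
#' group. Low ENC = strong bias, the proxy for high expression used by the
#' delta-RSCU method.
#'
#' @param enc_results data.frame from [enc()].
#' @param fraction fraction of genes per group (default 0.10).
#' @return A list of class \code{"extreme_groups"}: \code{high_expression},
#'   \code{low_expression} (gene id vectors), \code{fraction},
#'   \code{group_size}.
#' @examples
#' # 151 genes at 10% -> groups of 15
#' @export
extremeGroups <- function(enc_results, fraction = 0.10) {
  d <- enc_results[!is.na(enc_results$enc), ]
  n <- nrow(d)
  size <- max(1L, floor(fraction * n))
  if (2L * size > n)
    stop("groups would overlap: ", n, " genes cannot fill two groups of ", size)
  ord <- order(d$enc, d$gene_id)
  structure(list(
    high_expression = d$gene_id[ord[seq_len(size)]],
    low_expression = d$gene_id[ord[seq(n - size + 1L, n)]],
    fraction = fraction,
    group_size = size
  ), class = "extreme_groups")
}

#' @export
print.extreme_groups <- function(x, ...) {
  cat("Extreme ENC groups: ", x$group_size, " genes each (fraction ",
      x$fraction, ")\n", sep = "")
  invisible(x)
}

# classification shared by the counts-based and table-based entry points
.classify_delta <- function(tab, high_frequency, delta_threshold) {
  tab$delta <- tab$rscu_high - tab$rscu_low
  tab$highly_expressed <- !is.na(tab$delta) & tab$delta >= delta_threshold
  tab$high_frequency <- tab$codon %in% toRna(high_frequency)
  tab$optimal <- tab$highly_expressed & tab$high_frequency
  tab
}

#' Delta-RSCU table for optimal codon identification
#'
#' Computes pooled RSCU within the high- and low-expression extreme groups,
#' their difference delta = rscu_high - rscu_low per codon, and the three
#' classification flags: \code{highly_expressed} (delta >= threshold, default
#' 0.08), \code{high_frequency} (pooled RSCU over all genes > 1), and
#' \code{optimal} (both). Rows cover the 56-codon analysis set; codons whose
#' amino acid is absent from either group have NA delta and are excluded from
#' classification.
#'
#' @param x a [CodonCounts-class] object.
#' @param groups an [extremeGroups()] result.
#' @param delta_threshold minimum delta for a high-expression-preferred codon
#'   (default 0.08).
#' @param rscu_threshold pooled-RSCU cutoff for high-frequency codons
#'   (default 1.0, strict inequality).
#' @return data.frame: \code{amino_acid}, \code{codon} (RNA), \code{rscu_high},
#'   \code{rscu_low}, \code{delta}, \code{highly_expressed},
#'   \code{high_frequency}, \code{optimal}.
#' @export
deltaRscuTable <- function(x, groups, delta_threshold = 0.08,
                           rscu_threshold = 1.0) {
  stopifnot(is(x, "CodonCounts"), inherits(groups, "extreme_groups"))
  code <- .code()
  set_dna <- toDna(code$analysis_set)
  r_hi <- pooledRscu(x, groups$high_expression)[code$analysis_set]
  r_lo <- pooledRscu(x, groups$low_expression)[code$analysis_set]
  r_all <- pooledRscu(x)[code$analysis_set]
  aa <- code$aa[match(set_dna, code$codons)]
  tab <- data.frame(
    amino_acid = aa, codon = code$analysis_set,
    rscu_high = unname(r_hi), rscu_low = unname(r_lo),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$amino_acid, tab$codon), ]
  rownames(tab) <- NULL
  hf <- names(which(!is.na(r_all) & r_all > rscu_threshold))
  .classify_delta(tab, hf, delta_threshold)
}

#' Delta-RSCU classification from an externally supplied group-RSCU table
#'
#' Applies the same classification as [deltaRscuTable()] to a table of
#' precomputed group RSCU values plus a high-frequency codon list, so
#' published extreme-group tables can be re-analyzed without the underlying
#' sequences. Ingestion performs QC: within each group, every amino-acid
#' family's RSCU values must sum to its degeneracy; families off by more than
#' \code{sum_tolerance} (default 0.05, generous enough for values rounded to
#' two decimals) are flagged in the \code{family_sum_ok} column.
#'
#' @param group_rscu data.frame with columns \code{codon} (RNA or DNA),
#'   \code{rscu_high}, \code{rscu_low} (an \code{amino_acid} column is
#'   derived if absent).
#' @param high_frequency character vector of high-frequency codons.
#' @param delta_threshold as in [deltaRscuTable()].
#' @param sum_tolerance allowed deviation of each family's group RSCU sum
#'   from its degeneracy before the family is QC-flagged.
#' @return data.frame as in [deltaRscuTable()] plus \code{family_sum_ok}.
#' @export
deltaRscuFromTable <- function(group_rscu, high_frequency,
                               delta_threshold = 0.08, sum_tolerance = 0.05) {
  stopifnot(all(c("codon", "rscu_high", "rscu_low") %in% names(group_rscu)))
  code <- .code()
  tab <- group_rscu
  tab$codon <- toRna(toupper(tab$codon))
  dna <- toDna(tab$codon)
  bad <- dna[!dna %in% code$sense_codons]
  if (length(bad)) stop("unknown codon(s): ", paste(toRna(bad), collapse = ", "))
  tab$amino_acid <- code$aa[match(dna, code$codons)]
  deg <- code$degeneracy[match(dna, code$codons)]
  fam_hi <- tapply(tab$rscu_high, tab$amino_acid, sum)
  fam_lo <- tapply(tab$rscu_low, tab$amino_acid, sum)
  fam_deg <- tapply(deg, tab$amino_acid, unique)
  fam_n <- tapply(deg, tab$amino_acid, length)
  complete <- fam_n == fam_deg            # only complete families are checkable
  ok <- complete &
    abs(fam_hi - fam_deg) <= sum_tolerance &
    abs(fam_lo - fam_deg) <= sum_tolerance
  tab$family_sum_ok <- as.vector(ok[tab$amino_acid])
  tab <- tab[order(tab$amino_acid, tab$codon),
             c("amino_acid", "codon", "rscu_high", "rscu_low", "family_sum_ok")]
  rownames(tab) <- NULL
  out <- .classify_delta(tab, high_frequency, delta_threshold)
  out[, c("amino_acid", "codon", "rscu_high", "rscu_low", "delta",
          "highly_expressed", "high_frequency", "optimal", "family_sum_ok")]
}

#' Extract the optimal codon set
#'
#' @param rows a classified delta-RSCU table.
#' @return Character vector of optimal codons (RNA), ordered by amino acid
#'   then codon.
#' @export
optimalCodonSet <- function(rows) {
  rows <- rows[order(rows$amino_acid, rows$codon), ]
  rows$codon[rows$optimal]
}

#' Reference extreme-group RSCU values for the banana WRKY gene family
#'
#' Published extreme-group (low-ENC vs high-ENC decile) RSCU values for the
#' 151 WRKY transcription-factor coding sequences of *Musa acuminata*
#' 'Guijiao 9', shipped as a worked example for the table-mode delta-RSCU
#' classifier. \code{wrkyHighFrequencyCodons()} returns the matching 26-codon
#' high-frequency (pooled RSCU > 1) list.
#'
#' @return \code{wrkyGroupRscu()}: data.frame with \code{amino_acid},
#'   \code{codon}, \code{rscu_high}, \code{rscu_low};
#'   \code{wrkyHighFrequencyCodons()}: character vector of 26 RNA codons.
#' @examples
#' tab <- deltaRscuFromTable(wrkyGroupRscu(), wrkyHighFrequencyCodons())
#' optimalCodonSet(tab)  # 15 codons, all G/C-ending
#' @export
wrkyGroupRscu <- function() {
  read.delim(system.file("extdata", "wrky_group_rscu.tsv", package = "cubana"),
             stringsAsFactors = FALSE)
}

#' @rdname wrkyGroupRscu
#' @export
wrkyHighFrequencyCodons <- function() {
  readLines(system.file("extdata", "wrky_high_frequency_codons.txt",
                        package = "cubana"))
}
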