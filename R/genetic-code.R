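#' @import methods
#' @importFrom stats cor cor.test lm coef prcomp rbeta rlnorm runif setNames
#'   complete.cases
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom graphics plot lines abline
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors DataFrame
NULL

# Canonical codon order: alphabetical over the DNA alphabet. All matrices and
# tables in the package index codons in this order.
.codon_order <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

#' The standard nuclear genetic code used throughout the package
#'
#' Returns the standard genetic code (translation table 1) annotated with the
#' quantities codon-usage statistics need: the amino acid encoded by each
#' codon, the synonymous-family size (degeneracy) of that amino acid, and the
#' 56-codon analysis set used for RSCU reporting and PCA. The analysis set
#' drops the initiation codon AUG, the tryptophan codon UGG, the three
#' isoleucine codons, and the three stop codons.
#'
#' Sequences are handled internally in the DNA alphabet; reported codon names
#' use the RNA alphabet (U for T), matching the convention of codon-usage
#' tables.
#'
#' @return A list with components:
#'   \item{codons}{character(64), DNA codons in canonical (alphabetical) order.}
#'   \item{rna}{character(64), the same codons written with U.}
#'   \item{aa}{character(64), one-letter amino acid (\code{"*"} for stops).}
#'   \item{degeneracy}{integer(64), synonymous-family size of each codon's
#'     amino acid (NA for stops).}
#'   \item{stop_codons}{character(3).}
#'   \item{sense_codons}{character(61).}
#'   \item{analysis_set}{character(56), RNA-alphabet names.}
#' @examples
#' gc <- geneticCode()
#' length(gc$analysis_set)  # 56
#' @export
geneticCode <- function() {
  codons <- .codon_order()
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  deg_tab <- table(aa[aa != "*"])
  degeneracy <- ifelse(aa == "*", NA_integer_, as.integer(deg_tab[aa]))
  stop_codons <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  drop <- c("ATG", "TGG", "ATT", "ATC", "ATA")
  analysis <- setdiff(sense, drop)
  list(
    codons = codons,
    rna = chartr("T", "U", codons),
    aa = aa,
    degeneracy = degeneracy,
    stop_codons = stop_codons,
    sense_codons = sense,
    analysis_set = chartr("T", "U", analysis)
  )
}

# cached copy; the code is fixed, recomputing it everywhere is wasteful
.gc_cache <- new.env(parent = emptyenv())

.code <- function() {
  if (is.null(.gc_cache$code)) .gc_cache$code <- geneticCode()
  .gc_cache$code
}

#' Convert codon names between DNA and RNA alphabets
#'
#' @param x character vector of codons.
#' @return character vector of the same length.
#' @examples
#' toRna("ATG")  # "AUG"
#' toDna("AUG")  # "ATG"
#' @export
toRna <- function(x) chartr("Tt", "Uu", x)

#' @rdname toRna
#' @export
toDna <- function(x) chartr("Uu", "Tt", x)

# amino acids by degeneracy class, sense codons only
.aa_by_class <- function(k) {
  code <- .code()
  aa <- unique(code$aa[!is.na(code$degeneracy) & code$degeneracy == k])
  aa
}

# codons (DNA) of one amino acid
.codons_of <- function(aa1) {
  code <- .code()
  code$codons[code$aa == aa1]
}
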