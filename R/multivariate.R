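#' Build the 56 x n_genes RSCU matrix for multivariate analysis
#'
#' Restricts per-gene RSCU values to the 56-codon analysis set (no AUG, UGG,
#' isoleucine or stop codons). Codons of amino-acid families a gene never uses
#' have no defined RSCU; they are imputed as 0 and recorded in the
#' \code{"mask"} attribute (a logical matrix, TRUE where imputed).
#'
#' @param x a [CodonCounts-class] object (needs >= 2 genes).
#' @return Numeric matrix, 56 codons (RNA rownames) x genes, with a
#'   \code{"mask"} attribute.
#' @export
buildRscuMatrix <- function(x) {
  stopifnot(is(x, "CodonCounts"))
  if (ncol(x) < 2) stop("need at least 2 genes")
  r <- rscu(x)[.code()$analysis_set, , drop = FALSE]
  mask <- is.na(r)
  r[mask] <- 0
  attr(r, "mask") <- mask
  r
}

#' PCA of the RSCU matrix
#'
#' Covariance-matrix principal component analysis with codons as observations
#' (rows) and genes as variables (columns): each gene column is mean-centered,
#' no scaling, decomposition by SVD ([stats::prcomp()]). Signs are fixed
#' deterministically — the largest-magnitude score of each component is made
#' positive — so results are stable across linear-algebra backends.
#'
#' @param m matrix from [buildRscuMatrix()] (or any observations x variables
#'   matrix).
#' @param n_components number of components to retain; default all (the rank).
#' @return A list of class \code{"cub_pca"}: \code{scores} (codon x
#'   component), \code{loadings} (gene x component), \code{explained_pct},
#'   \code{cumulative_pct} (over all components, so the last equals 100),
#'   \code{sdev}.
#' @export
rscuPca <- function(m, n_components = NULL) {
  pr <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank)
    stop("n_components (", n_components, ") exceeds matrix rank (", rank, ")")
  expl <- 100 * ev / sum(ev)
  keep <- seq_len(n_components)
  scores <- pr$x
  loadings <- pr$rotation
  for (j in seq_len(ncol(scores))) {            # deterministic sign
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  structure(list(
    scores = scores[, keep, drop = FALSE],
    loadings = loadings[, keep, drop = FALSE],
    explained_pct = expl,
    cumulative_pct = cumsum(expl),
    sdev = pr$sdev
  ), class = "cub_pca")
}

#' @export
print.cub_pca <- function(x, ...) {
  k <- min(4, length(x$explained_pct))
  cat("RSCU PCA: ", ncol(x$scores), " component(s) retained\n", sep = "")
  cat("  explained %:", paste(sprintf("%.2f", x$explained_pct[1:k]),
                              collapse = ", "),
      if (length(x$explained_pct) > k) "..." else "", "\n")
  invisible(x)
}

#' Group codons by their third base
#'
#' Classifies codons by their ending nucleotide (reported in the RNA
#' alphabet), the conventional coloring of RSCU PCA score plots.
#'
#' @param codons character vector of codons (RNA or DNA).
#' @return Named character vector mapping each codon to "A", "U", "G" or "C".
#' @examples
#' codonEndingGroups(c("AGG", "GCU"))
#' @export
codonEndingGroups <- function(codons) {
  ends <- toRna(toupper(substr(codons, 3, 3)))
  if (any(!ends %in% c("A", "U", "G", "C")))
    stop("invalid codon(s): ", paste(codons[!ends %in% c("A","U","G","C")],
                                     collapse = ", "))
  setNames(ends, toRna(codons))
}
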