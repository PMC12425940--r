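#' Read coding sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that extracts the
#' header token before the first whitespace as the gene identifier and checks
#' identifiers are unique.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by gene id, in file order.
#'   An empty file yields an empty set with a warning.
#' @export
readCdsFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("no sequences found in ", path)
    return(seqs)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate gene ids in ", path, ": ", paste(dup, collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Validation policy for coding sequences
#'
#' @param min_length minimum CDS length in nucleotides (default 300).
#' @param frame how to treat lengths that are not multiples of 3:
#'   \code{"reject"} (default) or \code{"trim"} (drop the trailing 1-2 nt).
#' @param internal_stop \code{"reject"} (default; internal stops indicate a
#'   frame error in a screened CDS set) or \code{"mask"} (warn; the stop codon
#'   is skipped from counting like an ambiguous codon).
#' @return A named list of class \code{"cds_policy"}.
#' @export
cdsPolicy <- function(min_length = 300L,
                      frame = c("reject", "trim"),
                      internal_stop = c("reject", "mask")) {
  structure(list(
    min_length = as.integer(min_length),
    frame = match.arg(frame),
    internal_stop = match.arg(internal_stop)
  ), class = "cds_policy")
}

#' Validate CDS records and tokenize them into codons
#'
#' Applies a [cdsPolicy()]: short sequences and (under the default policy)
#' off-frame or internally stopped sequences are rejected; a terminal stop
#' codon is stripped before counting; codons containing ambiguity codes (N, R,
#' Y, ...) are skipped and counted per gene for QC. Rejections never abort the
#' batch.
#'
#' @param seqs a named [Biostrings::DNAStringSet] (as from [readCdsFasta()]),
#'   or a named character vector of sequences.
#' @param policy a [cdsPolicy()].
#' @return A list with components \code{codons} (named list of per-gene codon
#'   character vectors, DNA alphabet), \code{info} (data.frame: gene_id,
#'   length_nt, n_codons, n_skipped_ambiguous, had_terminal_stop) and
#'   \code{rejects} (data.frame: gene_id, reason).
#' @export
validateCds <- function(seqs, policy = cdsPolicy()) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by gene id")
  code <- .code()
  out <- list()
  info <- list()
  rejects <- list()
  for (id in names(seqs)) {
    s <- toupper(toDna(seqs[[id]]))
    len <- nchar(s)
    if (len < policy$min_length) {
      rejects[[id]] <- sprintf("length %d < minimum %d", len, policy$min_length)
      next
    }
    if (len %% 3L != 0L) {
      if (policy$frame == "reject") {
        rejects[[id]] <- "length not multiple of 3"
        next
      }
      s <- substr(s, 1L, len - len %% 3L)
    }
    cods <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                      seq(3L, nchar(s), by = 3L))
    had_stop <- cods[length(cods)] %in% code$stop_codons
    if (had_stop) cods <- cods[-length(cods)]
    ok <- !grepl("[^ACGT]", cods)
    n_skip <- sum(!ok)
    cods <- cods[ok]
    internal <- cods %in% code$stop_codons
    if (any(internal)) {
      if (policy$internal_stop == "reject") {
        rejects[[id]] <- sprintf("%d internal stop codon(s)", sum(internal))
        next
      }
      warning(id, ": masking ", sum(internal), " internal stop codon(s)")
      n_skip <- n_skip + sum(internal)
      cods <- cods[!internal]
    }
    out[[id]] <- cods
    info[[id]] <- data.frame(
      gene_id = id, length_nt = len, n_codons = length(cods),
      n_skipped_ambiguous = n_skip, had_terminal_stop = had_stop,
      stringsAsFactors = FALSE
    )
  }
  list(
    codons = out,
    info = if (length(info)) do.call(rbind, c(info, make.row.names = FALSE))
           else data.frame(gene_id = character(), length_nt = integer(),
                           n_codons = integer(), n_skipped_ambiguous = integer(),
                           had_terminal_stop = logical()),
    rejects = if (length(rejects))
                data.frame(gene_id = names(rejects),
                           reason = unlist(rejects, use.names = FALSE),
                           stringsAsFactors = FALSE)
              else data.frame(gene_id = character(), reason = character())
  )
}

#' CodonCounts: per-gene codon counts
#'
#' An S4 container for the 64 x n_genes matrix of codon counts that underlies
#' every statistic in the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with codons as rows (canonical
#' alphabetical DNA order) and genes as columns; \code{rowData} carries the
#' genetic-code annotation (RNA codon name, amino acid, degeneracy) and
#' \code{colData} the per-gene QC fields from validation.
#'
#' Stop-codon rows are present but always excluded from downstream statistics;
#' under the default validation policy they are zero.
#'
#' @aliases CodonCounts-class
#' @export
setClass("CodonCounts", contains = "SummarizedExperiment")

setValidity("CodonCounts", function(object) {
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (!identical(rownames(cnt), .codon_order()))
    return("rows must be the 64 codons in canonical order")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    return("counts must be non-negative integers")
  if (is.null(colnames(cnt)) || anyDuplicated(colnames(cnt)))
    return("gene ids (column names) must be present and unique")
  TRUE
})

#' Count codons for validated coding sequences
#'
#' @param x output of [validateCds()], a named [Biostrings::DNAStringSet], or
#'   a named list of codon character vectors.
#' @param policy a [cdsPolicy()], used when \code{x} is a raw sequence set.
#' @return A [CodonCounts-class] object.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(g1 = strrep("ATGGGCAAGCTT", 26)))
#' cc <- countCodons(seqs)
#' totalCodons(cc)
#' @export
countCodons <- function(x, policy = cdsPolicy()) {
  if (is(x, "DNAStringSet") || (is.character(x) && !is.list(x)))
    x <- validateCds(x, policy)
  if (is.list(x) && !is.null(x$codons)) {
    codons <- x$codons
    info <- x$info
  } else {
    codons <- x
    info <- data.frame(
      gene_id = names(codons),
      length_nt = 3L * lengths(codons),
      n_codons = lengths(codons),
      n_skipped_ambiguous = 0L,
      had_terminal_stop = FALSE,
      stringsAsFactors = FALSE
    )
  }
  if (length(codons) == 0L) stop("no valid genes to count")
  ord <- .codon_order()
  cnt <- vapply(codons, function(cv) {
    tab <- table(factor(cv, levels = ord))
    as.integer(tab)
  }, integer(64L))
  dimnames(cnt) <- list(ord, names(codons))
  codonCountsFromMatrix(cnt, geneData = info)
}

#' Build a CodonCounts object from a counts matrix
#'
#' @param counts integer matrix, 64 codons x genes. Rownames may be DNA or RNA
#'   codons in any order; genes may alternatively be rows (the matrix is
#'   oriented automatically when unambiguous).
#' @param geneData optional data.frame of per-gene columns (must contain
#'   \code{gene_id} if given).
#' @return A [CodonCounts-class] object.
#' @export
codonCountsFromMatrix <- function(counts, geneData = NULL) {
  ord <- .codon_order()
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!all(ord %in% toDna(rownames(counts) %||% ""))) {
    if (all(ord %in% toDna(colnames(counts) %||% ""))) counts <- t(counts)
    else stop("counts must have the 64 codons as row (or column) names")
  }
  rownames(counts) <- toDna(rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  storage.mode(counts) <- "integer"
  code <- .code()
  rd <- S4Vectors::DataFrame(
    codon = code$rna, aa = code$aa, degeneracy = code$degeneracy,
    row.names = ord
  )
  cd <- S4Vectors::DataFrame(gene_id = colnames(counts),
                             row.names = colnames(counts))
  if (!is.null(geneData)) {
    geneData <- geneData[match(colnames(counts), geneData$gene_id), ,
                         drop = FALSE]
    for (nm in setdiff(names(geneData), "gene_id")) cd[[nm]] <- geneData[[nm]]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd
  )
  methods::new("CodonCounts", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for CodonCounts
#'
#' \code{codonCounts()} returns the 64 x n_genes count matrix (DNA rownames);
#' \code{geneIds()} the gene identifiers; \code{totalCodons()} the per-gene
#' number of sense (non-stop) codons counted.
#'
#' @param x a [CodonCounts-class] object.
#' @return See individual descriptions.
#' @name codonCounts
#' @export
codonCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname codonCounts
#' @export
geneIds <- function(x) colnames(x)

#' @rdname codonCounts
#' @export
totalCodons <- function(x) {
  cnt <- codonCounts(x)
  colSums(cnt[.code()$sense_codons, , drop = FALSE])
}

setMethod("show", "CodonCounts", function(object) {
  cat("CodonCounts: ", ncol(object), " gene(s), ",
      sum(codonCounts(object)), " codons counted\n", sep = "")
  tc <- totalCodons(object)
  cat("  sense codons/gene: min ", min(tc), ", median ",
      round(stats::median(tc)), ", max ", max(tc), "\n", sep = "")
})

#' Write validated coding sequences to FASTA
#'
#' @param codons named list of codon vectors (DNA), as produced by
#'   [validateCds()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCdsFasta <- function(codons, path) {
  seqs <- Biostrings::DNAStringSet(vapply(codons, paste0, "", collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
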