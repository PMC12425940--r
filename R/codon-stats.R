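# RSCU for one counts vector (named by DNA codon, sense codons at least).
# Returns a named numeric over sense codons; NA where the amino acid is absent.
.rscu_vec <- function(n) {
  code <- .code()
  cods <- code$sense_codons
  n <- n[cods]
  aa <- code$aa[match(cods, code$codons)]
  fam_tot <- tapply(n, aa, sum)[aa]
  k <- code$degeneracy[match(cods, code$codons)]
  r <- ifelse(fam_tot > 0, n * k / fam_tot, NA_real_)
  names(r) <- cods
  r
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c with amino-acid family count n_a and degeneracy k_a is
#' \code{count(c) * k_a / n_a}: the observed count relative to the count
#' expected if all synonymous codons of the amino acid were used equally.
#' Within every amino-acid family that is used at least once the values sum to
#' the degeneracy (so their mean is 1); families never used give NA.
#'
#' @param x a [CodonCounts-class] object.
#' @return A numeric matrix, 61 sense codons (RNA rownames) x genes.
#' @examples
#' cc <- countCodons(list(g = rep(c("CTC", "CTG"), 2)))
#' rscu(cc)["CUC", ]  # 3: two of six Leu codons used, equally
#' @export
rscu <- function(x) {
  stopifnot(is(x, "CodonCounts"))
  cnt <- codonCounts(x)
  m <- vapply(seq_len(ncol(cnt)), function(j) .rscu_vec(cnt[, j]),
              numeric(length(.code()$sense_codons)))
  if (!is.matrix(m)) m <- matrix(m, ncol = ncol(cnt))
  dimnames(m) <- list(toRna(.code()$sense_codons), colnames(cnt))
  m
}

#' Pooled (group-level) RSCU
#'
#' Sums codon counts over a set of genes and applies the RSCU formula to the
#' summed counts (usage-weighted pooling, the CodonW/EMBOSS convention) —
#' not the mean of per-gene RSCU values.
#'
#' @param x a [CodonCounts-class] object.
#' @param genes gene ids (or column indices) to pool; default all.
#' @return Named numeric vector over the 61 sense codons (RNA names).
#' @export
pooledRscu <- function(x, genes = NULL) {
  stopifnot(is(x, "CodonCounts"))
  cnt <- codonCounts(x)
  if (!is.null(genes)) cnt <- cnt[, genes, drop = FALSE]
  if (ncol(cnt) == 0L) stop("no genes to pool")
  r <- .rscu_vec(rowSums(cnt))
  names(r) <- toRna(names(r))
  r
}

#' High-frequency codons (RSCU > 1)
#'
#' Codons of the 56-codon analysis set whose pooled RSCU strictly exceeds 1.
#'
#' @param r a pooled RSCU vector as from [pooledRscu()] (RNA or DNA names).
#' @return Character vector of RNA codon names, sorted.
#' @export
highFrequencyCodons <- function(r) {
  names(r) <- toRna(names(r))
  set <- intersect(names(r), .code()$analysis_set)
  sort(names(which(r[set] > 1)))
}

# Wright's ENC for one counts vector (DNA codon names).
# impute_f3: when no Ile F-hat is observable, estimate F3 as mean(F2, F4).
.enc_vec <- function(n, impute_f3 = TRUE) {
  code <- .code()
  classes <- c(2L, 3L, 4L, 6L)
  n_per_class <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  fbar <- setNames(rep(NA_real_, 4), classes)
  for (k in classes) {
    fh <- c()
    for (a in .aa_by_class(k)) {
      cnts <- n[.codons_of(a)]
      na <- sum(cnts)
      if (na >= 2) {
        p <- cnts / na
        f <- (na * sum(p^2) - 1) / (na - 1)
        if (f > 0) fh <- c(fh, f)
      }
    }
    if (length(fh)) fbar[as.character(k)] <- mean(fh)
  }
  imputed <- character()
  if (is.na(fbar["3"]) && impute_f3 &&
      !is.na(fbar["2"]) && !is.na(fbar["4"])) {
    fbar["3"] <- mean(c(fbar["2"], fbar["4"]))
    imputed <- "3"
  }
  if (any(is.na(fbar))) {
    return(list(enc = NA_real_, fbar = fbar, imputed = imputed,
                capped = FALSE, qc_ok = FALSE))
  }
  raw <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  raw <- unname(raw)
  list(enc = min(max(raw, 20), 61), fbar = fbar, imputed = imputed,
       capped = raw > 61, qc_ok = TRUE)
}

#' Wright's effective number of codons (ENC)
#'
#' For each amino acid used n >= 2 times, the bias-corrected codon
#' homozygosity is \eqn{\hat F = (n \sum \hat p_i^2 - 1)/(n - 1)} over its
#' synonymous codons. Within each degeneracy class k (2, 3, 4, 6) the mean
#' \eqn{\bar F_k} is taken over amino acids with \eqn{n \ge 2} and
#' \eqn{\hat F > 0}, and
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' If isoleucine (the only 3-fold amino acid) is unobservable, \eqn{\bar F_3}
#' is imputed as the mean of \eqn{\bar F_2} and \eqn{\bar F_4} and recorded;
#' if any of classes 2/4/6 is entirely unobservable the ENC is NA with a QC
#' flag. Finite-sample \eqn{\hat F} can push the raw value above the
#' theoretical ceiling of 61 (no bias); results are capped into [20, 61] and
#' flagged.
#'
#' @param x a [CodonCounts-class] object.
#' @param impute_f3 impute the 3-fold class when isoleucine is missing
#'   (default TRUE).
#' @return A data.frame with one row per gene: \code{gene_id}, \code{enc},
#'   \code{f2}, \code{f3}, \code{f4}, \code{f6} (class mean homozygosities),
#'   \code{imputed_classes}, \code{capped}, \code{qc_ok}.
#' @examples
#' # complete bias: one codon per amino acid -> ENC = 20
#' one <- vapply(split(geneticCode()$sense_codons,
#'                     geneticCode()$aa[geneticCode()$aa != "*"]),
#'               `[`, "", 1)
#' cc <- countCodons(list(g = rep(one, 3)))
#' enc(cc)$enc
#' @export
enc <- function(x, impute_f3 = TRUE) {
  stopifnot(is(x, "CodonCounts"))
  cnt <- codonCounts(x)
  rows <- lapply(seq_len(ncol(cnt)), function(j) {
    e <- .enc_vec(cnt[, j], impute_f3 = impute_f3)
    data.frame(gene_id = colnames(cnt)[j], enc = e$enc,
               f2 = e$fbar[["2"]], f3 = e$fbar[["3"]],
               f4 = e$fbar[["4"]], f6 = e$fbar[["6"]],
               imputed_classes = paste(e$imputed, collapse = ","),
               capped = e$capped, qc_ok = e$qc_ok,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
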