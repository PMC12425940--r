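#' Expected ENC under composition-only bias
#'
#' Wright's null curve for the ENC-plot: the ENC expected when codon choice is
#' driven solely by the G+C content s at synonymous third positions,
#' \deqn{N_c^* = 2 + s + 29 / (s^2 + (1 - s)^2).}
#'
#' @param gc3s numeric vector of GC3s values in [0, 1].
#' @return Numeric vector of expected ENC values.
#' @examples
#' encExpected(0.5)  # 60.5
#' @export
encExpected <- function(gc3s) {
  if (any(!is.na(gc3s) & (gc3s < 0 | gc3s > 1)))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot table
#'
#' Pairs each gene's observed ENC with the value expected from its GC3s under
#' composition-only bias and reports the relative deviation
#' \code{(expected - observed) / expected}. Genes with deviation above the
#' threshold lie "noticeably below" the curve, the classical signature of
#' selection on codon usage; a summary of above/near/below counts is attached
#' as the \code{"summary"} attribute.
#'
#' @param profiles data.frame from [compositionProfile()].
#' @param enc_results data.frame from [enc()].
#' @param tau deviation threshold for "noticeably below" (default 0.1).
#' @param abscissa \code{"gc3s"} (default) or \code{"gc3"}.
#' @return data.frame: \code{gene_id}, \code{gc3s} (the abscissa used),
#'   \code{enc}, \code{enc_expected}, \code{deviation}.
#' @export
encPlotTable <- function(profiles, enc_results, tau = 0.1,
                         abscissa = c("gc3s", "gc3")) {
  abscissa <- match.arg(abscissa)
  d <- merge(profiles[, c("gene_id", abscissa)],
             enc_results[, c("gene_id", "enc")],
             by = "gene_id", sort = FALSE)
  names(d)[2] <- "gc3s"
  d$enc_expected <- encExpected(d$gc3s)
  d$deviation <- (d$enc_expected - d$enc) / d$enc_expected
  attr(d, "summary") <- c(
    above = sum(d$deviation < -tau, na.rm = TRUE),
    near = sum(abs(d$deviation) <= tau, na.rm = TRUE),
    below = sum(d$deviation > tau, na.rm = TRUE)
  )
  d
}

# third-position base counts per gene over the chosen site set
.third_base_counts <- function(cnt, sites = c("fourfold", "all")) {
  sites <- match.arg(sites)
  code <- .code()
  cods <- code$sense_codons
  deg <- code$degeneracy[match(cods, code$codons)]
  aa <- code$aa[match(cods, code$codons)]
  if (sites == "fourfold") {
    # eight four-fold families: Val Pro Thr Ala Gly plus the four-fold
    # subsets CUN (Leu), UCN (Ser), CGN (Arg)
    four_aa <- names(which(table(aa[deg == 4]) > 0))
    sub4 <- c("CTT","CTC","CTA","CTG", "TCT","TCC","TCA","TCG",
              "CGT","CGC","CGA","CGG")
    keep <- (aa %in% four_aa & deg == 4) | cods %in% sub4
  } else keep <- deg >= 2
  b3 <- substr(cods, 3, 3)
  sel <- cnt[code$sense_codons, , drop = FALSE][keep, , drop = FALSE]
  vapply(c("A", "T", "G", "C"),
         function(b) colSums(sel[b3[keep] == b, , drop = FALSE]),
         numeric(ncol(cnt)))
}

#' Parity Rule 2 (PR2) bias coordinates
#'
#' Tallies third-position bases over the eight four-fold degenerate codon
#' families (Val, Pro, Thr, Ala, Gly, and the four-fold subsets of Leu, Ser
#' and Arg — Sueoka's construction) and returns the PR2 plane coordinates:
#' GC bias x = G3/(G3+C3) and AT bias y = A3/(A3+T3). At (0.5, 0.5) the
#' complementary bases are in parity, as expected under mutation pressure
#' alone acting equally on both strands.
#'
#' @param x a [CodonCounts-class] object.
#' @param sites \code{"fourfold"} (default) or \code{"all"} synonymous third
#'   positions.
#' @return data.frame: \code{gene_id}, \code{x}, \code{y}, \code{n_sites},
#'   \code{qc_ok}. A coordinate whose denominator is zero is NA and flagged.
#' @examples
#' cc <- countCodons(list(g = rep(c("GGA", "GGT", "GGG", "GGC"), 3)))
#' pr2Point(cc)[, c("x", "y")]  # 0.5, 0.5
#' @export
pr2Point <- function(x, sites = c("fourfold", "all")) {
  stopifnot(is(x, "CodonCounts"))
  b <- .third_base_counts(codonCounts(x), sites = match.arg(sites))
  if (is.null(dim(b))) b <- matrix(b, nrow = 1, dimnames = list(NULL, names(b)))
  gx <- ifelse(b[, "G"] + b[, "C"] > 0, b[, "G"] / (b[, "G"] + b[, "C"]), NA)
  ay <- ifelse(b[, "A"] + b[, "T"] > 0, b[, "A"] / (b[, "A"] + b[, "T"]), NA)
  data.frame(gene_id = geneIds(x), x = gx, y = ay,
             n_sites = rowSums(b), qc_ok = !is.na(gx) & !is.na(ay),
             row.names = NULL)
}

#' Neutrality-plot regression of GC12 on GC3
#'
#' Ordinary least squares of GC12 (mean GC at the first two codon positions)
#' on GC3 across genes. A slope near 1 means directional mutation pressure
#' moves all three positions together (neutrality); a slope near 0 means the
#' first two positions are insulated from third-position pressure, implicating
#' selection.
#'
#' @param profiles data.frame from [compositionProfile()] (needs \code{gc3},
#'   \code{gc12}).
#' @return A list of class \code{"neutrality_fit"}: \code{slope},
#'   \code{intercept}, \code{r2}, \code{pearson_r}, \code{p_value},
#'   \code{n_genes}.
#' @export
neutralityFit <- function(profiles) {
  d <- profiles[stats::complete.cases(profiles[, c("gc3", "gc12")]), ]
  if (nrow(d) < 3) stop("need at least 3 genes with defined GC3 and GC12")
  if (stats::var(d$gc3) == 0) stop("degenerate regressor: GC3 has zero variance")
  if (stats::var(d$gc12) == 0) {
    # constant response: flat line, no explainable variance
    return(structure(list(slope = 0, intercept = mean(d$gc12), r2 = 0,
                          pearson_r = 0, p_value = 1, n_genes = nrow(d)),
                     class = "neutrality_fit"))
  }
  fit <- lm(gc12 ~ gc3, data = d)
  tss <- sum((d$gc12 - mean(d$gc12))^2)
  rss <- sum(stats::residuals(fit)^2)
  ct <- suppressWarnings(cor.test(d$gc3, d$gc12))
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r2 = 1 - rss / tss,
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n_genes = nrow(d)
  ), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality fit (n = %d): GC12 = %.4f + %.4f * GC3;  R2 = %.4f, p = %.3g\n",
    x$n_genes, x$intercept, x$slope, x$r2, x$p_value))
  invisible(x)
}

#' Pearson correlation matrix of codon-usage indices
#'
#' Pairwise Pearson correlations (with two-sided p-values from the exact t
#' transformation on n-2 degrees of freedom, as given by [stats::cor.test()])
#' among the nine indices conventionally tabulated: A3s, T3s, G3s, C3s, GC,
#' GC1, GC2, GC3s and ENC. Significance stars: * p < 0.05, ** p < 0.01.
#'
#' @param profiles data.frame from [compositionProfile()].
#' @param enc_results data.frame from [enc()].
#' @param indices index columns to correlate (defaults to the conventional
#'   nine).
#' @return A list of class \code{"cub_cormat"}: \code{labels}, \code{r},
#'   \code{p} (symmetric matrices) and \code{stars} (character matrix).
#' @export
correlationMatrix <- function(profiles, enc_results,
                              indices = c("a3s", "t3s", "g3s", "c3s", "gc",
                                          "gc1", "gc2", "gc3s", "enc")) {
  d <- merge(profiles, enc_results[, c("gene_id", "enc")], by = "gene_id",
             sort = FALSE)
  m <- as.matrix(d[, indices])
  if (nrow(m) < 3) stop("need at least 3 genes")
  labels <- c(a3s = "A3s", t3s = "T3s", g3s = "G3s", c3s = "C3s", gc = "GC",
              gc1 = "GC1", gc2 = "GC2", gc3 = "GC3", gc12 = "GC12",
              gc3s = "GC3s", enc = "ENC")[indices]
  p <- r <- matrix(NA_real_, length(indices), length(indices),
                   dimnames = list(labels, labels))
  for (i in seq_along(indices)) {
    for (j in seq_len(i)) {
      xi <- m[, i]; xj <- m[, j]
      ok <- stats::complete.cases(xi, xj)
      if (stats::var(xi[ok]) == 0 || stats::var(xj[ok]) == 0) next
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      ct <- suppressWarnings(cor.test(xi[ok], xj[ok]))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(labels = labels, r = r, p = p, stars = stars),
            class = "cub_cormat")
}

#' @export
print.cub_cormat <- function(x, ...) {
  out <- matrix(sprintf("%.3f%s", x$r, x$stars), nrow(x$r),
                dimnames = dimnames(x$r))
  out[is.na(x$r)] <- "NA"
  out[upper.tri(out)] <- ""
  print(noquote(out))
  invisible(x)
}
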