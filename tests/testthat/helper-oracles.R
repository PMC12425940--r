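# Independent brute-force oracles. These walk raw strings / apply textbook
# formulas directly and share no code with the package internals they check.

.ORACLE_CODE <- local({
  dna <- Biostrings::GENETIC_CODE
  list(aa = dna, stops = names(dna)[dna == "*"])
})

# random clean CDS (character string, no terminal stop, no internal stop)
random_cds <- function(n_codons, gc_bias = 0.5) {
  sense <- setdiff(names(.ORACLE_CODE$aa), .ORACLE_CODE$stops)
  b3 <- substr(sense, 3, 3)
  w <- ifelse(b3 %in% c("G", "C"), gc_bias, 1 - gc_bias)
  paste0(sample(sense, n_codons, replace = TRUE, prob = w / sum(w)),
         collapse = "")
}

# named list of k random codon vectors
random_codon_lists <- function(k, n_codons = 60, gc_bias = 0.5) {
  out <- lapply(seq_len(k), function(i) {
    s <- random_cds(n_codons, gc_bias)
    substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
  })
  names(out) <- paste0("g", seq_len(k))
  out
}

# -- composition oracle: per-nucleotide tally over the raw string ------------
oracle_composition <- function(codons) {
  seqstr <- paste0(codons, collapse = "")
  chars <- strsplit(seqstr, "")[[1]]
  pos <- rep(1:3, length.out = length(chars))
  gcch <- chars %in% c("G", "C")
  aa <- .ORACLE_CODE$aa[codons]
  deg <- table(.ORACLE_CODE$aa[setdiff(names(.ORACLE_CODE$aa),
                                       .ORACLE_CODE$stops)])
  syn <- deg[aa] >= 2
  third <- substr(codons, 3, 3)
  # CodonW denominators: synonymous codons of amino acids able to end in b
  sense <- setdiff(names(.ORACLE_CODE$aa), .ORACLE_CODE$stops)
  aa_all <- .ORACLE_CODE$aa[sense]
  x3s <- sapply(c("A", "T", "G", "C"), function(b) {
    can <- unique(aa_all[deg[aa_all] >= 2 & substr(sense, 3, 3) == b])
    den <- sum(syn & aa %in% can)
    if (den == 0) return(NA_real_)
    sum(syn & third == b) / den
  })
  gc1 <- mean(gcch[pos == 1]); gc2 <- mean(gcch[pos == 2])
  list(gc = mean(gcch), gc1 = gc1, gc2 = gc2, gc3 = mean(gcch[pos == 3]),
       gc12 = (gc1 + gc2) / 2,
       gc3s = sum(syn & third %in% c("G", "C")) / sum(syn),
       a3s = x3s[["A"]], t3s = x3s[["T"]], g3s = x3s[["G"]],
       c3s = x3s[["C"]])
}

# -- RSCU oracle -------------------------------------------------------------
oracle_rscu <- function(codons) {
  sense <- setdiff(names(.ORACLE_CODE$aa), .ORACLE_CODE$stops)
  deg <- table(.ORACLE_CODE$aa[sense])
  sapply(sense, function(cod) {
    a <- .ORACLE_CODE$aa[[cod]]
    fam <- sense[.ORACLE_CODE$aa[sense] == a]
    n_fam <- sum(codons %in% fam)
    if (n_fam == 0) return(NA_real_)
    sum(codons == cod) * deg[[a]] / n_fam
  })
}

# -- ENC oracle: spreadsheet-style evaluation of Wright's formula ------------
oracle_enc <- function(codons) {
  sense <- setdiff(names(.ORACLE_CODE$aa), .ORACLE_CODE$stops)
  deg <- table(.ORACLE_CODE$aa[sense])
  fhat <- list()
  for (a in names(deg)[deg >= 2]) {
    fam <- sense[.ORACLE_CODE$aa[sense] == a]
    n <- sum(codons %in% fam)
    if (n < 2) next
    p <- sapply(fam, function(cod) sum(codons == cod)) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f > 0) fhat[[a]] <- c(k = deg[[a]], f = f)
  }
  fh <- do.call(rbind, fhat)
  fbar <- sapply(c(2, 3, 4, 6), function(k)
    if (any(fh[, "k"] == k)) mean(fh[fh[, "k"] == k, "f"]) else NA)
  names(fbar) <- c(2, 3, 4, 6)
  if (is.na(fbar["3"])) fbar["3"] <- mean(c(fbar["2"], fbar["4"]))
  if (any(is.na(fbar))) return(NA_real_)
  raw <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(max(raw, 20), 61))
}

# -- PR2 oracle: string walk over four-fold sites ----------------------------
oracle_pr2 <- function(codons) {
  fourfold <- c("GTT","GTC","GTA","GTG", "CCT","CCC","CCA","CCG",
                "ACT","ACC","ACA","ACG", "GCT","GCC","GCA","GCG",
                "GGT","GGC","GGA","GGG", "CTT","CTC","CTA","CTG",
                "TCT","TCC","TCA","TCG", "CGT","CGC","CGA","CGG")
  third <- substr(codons[codons %in% fourfold], 3, 3)
  c(x = sum(third == "G") / sum(third %in% c("G", "C")),
    y = sum(third == "A") / sum(third %in% c("A", "T")),
    n = length(third))
}

# -- OLS oracle: closed-form sums --------------------------------------------
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  syy <- sum(y^2) - sum(y)^2 / n
  r <- sxy / sqrt(sxx * syy)
  c(slope = slope, intercept = intercept, r2 = r^2, r = r)
}

# -- Pearson oracle ----------------------------------------------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# -- PCA oracle: eigendecomposition of the covariance matrix -----------------
oracle_pca_eigenvalues <- function(m) {
  cm <- sweep(m, 2, colMeans(m))
  ev <- eigen(stats::cov(cm), symmetric = TRUE, only.values = TRUE)$values
  # prcomp variance uses denominator n-1, as does cov(): directly comparable
  ev[ev > 1e-12 * max(ev)]
}
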