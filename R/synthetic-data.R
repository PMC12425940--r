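# default amino-acid frequencies: typical plant-protein composition, fixed
.default_aa_freq <- function() {
  f <- c(A = 0.075, R = 0.055, N = 0.040, D = 0.052, C = 0.018,
         Q = 0.038, E = 0.062, G = 0.068, H = 0.022, I = 0.048,
         L = 0.092, K = 0.060, M = 0.022, F = 0.042, P = 0.050,
         S = 0.082, T = 0.050, V = 0.068, W = 0.012, Y = 0.028)
  f / sum(f)
}

# default selection target: one codon per degenerate amino acid, C-ending
# where the family has one, else G-ending
.default_optimal_set <- function() {
  code <- .code()
  aas <- sort(unique(code$aa[!is.na(code$degeneracy) & code$degeneracy >= 2]))
  sets <- lapply(aas, function(a) {
    cods <- .codons_of(a)
    b3 <- substr(cods, 3, 3)
    if (any(b3 == "C")) cods[b3 == "C"][1] else cods[b3 == "G"][1]
  })
  setNames(sets, aas)
}

#' Parameters for the synthetic CDS generator
#'
#' Defines a gene set with known mutational GC3 pressure and translational
#' selection strength. Defaults emulate the statistical structure of a
#' monocot transcription-factor family: 151 genes, log-normal codon counts
#' with a 100-codon (300 nt) floor, per-gene GC3 pressure drawn from
#' Beta(15.5, 9.5) (mean 0.62, the G/C-rich third-position regime typical of
#' such sets), and, in the default mixed mode, per-gene selection weights
#' spread over [0, 0.3] so ENC spans roughly 35-60 while mean GC stays near
#' 0.56. (Because selection targets G/C-ending codons, realized GC3s in mixed
#' mode runs somewhat above the mutation-kernel mean of 0.62.)
#'
#' @param n_genes number of genes (default 151).
#' @param mode \code{"mixed"} (default), \code{"mutation"} (no selection;
#'   amino-acid usage coupled to GC pressure so GC12 co-varies with GC3), or
#'   \code{"selection"} (fixed high selection weight).
#' @param gc_pressure per-gene probability of a G/C third base under the
#'   mutation kernel; scalar, vector of length \code{n_genes}, or NULL to
#'   draw from \code{Beta(gc_beta[1], gc_beta[2])}.
#' @param gc_beta Beta parameters for drawn GC pressure (default
#'   \code{c(15.5, 9.5)}).
#' @param selection_weight per-site probability of drawing the codon from the
#'   optimal set instead of the mutation kernel; scalar, vector, or NULL for
#'   the mode default (mutation: 0; selection: 0.8; mixed: Uniform(0, 0.3)
#'   per gene).
#' @param coupling coefficient tilting amino-acid frequencies by the GC
#'   content of each family's first two codon positions; NULL for the mode
#'   default (4 in mutation mode, 0 otherwise). Positive coupling gives the
#'   neutrality plot a recoverable positive slope.
#' @param optimal_set named list mapping amino acid to preferred codon(s)
#'   (DNA or RNA); default one C/G-ending codon per degenerate family.
#' @param aa_frequencies named amino-acid probability vector (normalized
#'   internally).
#' @param length_meanlog,length_sdlog log-normal parameters for the internal
#'   codon count (defaults log(170), 0.35).
#' @param min_codons minimum internal codon count (default 100, i.e. >= 300
#'   nt before the initiation and stop codons are added).
#' @param seed integer seed; each gene uses a substream keyed on
#'   \code{(seed, gene index)}, so the same seed gives byte-identical output
#'   and enlarging \code{n_genes} leaves earlier genes unchanged.
#' @return A list of class \code{"sim_params"}.
#' @export
simulationParams <- function(n_genes = 151L,
                             mode = c("mixed", "mutation", "selection"),
                             gc_pressure = NULL,
                             gc_beta = c(15.5, 9.5),
                             selection_weight = NULL,
                             coupling = NULL,
                             optimal_set = .default_optimal_set(),
                             aa_frequencies = .default_aa_freq(),
                             length_meanlog = log(170),
                             length_sdlog = 0.35,
                             min_codons = 100L,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(coupling)) coupling <- if (mode == "mutation") 4 else 0
  if (is.null(selection_weight) && mode == "mutation") selection_weight <- 0
  if (is.null(selection_weight) && mode == "selection") selection_weight <- 0.8
  if (mode == "selection" &&
      (length(optimal_set) == 0L || any(lengths(optimal_set) == 0L)))
    stop("selection mode requires a non-empty optimal_set")
  aa_frequencies <- aa_frequencies / sum(aa_frequencies)
  structure(list(
    n_genes = as.integer(n_genes), mode = mode, gc_pressure = gc_pressure,
    gc_beta = gc_beta, selection_weight = selection_weight,
    coupling = coupling, optimal_set = lapply(optimal_set, toDna),
    aa_frequencies = aa_frequencies, length_meanlog = length_meanlog,
    length_sdlog = length_sdlog, min_codons = as.integer(min_codons),
    seed = as.integer(seed)
  ), class = "sim_params")
}

# GC fraction of the first two positions, averaged over a family's codons
.family_gc12 <- function(aa1) {
  cods <- .codons_of(aa1)
  mean((substr(cods, 1, 1) %in% c("G", "C")) +
         (substr(cods, 2, 2) %in% c("G", "C"))) / 2
}

# deterministic substream seed for gene i (kept below 2^31)
.gene_seed <- function(seed, i) {
  (as.double(seed) * 69069 + as.double(i) * 1000003) %% 2147483629
}

#' Generate a synthetic CDS set
#'
#' For each gene, amino acids are drawn i.i.d. from the (possibly
#' GC-pressure-tilted) amino-acid frequencies; each site's codon comes from
#' the gene's optimal set with probability \code{selection_weight}, otherwise
#' from the mutation kernel, which weights each family codon by
#' \code{gc_pressure} for a G/C third base and \code{1 - gc_pressure} for an
#' A/T third base. Sequences are ATG-initiated and stop-terminated. Each gene
#' is generated in its own random substream, so output is byte-identical for
#' a given seed and extending \code{n_genes} does not disturb earlier genes.
#'
#' @param params a [simulationParams()] object.
#' @return A list with \code{sequences} (named [Biostrings::DNAStringSet])
#'   and \code{truth} (data.frame: gene_id, n_codons, length_nt, gc_pressure,
#'   selection_weight; the full \code{params} are attached as the
#'   \code{"params"} attribute).
#' @examples
#' sim <- simulateCdsSet(simulationParams(n_genes = 5, seed = 7))
#' sim$truth$gene_id
#' @export
simulateCdsSet <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  code <- .code()
  aas <- names(params$aa_frequencies)
  g12 <- vapply(aas, .family_gc12, numeric(1))
  fam <- lapply(setNames(aas, aas), .codons_of)
  b3gc <- lapply(fam, function(cods) substr(cods, 3, 3) %in% c("G", "C"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  seqs <- character(params$n_genes)
  truth <- vector("list", params$n_genes)
  for (i in seq_len(params$n_genes)) {
    set.seed(.gene_seed(params$seed, i))
    n_cod <- max(params$min_codons,
                 as.integer(round(rlnorm(1, params$length_meanlog,
                                         params$length_sdlog))))
    p <- if (is.null(params$gc_pressure))
           rbeta(1, params$gc_beta[1], params$gc_beta[2])
         else if (length(params$gc_pressure) > 1) params$gc_pressure[i]
         else params$gc_pressure
    s <- if (is.null(params$selection_weight)) runif(1, 0, 0.3)
         else if (length(params$selection_weight) > 1)
           params$selection_weight[i]
         else params$selection_weight
    w_aa <- params$aa_frequencies * exp(params$coupling * (2 * p - 1) * g12)
    aa_draw <- sample(aas, n_cod, replace = TRUE, prob = w_aa)
    use_opt <- runif(n_cod) < s
    u <- runif(n_cod)
    codons <- character(n_cod)
    for (a in unique(aa_draw)) {
      idx <- which(aa_draw == a)
      kernel <- ifelse(b3gc[[a]], p, 1 - p)
      kernel <- kernel / sum(kernel)
      opt <- params$optimal_set[[a]] %||% fam[[a]]
      sel <- use_opt[idx] & a %in% names(params$optimal_set)
      cw_mut <- cumsum(kernel)
      cw_mut[length(cw_mut)] <- 1          # guard against fp undershoot
      codons[idx[!sel]] <- fam[[a]][findInterval(u[idx[!sel]], cw_mut,
                                                 left.open = TRUE) + 1L]
      if (any(sel)) {
        cw_opt <- cumsum(rep(1 / length(opt), length(opt)))
        cw_opt[length(cw_opt)] <- 1
        codons[idx[sel]] <- opt[findInterval(u[idx[sel]], cw_opt,
                                             left.open = TRUE) + 1L]
      }
    }
    stop_cod <- code$stop_codons[sample.int(3L, 1L)]
    seqs[i] <- paste0("ATG", paste0(codons, collapse = ""), stop_cod)
    truth[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i), n_codons = n_cod,
      length_nt = 3L * (n_cod + 2L), gc_pressure = p, selection_weight = s,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  attr(truth, "params") <- params
  out <- Biostrings::DNAStringSet(setNames(seqs, truth$gene_id))
  list(sequences = out, truth = truth)
}

#' Regenerate a simulated CDS set from its truth table
#'
#' @param truth a truth data.frame from [simulateCdsSet()] (with its
#'   \code{"params"} attribute intact).
#' @return A named [Biostrings::DNAStringSet], byte-identical to the original
#'   generation.
#' @export
regenerate <- function(truth) {
  params <- attr(truth, "params")
  if (is.null(params) || is.null(params$seed))
    stop("truth table lacks generation parameters (seed)")
  simulateCdsSet(params)$sequences
}
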