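#' Default pipeline configuration
#'
#' All thresholds and dialect switches that affect any number the pipeline
#' emits, with their defaults. Every entry is echoed into the run manifest.
#'
#' @param ... overrides for any config entry.
#' @return A named list of class \code{"cub_config"}.
#' @export
cubConfig <- function(...) {
  cfg <- list(
    min_length = 300L,          # nt; shorter CDS are rejected
    frame = "reject",           # length not multiple of 3: reject | trim
    internal_stop = "reject",   # reject | mask
    x3s_dialect = "codonw",     # codonw | strict
    pr2_sites = "fourfold",     # fourfold | all
    enc_impute_f3 = TRUE,       # impute the Ile class when unobserved
    enc_plot_abscissa = "gc3s", # gc3s | gc3
    deviation_tau = 0.1,        # "noticeably below the curve" threshold
    group_fraction = 0.10,      # extreme-group size fraction
    delta_threshold = 0.08,     # delta-RSCU cutoff
    rscu_threshold = 1.0,       # high-frequency cutoff (strict >)
    scree_rows = 20L,           # components printed in scree.tsv
    plots = FALSE,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "cub_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of [cubConfig()] keys.
#' @return A \code{"cub_config"} list.
#' @export
readCubConfig <- function(path) {
  do.call(cubConfig, yaml::read_yaml(path))
}

.write_tsv <- function(d, dir, name, digits = 3L) {
  full <- d
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) formatC(v, digits = digits,
                                               format = "f"))
  write.table(d, file.path(dir, paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(full, file.path(dir, paste0(name, "_full.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the full codon-usage-bias pipeline
#'
#' Validates and tokenizes the input CDS set, then computes composition
#' profiles, per-gene ENC, pooled RSCU, ENC-plot / PR2 / neutrality
#' diagnostics, the index correlation matrix, PCA of the RSCU matrix, and the
#' delta-RSCU optimal-codon table, writing the full TSV bundle plus a run
#' manifest to \code{outdir}. Report tables are rounded to 3 decimals; each
#' has a full-precision \code{*_full.tsv} twin. Per-gene rejections are
#' written to \code{rejects.tsv} and never abort the batch.
#'
#' @param input path to a CDS FASTA file, or a [Biostrings::DNAStringSet].
#' @param outdir output directory (created if missing).
#' @param config a [cubConfig()] list.
#' @return Invisibly, a list with all in-memory results.
#' @export
runCubPipeline <- function(input, outdir, config = cubConfig()) {
  seqs <- if (is.character(input)) readCdsFasta(input) else input
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  policy <- cdsPolicy(min_length = config$min_length, frame = config$frame,
                      internal_stop = config$internal_stop)
  val <- validateCds(seqs, policy)
  write.table(val$rejects, file.path(outdir, "rejects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(val$codons) == 0L) stop("zero valid genes after validation")
  cc <- countCodons(val)

  prof <- compositionProfile(cc, x3s_dialect = config$x3s_dialect)
  enc_res <- enc(cc, impute_f3 = config$enc_impute_f3)
  pooled <- pooledRscu(cc)
  hf <- highFrequencyCodons(pooled)

  comp_out <- prof[, c("gene_id", "a3s", "t3s", "g3s", "c3s", "gc",
                       "gc1", "gc2", "gc3", "gc12", "gc3s")]
  names(comp_out) <- c("gene_id", "A3s", "T3s", "G3s", "C3s", "GC",
                       "GC1", "GC2", "GC3", "GC12", "GC3s")
  .write_tsv(comp_out, outdir, "composition")

  code <- .code()
  pooled_out <- data.frame(
    amino_acid = code$aa[match(toDna(names(pooled)), code$codons)],
    codon = names(pooled),
    count = rowSums(codonCounts(cc))[toDna(names(pooled))],
    rscu = unname(pooled),
    high_frequency = names(pooled) %in% hf
  )
  pooled_out <- pooled_out[order(pooled_out$amino_acid, pooled_out$codon), ]
  .write_tsv(pooled_out, outdir, "rscu_pooled")

  .write_tsv(enc_res[, c("gene_id", "enc", "capped", "imputed_classes",
                         "qc_ok")], outdir, "enc")

  ep <- encPlotTable(prof, enc_res, tau = config$deviation_tau,
                     abscissa = config$enc_plot_abscissa)
  .write_tsv(ep, outdir, "enc_plot")

  pr2 <- pr2Point(cc, sites = config$pr2_sites)
  .write_tsv(pr2, outdir, "pr2")

  nf <- neutralityFit(prof)
  neut <- cbind(
    data.frame(slope = nf$slope, intercept = nf$intercept, r2 = nf$r2,
               pearson_r = nf$pearson_r, p_value = nf$p_value,
               n_genes = nf$n_genes)
  )
  .write_tsv(neut, outdir, "neutrality")
  .write_tsv(prof[, c("gene_id", "gc3", "gc12")], outdir, "neutrality_points")

  cm <- correlationMatrix(prof, enc_res)
  long <- do.call(rbind, lapply(seq_along(cm$labels), function(i)
    do.call(rbind, lapply(seq_len(i - 1), function(j)
      data.frame(index_a = cm$labels[i], index_b = cm$labels[j],
                 r = cm$r[i, j], p = cm$p[i, j], stars = cm$stars[i, j])))))
  .write_tsv(long, outdir, "correlations")

  rm_mat <- buildRscuMatrix(cc)
  pca <- rscuPca(rm_mat)
  k <- min(config$scree_rows, length(pca$explained_pct))
  .write_tsv(data.frame(component = seq_len(k),
                        explained_pct = pca$explained_pct[seq_len(k)],
                        cumulative_pct = pca$cumulative_pct[seq_len(k)]),
             outdir, "scree")
  ends <- codonEndingGroups(rownames(rm_mat))
  npc <- min(2L, ncol(pca$scores))
  scores <- data.frame(codon = rownames(rm_mat),
                       pca$scores[, seq_len(npc), drop = FALSE],
                       third_base = unname(ends))
  names(scores)[1 + seq_len(npc)] <- paste0("PC", seq_len(npc))
  .write_tsv(scores, outdir, "scores")

  groups <- extremeGroups(enc_res, fraction = config$group_fraction)
  dr <- deltaRscuTable(cc, groups, delta_threshold = config$delta_threshold,
                       rscu_threshold = config$rscu_threshold)
  .write_tsv(dr, outdir, "optimal_codons")

  manifest <- c(
    list(package = "cubana", version = as.character(packageVersion("cubana")),
         n_input = length(seqs), n_accepted = ncol(cc),
         n_rejected = nrow(val$rejects),
         high_expression_group = groups$high_expression,
         low_expression_group = groups$low_expression),
    unclass(config)
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  if (isTRUE(config$plots)) {
    plotEncCurve(ep, file.path(outdir, "enc_plot.png"))
    plotPr2(pr2, file.path(outdir, "pr2.png"))
    plotNeutrality(prof, nf, file.path(outdir, "neutrality.png"))
  }
  invisible(list(counts = cc, profiles = prof, enc = enc_res,
                 pooled_rscu = pooled, high_frequency = hf,
                 enc_plot = ep, pr2 = pr2, neutrality = nf,
                 correlations = cm, pca = pca, groups = groups,
                 delta_rscu = dr, optimal = optimalCodonSet(dr),
                 rejects = val$rejects))
}

#' Quick-look diagnostic plots
#'
#' Minimal base-graphics renderings of the three diagnostic scatter plots.
#' These are working plots, not publication figures.
#'
#' @param ep,pr2,profiles,fit tables as produced by the corresponding
#'   functions.
#' @param file optional PNG path; if NULL, draws on the current device.
#' @return Invisibly, NULL.
#' @name cubPlots
#' @export
plotEncCurve <- function(ep, file = NULL) {
  .with_png(file, {
    s <- seq(0, 1, length.out = 200)
    plot(ep$gc3s, ep$enc, xlim = c(0, 1), ylim = c(15, 62),
         xlab = "GC3s", ylab = "ENC", pch = 19, col = "grey30")
    graphics::lines(s, encExpected(s), col = "red")
  })
}

#' @rdname cubPlots
#' @export
plotPr2 <- function(pr2, file = NULL) {
  .with_png(file, {
    plot(pr2$x, pr2$y, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)", pch = 19, col = "grey30")
    graphics::abline(h = 0.5, v = 0.5, lty = 2)
  })
}

#' @rdname cubPlots
#' @export
plotNeutrality <- function(profiles, fit, file = NULL) {
  .with_png(file, {
    plot(profiles$gc3, profiles$gc12, xlab = "GC3", ylab = "GC12",
         pch = 19, col = "grey30")
    graphics::abline(fit$intercept, fit$slope, col = "red")
  })
}

.with_png <- function(file, expr) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 600)
    on.exit(grDevices::dev.off())
  }
  force(expr)
  invisible(NULL)
}
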