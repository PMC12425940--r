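test_that("generation is seed-reproducible with per-gene substreams", {
  p <- simulationParams(n_genes = 10, seed = 7)
  s1 <- simulateCdsSet(p)
  s2 <- simulateCdsSet(p)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$truth, s2$truth)

  # different seeds differ
  s3 <- simulateCdsSet(simulationParams(n_genes = 10, seed = 8))
  expect_false(identical(as.character(s1$sequences),
                         as.character(s3$sequences)))

  # enlarging the set leaves earlier genes untouched
  s4 <- simulateCdsSet(simulationParams(n_genes = 25, seed = 7))
  expect_identical(unname(as.character(s4$sequences)[1:10]),
                   unname(as.character(s1$sequences)))

  # regenerate() round trip; missing params is an error
  expect_identical(as.character(regenerate(s1$truth)),
                   as.character(s1$sequences))
  bare <- s1$truth
  attr(bare, "params") <- NULL
  expect_error(regenerate(bare), "seed")

  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulateCdsSet(p)); after <- runif(3)
  expect_identical(before, after)
})

test_that("generated genes are valid ATG-initiated, stop-terminated CDS", {
  sim <- simulateCdsSet(simulationParams(n_genes = 20, seed = 11))
  seqs <- as.character(sim$sequences)
  expect_true(all(substr(seqs, 1, 3) == "ATG"))
  expect_true(all(substring(seqs, nchar(seqs) - 2) %in%
                    c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(seqs) %% 3 == 0))
  expect_true(all(nchar(seqs) >= 306))
  expect_equal(sim$truth$length_nt, nchar(seqs), ignore_attr = TRUE)
  # no internal stops: validation under the strict policy keeps every gene
  v <- validateCds(sim$sequences)
  expect_equal(nrow(v$rejects), 0)
})

test_that("full selection onto singleton codons drives ENC to 20", {
  sim <- simulateCdsSet(simulationParams(n_genes = 5, mode = "selection",
                                         selection_weight = 1, seed = 3))
  e <- enc(countCodons(sim$sequences))
  expect_equal(e$enc, rep(20, 5))
})

test_that("unselected uniform-pressure genes approach ENC 61 and uniform families", {
  sim <- simulateCdsSet(simulationParams(
    n_genes = 8, mode = "mutation", gc_pressure = 0.5, coupling = 0,
    length_meanlog = log(1200), length_sdlog = 0.01, seed = 5))
  e <- enc(countCodons(sim$sequences))
  expect_gt(mean(e$enc), 59)   # within 2 of the no-bias ceiling
})

test_that("the mutation kernel delivers the requested G/C-ending share", {
  sim <- simulateCdsSet(simulationParams(
    n_genes = 10, mode = "mutation", gc_pressure = 0.9, coupling = 0,
    length_meanlog = log(400), length_sdlog = 0.01, seed = 13))
  cc <- countCodons(sim$sequences)
  code <- geneticCode()
  # two-fold families: expected G/C-ending share 0.9
  twofold_aa <- names(which(table(code$aa[code$aa != "*"]) == 2))
  cnt <- codonCounts(cc)
  cods2 <- code$codons[code$aa %in% twofold_aa]
  gc_end <- substr(cods2, 3, 3) %in% c("G", "C")
  n_gc <- sum(cnt[cods2[gc_end], ])
  n_tot <- sum(cnt[cods2, ])
  se <- sqrt(0.9 * 0.1 / n_tot)
  expect_lt(abs(n_gc / n_tot - 0.9), 3 * se)
})

test_that("parameter recovery separates selection from mutation regimes", {
  slopes_sel <- numeric(0); devs_sel <- numeric(0)
  slopes_mut <- numeric(0)
  for (r in 1:6) {
    sel <- simulateCdsSet(simulationParams(
      n_genes = 60, mode = "selection", selection_weight = 0.8,
      gc_pressure = 0.5, seed = 1000 + r))
    cc <- countCodons(sel$sequences)
    prof <- compositionProfile(cc)
    er <- enc(cc)
    slopes_sel <- c(slopes_sel, neutralityFit(prof)$slope)
    devs_sel <- c(devs_sel, mean(encPlotTable(prof, er)$deviation))

    mut <- simulateCdsSet(simulationParams(
      n_genes = 60, mode = "mutation", seed = 2000 + r))
    ccm <- countCodons(mut$sequences)
    slopes_mut <- c(slopes_mut, neutralityFit(compositionProfile(ccm))$slope)
  }
  expect_true(all(slopes_sel < 0.3))
  expect_true(all(devs_sel > 0))
  expect_true(all(slopes_mut > 0.3))
  # one-sided location tests
  expect_lt(t.test(devs_sel, alternative = "greater")$p.value, 0.01)
  expect_lt(t.test(slopes_mut - 0.3, alternative = "greater")$p.value, 0.01)
})

test_that("PR2 centroid sits at parity only for symmetric kernels", {
  sym <- simulateCdsSet(simulationParams(
    n_genes = 30, mode = "mutation", gc_pressure = 0.5, coupling = 0,
    seed = 21))
  p_sym <- pr2Point(countCodons(sym$sequences))
  expect_lt(abs(mean(p_sym$x) - 0.5), 0.02)
  expect_lt(abs(mean(p_sym$y) - 0.5), 0.02)

  # selection toward C-preferring optimal set drags x below 0.5
  asym <- simulateCdsSet(simulationParams(
    n_genes = 30, mode = "selection", selection_weight = 0.7,
    gc_pressure = 0.5, seed = 22))
  p_asym <- pr2Point(countCodons(asym$sequences))
  expect_lt(mean(p_asym$x), 0.4)
})

test_that("invalid parameters are rejected", {
  expect_error(simulationParams(mode = "selection", optimal_set = list()),
               "optimal_set")
})
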