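---
title: "Codon usage bias methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubana)
```

`cubana` computes codon usage bias (CUB) statistics for a set of coding
sequences and the classical diagnostics that separate the two forces shaping
them: directional mutation pressure on base composition and translational
selection for preferred codons. This vignette records the exact conventions
implemented, the reasoning behind choices that the literature leaves open,
and what the accompanying tests do and do not establish.

## Sequence handling and the genetic code

All statistics derive from one object, the `CodonCounts` container: a
64 × n-genes matrix of in-frame codon counts (a `SummarizedExperiment`
subclass, codons as rows). The genetic code is fixed to the standard nuclear
code (translation table 1); the package targets nuclear plant genes and
offers no hook for alternative codes.

Validation policy (`cdsPolicy()`), applied before counting:

* **Minimum length 300 nt** — the conventional floor for a credible complete
  CDS from a screened transcriptome; shorter records are rejected.
* **Frame**: lengths not divisible by 3 are rejected by default (`trim`
  optionally drops the 1–2 nt tail). A screened CDS should be in frame;
  silent trimming hides upstream errors.
* **Terminal stop codons** are recorded and stripped: stops have no
  synonymous family and would distort third-position tallies.
* **Internal stops** are rejected by default (they indicate a frame or
  assembly error); `mask` demotes them to skipped codons with a warning.
* **Ambiguity codes** (N, R, Y, …) invalidate only the containing codon,
  which is skipped and counted per gene (`n_skipped_ambiguous`) for QC; a
  single N should not discard an otherwise clean gene.

Rejections are collected, never fatal to the batch — the pipeline mirrors a
screening workflow in which individual candidates routinely drop out.

Codon names are reported in the RNA alphabet (AUG, not ATG), the convention
of codon-usage tables; sequences are stored as DNA internally.

## Composition indices

Per gene, from counts over sense codons: GC (per-nucleotide G+C of the
stop-stripped CDS, all three positions weighted equally), GC1/GC2/GC3
(positional G+C over **all** sense codons), GC12 = (GC1+GC2)/2, and GC3s
(third-position G+C over **synonymous** codons only: amino acids with
degeneracy ≥ 2, so Met and Trp are excluded but isoleucine is included).

GC3 and GC3s are deliberately kept as two distinct columns and never
aliased: the neutrality plot regresses on GC3 (all sense codons) while the
ENC-plot abscissa is GC3s. Much of the literature blurs the two; keeping
both makes every downstream table unambiguous, and the ENC-plot abscissa is
switchable (`enc_plot_abscissa`) for comparison with tools that used GC3.

The third-position base frequencies A3s/T3s/G3s/C3s follow the **CodonW
dialect**: the frequency of base *x* is the number of synonymous codons
ending in *x* divided by the number of synonymous codons *belonging to amino
acids that can end in x*. (Phenylalanine codons, for instance, never enter
the A3s denominator because no Phe codon ends in A.) The four frequencies
therefore do not sum to 1 except when every family present is four-fold
degenerate. This dialect was chosen because it is what the classical
tool chain computes and what published index tables of this kind contain; a
`strict` dialect (single denominator, frequencies summing to 1) is available
as a config switch.

## RSCU and the 56-codon analysis set

RSCU(c) = count(c)·k/n over each amino-acid family; within every used family
the values sum to the degeneracy k (asserted to 1e-9 in the tests). Families
never used yield `NA`, never 0 — a zero RSCU is a strong statement (codon
avoided), not a missing one.

Group-level RSCU is computed by **pooling counts** (summing, then applying
the formula), not by averaging per-gene RSCU values. Pooling is the
CodonW/EMBOSS convention, weights genes by their usage, and keeps family
sums exact; averaging per-gene ratios does neither.

Reporting, PCA and optimal-codon classification restrict to the standard
**56-codon analysis set**: the 61 sense codons minus AUG (initiation), UGG
(sole Trp codon) and the three isoleucine codons. AUG and UGG carry no
synonymous choice; isoleucine's three-codon family is conventionally dropped
alongside them in this analysis tradition. High-frequency codons are those
with pooled RSCU strictly > 1.

## Wright's effective number of codons

Per amino acid with usage n ≥ 2, homozygosity F̂ = (n·Σp̂ᵢ² − 1)/(n − 1);
class means F̄ₖ are taken over amino acids with n ≥ 2 and F̂ > 0, and

Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆.

Numerical choices:

* **Wright's original estimator**, with six-fold families treated as single
  families. This matches the classical tool chain and the 20–61 bounds
  quoted everywhere; variants that split Leu/Ser/Arg into 2+4 subfamilies
  give systematically different values.
* **n < 2 contributes nothing**: F̂ divides by n − 1 and is undefined at a
  single observation.
* **F̂ ≤ 0 is dropped** from the class mean; a non-positive homozygosity is
  a finite-sample artifact that would otherwise explode 1/F̄.
* **Missing isoleucine** (the only 3-fold amino acid) is imputed as
  F̄₃ = (F̄₂+F̄₄)/2 and recorded in `imputed_classes`; short genes often lack
  Ile entirely, and losing ENC for them is worse than this mild
  interpolation. The switch `enc_impute_f3 = FALSE` disables it.
* **Classes 2, 4 or 6 unobservable** ⇒ ENC is `NA` with `qc_ok = FALSE`,
  never silently imputed — those classes carry 9, 5 and 3 amino acids and
  their absence means the gene is not a credible CDS sample.
* **Capping into [20, 61]** with a `capped` flag: finite-sample F̂ routinely
  pushes the raw formula above the theoretical no-bias ceiling of 61.

ENC is only asymptotically scale-invariant: the n/(n−1) correction shifts
the value by O(1/n) when all counts are doubled, an effect of order one unit
at a few hundred codons. The test suite asserts near-invariance (< 0.5) at
2000 codons, where the limit behavior is visible.

## Diagnostics

**ENC-plot.** Observed ENC against GC3s, with the composition-only
expectation Nc\* = 2 + s + 29/(s² + (1−s)²). The classical sources describe
"the standard curve" without printing a formula; this closed form is the
de-facto standard implemented by the usual plotting scripts and is exposed
in the documentation and config. The relative deviation
(Nc\* − Nc)/Nc\* quantifies "noticeably below the curve"; the threshold
τ = 0.1 is configurable because no published number exists — it is an
order-of-magnitude choice meant to sit above sampling scatter around the
curve, and every classification the pipeline emits records the τ used.

**PR2 bias plot.** A3/(A3+T3) against G3/(G3+C3), tallied over the eight
four-fold degenerate families (Val, Pro, Thr, Ala, Gly and the four-fold
subsets of Leu, Ser, Arg) — Sueoka's construction, in which the amino acid
is held fixed and any departure from (0.5, 0.5) must come from mutation
asymmetry or selection. An `all` site dialect (all synonymous third
positions) is provided for comparison with looser implementations. Points
with an empty denominator (no A/T-ending or no G/C-ending usage) are `NA`
with a QC flag rather than 0 or 1.

**Neutrality plot.** OLS of GC12 on GC3 via `lm()`, with R² computed from
residual and total sums of squares and Pearson r/p from `cor.test()`. A
constant-GC12 input returns slope 0 and R² = 0 exactly (the natural limit),
and a constant-GC3 regressor is an error. Fewer than 3 genes is an error.

**Correlation matrix.** Pairwise Pearson r among the nine conventional
indices with two-sided p from the exact t transformation on n − 2 df
(`cor.test()`), starred \*/\*\* at 0.05/0.01. Constant columns give `NA`
rows rather than failing.

## PCA of the RSCU matrix

The 56 × n-genes RSCU matrix is decomposed with **codons as observations and
genes as variables**, column-mean-centered, unscaled, via SVD (`prcomp`).
This orientation — reducing the gene dimension — follows the convention of
treating each codon's usage profile across genes as the observation being
embedded; the transposed analysis can be run by passing the transposed
matrix. Covariance (not correlation) PCA is used because RSCU values are
already on a common, dimensionless scale; correspondence analysis, the other
tradition in CUB work, is out of scope. Missing families are imputed as 0
with a mask recorded. Signs are fixed deterministically (largest-magnitude
score of each component made positive) so results are identical across
linear-algebra backends; explained percentages are reported over all
components and always sum to 100.

## Optimal codons by ΔRSCU

Genes are sorted by ENC (ties broken lexicographically by gene id, making
membership deterministic); the lowest decile (floor(0.10·n), minimum 1) is
the putative high-expression group, the highest decile the low-expression
group. Pooled RSCU is computed within each group; a codon is
*highly expressed* when ΔRSCU = RSCU_high − RSCU_low ≥ 0.08, *high
frequency* when its genome-wide pooled RSCU > 1, and **optimal** when both.
Within every family ΔRSCU sums to zero exactly, a consequence of pooling —
the tests assert it at 1e-9.

`deltaRscuFromTable()` applies the same classifier to an externally supplied
group-RSCU table, so published tables can be re-analyzed without sequences.
Ingestion QC checks that each group's family RSCU values sum to the family
degeneracy within 0.05 (generous for values printed to two decimals);
families failing are flagged `family_sum_ok = FALSE` but still classified.
In the bundled WRKY reference table exactly two families (Cys and Gly) fail
this check — their published high-expression values sum to 1.85 and 4.15
instead of 2 and 4, evidently transcription errors — and the flag makes that
visible instead of hiding it. The classification itself is insensitive to
these defects.

## The synthetic generator

`simulateCdsSet()` emulates the statistical structure the analysis assumes,
not molecular evolution: there is no phylogeny, no substitution matrix, no
indels and no real protein content. Per gene, amino acids are drawn i.i.d.
from fixed frequencies (a typical plant-protein composition) and each site's
codon comes from a two-component mixture:

* with probability `selection_weight`, uniformly from the gene's
  **optimal set** (default: one C-ending codon per degenerate family, or
  G-ending where no C exists);
* otherwise from the **mutation kernel**, which weights each family codon by
  `gc_pressure` for a G/C third base and 1 − `gc_pressure` for A/T.

In mutation mode the amino-acid draw is additionally tilted by
exp(coupling · (2p − 1) · gc12(aa)), where gc12(aa) is the mean G+C of the
family's first two positions — the minimal mechanism by which third-position
pressure propagates into GC12 and gives the neutrality plot a recoverable
positive slope. The coupling default of 4 was chosen once, from the
small-perturbation relation slope ≈ 2·coupling·var(gc12(aa)), so that
mutation-mode replicates sit clearly above the 0.3 slope that separates the
regimes in the recovery tests; it is configurable.

Default calibration (chosen once, as the package's reference conditions):
151 genes; log-normal internal codon counts (meanlog log 170, sdlog 0.35,
floor 100 codons = 300 nt); per-gene GC pressure ~ Beta(15.5, 9.5), mean
0.62 — the G/C-rich third-position regime of a monocot transcription-factor
family; mixed-mode selection weights ~ Uniform(0, 0.3), which keeps overall
GC near 0.56 and spreads ENC over roughly 35–60. Because selection targets
G/C-ending codons, realized GC3s in mixed mode runs above the kernel mean
(≈ 0.65–0.68); the 0.62 kernel mean is realized directly in mutation mode.
These are calibration targets for realism, never test assertions.

Reproducibility contract: every gene is generated in its own RNG substream
keyed on (seed, gene index), so the same seed is byte-identical, enlarging
`n_genes` leaves earlier genes unchanged, and `regenerate()` rebuilds a set
from its truth table. The generator saves and restores the caller's RNG
state.

What passing the recovery tests shows: the pipeline correctly attributes
codon bias to composition versus selection *when the data really are an
i.i.d. mixture of those two forces*. Real gene families add phylogenetic
correlation between paralogs, length- and expression-dependent bias,
context effects and domain-driven amino-acid composition, none of which the
generator produces; recovery on synthetic data is a necessary check, not
evidence about any real genome.

## Problem sizes and determinism

The test suite and acceptance checks run the oracle comparisons on dozens of
random small fixtures (60–200 codons, 3–50 genes) and the regime-recovery
check on 10 replicate sets per regime at the full 151-gene default — sizes
at which every statistic is well-conditioned while the whole suite stays
fast. All randomness flows through explicit seeds; pipeline reruns are
asserted byte-identical, and no output depends on wall clock, locale or hash
iteration order.

## Known limitations

* Single genetic code (standard nuclear); no mitochondrial/plastid tables.
* No CAI, Fop or tAI — indices that need an external reference set.
* Correspondence analysis of RSCU is not implemented (PCA only).
* The ENC-plot, PR2 and neutrality outputs are tables plus quick-look plots;
  publication graphics are left to the user.
* ENC for very short genes rests on the Ile imputation rule; cross-tool
  comparisons should fix the same rule (`enc_impute_f3`).
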