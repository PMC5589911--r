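---
title: "Discriminating X inactivation from X dampening in single-cell allelic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating X inactivation from X dampening in single-cell allelic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcitrace)
library(dplyr)
```

## The question

Female mammalian cells carry two X chromosomes against the male's one, and
development must compensate the dose. The classical route is X chromosome
inactivation (XCI): one X per cell is transcriptionally silenced, gene by
gene, so X-linked genes become *monoallelically* expressed. An alternative
proposal for human preimplantation embryos is X *dampening*: both X copies
stay active but are partially downregulated, so expression stays
*biallelic* at reduced per-allele output. The two mechanisms produce the
same bulk trajectory — total female X output falls toward the male level —
which is exactly why bulk dosage curves cannot separate them.

xcitrace implements an allele-resolution analysis that can. From per-cell,
per-SNP reference/alternative read counts it calls each heterozygous site
biallelic or monoallelic, aggregates calls into embryo-level gene
informativeness, and tracks three statistics across developmental stages
that react differently to the two mechanisms:

1. **Fractions.** The per-cell fraction of X-linked genes with biallelic
   calls falls under XCI and stays flat under dampening; the monoallelic
   fraction rises only under random XCI.
2. **Sum vs median.** Over the X-linked genes still biallelically expressed
   in a female cell, the *sum* of expression falls under both mechanisms,
   but the *median* falls only under dampening — under XCI the surviving
   biallelic genes are expressed from two unweakened alleles.
3. **Female-to-male ratio.** For genes biallelically expressed in females,
   the gene-wise ratio of female to male mean expression approaches 1 under
   dampening (two weakened alleles ≈ one normal allele) and 2 under XCI
   (two normal alleles vs one).

A fourth axis, the X:A ratio (median expression of X-linked over autosomal
genes per cell), locates the dose itself: ≈1 with two active X's or one
upregulated X, ≈0.5 with a single non-upregulated X.

## The calling procedure and its filters

Allelic calls from single cells are fragile, so every call must clear a
stack of filters before it counts:

* **Coverage**: at least 20 reads over the SNP (`allelic.min_reads`), and
  the same SNP at that depth in at least two cells of the same embryo. At
  20 reads a monoallelic site has a ~1% chance of faking a biallelic call
  from ~2.5% sequencing error, and allelic dropout rarely fakes
  monoallelic expression.
* **Annotation**: ambiguous dbSNP-style IDs (same ID at several positions),
  SNPs without a unique gene, and SNPs in pseudogenes, overlapping-gene
  regions or intergenic space are removed — all are false-biallelic
  factories via multi-mapping. Pseudoautosomal (PAR) genes are excluded
  from every X-specific analysis since both sexes carry two copies.
* **Ratio band**: with ratio = ref/(ref+alt), calls with 0.2 < ratio < 0.8
  are biallelic; at or beyond the boundaries they are monoallelic
  (`allelic.boundary_biallelic` flips the boundary convention, which is
  stated inconsistently in the field's descriptions).
* **Male-control artifact screen**: any X-linked SNP biallelic in a
  hemizygous male control line is an artifact by construction and is
  removed from all samples.

A gene is **informative** in an embryo if some cell shows a biallelic call
(criterion i) or two cells express single but *different* alleles of the
same SNP (criterion ii — the random-XCI signature). A gene expressing the
same single allele in every cell is non-informative: without a second
allele ever seen, heterozygosity itself is unproven, which is also why
imprinted XCI (every cell silencing the same parental X) yields *zero*
informative monoallelic genes rather than many. When two SNPs of one gene
contradict each other inside the same cell, that gene is dropped from that
cell's analyses.

Because embryos with more sequenced cells have more chances to catch
discordant alleles, monoallelic trend analyses subsample a fixed number of
cells per embryo (`xci.subsample_k = 4`, seeded).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `expressed_rpkm_min` | 0.1 | rpkm | floor for calling a gene expressed (denominator of fractions) |
| `min_reads` | 20 | reads | SNP call depth; controls false biallelic/monoallelic rates |
| `min_cells` | 2 | cells | within-embryo support for a SNP |
| `ratio_lo`, `ratio_hi` | 0.2, 0.8 | ratio | monoallelic boundaries |
| `subsample_k` | 4 | cells | removes cell-count bias in monoallelic detection |
| `min_mean_rpkm` | 5 | rpkm | F:M ratio floor; near-zero means make ratios unstable |
| `fold_hi`, `fold_lo` | 1.5, 0.67 | fold | ploidy over/under thresholds (strict inequalities) |
| `window` | 188 | genes | ploidy moving-average window |
| `alpha` | 0.05 | — | family-wise level before Bonferroni division |

Trend tests use Pearson correlation against ordinal stage coding
(oocyte = 0 … E7 blastocyst = 8) with three or more stages, and a
non-paired Wilcoxon with exactly two; embryonic-day coding is available
where metadata provide it. Statistical engines are the stock R ones
(`fisher.test`, `wilcox.test`, `cor.test`, `chisq.test`); the test suite
re-derives Fisher p-values by exhaustive hypergeometric enumeration and
the allelic classifier by integer brute force as independent oracles.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates complete pipeline inputs — counts, allele
counts, annotations, metadata, and latent truth tables — under controlled
scenarios (`pre_xci`, `progressive_xci`, `imprinted_xci`, `dampening`,
`male`, `aneuploid`, `upregulated_xa`). The model:

* Per-gene abundance is log-normal (`expr_meanlog = 3`, `expr_sdlog = 1`),
  identical for X-linked and autosomal genes, so a two-active-X cell has
  X:A = 1 by construction. Each allele of a diploid locus emits half the
  gene's output.
* **Silencing progression is gene-ordered.** Each X gene draws one latent
  threshold u ~ U(0,1) for the cohort and is silenced at a stage when
  u < p_inactivated(stage) (default 0 → 0.4 → 0.8 across three stages).
  Genes above the final p form an escape-like residual biallelic pool.
  Which parental X is silenced is one coin flip per cell (fixed to the
  maternal X in imprinted scenarios). We chose gene-level rather than
  per-(cell, gene) incompleteness deliberately: only a gene-intrinsic
  residual pool reproduces the F:M ≈ 2 signature of the biallelic residue,
  because a per-cell coin would mix silenced and active cells in every
  gene's female mean and drag the ratio toward 1.2. It also matches the
  observation that escape from XCI is largely a property of genes, not
  cells.
* **Dampening** multiplies both alleles by a factor falling 1 → 0.75 → 0.5.
  The endpoint 0.5 is full female-to-male dosage compensation — the state
  the dampening hypothesis posits — and equals the asymptote complete XCI
  drives toward. (Calibrating instead to the partial-XCI trajectory's
  total, factor 0.6, would place the F:M ratio at 1.2, contradicting the
  mechanism's defining prediction of ratio ≈ 1.)
* **Males** carry one X allele (optionally upregulated ×2) plus a
  biallelic maternal RNA pool that is 1 before embryonic genome activation
  and decays to 0 across post-EGA stages — so early male embryos show
  "heterozygous" X sites that vanish with development, and pre-EGA embryos
  of either sex show maternal X:A ≈ 1.
* **Reads.** Gene counts are negative binomial (size 2) around
  output × exonic length × cell depth (log-normal depth, sd 0.3 on the log
  scale), with 5% gene-cell dropout. Per-SNP coverage is negative binomial
  (mean 60, size 3) *independent of the gene's current output* (zeroed
  only when output is zero or the gene-cell drops out), and ref reads are
  Binomial(coverage, ref-allele output share). Decoupling coverage from
  silencing/dampening keeps informativeness comparable across scenarios —
  the discrimination logic is then tested on allelic structure, not on
  depth attrition. Real data couple them, which is why depth confounds
  must be checked separately in any real analysis.

Default cohort shape: 6 embryos per stage and sex, 4 cells per embryo,
3 stages (8-cell, morula, E6 blastocyst), 300 X-linked, 2,000 autosomal,
24 Y-linked and 10 PAR genes, ~0.8 heterozygous SNPs per gene. These sizes
keep a 100-seed battery of full cohorts within a few minutes on one CPU
while leaving each statistic comfortably powered.

What the simulator does **not** emulate: splicing, amplification and batch
effects, lineage structure (ICM/TE), cell-cycle dosage, or any specific
deposited dataset's depth profile. Passing tests on synthetic cohorts
demonstrates that the pipeline recovers the mechanisms it is designed to
separate under its own stated assumptions — not that any particular real
dataset satisfies those assumptions.

## Numerical and design choices

* Boundary handling: ratios exactly 0.2/0.8 are monoallelic by default;
  a config switch restores the inclusive-biallelic reading.
* rpkm uses exonic length (counting is exonic), and its library size is
  the genic column sum by default with an option for stored totals, since
  descriptions of "uniquely aligned reads" leave the denominator open.
* The F:M 5-rpkm floor applies when *either* sex's mean falls below 5: a
  near-zero male mean destabilises the ratio in exactly the way the filter
  targets.
* Outlier removal for ratio distributions is a Tukey-style fence,
  median ± 1.5 × IQR, flagged rather than deleted; tests and plots drop
  flagged rows.
* The ploidy screen is control-relative (chi-square of each cell ×
  chromosome's over/under/neutral partition against a euploid sample,
  Bonferroni over cells × chromosomes), because single-cell expression
  ratios are over/under the 1.5/0.67 folds ~20% of the time even in
  euploid cells; an absolute test would flag everything. The
  moving-average window is in genes (188), configurable; a base-pair
  window is not meaningful over gene-level values.
* Embryo sexing builds 2×2 tables of expressed vs non-expressed Y-linked
  genes against oocyte and male-line pools; Fisher's test needs counts,
  and pool comparisons of the Y-expressed count are the natural 2×2. The
  Bonferroni divisor defaults to embryos × control pools.
* Single-cell gains/losses only: the ploidy simulation injects the fold
  into one cell, because a whole-embryo event cancels out of the
  within-embryo median normalisation and is invisible to this class of
  screen.

## Known limitations

* With ~300 X-linked genes, the escape-like residual pool (~60 genes) has
  a sample-median sampling error of ~14% per cohort, shared by all cells
  of the final stage. Per-cell median comparisons across stages therefore
  flag a spurious "decrease" in roughly one cohort in ten at the 5% level
  — a gene-sampling effect, not a dosage one. Interpret per-cohort median
  tests together with the F:M ratio, which is robust to it.
* The biallelic-fraction denominator is the per-cell expressed-gene count,
  so global downscaling (dampening) nudges weak genes under the rpkm
  threshold and drifts the fraction slightly *upward*; the discriminating
  feature is the absence of the steep XCI decline, not exact flatness.
* Phasing across SNPs within a gene is out of scope; criterion (ii)
  operates per SNP.
* The sexing refusal for pre-EGA embryos is principled, not technical:
  their transcripts are maternal and carry no Y signal regardless of sex.

## A worked run

```{r example, eval = FALSE}
dir <- tempfile()
make_fixture("tiny_xci", dir, seed = 3)
report <- run_xci_pipeline(read_cohort(dir))
report$trends
plot_allelic_fractions(report$fractions_x |> filter(sex == "female"))
plot_fm_ratio(report$fm_ratio)

# the discrimination experiment at full scale, one seed:
xci_scenario_stats("progressive_xci", seed = 1)
xci_scenario_stats("dampening", seed = 1)
```

Both scenario statistics and the X:A construction oracles
(`xa_ratio_median()`) are recomputed from scratch, over 100 seeds, by
`scripts/acceptance.R`.
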