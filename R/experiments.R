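# One-call scenario experiments: simulate a cohort and reduce it to the
# statistics that separate X inactivation from X dampening.

#' Run one seeded scenario and collect its discrimination statistics
#'
#' Simulates a cohort under `scenario` (default study conditions: 6 embryos
#' per stage and sex, 4 cells each, 3 stages, 300 X-linked and 2,000
#' autosomal genes), runs the allelic pipeline on the X chromosome, and
#' returns the quantities of interest in one row:
#' * `fm_median_final`: median gene-wise female/male expression ratio of
#'   X-linked genes biallelically expressed in females at the final stage
#'   (outliers removed); NA when the cohort has a single sex.
#' * `p_median_decrease`, `p_sum_decrease`: one-sided non-paired Wilcoxon
#'   p-values for a decrease, from the first to the final stage, of the
#'   per-cell median and sum of biallelic X-linked tpm in females.
#' * `bi_r`, `bi_p`, `mono_r`, `mono_p`: Pearson trend of the female
#'   per-cell biallelic / monoallelic X fraction against stage.
#'
#' Only X-linked SNPs are run through the allelic filters here, since every
#' reported statistic is X-linked; expression layers use the whole
#' transcriptome.
#'
#' @param scenario Scenario name (see [scenario_config()]).
#' @param seed Simulation seed.
#' @param config A [pipeline_config()] supplying thresholds.
#' @param ... Overrides passed to [scenario_config()].
#' @return One-row tibble.
#' @export
xci_scenario_stats <- function(scenario = "progressive_xci", seed = 1,
                               config = pipeline_config(), ...) {
  cohort <- simulate_cohort(scenario_config(scenario, seed = seed, ...))
  em <- cohort$em |> compute_rpkm() |> compute_tpm()
  mask <- flag_expressed(em, config$expressed_rpkm_min)
  ac_x <- cohort$allele_counts |>
    semi_join(cohort$snps |> filter(is_x_chrom(.data$chrom)), by = "snp_id")
  calls <- filter_snps(ac_x, cohort$snps, cohort$genes, cohort$cells,
                       min_reads = config$min_reads, min_cells = config$min_cells) |>
    classify_snps(lo = config$ratio_lo, hi = config$ratio_hi,
                  boundary_biallelic = config$boundary_biallelic)
  stages <- cohort$config$stages
  final <- stages[length(stages)]

  both_sexes <- all(c("female", "male") %in% cohort$cells$sex)
  fm_median_final <- NA_real_
  if (both_sexes) {
    fm <- fm_ratio_genewise(calls, em, cohort$cells,
                            min_mean = config$min_mean_rpkm,
                            outlier_k = config$outlier_k)
    fin <- fm |> filter(.data$stage == final, !.data$outlier)
    if (nrow(fin) > 0) fm_median_final <- median(fin$ratio)
  }

  p_median <- p_sum <- NA_real_
  dos <- biallelic_dosage_summary(calls, em, cohort$cells,
                                  expressed_threshold = config$expressed_rpkm_min)
  first <- stages[1]
  if (sum(dos$stage == first) >= 2 && sum(dos$stage == final) >= 2) {
    dec_p <- function(v) {
      suppressWarnings(wilcox.test(dos[[v]][dos$stage == first],
                                   dos[[v]][dos$stage == final],
                                   alternative = "greater", exact = FALSE))$p.value
    }
    p_median <- dec_p("median_tpm")
    p_sum <- dec_p("sum_tpm")
  }

  bi_r <- bi_p <- mono_r <- mono_p <- NA_real_
  fem <- cohort$cells |> filter(.data$sex == "female")
  if (nrow(fem) >= 3) {
    info <- gene_informativeness(calls)
    fr <- suppressWarnings(
      cell_allelic_fractions(calls, info, mask, cohort$genes,
                             subsample_cells(fem, k = config$subsample_k,
                                             seed = config$seed), "X"))
    tb <- tryCatch(stage_trend(fr, "frac_biallelic"), error = function(e) NULL)
    tm <- tryCatch(stage_trend(fr, "frac_monoallelic"), error = function(e) NULL)
    if (!is.null(tb)) { bi_r <- tb$estimate; bi_p <- tb$p_value }
    if (!is.null(tm)) { mono_r <- tm$estimate; mono_p <- tm$p_value }
  }

  tibble(scenario = scenario, seed = seed,
         fm_median_final = fm_median_final,
         p_median_decrease = p_median, p_sum_decrease = p_sum,
         bi_r = bi_r, bi_p = bi_p, mono_r = mono_r, mono_p = mono_p)
}

#' Median per-cell X:A ratio of a simulated population
#'
#' Simulates a one-stage cohort and returns the median over cells of the
#' X-to-autosome median-tpm ratio, the construction-oracle check for
#' dosage-compensation states (two active X's or an upregulated single X
#' give ~1, a single non-upregulated X gives ~0.5).
#'
#' @param scenario Scenario name.
#' @param seed Simulation seed.
#' @param sexes,stages Cohort composition (defaults: one 8-cell stage).
#' @param ... Further [scenario_config()] overrides.
#' @return Median per-cell ratio (numeric scalar).
#' @export
xa_ratio_median <- function(scenario = "pre_xci", seed = 1,
                            sexes = "female", stages = "cell8", ...) {
  cohort <- simulate_cohort(scenario_config(scenario, seed = seed, sexes = sexes,
                                            stages = stages, ...))
  em <- cohort$em |> compute_rpkm() |> compute_tpm()
  median(xa_ratio(em, cohort$cells)$ratio)
}
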