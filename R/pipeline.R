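# End-to-end orchestration: quantify -> qc -> allelic -> fractions/trends ->
# dosage, under a single configuration object.

#' Pipeline configuration
#'
#' All thresholds of the analysis in one flat list. The defaults are the
#' stringent settings the pipeline is built around: expression at
#' rpkm >= 0.1, SNP calls at >= 20 reads seen in >= 2 cells of the embryo,
#' the 0.2--0.8 allelic-ratio band with boundaries monoallelic, 4-cell
#' subsampling for monoallelic trend analyses, a 5-rpkm floor for
#' female-to-male gene means, 1.5 / 0.67 over/under folds and a 188-gene
#' moving-average window for the ploidy screen, and alpha = 0.05.
#'
#' @param ... Named overrides of any default.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    expressed_rpkm_min = 0.1,
    min_reads = 20,
    min_cells = 2,
    ratio_lo = 0.2,
    ratio_hi = 0.8,
    boundary_biallelic = FALSE,
    subsample_k = 4,
    use_all_cells = FALSE,
    seed = 1,
    min_mean_rpkm = 5,
    outlier_k = 1.5,
    fold_hi = 1.5,
    fold_lo = 0.67,
    window = 188,
    min_xa_genes = 20,
    alpha = 0.05,
    par_intervals = default_par_intervals()
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full XCI analysis pipeline on a cohort
#'
#' Executes, in order: rpkm/tpm quantification and the expressed mask;
#' optional embryo sexing and ploidy screening (when control cells are
#' supplied); allelic filtering, classification, male-control artifact
#' exclusion and gene informativeness; per-cell biallelic/monoallelic
#' fraction trajectories with stage trends (X per sex, autosomes pooled,
#' on the subsampled cells unless `use_all_cells`); and the dosage
#' statistics (per-cell biallelic sums/medians with stage comparisons,
#' gene-wise female-to-male ratios, per-cell X:A ratios).
#'
#' @param cohort An `xci_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param female_control_cells,male_control_cells Optional control cell ids
#'   for sexing / artifact exclusion / ploidy.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV.
#' @return A list of class `xci_report` with the result tables and a `log`
#'   tibble of record counts at each stage boundary.
#' @export
run_xci_pipeline <- function(cohort, config = pipeline_config(),
                             female_control_cells = NULL,
                             male_control_cells = NULL,
                             out_dir = NULL) {
  stopifnot(inherits(cohort, "xci_cohort"))
  log <- list()
  note <- function(stage, what, n) {
    log[[length(log) + 1]] <<- tibble(stage = stage, what = what, n = n)
  }

  em <- cohort$em |> compute_rpkm() |> compute_tpm()
  mask <- flag_expressed(em, config$expressed_rpkm_min)
  note("quantify", "cells", ncol(em$counts))
  note("quantify", "genes", nrow(em$counts))
  note("quantify", "expressed gene-cells", sum(mask))

  ctrl <- c(female_control_cells, male_control_cells)
  embryo_cells <- cohort$cells |> filter(!.data$cell_id %in% ctrl)

  sexing <- NULL
  if (!is.null(female_control_cells) && !is.null(male_control_cells)) {
    sexing <- sex_embryos(em, cohort$cells, female_control_cells, male_control_cells,
                          alpha = config$alpha,
                          expressed_threshold = config$expressed_rpkm_min)
    note("qc", "embryos sexed", nrow(sexing))
  }
  ploidy <- NULL
  if (!is.null(male_control_cells) && length(male_control_cells) >= 2) {
    ploidy <- ploidy_screen(em, embryo_cells |> filter(!(.data$stage %in% pre_ega_stages)),
                            control_cells = male_control_cells,
                            window = config$window, fold_hi = config$fold_hi,
                            fold_lo = config$fold_lo, alpha = config$alpha)
    note("qc", "ploidy flags", sum(ploidy$flagged))
  }

  calls <- filter_snps(cohort$allele_counts, cohort$snps, cohort$genes, cohort$cells,
                       min_reads = config$min_reads, min_cells = config$min_cells) |>
    classify_snps(lo = config$ratio_lo, hi = config$ratio_hi,
                  boundary_biallelic = config$boundary_biallelic)
  note("allelic", "allele-count records", nrow(cohort$allele_counts))
  note("allelic", "calls passing filters", sum(!startsWith(calls$klass, "filtered")))
  if (!is.null(male_control_cells)) {
    calls <- exclude_male_control_biallelics(calls, male_control_cells)
    note("allelic", "calls after male-control exclusion",
         sum(!startsWith(calls$klass, "filtered")))
  }
  info <- gene_informativeness(calls |> semi_join(embryo_cells, by = "cell_id"))
  note("allelic", "informative genes",
       sum(info$status %in% c("informative_biallelic", "informative_monoallelic")))

  cells_used <- if (config$use_all_cells) embryo_cells
                else subsample_cells(embryo_cells, k = config$subsample_k,
                                     seed = config$seed)
  note("xci_metrics", "cells after subsampling", nrow(cells_used))

  frac_x <- cell_allelic_fractions(calls, info, mask, cohort$genes, cells_used, "X")
  frac_auto <- cell_allelic_fractions(calls, info, mask, cohort$genes, cells_used, "autosomes")

  trend_one <- function(df, value) {
    tryCatch(tidy(stage_trend(df, value = value)), error = function(e) tibble())
  }
  trends <- bind_rows(
    frac_x |> filter(.data$sex == "female") |> trend_one("frac_biallelic") |>
      mutate(group = "X_female_biallelic"),
    frac_x |> filter(.data$sex == "female") |> trend_one("frac_monoallelic") |>
      mutate(group = "X_female_monoallelic"),
    frac_x |> filter(.data$sex == "male") |> trend_one("frac_biallelic") |>
      mutate(group = "X_male_biallelic"),
    frac_auto |> trend_one("frac_biallelic") |> mutate(group = "autosomes_biallelic"),
    frac_auto |> trend_one("frac_monoallelic") |> mutate(group = "autosomes_monoallelic")
  )

  dosage <- biallelic_dosage_summary(calls, em, embryo_cells, info,
                                     expressed_threshold = config$expressed_rpkm_min)
  dosage_tests <- if (nrow(dosage) > 0 && n_distinct(dosage$stage) >= 2) {
    bind_rows(stage_comparisons(dosage, "sum_tpm"),
              stage_comparisons(dosage, "median_tpm"))
  } else tibble()
  fm <- if (all(c("female", "male") %in% embryo_cells$sex)) {
    fm_ratio_genewise(calls, em, embryo_cells, info,
                      min_mean = config$min_mean_rpkm, outlier_k = config$outlier_k)
  } else tibble()
  xa <- xa_ratio(em, embryo_cells, min_genes = config$min_xa_genes,
                 expressed_threshold = config$expressed_rpkm_min)

  report <- structure(
    list(em = em, expressed = mask, sexing = sexing, ploidy = ploidy,
         snp_calls = calls, informativeness = info,
         fractions_x = frac_x, fractions_autosomes = frac_auto, trends = trends,
         dosage = dosage, dosage_tests = dosage_tests, fm_ratio = fm, xa = xa,
         log = bind_rows(log), config = config),
    class = "xci_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.xci_report <- function(x, ...) {
  cat("<xci_report>\n")
  print(x$log, n = Inf)
  if (nrow(x$trends) > 0) {
    cat("\nStage trends:\n")
    print(x$trends |> select("group", "statistic_name", "estimate", "p.value", "n"), n = Inf)
  }
  invisible(x)
}

#' Write every pipeline result table as TSV
#'
#' @param report An `xci_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(sexing = report$sexing, ploidy = report$ploidy,
               snp_calls = report$snp_calls, informativeness = report$informativeness,
               fractions_x = report$fractions_x,
               fractions_autosomes = report$fractions_autosomes,
               trends = report$trends, dosage = report$dosage,
               dosage_tests = report$dosage_tests, fm_ratio = report$fm_ratio,
               xa_ratio = report$xa, log = report$log)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]]) && nrow(tabs[[nm]]) > 0) {
      readr::write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")), na = ".")
    }
  }
  invisible(dir)
}
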