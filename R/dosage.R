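# Dosage statistics separating X inactivation from X dampening, and
# X-to-autosome expression ratios.
#
# The discriminating logic: both XCI and dampening lower the summed
# expression of biallelically expressed X-linked genes in females. Under
# dampening every biallelic gene is itself expressed less, so the per-cell
# MEDIAN of those genes falls and the gene-wise female-to-male ratio tends
# to 1. Under XCI genes leave the biallelic pool but the remaining ones are
# expressed from two normal alleles, so the median holds and the F:M ratio
# of the biallelic pool tends to 2.

# Tukey-style fences around the median: outside median +/- k * IQR.
tukey_outlier <- function(x, k = 1.5) {
  med <- median(x, na.rm = TRUE)
  iqr <- stats::IQR(x, na.rm = TRUE)
  x < med - k * iqr | x > med + k * iqr
}

# Genes biallelic in a given cell, honouring the inconsistent-cell
# exclusions carried by gene_informativeness().
biallelic_gene_cells <- function(calls, informativeness = NULL) {
  excl <- if (is.null(informativeness)) NULL else attr(informativeness, "cell_exclusions")
  out <- calls |> filter(.data$klass == "biallelic")
  if (!is.null(excl) && nrow(excl) > 0) {
    out <- out |> anti_join(excl, by = c("embryo_id", "gene_id", "cell_id"))
  }
  out |> distinct(.data$cell_id, .data$embryo_id, .data$gene_id, .data$chrom)
}

#' Per-cell sum and median of biallelically expressed X-linked genes
#'
#' For each female cell, restricts to expressed (rpkm >= 0.1 by default),
#' non-PAR X-linked genes with a biallelic SNP call in that cell, and
#' reports the sum and the median of their tpm values. Cells with no such
#' gene are excluded and counted.
#'
#' @param calls Classified SNP-call tibble.
#' @param x An [expr_matrix()] with rpkm and tpm layers filled.
#' @param cells Cell metadata; only `sex == "female"` cells are summarised.
#' @param informativeness Optional [gene_informativeness()] output (for
#'   inconsistent-cell exclusions).
#' @param expressed_threshold rpkm threshold for the expressed mask.
#' @return Tibble `cell_id, embryo_id, stage, n_biallelic, sum_tpm,
#'   median_tpm`, classed `xci_dosage`; attribute `n_excluded_cells` counts
#'   female cells without biallelic X genes.
#' @export
biallelic_dosage_summary <- function(calls, x, cells, informativeness = NULL,
                                     expressed_threshold = 0.1) {
  mask <- flag_expressed(x, expressed_threshold)
  tpm <- x$layers$tpm
  if (is.null(tpm)) abort("tpm layer not filled; run compute_tpm() first")
  fem <- cells |> filter(.data$sex == "female")
  bi <- biallelic_gene_cells(calls, informativeness) |>
    filter(is_x_chrom(.data$chrom), .data$cell_id %in% fem$cell_id) |>
    semi_join(x$genes |> filter(!.data$par), by = "gene_id")
  bi <- bi |>
    mutate(expressed = mask[cbind(match(.data$gene_id, rownames(mask)),
                                  match(.data$cell_id, colnames(mask)))]) |>
    filter(.data$expressed %in% TRUE) |>
    mutate(tpm = tpm[cbind(match(.data$gene_id, rownames(tpm)),
                           match(.data$cell_id, colnames(tpm)))])
  out <- bi |>
    group_by(.data$cell_id) |>
    summarise(n_biallelic = n(), sum_tpm = sum(.data$tpm),
              median_tpm = median(.data$tpm), .groups = "drop") |>
    inner_join(fem |> select("cell_id", "embryo_id", "stage"), by = "cell_id") |>
    relocate("embryo_id", "stage", .after = "cell_id")
  attr(out, "n_excluded_cells") <- sum(!fem$cell_id %in% out$cell_id)
  class(out) <- c("xci_dosage", class(out))
  out
}

#' Non-paired Wilcoxon comparisons between consecutive stages
#'
#' @param summary A per-cell tibble with `stage` and the column named by
#'   `value` (e.g. [biallelic_dosage_summary()] output).
#' @param value Column to compare (`"sum_tpm"`, `"median_tpm"`, ...).
#' @param alternative Passed to [stats::wilcox.test()]; the default
#'   two-sided test reports any shift, `"greater"` tests for a decrease from
#'   the earlier to the later stage.
#' @return Tibble with one row per consecutive stage pair.
#' @export
stage_comparisons <- function(summary, value = "sum_tpm", alternative = "two.sided") {
  stages <- intersect(xci_stage_levels, unique(as.character(summary$stage)))
  if (length(stages) < 2) abort("need at least two stages")
  map_dfr(seq_len(length(stages) - 1), function(i) {
    a <- summary[[value]][summary$stage == stages[i]]
    b <- summary[[value]][summary$stage == stages[i + 1]]
    ht <- suppressWarnings(wilcox.test(a, b, paired = FALSE, exact = FALSE,
                                       alternative = alternative))
    tibble(stage_from = stages[i], stage_to = stages[i + 1], value = value,
           n_from = length(a), n_to = length(b),
           statistic = unname(ht$statistic), p.value = ht$p.value)
  })
}

#' Gene-wise female-to-male expression ratios of biallelic X-linked genes
#'
#' For each developmental stage with cells of both sexes: takes the X-linked
#' non-PAR genes biallelically expressed in at least one female cell of the
#' stage, computes the gene's mean rpkm over the stage's female cells and
#' over its male cells, drops genes where either mean is below `min_mean`
#' (near-zero denominators make the ratio meaningless), and reports the
#' female/male ratio. Outliers by Tukey-style fences (outside
#' median +/- `outlier_k` * IQR, per stage) are flagged, not removed;
#' downstream tests and plots drop flagged rows.
#'
#' @param calls Classified SNP-call tibble.
#' @param x An [expr_matrix()] with the rpkm layer filled.
#' @param cells Cell metadata.
#' @param informativeness Optional informativeness for exclusions.
#' @param min_mean Minimum mean rpkm in each sex (default 5).
#' @param outlier_k Fence multiplier (default 1.5).
#' @return Tibble `gene_id, stage, n_female_cells, n_male_cells, mean_f,
#'   mean_m, ratio, outlier`, classed `fm_ratio`; attribute
#'   `skipped_stages` lists stages without male cells.
#' @export
fm_ratio_genewise <- function(calls, x, cells, informativeness = NULL,
                              min_mean = 5, outlier_k = 1.5) {
  rpkm <- x$layers$rpkm
  if (is.null(rpkm)) abort("rpkm layer not filled; run compute_rpkm() first")
  stages <- intersect(xci_stage_levels, unique(as.character(cells$stage)))
  skipped <- character()
  bi <- biallelic_gene_cells(calls, informativeness) |>
    filter(is_x_chrom(.data$chrom)) |>
    semi_join(x$genes |> filter(!.data$par), by = "gene_id") |>
    inner_join(cells |> select("cell_id", "stage", "sex"), by = "cell_id")

  res <- map_dfr(stages, function(st) {
    fcells <- cells$cell_id[cells$stage == st & cells$sex == "female"]
    mcells <- cells$cell_id[cells$stage == st & cells$sex == "male"]
    if (length(mcells) == 0 || length(fcells) == 0) {
      skipped <<- c(skipped, st)
      return(tibble())
    }
    gset <- bi |>
      filter(.data$stage == st, .data$sex == "female") |>
      distinct(.data$gene_id) |>
      pull()
    if (length(gset) == 0) return(tibble())
    gi <- match(gset, rownames(rpkm))
    mean_f <- rowMeans(rpkm[gi, fcells, drop = FALSE])
    mean_m <- rowMeans(rpkm[gi, mcells, drop = FALSE])
    tibble(gene_id = gset, stage = st,
           n_female_cells = length(fcells), n_male_cells = length(mcells),
           mean_f = unname(mean_f), mean_m = unname(mean_m)) |>
      filter(.data$mean_f >= min_mean, .data$mean_m >= min_mean) |>
      mutate(ratio = .data$mean_f / .data$mean_m,
             outlier = tukey_outlier(.data$ratio, outlier_k))
  })
  attr(res, "skipped_stages") <- skipped
  class(res) <- c("fm_ratio", class(res))
  res
}

#' Tests on female-to-male ratio distributions
#'
#' Between consecutive stages: paired Wilcoxon on the log-ratio of genes
#' present (non-outlier) in both stages. Within each stage: paired Wilcoxon
#' of the female vs male gene means.
#'
#' @param fm Output of [fm_ratio_genewise()].
#' @return Tibble of tests (`comparison`, `stage_from`, `stage_to`, `n`,
#'   `p.value`).
#' @export
fm_ratio_tests <- function(fm) {
  fm <- fm |> filter(!.data$outlier)
  stages <- intersect(xci_stage_levels, unique(fm$stage))
  between <- if (length(stages) >= 2) {
    map_dfr(seq_len(length(stages) - 1), function(i) {
      a <- fm |> filter(.data$stage == stages[i]) |> select("gene_id", r1 = "ratio")
      b <- fm |> filter(.data$stage == stages[i + 1]) |> select("gene_id", r2 = "ratio")
      ab <- inner_join(a, b, by = "gene_id")
      if (nrow(ab) < 3) return(tibble())
      ht <- suppressWarnings(wilcox.test(ab$r1, ab$r2, paired = TRUE, exact = FALSE))
      tibble(comparison = "between_stages", stage_from = stages[i],
             stage_to = stages[i + 1], n = nrow(ab),
             statistic = unname(ht$statistic), p.value = ht$p.value)
    })
  } else tibble()
  within <- map_dfr(stages, function(st) {
    sub <- fm |> filter(.data$stage == st)
    if (nrow(sub) < 3) return(tibble())
    ht <- suppressWarnings(wilcox.test(sub$mean_f, sub$mean_m, paired = TRUE, exact = FALSE))
    tibble(comparison = "female_vs_male", stage_from = st, stage_to = st,
           n = nrow(sub), statistic = unname(ht$statistic), p.value = ht$p.value)
  })
  bind_rows(between, within)
}

#' Per-cell X-to-autosome expression ratio
#'
#' Ratio of the median tpm of expressed non-PAR X-linked genes to the median
#' tpm of expressed autosomal genes in each cell. Approximately 1 under two
#' active X's (or one upregulated X), about 0.5 under a single
#' non-upregulated X. Cells with too few expressed genes on either side are
#' skipped and recorded.
#'
#' @param x An [expr_matrix()] with rpkm and tpm layers filled.
#' @param cells Cell metadata (cells to evaluate).
#' @param min_genes Minimum expressed genes required on X and on autosomes
#'   (default 20).
#' @param expressed_threshold rpkm threshold (default 0.1).
#' @return Tibble `cell_id, embryo_id, stage, sex, n_x, n_autosome,
#'   x_median_tpm, autosome_median_tpm, ratio`, classed `xa_ratio`;
#'   attribute `skipped_cells` lists skipped cell ids.
#' @export
xa_ratio <- function(x, cells, min_genes = 20, expressed_threshold = 0.1) {
  mask <- flag_expressed(x, expressed_threshold)
  tpm <- x$layers$tpm
  if (is.null(tpm)) abort("tpm layer not filled; run compute_tpm() first")
  xg <- x$genes$gene_id[is_x_chrom(x$genes$chrom) & !x$genes$par]
  ag <- x$genes$gene_id[is_autosome(x$genes$chrom)]
  ids <- intersect(cells$cell_id, colnames(tpm))
  res <- map_dfr(ids, function(cid) {
    ex <- xg[mask[xg, cid]]
    ea <- ag[mask[ag, cid]]
    tibble(cell_id = cid, n_x = length(ex), n_autosome = length(ea),
           x_median_tpm = if (length(ex)) median(tpm[ex, cid]) else NA_real_,
           autosome_median_tpm = if (length(ea)) median(tpm[ea, cid]) else NA_real_)
  })
  keep <- res$n_x >= min_genes & res$n_autosome >= min_genes
  out <- res[keep, , drop = FALSE] |>
    mutate(ratio = .data$x_median_tpm / .data$autosome_median_tpm) |>
    inner_join(cells |> select("cell_id", "embryo_id", "stage", "sex"), by = "cell_id") |>
    relocate("embryo_id", "stage", "sex", .after = "cell_id")
  attr(out, "skipped_cells") <- res$cell_id[!keep]
  class(out) <- c("xa_ratio", class(out))
  out
}

#' Per-embryo summary of X:A ratios
#'
#' @param xa Output of [xa_ratio()].
#' @return Tibble with per-embryo mean ratio and standard error.
#' @export
xa_embryo_summary <- function(xa) {
  xa |>
    group_by(.data$embryo_id, .data$stage, .data$sex) |>
    summarise(n_cells = n(), mean_ratio = mean(.data$ratio),
              sem = sd(.data$ratio) / sqrt(n()), .groups = "drop")
}

#' Compare X:A ratios between two groups of cells
#'
#' Non-paired Wilcoxon on per-cell ratios.
#'
#' @param xa Output of [xa_ratio()].
#' @param group_a,group_b Character vectors of cell ids.
#' @return One-row tibble with the test result.
#' @export
xa_group_test <- function(xa, group_a, group_b) {
  a <- xa$ratio[xa$cell_id %in% group_a]
  b <- xa$ratio[xa$cell_id %in% group_b]
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 cells per group")
  ht <- suppressWarnings(wilcox.test(a, b, paired = FALSE, exact = FALSE))
  tibble(n_a = length(a), n_b = length(b), mean_a = mean(a), mean_b = mean(b),
         statistic = unname(ht$statistic), p.value = ht$p.value)
}
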