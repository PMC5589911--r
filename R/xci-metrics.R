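# Per-cell biallelic/monoallelic fractions and trend statistics across
# development.

#' Randomly subsample cells per embryo
#'
#' Embryos with many sequenced cells offer more chances to observe
#' discordant alleles, inflating monoallelic informativeness; sampling a
#' fixed number of cells per embryo removes that bias. Embryos with at most
#' `k` cells keep all their cells.
#'
#' @param cells Cell metadata tibble.
#' @param k Cells to keep per embryo (default 4).
#' @param seed Optional integer; fixing it makes the draw deterministic
#'   without touching the caller's RNG state.
#' @return Subset of `cells`.
#' @export
subsample_cells <- function(cells, k = 4, seed = NULL) {
  stopifnot(k >= 1)
  draw <- function() {
    cells |>
      group_by(.data$embryo_id) |>
      slice_sample(n = k) |>
      ungroup()
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-cell fractions of biallelically and monoallelically expressed genes
#'
#' For each cell and chromosome group, counts genes expressed in the cell
#' (rpkm mask, PAR genes excluded), genes biallelic in the cell (any SNP of
#' the gene called biallelic in that cell), and genes monoallelic in the
#' cell (gene `informative_monoallelic` for the embryo and carrying a
#' monoallelic call in that cell). Fractions divide by the expressed-gene
#' count. Cells expressing no gene in the group are skipped with a warning.
#'
#' @param calls Classified SNP-call tibble.
#' @param informativeness Output of [gene_informativeness()].
#' @param expressed Logical genes x cells mask from [flag_expressed()].
#' @param genes Gene annotation tibble.
#' @param cells Cell metadata tibble (defines which cells are summarised).
#' @param chrom_group `"X"`, `"autosomes"`, or a single chromosome name.
#' @return Tibble of per-cell counts and fractions, classed `xci_fractions`.
#' @export
cell_allelic_fractions <- function(calls, informativeness, expressed, genes, cells,
                                   chrom_group = "X") {
  in_group <- function(chrom) {
    if (identical(chrom_group, "X")) is_x_chrom(chrom)
    else if (identical(chrom_group, "autosomes")) is_autosome(chrom)
    else chrom == chrom_group
  }
  grp_genes <- genes |> filter(in_group(.data$chrom), !.data$par)
  mask <- expressed[rownames(expressed) %in% grp_genes$gene_id,
                    colnames(expressed) %in% cells$cell_id, drop = FALSE]
  n_expressed <- colSums(mask)

  excl <- attr(informativeness, "cell_exclusions") %||%
    tibble(embryo_id = character(), gene_id = character(), cell_id = character())
  usable <- calls |>
    filter(.data$cell_id %in% cells$cell_id,
           .data$gene_id %in% grp_genes$gene_id,
           .data$klass %in% c("biallelic", "mono_ref", "mono_alt")) |>
    anti_join(excl, by = c("embryo_id", "gene_id", "cell_id"))

  bi <- usable |>
    filter(.data$klass == "biallelic") |>
    distinct(.data$cell_id, .data$gene_id) |>
    count(.data$cell_id, name = "n_biallelic")

  mono_genes <- informativeness |>
    filter(.data$status == "informative_monoallelic") |>
    select("embryo_id", "gene_id")
  mono <- usable |>
    filter(.data$klass %in% c("mono_ref", "mono_alt")) |>
    semi_join(mono_genes, by = c("embryo_id", "gene_id")) |>
    distinct(.data$cell_id, .data$gene_id) |>
    count(.data$cell_id, name = "n_monoallelic")

  out <- cells |>
    select("cell_id", "embryo_id", "stage", "sex") |>
    mutate(chrom_group = if (length(chrom_group) == 1) chrom_group else "group",
           n_expressed = as.integer(n_expressed[.data$cell_id])) |>
    left_join(bi, by = "cell_id") |>
    left_join(mono, by = "cell_id") |>
    mutate(n_biallelic = ifelse(is.na(.data$n_biallelic), 0L, .data$n_biallelic),
           n_monoallelic = ifelse(is.na(.data$n_monoallelic), 0L, .data$n_monoallelic))

  none <- is.na(out$n_expressed) | out$n_expressed == 0
  if (any(none)) {
    warn(paste0(sum(none), " cell(s) with no expressed gene in group '",
                paste(chrom_group, collapse = ","), "' skipped"))
    out <- out[!none, , drop = FALSE]
  }
  out <- out |>
    mutate(frac_biallelic = .data$n_biallelic / .data$n_expressed,
           frac_monoallelic = .data$n_monoallelic / .data$n_expressed)
  class(out) <- c("xci_fractions", class(out))
  out
}

new_xci_trend <- function(statistic_name, estimate, statistic, p_value, n, method,
                          groups = NULL) {
  structure(
    list(statistic_name = statistic_name, estimate = estimate, statistic = statistic,
         p_value = p_value, n = n, method = method, groups = groups),
    class = "xci_trend"
  )
}

#' Trend of a per-cell fraction across developmental stages
#'
#' With three or more stages the fraction is correlated against the numeric
#' stage coding (Pearson r, two-sided p from the t transform). With exactly
#' two stages a non-paired Wilcoxon (Mann-Whitney) test is used instead,
#' since a correlation over two groups is just a location comparison.
#'
#' @param fractions Tibble with a `stage` column (and `embryonic_day` if that
#'   coding is requested).
#' @param value Name of the fraction column to test (default
#'   `"frac_biallelic"`).
#' @param coding `"ordinal"` developmental order or `"embryonic_day"`.
#' @return An `xci_trend` object (see [tidy.xci_trend()]).
#' @export
stage_trend <- function(fractions, value = "frac_biallelic", coding = "ordinal") {
  y <- fractions[[value]]
  if (is.null(y)) abort(paste0("no column '", value, "' in fractions"))
  x <- if (coding == "embryonic_day") as.numeric(fractions$embryonic_day)
       else stage_code(fractions$stage)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3) abort("need at least 3 cells with usable stage coding")
  stages <- sort(unique(x))
  if (length(stages) < 2) abort("need cells from at least 2 stages")
  if (length(stages) == 2) {
    ht <- suppressWarnings(wilcox.test(y[x == stages[1]], y[x == stages[2]],
                                       paired = FALSE, exact = FALSE))
    return(new_xci_trend("wilcoxon_W", estimate = NA_real_,
                         statistic = unname(ht$statistic), p_value = ht$p.value,
                         n = length(y), method = "Wilcoxon rank sum (two stages)",
                         groups = stages))
  }
  if (sd(y) == 0 || sd(x) == 0) abort("zero variance; Pearson correlation undefined")
  ht <- cor.test(x, y, method = "pearson")
  new_xci_trend("pearson_r", estimate = unname(ht$estimate),
                statistic = unname(ht$statistic), p_value = ht$p.value,
                n = length(y), method = "Pearson correlation vs stage",
                groups = stages)
}

#' @export
print.xci_trend <- function(x, ...) {
  cat("<xci_trend> ", x$method, "\n", sep = "")
  if (!is.na(x$estimate)) cat("  r = ", signif(x$estimate, 4), sep = "")
  cat("  statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy / glance methods for trend objects
#'
#' @param x An `xci_trend`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.xci_trend <- function(x, ...) {
  tibble(statistic_name = x$statistic_name, estimate = x$estimate,
         statistic = x$statistic, p.value = x$p_value, n = x$n, method = x$method)
}

#' @rdname tidy.xci_trend
#' @export
glance.xci_trend <- function(x, ...) tidy(x)

#' Per-chromosome trends with Bonferroni flags
#'
#' Runs [stage_trend()] separately for each chromosome present in
#' `fractions` (which must carry a `chrom_group` column of single
#' chromosomes) and flags significance at `alpha / n_chromosomes_tested`.
#' Chromosomes without enough usable cells are skipped and recorded with NA
#' statistics.
#'
#' @param fractions Per-cell fractions with a `chrom_group` column.
#' @param value Fraction column to test.
#' @param alpha Family-wise level (default 0.05).
#' @param coding Stage coding passed to [stage_trend()].
#' @return Tibble, one row per chromosome, with `significant` flags.
#' @export
per_chromosome_trends <- function(fractions, value = "frac_biallelic",
                                  alpha = 0.05, coding = "ordinal") {
  chroms <- unique(fractions$chrom_group)
  res <- map_dfr(chroms, function(ch) {
    sub <- fractions |> filter(.data$chrom_group == ch)
    tr <- tryCatch(stage_trend(sub, value = value, coding = coding),
                   error = function(e) NULL)
    if (is.null(tr)) {
      tibble(chrom = ch, statistic_name = NA_character_, estimate = NA_real_,
             statistic = NA_real_, p.value = NA_real_, n = nrow(sub))
    } else {
      tidy(tr) |> mutate(chrom = ch, .before = 1) |> select(-"method")
    }
  })
  n_tested <- sum(!is.na(res$p.value))
  res |> mutate(threshold = alpha / max(n_tested, 1L),
                significant = !is.na(.data$p.value) & .data$p.value < .data$threshold)
}
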