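# Embryo sexing from Y-linked expression and expression-based ploidy
# screening.

count_y_expressed <- function(x, mask, cell_ids) {
  yg <- x$genes$gene_id[is_y_chrom(x$genes$chrom) & !x$genes$par]
  if (length(yg) == 0) abort("no non-PAR Y-linked genes in the matrix")
  sub <- mask[yg, colnames(mask) %in% cell_ids, drop = FALSE]
  list(n_expressed = sum(rowSums(sub) > 0), n_tested = length(yg))
}

#' Sex one embryo from Y-linked gene expression
#'
#' Counts non-PAR Y-linked genes expressed (rpkm >= `expressed_threshold` in
#' at least one cell) in the embryo and compares that count against a
#' female control pool (oocytes) and a male control pool (e.g. a male hESC
#' line) with two-sided Fisher exact tests on 2x2 tables of
#' expressed/non-expressed Y genes. With Bonferroni correction for
#' `n_tests`, the embryo is called female when it differs from the male
#' pool but not from the female pool, male in the mirrored case, and
#' unknown otherwise. Embryos before full embryonic genome activation
#' (earlier than the 8-cell stage) are refused: their transcripts are
#' maternal and carry no Y signal regardless of sex.
#'
#' @param x An [expr_matrix()] with the rpkm layer filled.
#' @param embryo_cells Cell ids of the embryo.
#' @param female_control_cells,male_control_cells Cell ids of the control
#'   pools.
#' @param stage Developmental stage of the embryo.
#' @param n_tests Bonferroni divisor; with the paper-style design this is
#'   (number of embryos sexed) x (number of control pools).
#' @param alpha Family-wise level (default 0.05).
#' @param expressed_threshold rpkm cutoff (default 0.1).
#' @return One-row tibble: `n_y_expressed`, `n_y_tested`,
#'   `p_vs_female_control`, `p_vs_male_control`, `call`.
#' @export
sex_embryo <- function(x, embryo_cells, female_control_cells, male_control_cells,
                       stage, n_tests, alpha = 0.05, expressed_threshold = 0.1) {
  if (as.character(stage) %in% pre_ega_stages) {
    abort("embryos prior to embryonic genome activation (8-cell) cannot be sexed from expression")
  }
  mask <- flag_expressed(x, expressed_threshold)
  emb <- count_y_expressed(x, mask, embryo_cells)
  fem <- count_y_expressed(x, mask, female_control_cells)
  mal <- count_y_expressed(x, mask, male_control_cells)
  fisher_p <- function(a, b) {
    tab <- matrix(c(a$n_expressed, a$n_tested - a$n_expressed,
                    b$n_expressed, b$n_tested - b$n_expressed), nrow = 2, byrow = TRUE)
    fisher.test(tab)$p.value
  }
  p_f <- fisher_p(emb, fem)
  p_m <- fisher_p(emb, mal)
  thr <- alpha / n_tests
  call <- if (p_f > thr && p_m <= thr) "female"
          else if (p_m > thr && p_f <= thr) "male"
          else "unknown"
  tibble(n_y_expressed = emb$n_expressed, n_y_tested = emb$n_tested,
         p_vs_female_control = p_f, p_vs_male_control = p_m,
         threshold = thr, call = call)
}

#' Sex every post-EGA embryo in a cohort
#'
#' Pre-EGA embryos are skipped with a warning. `n_tests` defaults to the
#' number of embryos sexed times two (two control pools).
#'
#' @param x An [expr_matrix()] with rpkm filled.
#' @param cells Cell metadata.
#' @param female_control_cells,male_control_cells Control cell ids.
#' @param n_tests Bonferroni divisor; NULL computes it from the input.
#' @inheritParams sex_embryo
#' @return Tibble with one row per sexed embryo.
#' @export
sex_embryos <- function(x, cells, female_control_cells, male_control_cells,
                        n_tests = NULL, alpha = 0.05, expressed_threshold = 0.1) {
  ctrl <- c(female_control_cells, male_control_cells)
  embs <- cells |>
    filter(!.data$cell_id %in% ctrl) |>
    distinct(.data$embryo_id, .data$stage)
  pre <- embs$embryo_id[as.character(embs$stage) %in% pre_ega_stages]
  if (length(pre) > 0) {
    warn(paste0("pre-EGA embryo(s) not sexed: ", paste(pre, collapse = ", ")))
    embs <- embs |> filter(!.data$embryo_id %in% pre)
  }
  n_tests <- n_tests %||% (nrow(embs) * 2L)
  map_dfr(seq_len(nrow(embs)), function(i) {
    ids <- cells$cell_id[cells$embryo_id == embs$embryo_id[i]]
    sex_embryo(x, ids, female_control_cells, male_control_cells,
               stage = embs$stage[i], n_tests = n_tests, alpha = alpha,
               expressed_threshold = expressed_threshold) |>
      mutate(embryo_id = embs$embryo_id[i], stage = as.character(embs$stage[i]),
             .before = 1)
  })
}

#' Cross-check reported sex against X-linked heterozygosity
#'
#' A genuinely female embryo carries heterozygous X-linked SNPs; a male
#' embryo (hemizygous X) should carry almost none. For each embryo, the
#' per-cell count of biallelically called X-linked SNPs is compared against
#' the pooled per-cell counts of the other embryos with the same label
#' (non-paired Wilcoxon): a "female" embryo significantly below its group,
#' or a "male" embryo significantly above its group, is flagged for
#' exclusion. Groups with fewer than two embryos are skipped with a warning.
#'
#' @param calls Classified SNP-call tibble.
#' @param cells Cell metadata with a `sex` column holding the labels under
#'   scrutiny.
#' @param alpha Test level (default 0.05).
#' @return Tibble `embryo_id, sex, mean_count, group_mean, p.value, flagged`.
#' @export
sex_consistency_check <- function(calls, cells, alpha = 0.05) {
  per_cell <- cells |>
    select("cell_id", "embryo_id", "sex") |>
    left_join(
      calls |>
        filter(is_x_chrom(.data$chrom), .data$klass == "biallelic") |>
        count(.data$cell_id, name = "n_het_x"),
      by = "cell_id") |>
    mutate(n_het_x = ifelse(is.na(.data$n_het_x), 0L, .data$n_het_x)) |>
    filter(.data$sex %in% c("male", "female"))

  map_dfr(unique(per_cell$embryo_id), function(eid) {
    sx <- per_cell$sex[per_cell$embryo_id == eid][1]
    own <- per_cell$n_het_x[per_cell$embryo_id == eid]
    grp <- per_cell |> filter(.data$sex == sx, .data$embryo_id != eid)
    if (n_distinct(grp$embryo_id) < 1 || nrow(grp) < 2) {
      warn(paste0("group too small to check embryo ", eid))
      return(tibble(embryo_id = eid, sex = sx, mean_count = mean(own),
                    group_mean = NA_real_, p.value = NA_real_, flagged = FALSE))
    }
    alt <- if (sx == "female") "less" else "greater"
    ht <- suppressWarnings(wilcox.test(own, grp$n_het_x, alternative = alt,
                                       paired = FALSE, exact = FALSE))
    p <- ht$p.value
    tibble(embryo_id = eid, sex = sx, mean_count = mean(own),
           group_mean = mean(grp$n_het_x), p.value = p,
           flagged = !is.na(p) && p <= alpha)
  })
}

# Per-gene expression ratios to the embryo median, genes ordered by genome
# position; genes whose median across the embryo's cells is 0 are dropped.
ploidy_ratios <- function(tpm, genes, cell_ids) {
  sub <- tpm[, cell_ids, drop = FALSE]
  med <- apply(sub, 1, median)
  keep <- med > 0
  ord <- genes |>
    filter(.data$gene_id %in% rownames(sub)[keep]) |>
    arrange(.data$chrom, .data$start)
  ratios <- sub[ord$gene_id, , drop = FALSE] / med[ord$gene_id]
  list(ratios = ratios, genes = ord)
}

moving_average <- function(v, window) {
  w <- min(window, length(v))
  as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
}

#' Moving-average expression profile for ploidy inspection
#'
#' Per cell, the ratio of each gene's tpm to its median across the embryo's
#' cells, smoothed with a moving average over `window` consecutive genes in
#' chromosomal order. Intended for plotting chromosome-scale gains/losses.
#'
#' @param x An [expr_matrix()] with tpm filled.
#' @param cell_ids Cells of one embryo.
#' @param window Genes per window (default 188).
#' @return Long tibble `cell_id, chrom, gene_id, start, ratio,
#'   moving_average`.
#' @export
ploidy_profile <- function(x, cell_ids, window = 188) {
  if (is.null(x$layers$tpm)) abort("tpm layer not filled; run compute_tpm() first")
  pr <- ploidy_ratios(x$layers$tpm, x$genes, cell_ids)
  map_dfr(colnames(pr$ratios), function(cid) {
    tibble(cell_id = cid, chrom = pr$genes$chrom, gene_id = pr$genes$gene_id,
           start = pr$genes$start, ratio = pr$ratios[, cid]) |>
      group_by(.data$chrom) |>
      mutate(moving_average = moving_average(.data$ratio, window)) |>
      ungroup()
  })
}

#' Expression-based ploidy screen
#'
#' For every cell of every embryo (>= 3 cells) and every chromosome, counts
#' genes overexpressed (ratio to the embryo median strictly above
#' `fold_hi`) and underexpressed (strictly below `fold_lo`), and tests the
#' over/under/neutral partition against the partition observed in a euploid
#' control sample (chi-square on the 2x3 table). A (cell, chromosome) is
#' flagged when its Bonferroni-adjusted p-value (over cells x chromosomes
#' tested) falls below `alpha`. The comparison is relative to the control
#' because single-cell expression ratios are broadly dispersed even in
#' euploid cells.
#'
#' @param x An [expr_matrix()] with tpm filled, containing embryo and
#'   control cells.
#' @param cells Cell metadata for the embryos to screen.
#' @param control_cells Cell ids of the euploid control sample (required).
#' @param window Moving-average window in genes (default 188), used by
#'   [ploidy_profile()]; kept here so reports record it.
#' @param fold_hi,fold_lo Over/under thresholds (defaults 1.5 and 0.67,
#'   strict inequalities).
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble `embryo_id, cell_id, chrom, n_over, n_under, n_tested,
#'   chi2_p, p_adj, flagged`.
#' @export
ploidy_screen <- function(x, cells, control_cells, window = 188,
                          fold_hi = 1.5, fold_lo = 0.67, alpha = 0.05) {
  if (missing(control_cells) || is.null(control_cells) || length(control_cells) < 2) {
    abort("ploidy screening needs a euploid control sample (>= 2 cells)")
  }
  if (is.null(x$layers$tpm)) abort("tpm layer not filled; run compute_tpm() first")
  tpm <- x$layers$tpm

  partition <- function(ratios, genes_chrom) {
    # counts over/under/neutral per cell x chrom
    map_dfr(colnames(ratios), function(cid) {
      r <- ratios[, cid]
      tibble(chrom = genes_chrom, r = r) |>
        group_by(.data$chrom) |>
        summarise(n_over = sum(.data$r > fold_hi),
                  n_under = sum(.data$r < fold_lo),
                  n_tested = n(), .groups = "drop") |>
        mutate(cell_id = cid, .before = 1)
    })
  }

  ctrl <- ploidy_ratios(tpm, x$genes, control_cells)
  ctrl_part <- partition(ctrl$ratios, ctrl$genes$chrom) |>
    group_by(.data$chrom) |>
    summarise(c_over = sum(.data$n_over), c_under = sum(.data$n_under),
              c_neutral = sum(.data$n_tested - .data$n_over - .data$n_under),
              .groups = "drop")

  embs <- cells |> distinct(.data$embryo_id)
  res <- map_dfr(embs$embryo_id, function(eid) {
    ids <- cells$cell_id[cells$embryo_id == eid]
    if (length(ids) < 3) {
      warn(paste0("embryo ", eid, " has < 3 cells; skipped"))
      return(tibble())
    }
    pr <- ploidy_ratios(tpm, x$genes, ids)
    partition(pr$ratios, pr$genes$chrom) |> mutate(embryo_id = eid, .before = 1)
  })
  if (nrow(res) == 0) return(res)

  res <- res |>
    inner_join(ctrl_part, by = "chrom") |>
    mutate(chi2_p = purrr::pmap_dbl(
      list(.data$n_over, .data$n_under, .data$n_tested,
           .data$c_over, .data$c_under, .data$c_neutral),
      function(o, u, t, co, cu, cn) {
        tab <- rbind(c(o, u, t - o - u), c(co, cu, cn))
        if (any(colSums(tab) == 0)) return(1)
        suppressWarnings(chisq.test(tab)$p.value)
      }))
  n_tests <- nrow(res)
  res |>
    mutate(p_adj = pmin(1, .data$chi2_p * n_tests),
           flagged = .data$p_adj < alpha) |>
    select("embryo_id", "cell_id", "chrom", "n_over", "n_under", "n_tested",
           "chi2_p", "p_adj", "flagged")
}
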