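# ggplot2 views of the main result types.

#' Plot biallelic/monoallelic fraction trajectories
#'
#' Boxplots of per-cell fractions by developmental stage, one panel colour
#' per allelic class.
#'
#' @param fractions Output of [cell_allelic_fractions()].
#' @return A ggplot object.
#' @export
plot_allelic_fractions <- function(fractions) {
  long <- fractions |>
    tidyr::pivot_longer(c("frac_biallelic", "frac_monoallelic"),
                        names_to = "class", values_to = "fraction") |>
    mutate(class = sub("frac_", "", .data$class),
           stage = factor(.data$stage, levels = xci_stage_levels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::scale_fill_manual(values = c(biallelic = "grey25", monoallelic = "firebrick")) +
    ggplot2::labs(x = NULL, y = "fraction of expressed genes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_allelic_fractions
#' @param object An `xci_fractions` tibble.
#' @param ... Unused.
#' @export
autoplot.xci_fractions <- function(object, ...) plot_allelic_fractions(object)

#' Plot per-cell sums and medians of biallelic X-linked expression
#'
#' @param dosage Output of [biallelic_dosage_summary()].
#' @return A ggplot object.
#' @export
plot_dosage_summary <- function(dosage) {
  long <- dosage |>
    tidyr::pivot_longer(c("sum_tpm", "median_tpm"),
                        names_to = "statistic", values_to = "tpm") |>
    mutate(stage = factor(.data$stage, levels = xci_stage_levels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$tpm,
                                     fill = .data$statistic)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(sum_tpm = "seagreen", median_tpm = "darkorange")) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "tpm (biallelic X-linked genes)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_dosage_summary
#' @param object An `xci_dosage` tibble.
#' @param ... Unused.
#' @export
autoplot.xci_dosage <- function(object, ...) plot_dosage_summary(object)

#' Plot gene-wise female-to-male ratio distributions by stage
#'
#' Flagged outliers are dropped, matching how the distributions are tested.
#'
#' @param fm Output of [fm_ratio_genewise()].
#' @return A ggplot object.
#' @export
plot_fm_ratio <- function(fm) {
  fm |>
    filter(!.data$outlier) |>
    mutate(stage = factor(.data$stage, levels = xci_stage_levels)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$stage, y = .data$ratio)) +
    ggplot2::geom_boxplot(fill = "grey80", outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = c(1, 2), linetype = "dashed",
                        colour = c("steelblue", "firebrick")) +
    ggplot2::labs(x = NULL, y = "female / male mean expression") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fm_ratio
#' @param object An `fm_ratio` tibble.
#' @param ... Unused.
#' @export
autoplot.fm_ratio <- function(object, ...) plot_fm_ratio(object)

#' Plot per-cell X:A ratios with per-embryo mean and standard error
#'
#' @param xa Output of [xa_ratio()].
#' @return A ggplot object.
#' @export
plot_xa_ratio <- function(xa) {
  summ <- xa_embryo_summary(xa)
  ggplot2::ggplot(xa, ggplot2::aes(x = .data$embryo_id, y = .data$ratio,
                                   colour = .data$sex)) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.7) +
    ggplot2::geom_pointrange(data = summ,
                             ggplot2::aes(y = .data$mean_ratio,
                                          ymin = .data$mean_ratio - .data$sem,
                                          ymax = .data$mean_ratio + .data$sem),
                             colour = "grey30", size = 0.3) +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = NULL, y = "X : autosome median tpm ratio") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname plot_xa_ratio
#' @param object An `xa_ratio` tibble.
#' @param ... Unused.
#' @export
autoplot.xa_ratio <- function(object, ...) plot_xa_ratio(object)

#' Plot a moving-average ploidy profile for one embryo
#'
#' @param x An [expr_matrix()] with tpm filled.
#' @param cell_ids Cells of the embryo.
#' @param window Genes per moving-average window (default 188).
#' @return A ggplot object.
#' @export
plot_ploidy_profile <- function(x, cell_ids, window = 188) {
  prof <- ploidy_profile(x, cell_ids, window)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$start, y = .data$moving_average,
                                     colour = .data$cell_id)) +
    ggplot2::geom_line(na.rm = TRUE, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "expression / embryo median") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
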