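# SNP-level allelic calls and embryo-level gene informativeness.
#
# The calling strategy is deliberately stringent: >= 20 reads over the SNP,
# the SNP detected at that depth in at least two cells of the same embryo,
# ambiguous / intergenic / pseudogene / overlapping-gene annotations removed,
# and (for X analyses) pseudoautosomal SNPs excluded. Loose thresholds
# inflate both false biallelic calls (sequencing error on a monoallelic
# site) and false monoallelic calls (allelic dropout at low depth).

snp_call_classes <- c("biallelic", "mono_ref", "mono_alt",
                      "filtered_low_coverage", "filtered_annotation")

#' Annotation and coverage filters for allele counts
#'
#' Joins allele counts to SNP/gene annotation and cell metadata, then applies
#' the pre-classification filters:
#' * `filtered_annotation`: ambiguous SNP ID, no gene assignment, gene
#'   region class in (intergenic, pseudogene, overlapping), or (when
#'   `drop_par`) a pseudoautosomal gene;
#' * `filtered_low_coverage`: fewer than `min_reads` ref+alt reads, or the
#'   SNP not covered at `min_reads` in at least `min_cells` cells of the
#'   same embryo (both support rules share this class).
#'
#' Rows passing all filters have `klass = NA` and are classified by
#' [classify_snps()].
#'
#' @param counts Allele-count tibble (`cell_id, snp_id, ref_reads, alt_reads`).
#' @param snps SNP annotation tibble.
#' @param genes Gene annotation tibble.
#' @param cells Cell metadata tibble (embryo assignment).
#' @param min_reads Minimum reads over the SNP position (default 20).
#' @param min_cells Minimum cells of the embryo where the SNP reaches
#'   `min_reads` (default 2).
#' @param drop_par Exclude SNPs in PAR genes (default TRUE).
#' @return SNP-call tibble with `cell_id, snp_id, gene_id, chrom, embryo_id,
#'   coverage, ratio, klass`.
#' @export
filter_snps <- function(counts, snps, genes, cells,
                        min_reads = 20, min_cells = 2, drop_par = TRUE) {
  # ambiguous IDs occur at several positions in the annotation; collapse to
  # one row per ID (they are removed below regardless of which position wins)
  snps_u <- snps |>
    select("snp_id", "ambiguous", "gene_id") |>
    group_by(.data$snp_id) |>
    summarise(ambiguous = any(.data$ambiguous), gene_id = .data$gene_id[1],
              .groups = "drop")
  calls <- counts |>
    inner_join(snps_u, by = "snp_id") |>
    left_join(genes |> select("gene_id", "chrom", "region_class", "par"), by = "gene_id") |>
    inner_join(cells |> select("cell_id", "embryo_id"), by = "cell_id") |>
    mutate(
      coverage = .data$ref_reads + .data$alt_reads,
      ratio = ifelse(.data$coverage > 0, .data$ref_reads / .data$coverage, NA_real_)
    )

  bad_annot <- calls$ambiguous | is.na(calls$gene_id) |
    calls$region_class %in% c("intergenic", "pseudogene", "overlapping") |
    (drop_par & calls$par %in% TRUE)
  low_cov <- !bad_annot & calls$coverage < min_reads

  calls <- calls |>
    mutate(klass = case_when(bad_annot ~ "filtered_annotation",
                             low_cov ~ "filtered_low_coverage",
                             TRUE ~ NA_character_))

  # detection support: covered >= min_reads in >= min_cells cells of the embryo
  support <- calls |>
    filter(is.na(.data$klass)) |>
    count(.data$embryo_id, .data$snp_id, name = "n_cells_covered")
  calls |>
    left_join(support, by = c("embryo_id", "snp_id")) |>
    mutate(klass = ifelse(is.na(.data$klass) & .data$n_cells_covered < min_cells,
                          "filtered_low_coverage", .data$klass)) |>
    select("cell_id", "snp_id", "gene_id", "chrom", "embryo_id",
           "ref_reads", "alt_reads", "coverage", "ratio", "klass")
}

#' Classify an allelic expression ratio
#'
#' The relative expression ratio is ref / (ref + alt). By default the
#' boundaries are monoallelic: ratio <= `lo` is `mono_alt`, ratio >= `hi` is
#' `mono_ref`, strictly between is `biallelic`. Setting
#' `boundary_biallelic = TRUE` moves the exact boundary values into the
#' biallelic class.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors.
#' @param lo,hi Ratio band (defaults 0.2 and 0.8).
#' @param boundary_biallelic Whether ratios exactly at `lo`/`hi` count as
#'   biallelic (default FALSE).
#' @return Character vector of classes.
#' @export
classify_allele_ratio <- function(ref_reads, alt_reads, lo = 0.2, hi = 0.8,
                                  boundary_biallelic = FALSE) {
  cov <- ref_reads + alt_reads
  if (any(cov == 0)) abort("zero-coverage record reached classification; filter first")
  ratio <- ref_reads / cov
  if (boundary_biallelic) {
    ifelse(ratio > hi, "mono_ref", ifelse(ratio < lo, "mono_alt", "biallelic"))
  } else {
    ifelse(ratio >= hi, "mono_ref", ifelse(ratio <= lo, "mono_alt", "biallelic"))
  }
}

#' Classify filtered SNP calls
#'
#' Fills `klass` for rows that passed [filter_snps()].
#'
#' @param calls Output of [filter_snps()].
#' @inheritParams classify_allele_ratio
#' @return The calls tibble with `klass` completed.
#' @export
classify_snps <- function(calls, lo = 0.2, hi = 0.8, boundary_biallelic = FALSE) {
  keep <- is.na(calls$klass)
  calls$klass[keep] <- classify_allele_ratio(calls$ref_reads[keep], calls$alt_reads[keep],
                                             lo, hi, boundary_biallelic)
  calls
}

#' Remove X-linked SNPs biallelic in a male control
#'
#' A male line is hemizygous for the X, so any X-linked SNP called biallelic
#' there is an artifact (mapping or annotation); such SNPs are removed from
#' every sample's calls.
#'
#' @param calls Classified SNP-call tibble.
#' @param male_control_cells Character vector of control cell ids. Empty or
#'   NULL is a no-op with a warning.
#' @return Calls with artifact SNPs removed.
#' @export
exclude_male_control_biallelics <- function(calls, male_control_cells) {
  if (is.null(male_control_cells) || length(male_control_cells) == 0) {
    warn("no male control cells supplied; X-linked artifact filter skipped")
    return(calls)
  }
  bad <- calls |>
    filter(.data$cell_id %in% male_control_cells,
           is_x_chrom(.data$chrom),
           .data$klass == "biallelic") |>
    pull(.data$snp_id) |>
    unique()
  calls |> filter(!.data$snp_id %in% bad)
}

# Per (embryo, gene, snp): monoallelic calls on both alleles in different
# cells (one call per cell-snp, so the cells are necessarily distinct).
discordant_mono_snps <- function(calls) {
  calls |>
    filter(.data$klass %in% c("mono_ref", "mono_alt")) |>
    distinct(.data$embryo_id, .data$gene_id, .data$snp_id, .data$klass) |>
    count(.data$embryo_id, .data$gene_id, .data$snp_id) |>
    filter(.data$n == 2L) |>
    select(-"n")
}

# Gene-cells where one SNP is biallelic while another SNP of the same gene in
# the same cell is part of a cross-cell monoallelic pattern: contradictory
# within one cell, so the gene is dropped from that cell's analyses.
flag_inconsistent_cells <- function(calls) {
  disc <- discordant_mono_snps(calls)
  bi_cells <- calls |>
    filter(.data$klass == "biallelic") |>
    distinct(.data$embryo_id, .data$gene_id, .data$cell_id)
  disc_mono_cells <- calls |>
    filter(.data$klass %in% c("mono_ref", "mono_alt")) |>
    semi_join(disc, by = c("embryo_id", "gene_id", "snp_id")) |>
    distinct(.data$embryo_id, .data$gene_id, .data$cell_id)
  inner_join(bi_cells, disc_mono_cells, by = c("embryo_id", "gene_id", "cell_id"))
}

#' Embryo-level gene informativeness
#'
#' A gene is informative in an embryo when its allelic state can be
#' established: `informative_biallelic` when some cell shows biallelic
#' expression at one of its SNPs, `informative_monoallelic` when at least
#' two cells express single but different alleles of the same SNP (the
#' random-XCI signature). A gene expressing the same single allele in every
#' cell (the imprinted pattern) is `non_informative` -- with one expressed
#' allele there is no evidence the embryo is heterozygous rather than
#' homozygous. Gene-cells where two SNPs contradict each other within the
#' same cell are excluded before status is computed; a gene left with no
#' usable cells is `inconsistent`.
#'
#' When both criteria hold on distinct cells (a mosaic embryo part-way
#' through XCI) the monoallelic status takes precedence; per-cell counting
#' for fraction trajectories is done by [cell_allelic_fractions()] from the
#' calls themselves and is unaffected by this precedence.
#'
#' @param calls Classified SNP-call tibble (after any control exclusion).
#' @return Tibble with `embryo_id, gene_id, chrom, status,
#'   n_cells_biallelic, n_cells_monoallelic, n_snps`, plus an attribute
#'   `cell_exclusions` listing the dropped (embryo, gene, cell) triples.
#' @export
gene_informativeness <- function(calls) {
  excl <- flag_inconsistent_cells(calls)
  kept <- calls |>
    filter(.data$klass %in% c("biallelic", "mono_ref", "mono_alt")) |>
    anti_join(excl, by = c("embryo_id", "gene_id", "cell_id"))

  disc <- discordant_mono_snps(kept)

  base <- kept |> distinct(.data$embryo_id, .data$gene_id, .data$chrom)
  n_bi <- kept |>
    filter(.data$klass == "biallelic") |>
    distinct(.data$embryo_id, .data$gene_id, .data$cell_id) |>
    count(.data$embryo_id, .data$gene_id, name = "n_cells_biallelic")
  n_mono <- kept |>
    filter(.data$klass %in% c("mono_ref", "mono_alt")) |>
    semi_join(disc, by = c("embryo_id", "gene_id", "snp_id")) |>
    distinct(.data$embryo_id, .data$gene_id, .data$cell_id) |>
    count(.data$embryo_id, .data$gene_id, name = "n_cells_monoallelic")
  n_snp <- kept |>
    distinct(.data$embryo_id, .data$gene_id, .data$snp_id) |>
    count(.data$embryo_id, .data$gene_id, name = "n_snps")

  status <- base |>
    left_join(n_bi, by = c("embryo_id", "gene_id")) |>
    left_join(n_mono, by = c("embryo_id", "gene_id")) |>
    left_join(n_snp, by = c("embryo_id", "gene_id")) |>
    mutate(across(c("n_cells_biallelic", "n_cells_monoallelic"),
                  ~ifelse(is.na(.x), 0L, .x)),
           status = case_when(
             .data$n_cells_monoallelic > 0 ~ "informative_monoallelic",
             .data$n_cells_biallelic > 0 ~ "informative_biallelic",
             TRUE ~ "non_informative"
           ))

  # genes whose every supporting cell was contradictory
  gone <- excl |>
    distinct(.data$embryo_id, .data$gene_id) |>
    anti_join(status, by = c("embryo_id", "gene_id")) |>
    left_join(calls |> distinct(.data$gene_id, .data$chrom), by = "gene_id") |>
    mutate(status = "inconsistent",
           n_cells_biallelic = 0L, n_cells_monoallelic = 0L, n_snps = NA_integer_)

  out <- bind_rows(status, gone) |>
    select("embryo_id", "gene_id", "chrom", "status",
           "n_cells_biallelic", "n_cells_monoallelic", "n_snps")
  attr(out, "cell_exclusions") <- excl
  out
}
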