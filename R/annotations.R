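# Gene/SNP annotation tables, cell metadata, and allele-count IO.
#
# All coordinates are 1-based inclusive. Tables are plain TSV with a header
# row; missing values are written as ".". VCF (v4.x) is accepted read-only
# for SNP annotation and AD-style allele depths.

gene_region_classes <- c("unique_gene", "pseudogene", "overlapping", "intergenic")

#' Validate a gene annotation table
#'
#' Checks the schema used throughout the package: `gene_id`, `chrom`,
#' `start`, `end` (1-based inclusive), `exonic_length` (bp of exonic
#' sequence, used as the length term of rpkm/tpm), `region_class`
#' (`unique_gene`, `pseudogene`, `overlapping`, `intergenic`) and `par`
#' (logical; gene lies wholly inside a pseudoautosomal interval).
#'
#' @param genes Data frame of gene annotations.
#' @param par_intervals PAR intervals as from [default_par_intervals()];
#'   used to verify `par` flags.
#' @return The validated tibble, invisibly classed.
#' @export
validate_gene_annotation <- function(genes, par_intervals = default_par_intervals()) {
  genes <- as_tibble(genes)
  need <- c("gene_id", "chrom", "start", "end", "exonic_length", "region_class", "par")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) abort(paste0("gene annotation lacks column(s): ", paste(miss, collapse = ", ")))
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) abort(paste0("duplicate gene_id: ", paste(unique(dup), collapse = ", ")))
  if (any(genes$start > genes$end)) abort("gene annotation has start > end")
  if (any(genes$exonic_length <= 0)) abort("exonic_length must be > 0")
  if (any(genes$exonic_length > genes$end - genes$start + 1)) {
    abort("exonic_length exceeds genomic span for some gene(s)")
  }
  bad_class <- setdiff(unique(genes$region_class), gene_region_classes)
  if (length(bad_class) > 0) abort(paste0("unknown region_class: ", paste(bad_class, collapse = ", ")))
  # par = TRUE only allowed for sex chromosomes, wholly inside an interval
  parg <- genes[genes$par, , drop = FALSE]
  if (nrow(parg) > 0) {
    ok <- vapply(seq_len(nrow(parg)), function(i) {
      iv <- par_intervals[par_intervals$chrom == parg$chrom[i], , drop = FALSE]
      (is_x_chrom(parg$chrom[i]) || is_y_chrom(parg$chrom[i])) &&
        any(iv$start <= parg$start[i] & parg$end[i] <= iv$end)
    }, logical(1))
    if (!all(ok)) abort(paste0("par = TRUE outside configured PAR intervals: ",
                               paste(parg$gene_id[!ok], collapse = ", ")))
  }
  genes
}

#' Read / write gene annotations (TSV)
#'
#' @param path File path. Tab-separated with the columns documented in
#'   [validate_gene_annotation()].
#' @param par_intervals PAR intervals for flag validation.
#' @return Tibble of gene annotations.
#' @export
read_gene_annotation <- function(path, par_intervals = default_par_intervals()) {
  genes <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                           col_types = readr::cols(
                             gene_id = "c", chrom = "c", start = "d", end = "d",
                             exonic_length = "d", region_class = "c", par = "l"
                           ))
  prob <- readr::problems(genes)
  if (nrow(prob) > 0) {
    abort(paste0("malformed gene annotation row(s) at line(s): ",
                 paste(unique(prob$row), collapse = ", "), " in ", path))
  }
  validate_gene_annotation(genes, par_intervals)
}

#' @rdname read_gene_annotation
#' @param genes Gene annotation tibble.
#' @export
write_gene_annotation <- function(genes, path) {
  readr::write_tsv(genes, path, na = ".")
  invisible(path)
}

#' Convert half-open BED-style intervals to 1-based inclusive
#'
#' Shifts `start` by +1; `end` is already inclusive under BED conventions.
#' Apply exactly once when ingesting BED-derived gene tables.
#'
#' @param df Data frame with `start` and `end` columns.
#' @return The data frame with 1-based inclusive coordinates.
#' @export
from_bed_coords <- function(df) {
  df$start <- df$start + 1L
  df
}

#' Validate a SNP annotation table
#'
#' Schema: `snp_id` (dbSNP-style), `chrom`, `pos` (1-based), `ref_allele`,
#' `alt_allele` (single distinct nucleotides), `gene_id` (NA when not
#' assigned), `ambiguous` (logical: the same ID occurs at more than one
#' genomic position). Ambiguous IDs are flagged here, not dropped; dropping
#' happens in [filter_snps()].
#'
#' @param snps Data frame of SNP annotations.
#' @param genes Optional gene annotation; when given, checks that assigned
#'   SNPs fall inside their gene.
#' @return Validated tibble.
#' @export
validate_snp_annotation <- function(snps, genes = NULL) {
  snps <- as_tibble(snps)
  need <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele", "gene_id", "ambiguous")
  miss <- setdiff(need, names(snps))
  if (length(miss) > 0) abort(paste0("SNP annotation lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(snps$ref_allele == snps$alt_allele)) abort("ref_allele == alt_allele for some SNP(s)")
  if (!is.null(genes)) {
    chk <- snps |>
      filter(!is.na(.data$gene_id)) |>
      inner_join(genes |> select("gene_id", g_start = "start", g_end = "end"), by = "gene_id")
    bad <- chk$snp_id[chk$pos < chk$g_start | chk$pos > chk$g_end]
    if (length(bad) > 0) abort(paste0("SNP outside assigned gene: ", paste(bad, collapse = ", ")))
  }
  snps
}

# Same rsID at >1 position => every such record is ambiguous.
flag_ambiguous_ids <- function(snps) {
  snps |>
    group_by(.data$snp_id) |>
    mutate(ambiguous = n_distinct(paste(.data$chrom, .data$pos)) > 1L) |>
    ungroup()
}

# Assign each SNP to the unique gene containing it; NA when none or several
# genes contain the position (overlapping-gene regions are filtered later via
# region_class anyway).
assign_snps_to_genes <- function(snps, genes) {
  hits <- snps |>
    select("snp_id", "chrom", "pos") |>
    inner_join(genes |> select("gene_id", "chrom", "start", "end"),
               by = "chrom", relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    group_by(.data$snp_id) |>
    summarise(gene_id = if (n() == 1L) .data$gene_id[1] else NA_character_,
              .groups = "drop")
  snps |>
    select(-any_of("gene_id")) |>
    left_join(hits |> select("snp_id", "gene_id"), by = "snp_id")
}

#' Read SNP annotations from TSV
#'
#' The `ambiguous` column is recomputed from the data (same ID at multiple
#' positions) regardless of any stored value. If `gene_id` is absent and a
#' gene table is supplied, SNPs are assigned to the unique containing gene.
#'
#' @param path TSV path with at least `snp_id, chrom, pos, ref_allele,
#'   alt_allele` and optionally `gene_id`.
#' @param genes Optional gene annotation tibble for assignment/validation.
#' @return Tibble of SNP annotations.
#' @export
read_snp_annotation <- function(path, genes = NULL) {
  snps <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
  prob <- readr::problems(snps)
  if (nrow(prob) > 0) {
    abort(paste0("malformed SNP annotation row(s) at line(s): ",
                 paste(unique(prob$row), collapse = ", "), " in ", path))
  }
  if (!"gene_id" %in% names(snps)) {
    if (is.null(genes)) snps$gene_id <- NA_character_ else snps <- assign_snps_to_genes(snps, genes)
  }
  snps <- flag_ambiguous_ids(snps)
  validate_snp_annotation(snps, genes)
}

#' @rdname read_snp_annotation
#' @param snps SNP annotation tibble.
#' @export
write_snp_annotation <- function(snps, path) {
  readr::write_tsv(snps, path, na = ".")
  invisible(path)
}

#' Read SNP annotations from a VCF file
#'
#' Keeps biallelic single-nucleotide records. Missing IDs (`.`) are
#' synthesized as `chrom:pos`; IDs occurring at several positions are
#' flagged `ambiguous`. Gene assignment uses the supplied gene table.
#'
#' @param path VCF (v4.x) path, plain text or bgzipped.
#' @param genes Optional gene annotation tibble.
#' @return Tibble of SNP annotations.
#' @export
read_snp_vcf <- function(path, genes = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- tibble(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT
  ) |>
    filter(nchar(.data$ref_allele) == 1L, nchar(.data$alt_allele) == 1L,
           !grepl(",", .data$alt_allele, fixed = TRUE))
  snps$snp_id[is.na(snps$snp_id) | snps$snp_id == "."] <-
    paste0(snps$chrom, ":", snps$pos)[is.na(snps$snp_id) | snps$snp_id == "."]
  if (is.null(genes)) snps$gene_id <- NA_character_ else snps <- assign_snps_to_genes(snps, genes)
  snps <- flag_ambiguous_ids(snps)
  validate_snp_annotation(snps, genes)
}

#' Read per-cell allele depths from a VCF with AD fields
#'
#' Extracts ref/alt read counts from the `AD` FORMAT field, one record per
#' (sample, variant) with nonzero data. Sample names become `cell_id`.
#'
#' @param path VCF path.
#' @return Allele-count tibble (`cell_id`, `snp_id`, `ref_reads`, `alt_reads`).
#' @export
read_allele_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".", paste0(fix$CHROM, ":", fix$POS), fix$ID)
  ad <- vcfR::extract.gt(v, element = "AD")
  dup <- ids %in% ids[duplicated(ids)]
  if (any(dup)) {
    # ambiguous IDs (same ID at several positions) cannot be keyed by snp_id;
    # the annotation filters remove them from every analysis anyway
    warn(paste0(sum(dup), " variant row(s) with duplicated IDs dropped from depths"))
    ad <- ad[!dup, , drop = FALSE]
    ids <- ids[!dup]
  }
  rownames(ad) <- ids
  long <- as_tibble(ad, rownames = "snp_id") |>
    tidyr::pivot_longer(-"snp_id", names_to = "cell_id", values_to = "ad") |>
    filter(!is.na(.data$ad), .data$ad != ".") |>
    tidyr::separate("ad", into = c("ref_reads", "alt_reads"), sep = ",",
                    extra = "drop", convert = TRUE)
  validate_allele_counts(long |> select("cell_id", "snp_id", "ref_reads", "alt_reads"))
}

#' Validate / read / write allele-count tables
#'
#' Allele counts are the downstream equivalent of a variant caller's
#' per-sample ref/alt read depths: one row per (cell, SNP) with non-negative
#' integer `ref_reads` and `alt_reads`.
#'
#' @param counts Data frame of allele counts.
#' @param known_snps Optional vector of annotated SNP IDs; unknown IDs are
#'   tolerated with a warning that reports how many were seen.
#' @return Validated tibble.
#' @export
validate_allele_counts <- function(counts, known_snps = NULL) {
  counts <- as_tibble(counts)
  need <- c("cell_id", "snp_id", "ref_reads", "alt_reads")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) abort(paste0("allele counts lack column(s): ", paste(miss, collapse = ", ")))
  if (nrow(counts) > 0 && (any(counts$ref_reads < 0) || any(counts$alt_reads < 0))) {
    abort("negative allele read counts")
  }
  if (anyDuplicated(counts[c("cell_id", "snp_id")]) > 0) {
    abort("more than one allele-count record for some (cell, snp)")
  }
  if (!is.null(known_snps)) {
    n_unknown <- sum(!counts$snp_id %in% known_snps)
    if (n_unknown > 0) warn(paste0(n_unknown, " allele-count record(s) with unannotated snp_id"))
  }
  counts
}

#' @rdname validate_allele_counts
#' @param path TSV path with columns `cell_id, snp_id, ref_reads, alt_reads`.
#' @export
read_allele_counts <- function(path, known_snps = NULL) {
  counts <- readr::read_tsv(path, na = ".", show_col_types = FALSE,
                            col_types = readr::cols(
                              cell_id = "c", snp_id = "c",
                              ref_reads = "i", alt_reads = "i"
                            ))
  validate_allele_counts(counts, known_snps)
}

#' @rdname validate_allele_counts
#' @export
write_allele_counts <- function(counts, path) {
  readr::write_tsv(counts, path, na = ".")
  invisible(path)
}

#' Validate / read / write cell metadata
#'
#' Schema: `cell_id` (unique), `embryo_id`, `stage` (one of
#' [xci_stage_levels]), `embryonic_day` (integer or NA), `sex`
#' (`male`/`female`/`unknown`), `lineage` (`ICM`/`TE`/NA), `dataset`.
#' All cells of an embryo must share stage and sex.
#'
#' @param meta Data frame of cell metadata.
#' @return Validated tibble.
#' @export
validate_cell_meta <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("cell_id", "embryo_id", "stage", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) abort(paste0("cell metadata lacks column(s): ", paste(miss, collapse = ", ")))
  if (!"embryonic_day" %in% names(meta)) meta$embryonic_day <- NA_integer_
  if (!"lineage" %in% names(meta)) meta$lineage <- NA_character_
  if (!"dataset" %in% names(meta)) meta$dataset <- "unspecified"
  meta$embryonic_day <- as.integer(meta$embryonic_day)
  meta$lineage <- as.character(meta$lineage)
  if (anyDuplicated(meta$cell_id) > 0) abort("duplicate cell_id in metadata")
  bad <- setdiff(unique(meta$stage), xci_stage_levels)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  if (!all(meta$sex %in% c("male", "female", "unknown"))) abort("sex must be male/female/unknown")
  inc <- meta |>
    group_by(.data$embryo_id) |>
    summarise(ok = n_distinct(.data$stage) == 1L && n_distinct(.data$sex) == 1L, .groups = "drop")
  if (!all(inc$ok)) {
    abort(paste0("embryo(s) with mixed stage or sex: ",
                 paste(inc$embryo_id[!inc$ok], collapse = ", ")))
  }
  meta
}

#' @rdname validate_cell_meta
#' @param path TSV path.
#' @export
read_cell_meta <- function(path) {
  meta <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
  validate_cell_meta(meta)
}

#' @rdname validate_cell_meta
#' @export
write_cell_meta <- function(meta, path) {
  readr::write_tsv(meta, path, na = ".")
  invisible(path)
}
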