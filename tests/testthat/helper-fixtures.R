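# Tiny deterministic builders shared across test files. Everything is
# constructed in code; no fixture files.

library(dplyr)
library(tibble)

toy_genes <- function() {
  tribble(
    ~gene_id, ~chrom,  ~start,   ~end,     ~exonic_length, ~region_class, ~par,
    "AUT1",   "chr1",  1000,     9000,     2000,           "unique_gene", FALSE,
    "AUT2",   "chr1",  20000,    28000,    1500,           "overlapping", FALSE,
    "PSG1",   "chr2",  1000,     6000,     1000,           "pseudogene",  FALSE,
    "AUT3",   "chr2",  10000,    18000,    1200,           "unique_gene", FALSE,
    "XA",     "chrX",  3000000,  3008000,  1000,           "unique_gene", FALSE,
    "XB",     "chrX",  4000000,  4009000,  2000,           "unique_gene", FALSE,
    "XPAR",   "chrX",  70001,    80000,    1000,           "unique_gene", TRUE,
    "YG1",    "chrY",  3000000,  3006000,  800,            "unique_gene", FALSE
  )
}

toy_snps <- function() {
  tribble(
    ~snp_id, ~chrom, ~pos,     ~ref_allele, ~alt_allele, ~gene_id, ~ambiguous,
    "rsA1",  "chr1", 2000,     "A", "G", "AUT1", FALSE,
    "rsA2",  "chr1", 21000,    "C", "T", "AUT2", FALSE,
    "rsP1",  "chr2", 2000,     "G", "A", "PSG1", FALSE,
    "rsA3",  "chr2", 11000,    "T", "C", "AUT3", FALSE,
    "rsXA",  "chrX", 3000100,  "A", "C", "XA",   FALSE,
    "rsXB",  "chrX", 4000200,  "G", "T", "XB",   FALSE,
    "rsPAR", "chrX", 71000,    "A", "T", "XPAR", FALSE,
    "rsNOG", "chr1", 500,      "A", "G", NA,     FALSE,
    "rsDUP", "chr1", 3000,     "A", "G", "AUT1", TRUE,
    "rsDUP", "chr2", 12000,    "A", "G", "AUT3", TRUE
  )
}

toy_cells <- function() {
  tribble(
    ~cell_id, ~embryo_id, ~stage,  ~sex,
    "e1c1",   "E1",       "cell8", "female",
    "e1c2",   "E1",       "cell8", "female",
    "e1c3",   "E1",       "cell8", "female",
    "e2c1",   "E2",       "morula", "male",
    "e2c2",   "E2",       "morula", "male",
    "ctrl1",  "CTRL",     "cell_line", "male"
  ) |> mutate(embryonic_day = NA_integer_, lineage = NA_character_, dataset = "toy")
}

# expression matrix with chosen counts; counts: named list gene_id -> vector
# over cells (in toy_cells order unless cells supplied)
toy_em <- function(counts_list, genes = toy_genes(), cells = toy_cells(),
                   library_size = NULL) {
  m <- do.call(rbind, counts_list)
  rownames(m) <- names(counts_list)
  colnames(m) <- cells$cell_id
  expr_matrix(m, genes, cells, library_size)
}

# allele-count row builder
ac <- function(cell, snp, ref, alt) {
  tibble(cell_id = cell, snp_id = snp, ref_reads = as.integer(ref),
         alt_reads = as.integer(alt))
}

# run counts through the standard filter+classify path with toy annotations
toy_calls <- function(counts, min_reads = 20, min_cells = 2, drop_par = TRUE, ...) {
  filter_snps(counts, toy_snps(), toy_genes(), toy_cells(),
              min_reads = min_reads, min_cells = min_cells, drop_par = drop_par) |>
    classify_snps(...)
}

# a small expression matrix for sexing: 12 Y genes plus autosomes, with male
# embryos/controls expressing Y and females/oocytes silent
sexing_em <- function() {
  ny <- 12
  ygenes <- tibble(gene_id = sprintf("Y%02d", 1:ny), chrom = "chrY",
                   start = 3e6 + (1:ny) * 2e4, end = 3e6 + (1:ny) * 2e4 + 5000,
                   exonic_length = 1000, region_class = "unique_gene", par = FALSE)
  agenes <- tibble(gene_id = sprintf("A%02d", 1:8), chrom = "chr1",
                   start = 1e6 + (1:8) * 2e4, end = 1e6 + (1:8) * 2e4 + 5000,
                   exonic_length = 1000, region_class = "unique_gene", par = FALSE)
  genes <- bind_rows(agenes, ygenes)
  cells <- tribble(
    ~cell_id, ~embryo_id, ~stage, ~sex,
    "m1c1", "M1", "cell8", "unknown",
    "m1c2", "M1", "cell8", "unknown",
    "f1c1", "F1", "cell8", "unknown",
    "f1c2", "F1", "cell8", "unknown",
    "oo1",  "OO1", "oocyte", "female",
    "oo2",  "OO2", "oocyte", "female",
    "oo3",  "OO3", "oocyte", "female",
    "hes1", "HES", "cell_line", "male",
    "hes2", "HES", "cell_line", "male"
  ) |> mutate(embryonic_day = NA_integer_, lineage = NA_character_, dataset = "toy")
  male_like <- c("m1c1", "m1c2", "hes1", "hes2")
  counts <- matrix(100L, nrow(genes), nrow(cells),
                   dimnames = list(genes$gene_id, cells$cell_id))
  counts[ygenes$gene_id, !colnames(counts) %in% male_like] <- 0L
  counts[ygenes$gene_id[11:12], ] <- 0L   # two Y genes expressed nowhere
  expr_matrix(counts, genes, cells) |> compute_rpkm()
}

# two-sided Fisher p by exhaustive hypergeometric tail enumeration for a
# 2x2 table [a b; c d] -- the independent oracle
fisher_enum_p <- function(a, b, c, d) {
  k <- max(0, (a + b) - (b + d)):min(a + b, a + c)
  dens <- stats::dhyper(k, a + c, b + d, a + b)
  sum(dens[dens <= stats::dhyper(a, a + c, b + d, a + b) * (1 + 1e-7)])
}
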