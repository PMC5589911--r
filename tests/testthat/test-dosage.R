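# builds an expr_matrix over the toy annotation with injected layers so the
# dosage statistics can be checked against hand-computed values
layered_em <- function(tpm_vals = NULL, rpkm_vals = NULL, genes = toy_genes(),
                       cells = toy_cells()) {
  m <- matrix(10L, nrow(genes), nrow(cells),
              dimnames = list(genes$gene_id, cells$cell_id))
  em <- expr_matrix(m, genes, cells)
  em <- compute_rpkm(em) |> compute_tpm()
  if (!is.null(tpm_vals)) em$layers$tpm[rownames(tpm_vals), colnames(tpm_vals)] <- tpm_vals
  if (!is.null(rpkm_vals)) em$layers$rpkm[rownames(rpkm_vals), colnames(rpkm_vals)] <- rpkm_vals
  em
}

test_that("per-cell biallelic sums and medians follow their definitions", {
  counts <- bind_rows(ac("e1c1", "rsXA", 15, 15), ac("e1c2", "rsXA", 16, 14))
  calls <- toy_calls(counts)
  tpm <- matrix(c(10, 40), 1, 2, dimnames = list("XA", c("e1c1", "e1c2")))
  em <- layered_em(tpm_vals = tpm)
  em$layers$rpkm["XA", c("e1c1", "e1c2")] <- c(5, 5)  # expressed
  dos <- biallelic_dosage_summary(calls, em, toy_cells())
  expect_equal(dos$sum_tpm[dos$cell_id == "e1c1"], 10)
  expect_equal(dos$median_tpm[dos$cell_id == "e1c1"], 10)
  expect_equal(dos$n_biallelic, c(1L, 1L))
  # the third female cell had no biallelic X gene and is counted as excluded
  expect_equal(attr(dos, "n_excluded_cells"), 1L)

  # genes below the expressed threshold in a cell do not enter the summary
  em$layers$rpkm["XA", "e1c2"] <- 0.05
  dos2 <- biallelic_dosage_summary(calls, em, toy_cells())
  expect_false("e1c2" %in% dos2$cell_id)
})

test_that("F:M gene ratios: equality, the 5-rpkm floor, and sex symmetry", {
  genes <- tibble(gene_id = c("X1", "X2", "X3"), chrom = "chrX",
                  start = c(3e6, 4e6, 5e6), end = c(3e6, 4e6, 5e6) + 9000,
                  exonic_length = 1000, region_class = "unique_gene", par = FALSE)
  cells <- tibble(cell_id = c("f1", "f2", "m1", "m2"),
                  embryo_id = c("EF", "EF", "EM", "EM"),
                  stage = "cell8", sex = c("female", "female", "male", "male"))
  snps <- tibble(snp_id = paste0("s", 1:3), chrom = "chrX",
                 pos = c(3e6, 4e6, 5e6) + 100, ref_allele = "A", alt_allele = "G",
                 gene_id = c("X1", "X2", "X3"), ambiguous = FALSE)
  counts <- bind_rows(ac("f1", "s1", 15, 15), ac("f2", "s1", 14, 16),
                      ac("f1", "s2", 15, 15), ac("f2", "s2", 14, 16),
                      ac("f1", "s3", 15, 15), ac("f2", "s3", 14, 16))
  calls <- filter_snps(counts, snps, genes, cells) |> classify_snps()

  m <- matrix(50L, 3, 4, dimnames = list(genes$gene_id, cells$cell_id))
  em <- expr_matrix(m, genes, cells) |> compute_rpkm() |> compute_tpm()
  em$layers$rpkm <- matrix(c(
    10, 10, 10, 10,    # X1: mean_f = mean_m = 10 -> ratio 1
    4.9, 4.9, 8, 8,    # X2: female mean below 5 -> excluded
    20, 20, 10, 10     # X3: ratio 2
  ), 3, 4, byrow = TRUE, dimnames = dimnames(m))
  fm <- fm_ratio_genewise(calls, em, cells)
  expect_equal(sort(fm$gene_id), c("X1", "X3"))
  expect_equal(fm$ratio[fm$gene_id == "X1"], 1)
  expect_equal(fm$ratio[fm$gene_id == "X3"], 2)

  # swapping the sex labels inverts every ratio
  cells_sw <- cells |> mutate(sex = ifelse(sex == "female", "male", "female"))
  calls_sw <- filter_snps(counts |>
                            mutate(cell_id = c("m1", "m2")[match(cell_id, c("f1", "f2"))]),
                          snps, genes, cells_sw) |> classify_snps()
  fm_sw <- fm_ratio_genewise(calls_sw, em, cells_sw)
  both <- inner_join(fm |> select(gene_id, r = ratio),
                     fm_sw |> select(gene_id, r_sw = ratio), by = "gene_id")
  expect_equal(both$r_sw, 1 / both$r)

  # a stage without male cells is skipped and recorded
  fm_f <- fm_ratio_genewise(calls, em, cells |> filter(sex == "female"))
  expect_equal(nrow(fm_f), 0L)
  expect_equal(attr(fm_f, "skipped_stages"), "cell8")
})

test_that("XCI and dampening cohorts separate on median and F:M signatures", {
  x <- xci_scenario_stats("progressive_xci", seed = 101)
  d <- xci_scenario_stats("dampening", seed = 102)
  # XCI: the sum collapses (fewer biallelic genes) but the F:M ratio of the
  # remaining biallelic genes approaches 2
  expect_lt(x$p_sum_decrease, 0.05)
  expect_gt(x$fm_median_final, 1.5)
  # dampening: every biallelic gene weakens -> median falls, F:M stays near 1
  expect_lt(d$p_median_decrease, 0.05)
  expect_gt(d$fm_median_final, 0.8)
  expect_lt(d$fm_median_final, 1.25)
  # trend signatures
  expect_lt(x$bi_r, 0); expect_lt(x$bi_p, 0.05)
  expect_gt(x$mono_r, 0); expect_lt(x$mono_p, 0.05)
})

test_that("paired stage tests on F:M distributions run on shared genes", {
  d <- simulate_cohort(scenario_config("dampening", seed = 9, embryos_per_stage = 4,
                                       n_genes_x = 150, n_genes_auto = 600))
  em <- d$em |> compute_rpkm() |> compute_tpm()
  calls <- filter_snps(d$allele_counts, d$snps, d$genes, d$cells) |> classify_snps()
  fm <- fm_ratio_genewise(calls, em, d$cells)
  tests <- fm_ratio_tests(fm)
  expect_true(all(tests$p.value >= 0 & tests$p.value <= 1))
  expect_true("between_stages" %in% tests$comparison)
  expect_true("female_vs_male" %in% tests$comparison)
})

test_that("X:A ratios are scale-invariant and match construction oracles", {
  co <- simulate_cohort(scenario_config("pre_xci", stages = "cell8",
                                        sexes = "female", seed = 3))
  em <- co$em |> compute_rpkm() |> compute_tpm()
  xa1 <- xa_ratio(em, co$cells)
  # common rescaling of one cell's tpm leaves its ratio unchanged
  em2 <- em
  em2$layers$tpm[, 1] <- em2$layers$tpm[, 1] * 3
  xa2 <- xa_ratio(em2, co$cells)
  expect_equal(xa2$ratio, xa1$ratio)

  # dosage-state oracles, averaged over a few seeds
  fem <- mean(sapply(1:4, function(s) xa_ratio_median("pre_xci", s)))
  mal <- mean(sapply(1:4, function(s) xa_ratio_median("male", s, sexes = "male")))
  upx <- mean(sapply(1:4, function(s)
    xa_ratio_median("upregulated_xa", s, sexes = "male", xa_upregulation = 2)))
  expect_lt(abs(fem - 1), 0.12)
  expect_lt(abs(mal - 0.5), 0.12)
  expect_lt(abs(upx - 1), 0.12)

  summ <- xa_embryo_summary(xa1)
  expect_equal(nrow(summ), dplyr::n_distinct(co$cells$embryo_id))
  gt <- xa_group_test(xa1, xa1$cell_id[1:12], xa1$cell_id[13:24])
  expect_true(gt$p.value >= 0 & gt$p.value <= 1)
})
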