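test_that("Fisher sexing p-values match hypergeometric enumeration", {
  # exhaustive over all tables with row sums <= 8, plus random larger tables
  # with margins <= 30
  tables <- list()
  for (r1 in 1:8) for (r2 in 1:8) for (a in 0:r1) for (c in 0:r2) {
    tables[[length(tables) + 1]] <- c(a, r1 - a, c, r2 - c)
  }
  set.seed(41)
  for (i in 1:300) {
    r1 <- sample(1:30, 1); r2 <- sample(1:30, 1)
    tables[[length(tables) + 1]] <- c(s1 <- sample(0:r1, 1), r1 - s1,
                                      s2 <- sample(0:r2, 1), r2 - s2)
  }
  for (tb in tables) {
    got <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(got, fisher_enum_p(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-8)
  }
  # the worked toy table
  expect_equal(stats::fisher.test(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))$p.value,
               fisher_enum_p(8, 2, 1, 9), tolerance = 1e-10)
})

test_that("embryos are sexed against oocyte and male-line pools", {
  em <- sexing_em()
  res <- sex_embryos(em, em$cells,
                     female_control_cells = c("oo1", "oo2", "oo3"),
                     male_control_cells = c("hes1", "hes2"))
  expect_equal(res$call[res$embryo_id == "M1"], "male")
  expect_equal(res$call[res$embryo_id == "F1"], "female")
  expect_equal(res$n_y_tested, rep(12L, 2))
  expect_equal(res$n_y_expressed[res$embryo_id == "M1"], 10L)
  expect_equal(res$n_y_expressed[res$embryo_id == "F1"], 0L)
  # n_tests defaults to embryos x control pools
  expect_equal(unique(res$threshold), 0.05 / 4)

  expect_error(sex_embryo(em, c("f1c1", "f1c2"), c("oo1", "oo2"), c("hes1", "hes2"),
                          stage = "cell4", n_tests = 18),
               "prior to embryonic genome activation")
})

test_that("the Bonferroni threshold for 18 tests matches the printed value", {
  em <- sexing_em()
  one <- sex_embryo(em, c("m1c1", "m1c2"), c("oo1", "oo2", "oo3"),
                    c("hes1", "hes2"), stage = "cell8", n_tests = 18)
  expect_equal(one$threshold, 0.05 / 18)
  # printed as 0.00277 (truncated at the third significant figure)
  expect_equal(floor(one$threshold * 1e5) / 1e5, 0.00277)
})

test_that("sex consistency flags embryos with discordant X heterozygosity", {
  mk_calls <- function(cell, n) {
    if (n == 0) return(tibble())
    tibble(cell_id = cell, snp_id = paste0(cell, "_s", seq_len(n)),
           gene_id = "XA", chrom = "chrX",
           embryo_id = NA_character_, coverage = 30L, ratio = 0.5,
           klass = "biallelic")
  }
  cells <- bind_rows(
    purrr::map_dfr(1:5, function(e) tibble(cell_id = paste0("f", e, "c", 1:4),
                                           embryo_id = paste0("F", e),
                                           stage = "cell8", sex = "female")),
    tibble(cell_id = paste0("m1c", 1:4), embryo_id = "M1", stage = "cell8",
           sex = "male"),
    tibble(cell_id = paste0("m2c", 1:4), embryo_id = "M2", stage = "cell8",
           sex = "male")
  )
  # F1 looks male (about 3 het X SNPs per cell); other females about 12
  n_het <- c(f1 = 3, f2 = 12, f3 = 13, f4 = 12, f5 = 11)
  calls <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cid <- cells$cell_id[i]
    n <- if (cells$sex[i] == "male") 0 else n_het[[substr(cid, 1, 2)]]
    mk_calls(cid, n)
  })
  res <- sex_consistency_check(calls, cells)
  expect_true(res$flagged[res$embryo_id == "F1"])
  expect_false(any(res$flagged[res$embryo_id %in% c("F2", "F3", "F4", "F5")]))
  expect_false(any(res$flagged[res$sex == "male"]))

  # a male-labelled embryo with female-like heterozygosity is flagged
  calls2 <- bind_rows(calls, purrr::map_dfr(paste0("m2c", 1:4), mk_calls, n = 10))
  res2 <- sex_consistency_check(calls2, cells)
  expect_true(res2$flagged[res2$embryo_id == "M2"])

  # identical embryos: nothing flagged
  calls3 <- purrr::map_dfr(cells$cell_id[cells$sex == "female"], mk_calls, n = 10)
  res3 <- sex_consistency_check(calls3, cells |> filter(sex == "female"))
  expect_false(any(res3$flagged))
})

test_that("ploidy ratios respect strict fold thresholds and clean profiles", {
  genes <- tibble(gene_id = paste0("G", 1:40), chrom = rep(c("chr1", "chr2"), each = 20),
                  start = rep((1:20) * 1e4, 2), end = rep((1:20) * 1e4 + 5000, 2),
                  exonic_length = 1000, region_class = "unique_gene", par = FALSE)
  cells <- tibble(cell_id = c(paste0("e1c", 1:3), paste0("k", 1:3)),
                  embryo_id = c(rep("E1", 3), rep("K", 3)),
                  stage = "cell8", sex = "female")
  cnt <- matrix(50L, 40, 6, dimnames = list(genes$gene_id, cells$cell_id))
  em <- expr_matrix(cnt, genes, cells) |> compute_tpm()
  # one cell at exactly 1.5x the embryo median: strict > keeps n_over at 0
  em$layers$tpm[, "e1c3"] <- em$layers$tpm[, "e1c3"] * 1.5
  rep <- ploidy_screen(em, cells |> filter(embryo_id == "E1"),
                       control_cells = paste0("k", 1:3), window = 5)
  expect_equal(sum(rep$n_over), 0L)
  expect_equal(sum(rep$n_under), 0L)
  expect_false(any(rep$flagged))

  expect_error(ploidy_screen(em, cells |> filter(embryo_id == "E1"),
                             control_cells = NULL), "euploid control")

  prof <- ploidy_profile(em, paste0("e1c", 1:3), window = 100)  # window > genes
  ma <- stats::na.omit(prof$moving_average[prof$cell_id == "e1c2"])
  expect_gt(length(ma), 0)
  expect_true(all(abs(ma - 1) < 1e-9))
})

test_that("an injected chromosomal gain is flagged against the euploid control", {
  # moderate technical dispersion so a 1.5-fold gain on ~50 genes is within
  # the screen's detection range
  co <- simulate_cohort(scenario_config("aneuploid", stages = "cell8",
                                        sexes = "female", embryos_per_stage = 2,
                                        n_genes_x = 50, n_genes_auto = 2200,
                                        n_genes_y = 0, n_genes_par = 0,
                                        count_dispersion = 10,
                                        aneuploid_chrom = "chr16",
                                        aneuploid_fold = 1.5, seed = 12))
  em <- co$em |> compute_tpm()
  screened <- co$cells |> filter(embryo_id == co$cells$embryo_id[1])
  control <- co$cells |> filter(embryo_id != co$cells$embryo_id[1])
  rep <- ploidy_screen(em, screened, control_cells = control$cell_id)
  hit <- rep |> filter(cell_id %in% co$truth$aneuploid_cells, chrom == "chr16")
  expect_true(any(hit$flagged))
  # other chromosomes of the same embryo stay largely clean
  other <- rep |> filter(chrom != "chr16")
  expect_lt(mean(other$flagged), 0.05)
})

test_that("the euploid false-flag rate stays within the nominal level", {
  n_runs <- 200
  flags <- tested <- 0
  for (s in seq_len(n_runs)) {
    co <- simulate_cohort(scenario_config("pre_xci", stages = "cell8",
                                          sexes = "female", embryos_per_stage = 2,
                                          cells_per_embryo = 4,
                                          n_genes_x = 40, n_genes_auto = 200,
                                          n_genes_y = 0, n_genes_par = 0,
                                          het_snp_rate = 0, seed = 1000 + s))
    em <- co$em |> compute_tpm()
    e1 <- co$cells$embryo_id[1]
    rep <- ploidy_screen(em, co$cells |> filter(embryo_id == e1),
                         control_cells = co$cells$cell_id[co$cells$embryo_id != e1])
    flags <- flags + sum(rep$flagged)
    tested <- tested + nrow(rep)
  }
  expect_lt(flags / tested, 0.05)
})
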