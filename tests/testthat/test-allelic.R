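# Brute-force classifier oracle on integer arithmetic: avoids the floating
# ratio the implementation divides, so the two routes are independent.
oracle_class <- function(ref, alt, boundary_biallelic = FALSE) {
  cov <- ref + alt
  if (boundary_biallelic) {
    if (5L * ref > 4L * cov) "mono_ref" else if (5L * ref < cov) "mono_alt" else "biallelic"
  } else {
    if (5L * ref >= 4L * cov) "mono_ref" else if (5L * ref <= cov) "mono_alt" else "biallelic"
  }
}

test_that("ratio classification matches the exhaustive oracle and examples", {
  expect_equal(classify_allele_ratio(10, 10), "biallelic")
  expect_equal(classify_allele_ratio(16, 4), "mono_ref")   # ratio exactly 0.8
  expect_equal(classify_allele_ratio(0, 25), "mono_alt")
  expect_equal(classify_allele_ratio(16, 4, boundary_biallelic = TRUE), "biallelic")
  expect_error(classify_allele_ratio(0, 0), "zero-coverage")

  for (cov in 20:60) {
    ref <- 0:cov
    got <- classify_allele_ratio(ref, cov - ref)
    want <- vapply(ref, function(r) oracle_class(r, cov - r), character(1))
    expect_equal(got, want)
    got_b <- classify_allele_ratio(ref, cov - ref, boundary_biallelic = TRUE)
    want_b <- vapply(ref, function(r) oracle_class(r, cov - r, TRUE), character(1))
    expect_equal(got_b, want_b)
  }
})

test_that("swapping ref/alt labels mirrors the monoallelic classes", {
  set.seed(31)
  ref <- rpois(500, 15); alt <- rpois(500, 15)
  keep <- ref + alt >= 20
  ref <- ref[keep]; alt <- alt[keep]
  fwd <- classify_allele_ratio(ref, alt)
  rev <- classify_allele_ratio(alt, ref)
  expect_equal(rev[fwd == "mono_ref"], rep("mono_alt", sum(fwd == "mono_ref")))
  expect_equal(rev[fwd == "mono_alt"], rep("mono_ref", sum(fwd == "mono_alt")))
  expect_equal(rev[fwd == "biallelic"], rep("biallelic", sum(fwd == "biallelic")))
})

test_that("annotation and coverage filters implement each exclusion rule", {
  counts <- bind_rows(
    ac("e1c1", "rsA1", 10, 9),    # coverage 19 -> low coverage
    ac("e1c1", "rsA2", 30, 30),   # overlapping-gene region
    ac("e1c1", "rsP1", 30, 30),   # pseudogene
    ac("e1c1", "rsNOG", 30, 30),  # no gene assignment
    ac("e1c1", "rsDUP", 30, 30),  # ambiguous ID
    ac("e1c1", "rsPAR", 30, 30),  # pseudoautosomal
    ac("e1c1", "rsXA", 15, 15),   # supported in two cells -> kept
    ac("e1c2", "rsXA", 20, 0),
    ac("e1c1", "rsXB", 25, 25),   # >= 20 reads in one cell only
    ac("e2c1", "rsA3", 12, 10),   # different embryo: support not shared
    ac("e1c3", "rsA3", 30, 3)
  )
  calls <- toy_calls(counts)
  k <- function(cell, snp) calls$klass[calls$cell_id == cell & calls$snp_id == snp]
  expect_equal(k("e1c1", "rsA1"), "filtered_low_coverage")
  expect_equal(k("e1c1", "rsA2"), "filtered_annotation")
  expect_equal(k("e1c1", "rsP1"), "filtered_annotation")
  expect_equal(k("e1c1", "rsNOG"), "filtered_annotation")
  expect_equal(k("e1c1", "rsDUP"), "filtered_annotation")
  expect_equal(k("e1c1", "rsPAR"), "filtered_annotation")
  expect_equal(k("e1c1", "rsXA"), "biallelic")
  expect_equal(k("e1c2", "rsXA"), "mono_ref")
  expect_equal(k("e1c1", "rsXB"), "filtered_low_coverage")  # single-cell support
  expect_equal(k("e1c3", "rsA3"), "filtered_low_coverage")  # other cell in E2
  # PAR SNPs survive when the X-specific exclusion is off
  calls_par <- toy_calls(bind_rows(ac("e1c1", "rsPAR", 30, 30),
                                   ac("e1c2", "rsPAR", 30, 28)), drop_par = FALSE)
  expect_equal(sort(unique(calls_par$klass)), "biallelic")
})

test_that("X-linked SNPs biallelic in the male control vanish from all samples", {
  counts <- bind_rows(
    ac("e1c1", "rsXA", 15, 15), ac("e1c2", "rsXA", 14, 16),
    ac("ctrl1", "rsXA", 12, 12),                        # biallelic in male control
    ac("e1c1", "rsA3", 15, 15), ac("e1c2", "rsA3", 16, 14),
    ac("ctrl1", "rsA3", 11, 11),                        # autosomal: rule is X-specific
    ac("e1c1", "rsXB", 15, 15), ac("e1c2", "rsXB", 14, 16),
    ac("ctrl1", "rsXB", 24, 0)                          # mono in control: kept
  )
  calls <- toy_calls(counts, min_cells = 1)
  cleaned <- exclude_male_control_biallelics(calls, "ctrl1")
  expect_false("rsXA" %in% cleaned$snp_id)
  expect_true(all(c("rsA3", "rsXB") %in% cleaned$snp_id))

  no_bi <- toy_calls(bind_rows(ac("ctrl1", "rsXB", 24, 0),
                               ac("e1c1", "rsXB", 15, 15)), min_cells = 1)
  expect_equal(exclude_male_control_biallelics(no_bi, "ctrl1"), no_bi)
  expect_warning(out <- exclude_male_control_biallelics(calls, NULL), "no male control")
  expect_equal(out, calls)
})

test_that("gene informativeness follows the biallelic/monoallelic criteria", {
  # XA: biallelic in one cell -> informative_biallelic
  # XB: mono_ref in e1c1, mono_alt in e1c2 -> informative_monoallelic
  # A3 (AUT3): mono_ref in all cells -> non_informative (imprinted pattern)
  counts <- bind_rows(
    ac("e1c1", "rsXA", 15, 15), ac("e1c2", "rsXA", 28, 1),
    ac("e1c1", "rsXB", 24, 0), ac("e1c2", "rsXB", 0, 26),
    ac("e1c1", "rsA3", 25, 0), ac("e1c2", "rsA3", 30, 1), ac("e1c3", "rsA3", 22, 0)
  )
  info <- gene_informativeness(toy_calls(counts))
  st <- function(g) info$status[info$gene_id == g & info$embryo_id == "E1"]
  expect_equal(st("XA"), "informative_biallelic")
  expect_equal(st("XB"), "informative_monoallelic")
  expect_equal(st("AUT3"), "non_informative")
})

test_that("within-cell contradictions remove the gene from that cell only", {
  genes <- toy_genes()
  # give XA a second SNP so one cell can contradict itself
  snps <- bind_rows(toy_snps(),
                    tibble(snp_id = "rsXA2", chrom = "chrX", pos = 3000500,
                           ref_allele = "G", alt_allele = "A", gene_id = "XA",
                           ambiguous = FALSE))
  counts <- bind_rows(
    ac("e1c1", "rsXA", 15, 15),               # biallelic in e1c1
    ac("e1c2", "rsXA", 28, 1),                # mono (one direction only)
    ac("e1c1", "rsXA2", 24, 0),               # same cell, discordant-pattern SNP
    ac("e1c2", "rsXA2", 0, 26),
    ac("e1c3", "rsXA2", 25, 0)
  )
  calls <- filter_snps(counts, snps, genes, toy_cells()) |> classify_snps()
  info <- gene_informativeness(calls)
  excl <- attr(info, "cell_exclusions")
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$cell_id, "e1c1")
  # after dropping e1c1, rsXA2 still discordant between e1c2 and e1c3
  expect_equal(info$status[info$gene_id == "XA"], "informative_monoallelic")

  # every supporting cell contradictory -> gene inconsistent
  counts2 <- bind_rows(
    ac("e1c1", "rsXA", 15, 15), ac("e1c2", "rsXA", 16, 14),
    ac("e1c1", "rsXA2", 24, 0), ac("e1c2", "rsXA2", 0, 26)
  )
  calls2 <- filter_snps(counts2, snps, genes, toy_cells()) |> classify_snps()
  info2 <- gene_informativeness(calls2)
  expect_equal(info2$status[info2$gene_id == "XA"], "inconsistent")
  expect_equal(nrow(attr(info2, "cell_exclusions")), 2L)
})

test_that("imprinted and hemizygous cohorts yield no informative monoallelic X genes", {
  co <- simulate_cohort(scenario_config("imprinted_xci", sexes = "female",
                                        embryos_per_stage = 2, n_genes_x = 60,
                                        n_genes_auto = 150, n_genes_y = 6,
                                        n_genes_par = 2, allelic_error = 0, seed = 7))
  calls <- filter_snps(co$allele_counts, co$snps, co$genes, co$cells) |> classify_snps()
  info <- gene_informativeness(calls)
  x_info <- info |> filter(chrom == "chrX")
  expect_equal(sum(x_info$status == "informative_monoallelic"), 0L)

  com <- simulate_cohort(scenario_config("male", embryos_per_stage = 2,
                                         n_genes_x = 60, n_genes_auto = 150,
                                         n_genes_y = 6, n_genes_par = 2,
                                         maternal_decay = 0, seed = 8))
  callsm <- filter_snps(com$allele_counts, com$snps, com$genes, com$cells) |>
    classify_snps()
  infom <- gene_informativeness(callsm)
  x_m <- infom |> filter(chrom == "chrX")
  expect_equal(sum(startsWith(x_m$status, "informative")), 0L)
})
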