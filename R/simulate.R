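# Seeded cohort simulator: complete pipeline inputs (counts, allele counts,
# annotations, metadata, latent truth) under controlled X-regulation
# scenarios.
#
# Generative model, in outline:
# * Per-gene molar abundance theta ~ logNormal, identical for X-linked and
#   autosomal genes, so the X:A ratio of a cell with two ordinary active X's
#   is 1 by construction.
# * Every allele of a diploid locus contributes theta/2. Female X silencing
#   multiplies the inactive-X allele by `allelic_error`; dampening
#   multiplies both alleles by `dampening_factor(stage)`; males carry one X
#   allele (optionally upregulated) plus a maternal biallelic RNA pool that
#   decays across stages.
# * Silencing progression is gene-ordered: each X gene draws a latent
#   threshold u_g ~ U(0,1) once per cohort and is silenced at stage s iff
#   u_g < p_inactivated(s). Genes with u_g above the final p are the
#   escape-like residual biallelic pool. Which parental X is inactivated is
#   one coin flip per cell (imprinted scenarios fix it to the maternal X).
# * Read counts are negative binomial around output x length x depth;
#   per-SNP coverage is negative binomial around `mean_coverage`
#   (independent of expression magnitude, zeroed when the gene-cell has no
#   output or drops out), and ref reads are Binomial(coverage, ref share).

xci_scenarios <- c("pre_xci", "progressive_xci", "imprinted_xci", "dampening",
                   "male", "aneuploid", "upregulated_xa")

#' Simulation scenario configuration
#'
#' Builds a validated parameter set for [simulate_cohort()]. Unset
#' trajectory parameters get scenario defaults:
#' * `progressive_xci` / `imprinted_xci`: `p_inactivated` rises linearly
#'   from 0 to 0.8 across the stages; no dampening.
#' * `dampening`: both alleles scaled by a factor falling linearly from 1
#'   to 0.5 (full female-to-male dosage compensation, the endpoint the
#'   dampening hypothesis posits); no silencing.
#' * `pre_xci`: no silencing, no dampening.
#' * `male` / `upregulated_xa`: male-only cohort; `upregulated_xa` doubles
#'   the active-X output.
#' * `aneuploid`: euploid expression plus a fold change on one chromosome
#'   in the cells of one embryo.
#'
#' The maternal RNA pool in males is 1 at pre-EGA stages and decays to 0
#' across post-EGA stages (default 0.5 at the first post-EGA stage, 0 at
#' the last).
#'
#' @param scenario One of `r paste(xci_scenarios, collapse = ", ")`.
#' @param stages Ordered stage names (default 8-cell, morula, E6
#'   blastocyst).
#' @param embryos_per_stage Embryos per stage and sex (default 6).
#' @param cells_per_embryo Cells per embryo (default 4).
#' @param sexes Cohort composition (default both sexes; male scenarios
#'   default to male only).
#' @param n_genes_x,n_genes_auto,n_genes_y,n_genes_par Gene counts.
#' @param het_snp_rate Expected heterozygous SNPs per gene (Poisson).
#' @param mean_coverage,coverage_dispersion Negative-binomial coverage per
#'   SNP per cell (mean, size).
#' @param expr_meanlog,expr_sdlog Log-normal abundance parameters.
#' @param mean_gene_counts Average reads per gene at baseline output.
#' @param count_dispersion Negative-binomial size of gene counts.
#' @param library_sdlog Log-normal sd of per-cell depth factors.
#' @param p_inactivated Per-stage silencing completion probabilities.
#' @param dampening_factor Per-stage scaling of both X alleles in females.
#' @param maternal_decay Per-stage male maternal-pool level.
#' @param allelic_error Residual output of a silenced allele (probability
#'   scale; 0 = complete silencing).
#' @param dropout Probability a gene is unobserved in a cell.
#' @param xa_upregulation Multiplier on active-X output in males.
#' @param aneuploid_chrom,aneuploid_fold Aneuploidy injection (chromosome,
#'   fold change applied to the first embryo's cells).
#' @param seed Integer seed; the whole cohort is deterministic under it.
#' @param allow_combined Permit silencing and dampening together (refused
#'   by default as an inconsistent configuration).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = "progressive_xci",
                            stages = c("cell8", "morula", "blastocyst_E6"),
                            embryos_per_stage = 6,
                            cells_per_embryo = 4,
                            sexes = NULL,
                            n_genes_x = 300, n_genes_auto = 2000,
                            n_genes_y = 24, n_genes_par = 10,
                            het_snp_rate = 0.8,
                            mean_coverage = 60, coverage_dispersion = 3,
                            expr_meanlog = 3, expr_sdlog = 1,
                            mean_gene_counts = 50, count_dispersion = 2,
                            library_sdlog = 0.3,
                            p_inactivated = NULL,
                            dampening_factor = NULL,
                            maternal_decay = NULL,
                            allelic_error = 0,
                            dropout = 0.05,
                            xa_upregulation = 1,
                            aneuploid_chrom = "chr16", aneuploid_fold = 1.5,
                            seed = 1,
                            allow_combined = FALSE) {
  scenario <- match.arg(scenario, xci_scenarios)
  stages <- as.character(stages)
  bad <- setdiff(stages, xci_stage_levels)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  ns <- length(stages)
  if (is.null(sexes)) {
    sexes <- if (scenario %in% c("male", "upregulated_xa")) "male" else c("female", "male")
  }
  if (scenario == "upregulated_xa" && missing(xa_upregulation)) xa_upregulation <- 2

  if (is.null(p_inactivated)) {
    p_inactivated <- if (scenario %in% c("progressive_xci", "imprinted_xci")) {
      if (ns == 1) 0.8 else seq(0, 0.8, length.out = ns)
    } else rep(0, ns)
  }
  if (is.null(dampening_factor)) {
    dampening_factor <- if (scenario == "dampening") {
      if (ns == 1) 0.5 else seq(1, 0.5, length.out = ns)
    } else rep(1, ns)
  }
  if (is.null(maternal_decay)) {
    post <- !(stages %in% pre_ega_stages)
    md <- rep(1, ns)
    if (any(post)) md[post] <- if (sum(post) == 1) 0 else seq(0.5, 0, length.out = sum(post))
    maternal_decay <- md
  }
  p_inactivated <- rep_len(p_inactivated, ns)
  dampening_factor <- rep_len(dampening_factor, ns)
  maternal_decay <- rep_len(maternal_decay, ns)
  stopifnot(all(p_inactivated >= 0 & p_inactivated <= 1),
            all(dampening_factor > 0 & dampening_factor <= 1),
            all(maternal_decay >= 0 & maternal_decay <= 1),
            allelic_error >= 0, allelic_error <= 1,
            dropout >= 0, dropout < 1)
  if (any(diff(p_inactivated) < 0)) abort("p_inactivated must be non-decreasing in stage")
  if (!allow_combined && any(p_inactivated > 0) && any(dampening_factor < 1)) {
    abort("silencing and dampening combined; pass allow_combined = TRUE if intended")
  }
  structure(
    list(scenario = scenario, stages = stages,
         embryos_per_stage = embryos_per_stage, cells_per_embryo = cells_per_embryo,
         sexes = sexes, n_genes_x = n_genes_x, n_genes_auto = n_genes_auto,
         n_genes_y = n_genes_y, n_genes_par = n_genes_par,
         het_snp_rate = het_snp_rate, mean_coverage = mean_coverage,
         coverage_dispersion = coverage_dispersion,
         expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
         mean_gene_counts = mean_gene_counts, count_dispersion = count_dispersion,
         library_sdlog = library_sdlog, p_inactivated = p_inactivated,
         dampening_factor = dampening_factor, maternal_decay = maternal_decay,
         allelic_error = allelic_error, dropout = dropout,
         xa_upregulation = xa_upregulation,
         aneuploid_chrom = aneuploid_chrom, aneuploid_fold = aneuploid_fold,
         seed = seed),
    class = "scenario_config"
  )
}

simulate_gene_table <- function(cfg) {
  mk <- function(n, prefix, chrom, base_start, spacing = 20000, par = FALSE) {
    if (n == 0) return(tibble())
    len <- round(runif(n, 500, 5000))
    start <- base_start + (seq_len(n) - 1L) * spacing
    tibble(gene_id = sprintf("%s%04d", prefix, seq_len(n)), chrom = chrom,
           start = start, end = start + len + round(runif(n, 1000, 9000)),
           exonic_length = len, region_class = "unique_gene", par = par)
  }
  autos <- split(seq_len(cfg$n_genes_auto),
                 rep_len(paste0("chr", 1:22), cfg$n_genes_auto))
  auto_tab <- map_dfr(names(autos), function(ch) {
    mk(length(autos[[ch]]), paste0("AG", sub("chr", "", ch), "_"), ch, 1e6)
  })
  bind_rows(
    auto_tab,
    mk(cfg$n_genes_x, "XG", "chrX", 3e6),
    mk(cfg$n_genes_par, "PG", "chrX", 70001, spacing = 15000, par = TRUE),
    mk(cfg$n_genes_y, "YG", "chrY", 3e6)
  )
}

simulate_cell_meta <- function(cfg) {
  grid <- expand.grid(stage = cfg$stages, sex = cfg$sexes,
                      emb = seq_len(cfg$embryos_per_stage),
                      stringsAsFactors = FALSE)
  map_dfr(seq_len(nrow(grid)), function(i) {
    st <- grid$stage[i]; sx <- grid$sex[i]
    eid <- sprintf("%s_%s_%d", toupper(substr(sx, 1, 1)), st, grid$emb[i])
    tibble(cell_id = sprintf("%s_c%d", eid, seq_len(cfg$cells_per_embryo)),
           embryo_id = eid, stage = st, embryonic_day = NA_integer_,
           sex = sx, lineage = NA_character_, dataset = "simulated")
  })
}

#' Simulate a single-cell cohort under an X-regulation scenario
#'
#' Generates a complete, internally consistent input bundle: a counts
#' [expr_matrix()], per-cell per-SNP allele counts, gene and SNP
#' annotations, cell metadata, and the latent truth (per-gene silencing
#' thresholds, per-cell inactive-X choices, per-SNP parental phase).
#' Deterministic under `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return A list of class `xci_cohort` with elements `em`, `allele_counts`,
#'   `genes`, `snps`, `cells`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    genes <- simulate_gene_table(cfg)
    cells <- simulate_cell_meta(cfg)
    ng <- nrow(genes); nc <- nrow(cells)
    stage_idx <- match(cells$stage, cfg$stages)
    female <- cells$sex == "female"
    ega <- as.numeric(!(cells$stage %in% pre_ega_stages))

    theta <- rlnorm(ng, cfg$expr_meanlog, cfg$expr_sdlog)
    names(theta) <- genes$gene_id
    gx <- is_x_chrom(genes$chrom) & !genes$par
    gy <- is_y_chrom(genes$chrom) & !genes$par
    e <- cfg$allelic_error

    # latent silencing order and per-cell inactive-X choice
    u <- rep(NA_real_, ng); u[gx] <- runif(sum(gx))
    xi_maternal <- rep(NA, nc)
    xi_maternal[female] <- if (cfg$scenario == "imprinted_xci") TRUE
                           else runif(sum(female)) < 0.5

    p_cell <- cfg$p_inactivated[stage_idx]
    d_cell <- cfg$dampening_factor[stage_idx]
    m_cell <- cfg$maternal_decay[stage_idx]

    # per-allele outputs; columns are cells
    a_mat <- matrix(theta / 2, ng, nc)
    a_pat <- matrix(theta / 2, ng, nc)

    if (any(female)) {
      # silenced(g, c) for X genes in female cells
      S <- outer(u[gx], p_cell, "<")          # ng_x x nc, TRUE where silenced
      S[, !female] <- FALSE
      sil_mat <- sweep(S, 2, xi_maternal %in% TRUE, "&")
      sil_pat <- S & !sil_mat
      fcols <- which(female)
      a_mat[gx, fcols] <- (theta[gx] / 2) * ifelse(sil_mat[, fcols, drop = FALSE], e, 1)
      a_pat[gx, fcols] <- (theta[gx] / 2) * ifelse(sil_pat[, fcols, drop = FALSE], e, 1)
      a_mat[gx, fcols] <- sweep(a_mat[gx, fcols, drop = FALSE], 2, d_cell[fcols], "*")
      a_pat[gx, fcols] <- sweep(a_pat[gx, fcols, drop = FALSE], 2, d_cell[fcols], "*")
    } else {
      S <- matrix(FALSE, sum(gx), nc)
    }

    male <- !female
    if (any(male)) {
      mcols <- which(male)
      # single (maternally inherited) X allele, optionally upregulated,
      # plus the decaying biallelic maternal pool
      own <- outer(theta[gx] / 2 * cfg$xa_upregulation, ega[mcols])
      pool <- outer(theta[gx] / 2, m_cell[mcols])
      a_mat[gx, mcols] <- own + pool
      a_pat[gx, mcols] <- pool
      a_mat[gy, mcols] <- outer(theta[gy] / 2, ega[mcols])
      a_pat[gy, mcols] <- 0
    }
    a_mat[gy, female] <- 0
    a_pat[gy, female] <- 0

    out <- a_mat + a_pat

    aneuploid_cells <- character()
    if (cfg$scenario == "aneuploid") {
      # a single-cell gain: a whole-embryo event would be normalised away by
      # the within-embryo median and is invisible to expression screens
      aneuploid_cells <- cells$cell_id[1]
      ga <- genes$chrom == cfg$aneuploid_chrom
      out[ga, cells$cell_id %in% aneuploid_cells] <-
        out[ga, cells$cell_id %in% aneuploid_cells] * cfg$aneuploid_fold
    }

    # read counts
    depth <- rlnorm(nc, 0, cfg$library_sdlog)
    len_kb <- genes$exonic_length / 1000
    c0 <- cfg$mean_gene_counts / mean(theta * len_kb)
    mu <- sweep(out * len_kb * c0, 2, depth, "*")
    counts <- matrix(rnbinom(ng * nc, size = cfg$count_dispersion, mu = mu), ng, nc)
    drop_mask <- matrix(runif(ng * nc) < cfg$dropout, ng, nc)
    counts[drop_mask] <- 0L
    dimnames(counts) <- list(genes$gene_id, cells$cell_id)

    # heterozygous SNPs (none on Y: males are the only Y carriers and
    # hemizygous there, females have no Y copy)
    snp_genes <- genes |> filter(!is_y_chrom(.data$chrom))
    n_per <- rpois(nrow(snp_genes), cfg$het_snp_rate)
    snp_gene_idx <- rep(seq_len(nrow(snp_genes)), n_per)
    n_snp <- length(snp_gene_idx)
    snps <- tibble(
      snp_id = sprintf("rs%07d", seq_len(n_snp)),
      chrom = snp_genes$chrom[snp_gene_idx],
      gene_id = snp_genes$gene_id[snp_gene_idx],
      pos = snp_genes$start[snp_gene_idx] +
        floor(runif(n_snp) * (snp_genes$end[snp_gene_idx] - snp_genes$start[snp_gene_idx] + 1)),
      ambiguous = FALSE
    )
    nts <- c("A", "C", "G", "T")
    ref <- sample(nts, n_snp, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), character(1))
    snps$ref_allele <- ref; snps$alt_allele <- unname(alt)
    ref_is_maternal <- runif(n_snp) < 0.5

    # maternal share of output per (snp, cell), via the gene's allele outputs
    grow <- match(snps$gene_id, genes$gene_id)
    tot <- a_mat[grow, , drop = FALSE] + a_pat[grow, , drop = FALSE]
    ms <- ifelse(tot > 0, a_mat[grow, , drop = FALSE] / tot, 0.5)
    p_ref <- ifelse(ref_is_maternal, 1, 0) * ms + ifelse(ref_is_maternal, 0, 1) * (1 - ms)

    cov <- matrix(rnbinom(n_snp * nc, size = cfg$coverage_dispersion,
                          mu = cfg$mean_coverage), n_snp, nc)
    cov[tot == 0] <- 0L
    cov[drop_mask[grow, , drop = FALSE]] <- 0L
    ref_mat <- matrix(rbinom(n_snp * nc, size = as.vector(cov), prob = as.vector(p_ref)),
                      n_snp, nc)
    keep <- which(cov > 0, arr.ind = TRUE)
    kept_ref <- ref_mat[keep]
    allele_counts <- tibble(
      cell_id = cells$cell_id[keep[, 2]],
      snp_id = snps$snp_id[keep[, 1]],
      ref_reads = kept_ref,
      alt_reads = cov[keep] - kept_ref
    )

    em <- expr_matrix(counts, genes, cells)
    truth <- list(
      gene = genes |> select("gene_id", "chrom") |>
        mutate(theta = unname(theta), u = u,
               escape_final = ifelse(gx, u >= max(cfg$p_inactivated), NA)),
      cell = cells |> select("cell_id", "embryo_id", "stage", "sex") |>
        mutate(xi_maternal = xi_maternal, depth = depth,
               p_inactivated = p_cell, dampening = d_cell, maternal_pool = m_cell),
      snp = snps |> select("snp_id", "gene_id", "chrom") |>
        mutate(ref_is_maternal = ref_is_maternal),
      silenced = {
        idx <- which(S, arr.ind = TRUE)
        tibble(gene_id = genes$gene_id[which(gx)][idx[, 1]],
               cell_id = cells$cell_id[idx[, 2]])
      },
      aneuploid_cells = aneuploid_cells
    )
    structure(
      list(em = em, allele_counts = allele_counts,
           genes = genes, snps = snps |> select(
             "snp_id", "chrom", "pos", "ref_allele", "alt_allele", "gene_id", "ambiguous"),
           cells = cells, truth = truth, config = cfg),
      class = "xci_cohort"
    )
  })
}

#' @export
print.xci_cohort <- function(x, ...) {
  cat("<xci_cohort> scenario ", x$config$scenario, ": ",
      nrow(x$genes), " genes, ", nrow(x$cells), " cells, ",
      nrow(x$allele_counts), " allele-count records\n", sep = "")
  invisible(x)
}

fixture_presets <- function() {
  list(
    tiny_xci = list(scenario = "progressive_xci", n_genes_x = 60, n_genes_auto = 200,
                    n_genes_y = 12, n_genes_par = 4, embryos_per_stage = 2),
    tiny_dampening = list(scenario = "dampening", n_genes_x = 60, n_genes_auto = 200,
                          n_genes_y = 12, n_genes_par = 4, embryos_per_stage = 2),
    tiny_male = list(scenario = "male", n_genes_x = 60, n_genes_auto = 200,
                     n_genes_y = 12, n_genes_par = 4, embryos_per_stage = 2),
    tiny_imprint = list(scenario = "imprinted_xci", n_genes_x = 60, n_genes_auto = 200,
                        n_genes_y = 12, n_genes_par = 4, embryos_per_stage = 2),
    tiny_aneuploid = list(scenario = "aneuploid", n_genes_x = 60, n_genes_auto = 200,
                          n_genes_y = 12, n_genes_par = 4, embryos_per_stage = 2,
                          aneuploid_chrom = "chr1", aneuploid_fold = 1.5)
  )
}

#' Write a simulated fixture bundle to disk
#'
#' Materialises one of the named tiny presets as the TSV bundle the readers
#' consume (gene/SNP annotation, counts matrix, allele counts, cell
#' metadata, truth tables). Small enough to run the whole pipeline in
#' seconds; byte-identical across runs with the same seed.
#'
#' @param preset One of `names(fixture_presets())`.
#' @param dir Output directory (created if needed).
#' @param seed Simulation seed (default 1).
#' @return The directory path, invisibly; files as a side effect.
#' @export
make_fixture <- function(preset, dir, seed = 1) {
  presets <- fixture_presets()
  if (!preset %in% names(presets)) {
    abort(paste0("unknown preset '", preset, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  args <- c(presets[[preset]], list(seed = seed))
  cohort <- simulate_cohort(do.call(scenario_config, args))
  write_cohort(cohort, dir)
}

#' Write / read a cohort bundle as TSV files
#'
#' @param cohort An `xci_cohort`.
#' @param dir Directory for `genes.tsv`, `snps.tsv`, `cell_meta.tsv`,
#'   `counts.tsv`, `allele_counts.tsv` and `truth_*.tsv`.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` an
#'   `xci_cohort` (without layers; truth tables reattached when present).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_annotation(cohort$genes, file.path(dir, "genes.tsv"))
  write_snp_annotation(cohort$snps, file.path(dir, "snps.tsv"))
  write_cell_meta(cohort$cells, file.path(dir, "cell_meta.tsv"))
  write_expr_layer(cohort$em, file.path(dir, "counts.tsv"), "counts")
  write_allele_counts(cohort$allele_counts, file.path(dir, "allele_counts.tsv"))
  if (!is.null(cohort$truth)) {
    readr::write_tsv(cohort$truth$gene, file.path(dir, "truth_genes.tsv"), na = ".")
    readr::write_tsv(cohort$truth$cell, file.path(dir, "truth_cells.tsv"), na = ".")
    readr::write_tsv(cohort$truth$snp, file.path(dir, "truth_snps.tsv"), na = ".")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("genes.tsv", "snps.tsv", "cell_meta.tsv",
                           "counts.tsv", "allele_counts.tsv"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files) > 0) {
    abort(paste0("missing input file(s): ", paste(missing_files, collapse = ", ")))
  }
  genes <- read_gene_annotation(file.path(dir, "genes.tsv"))
  snps <- read_snp_annotation(file.path(dir, "snps.tsv"), genes)
  cells <- read_cell_meta(file.path(dir, "cell_meta.tsv"))
  em <- read_expr_counts(file.path(dir, "counts.tsv"), genes, cells)
  counts <- read_allele_counts(file.path(dir, "allele_counts.tsv"), snps$snp_id)
  structure(list(em = em, allele_counts = counts, genes = genes, snps = snps,
                 cells = cells, truth = NULL, config = NULL),
            class = "xci_cohort")
}
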