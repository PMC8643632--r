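test_that("generators are deterministic and conserve configured counts", {
  p <- sim_params(n_chroms = 2, chrom_length = 40e6, n_lads_per_chrom = 3,
                  lad_size_range = c(2e6, 4e6), n_de_genes = 200, seed = 7)
  t1 <- generate_truth(p)
  t2 <- generate_truth(p)
  expect_identical(t1$lads, t2$lads)
  expect_identical(t1$planted, t2$planted)
  expect_equal(nrow(t1$lads), 6)

  expect_identical(simulate_differential_peaks(t1),
                   simulate_differential_peaks(t2))
  expect_identical(simulate_chip_peaks(t1, condition = "KO"),
                   simulate_chip_peaks(t2, condition = "KO"))
  g1 <- simulate_genes_and_expression(t1)
  g2 <- simulate_genes_and_expression(t2)
  expect_identical(g1$expression, g2$expression)
  expect_identical(simulate_isochores(t1$layout, 7), simulate_isochores(t1$layout, 7))
})

test_that("every planted domain is nested in exactly one LAD and LADs never overlap", {
  p <- sim_params(frac_lads_with_planted_domain = 1.0, seed = 3)
  tr <- generate_truth(p)
  expect_equal(nrow(tr$planted), nrow(tr$lads))
  for (i in seq_len(nrow(tr$planted))) {
    host <- interval_overlap_bp(tr$planted[i, c("chrom", "start", "end")],
                                tr$lads[, c("chrom", "start", "end")])
    containing <- sum(host == tr$planted$end[i] - tr$planted$start[i] & host > 0)
    expect_equal(containing, 1)
    # occupies 50-100% of its LAD
    j <- which(host > 0 & tr$lads$chrom == tr$planted$chrom[i])[1]
    occ <- (tr$planted$end[i] - tr$planted$start[i]) /
      (tr$lads$end[j] - tr$lads$start[j])
    expect_gte(occ, 0.5)
    expect_lte(occ, 1)
  }
  # overfull genomes are rejected with advice
  expect_error(
    generate_truth(sim_params(n_chroms = 1, chrom_length = 10e6,
                              n_lads_per_chrom = 5)),
    "fewer|reduce")
})

test_that("differential peaks follow the configured log2FC mixture", {
  tr <- generate_truth(sim_params(seed = 13))
  pk <- simulate_differential_peaks(tr)
  planted <- pk$in_planted & !pk$planted_up
  expect_gt(sum(planted), 1000)
  # law of large numbers: planted mean within 3 SE of the configured mean
  se <- 0.5 / sqrt(sum(planted))
  expect_lt(abs(mean(pk$log2fc[planted]) - (-1.5)), 3 * se)
  # p-values are the two-sided background tail of the drawn log2FC
  expect_equal(pk$p_value, pmin(1, 2 * stats::pnorm(-abs(pk$log2fc / 0.3))))
  # among selected sites, most lie in planted domains
  sel <- select_differential_sites(pk)$selected
  expect_gt(mean(sel$in_planted), 0.8)
  # null degeneracy: no planted-up peaks when domain model equals background
  null_tr <- generate_truth(sim_params(domain_lfc_mean = 0, domain_lfc_sd = 0.3,
                                       seed = 13))
  null_pk <- simulate_differential_peaks(null_tr)
  expect_equal(sum(null_pk$planted_up), 0)
  expect_lt(abs(mean(null_pk$log2fc[null_pk$in_planted])), 0.05)
})

test_that("ChIP peak counts follow the configured Poisson densities", {
  tr <- generate_truth(sim_params(seed = 23))
  wt <- simulate_chip_peaks(tr, condition = "WT")
  genome_mb <- sum(tr$layout$length) / 1e6
  expected <- 30 * genome_mb
  expect_lt(abs(nrow(wt) - expected), 4 * sqrt(expected))
  ko <- simulate_chip_peaks(tr, condition = "KO")
  planted_mb <- total_bp(tr$planted) / 1e6
  expected_ko <- expected + 10 * planted_mb
  expect_lt(abs(nrow(ko) - expected_ko), 4 * sqrt(expected_ko))
  # zero gain: conditions differ only by sampling noise
  tr0 <- generate_truth(sim_params(chip_density_gain_in_domains = 0, seed = 23))
  ko0 <- simulate_chip_peaks(tr0, condition = "KO")
  expect_lt(abs(nrow(ko0) - expected), 4 * sqrt(expected))
})

test_that("genes avoid the gene-poor compartment and DE calls concentrate outside planted domains", {
  tr <- generate_truth(sim_params(seed = 31))
  ge <- simulate_genes_and_expression(tr)
  tss <- ifelse(ge$genes$strand == "+", ge$genes$start, ge$genes$end - 1)
  inside <- hadcall:::points_in_intervals(ge$genes$chrom, tss, tr$planted)
  dens_in <- sum(inside) / (total_bp(tr$planted) / 1e6)
  expect_lt(dens_in, 5)
  # exon invariants
  for (i in sample(nrow(ge$genes), 25)) {
    ex <- ge$genes$exons[[i]]
    expect_gte(nrow(ex), 2); expect_lte(nrow(ex), 8)
    expect_true(all(ex$start >= ge$genes$start[i]))
    expect_true(all(ex$end <= ge$genes$end[i]))
    expect_true(all(ex$end > ex$start))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
  }
  # DE-down genes fall inside planted domains at ~ the 1/20 class odds
  expr <- ge$expression
  down <- expr$direction == "down"
  expect_equal(sum(down), 709)
  expect_equal(sum(expr$direction == "up"), 283)
  frac_in <- mean(inside[down])
  expect_lt(abs(frac_in - 0.05), 1.96 * sqrt(0.05 * 0.95 / sum(down)))
  # DE genes honor the fold/p thresholds
  expect_true(all(abs(expr$log2fc[expr$de]) >= log2(1.5)))
  expect_true(all(expr$p_value[expr$de] < 0.05))
  # zero in-domain density puts no genes in planted domains
  tr0 <- generate_truth(sim_params(gene_density_in_domains = 0,
                                   n_de_genes = 200, seed = 31))
  ge0 <- simulate_genes_and_expression(tr0)
  tss0 <- ifelse(ge0$genes$strand == "+", ge0$genes$start, ge0$genes$end - 1)
  expect_equal(sum(hadcall:::points_in_intervals(ge0$genes$chrom, tss0,
                                                 tr0$planted)), 0)
})

test_that("isochore tiling partitions the genome with the configured class mix", {
  layout <- genome_layout(c("chr1", "chr2"), c(60e6, 60e6))
  iso <- simulate_isochores(layout, seed = 5)
  for (cc in layout$chrom) {
    seg <- iso[iso$chrom == cc, ]
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], 60e6)
    expect_equal(seg$start[-1], seg$end[-nrow(seg)])  # exact partition
  }
  props <- c(L1 = 0.19, L2 = 0.37, H1 = 0.30, H2 = 0.11, H3 = 0.03)
  counts <- table(factor(iso$class, levels = names(props)))
  # rare-class expected counts are small; the chi-square is approximate here
  p_val <- suppressWarnings(stats::chisq.test(counts, p = props)$p.value)
  expect_gt(p_val, 0.001)
})

test_that("synthetic inputs written to disk read back consistently", {
  p <- sim_params(n_chroms = 2, chrom_length = 30e6, n_lads_per_chrom = 2,
                  lad_size_range = c(3e6, 5e6),
                  frac_lads_with_planted_domain = 1, n_de_genes = 50, seed = 2)
  tr <- generate_truth(p)
  dir <- tempfile()
  paths <- write_synthetic_inputs(tr, dir)
  layout <- read_chrom_sizes(paths["chrom_sizes"])
  expect_equal(layout$length, tr$layout$length)
  lads <- read_domains(paths["lads"], layout = layout)
  expect_equal(lads[, c("chrom", "start", "end")],
               tr$lads[, c("chrom", "start", "end")], ignore_attr = TRUE)
  tab <- read_diff_table(paths["diff_table"], layout)
  expect_equal(nrow(tab), nrow(simulate_differential_peaks(tr)))
  genes <- read_gtf_genes(paths["genes"])
  ge <- simulate_genes_and_expression(tr)
  expect_setequal(genes$gene_id, ge$genes$gene_id)
  g1 <- genes[match(ge$genes$gene_id, genes$gene_id), ]
  expect_equal(g1$start, ge$genes$start)
  expect_equal(g1$strand, ge$genes$strand)
  expect_equal(nrow(g1$exons[[3]]), nrow(ge$genes$exons[[3]]))
})
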