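test_that("size distribution and genome fraction compute the stated ratios", {
  layout <- genome_layout("chr1", 100e6)
  dom <- domain_set(tibble::tibble(
    chrom = "chr1", start = c(0, 10e6, 20e6, 40e6),
    end = c(0.5e6, 12e6, 23e6, 47e6)))
  sd <- size_distribution(dom)
  expect_equal(sd$sizes, c(0.5e6, 2e6, 3e6, 7e6))
  expect_equal(sd$fraction_in_range(1e6, 5e6), 0.5)
  expect_equal(sd$fraction_in_range(0, Inf), 1)
  expect_true(is.nan(size_distribution(dom[0, ])$fraction_in_range(0, Inf)))

  dom10 <- domain_set(tibble::tibble(chrom = "chr1", start = 0, end = 10e6))
  expect_equal(genome_fraction(dom10, layout), 0.10)
  expect_equal(genome_fraction(dom10[0, ], layout), 0)
  # excluded chromosomes leave both numerator and denominator
  layout2 <- genome_layout(c("chr1", "chrY"), c(100e6, 10e6))
  domY <- domain_set(tibble::tibble(chrom = c("chr1", "chrY"),
                                    start = c(0, 0), end = c(10e6, 10e6)))
  expect_equal(genome_fraction(domY, layout2, "chrY"), 0.10)
})

test_that("gene density counts TSS containment per Mb inside and outside", {
  layout <- genome_layout("chr1", 100e6)
  dom <- domain_set(tibble::tibble(chrom = "chr1", start = 0, end = 10e6))
  genes <- toy_genes("chr1", start = c(1e6, 5e6, 50e6, 80e6),
                     end = c(1.02e6, 5.02e6, 50.02e6, 80.02e6),
                     strand = c("+", "+", "+", "+"))
  gd <- gene_density(dom, genes, layout)
  expect_equal(gd$n_inside, 2)
  expect_equal(gd$inside, 2 / 10)
  expect_equal(gd$outside, 2 / 90)
  # minus-strand TSS is end-1
  g2 <- toy_genes("chr1", start = 9.99e6, end = 10.5e6, strand = "-")
  expect_equal(gene_density(dom, g2, layout)$n_inside, 0)
  g3 <- toy_genes("chr1", start = 9.5e6, end = 9.99e6, strand = "-")
  expect_equal(gene_density(dom, g3, layout)$n_inside, 1)
  none <- gene_density(dom, genes[0, ], layout)
  expect_equal(c(none$inside, none$outside), c(0, 0))
})

test_that("feature annotation follows promoter > exon > intron > downstream precedence", {
  genes <- toy_genes("chr1", start = 10000, end = 20000, strand = "+",
                     exons = list(tibble::tibble(start = c(10000, 19000),
                                                 end = c(11000, 20000))))
  ask <- function(s, e) {
    annotate_site_features(tibble::tibble(chrom = "chr1", start = s, end = e),
                           genes)$annotation$category
  }
  expect_equal(ask(8000, 9000), "promoter")      # midpoint 8500 in [7000,13000)
  expect_equal(ask(12000, 13000), "promoter")    # within 3 kb downstream of TSS
  expect_equal(ask(19200, 19600), "exon")
  expect_equal(ask(15000, 15400), "intron")
  expect_equal(ask(20500, 21500), "downstream")  # <= 3 kb past 3' end
  expect_equal(ask(500000, 501000), "distal_intergenic")

  # strand-oriented promoter for a minus-strand gene: upstream is rightward
  gneg <- toy_genes("chr1", start = 50000, end = 60000, strand = "-")
  annneg <- annotate_site_features(
    tibble::tibble(chrom = "chr1", start = c(61000, 48000), end = c(61400, 48400)),
    gneg)$annotation$category
  expect_equal(annneg[1], "promoter")    # 3' of coordinate = upstream of TSS
  expect_equal(annneg[2], "downstream")

  # fractions sum to one over annotated sites
  set.seed(5)
  sites <- tibble::tibble(chrom = "chr1",
                          start = sort(sample.int(1e6, 200)) * 5)
  sites$end <- sites$start + 300
  fr <- annotate_site_features(sites, genes)$fractions
  expect_equal(sum(fr), 1)
})

test_that("feature annotation matches a brute-force check on a toy gene model", {
  params <- analysis_params()
  genes <- toy_genes(
    chrom = rep("chr1", 3),
    start = c(10000, 30000, 100000), end = c(20000, 42000, 130000),
    strand = c("+", "-", "+"),
    exons = list(
      tibble::tibble(start = c(10000, 15000), end = c(12000, 16000)),
      tibble::tibble(start = c(30000, 40000), end = c(31000, 42000)),
      tibble::tibble(start = c(100000, 120000), end = c(101000, 121000))))
  tss <- c(10000, 41999, 100000)
  brute_category <- function(mid) {
    in_prom <- logical(3); in_ex <- logical(3); in_body <- logical(3); in_dn <- logical(3)
    for (g in 1:3) {
      if (genes$strand[g] == "+") {
        in_prom[g] <- mid >= tss[g] - 3000 && mid < tss[g] + 3000
        in_dn[g] <- mid >= genes$end[g] && mid < genes$end[g] + 3000
      } else {
        in_prom[g] <- mid > tss[g] - 3000 && mid <= tss[g] + 3000
        in_dn[g] <- mid >= genes$start[g] - 3000 && mid < genes$start[g]
      }
      ex <- genes$exons[[g]]
      in_ex[g] <- any(mid >= ex$start & mid < ex$end)
      in_body[g] <- mid >= genes$start[g] && mid < genes$end[g]
    }
    if (any(in_prom)) "promoter"
    else if (any(in_ex)) "exon"
    else if (any(in_body)) "intron"
    else if (any(in_dn)) "downstream"
    else "distal_intergenic"
  }
  set.seed(21)
  mids <- sort(sample(0:150000, 400))
  sites <- tibble::tibble(chrom = "chr1", start = mids, end = mids + 1)
  got <- annotate_site_features(sites, genes, params)$annotation$category
  want <- vapply(mids, brute_category, character(1))
  expect_equal(got, want)
})

test_that("isochore fractions assign by midpoint and ignore unassigned sites", {
  iso <- tibble::tibble(chrom = "chr1", start = c(0, 50e6),
                        end = c(50e6, 60e6), class = c("L1", "H3"))
  sites <- tibble::tibble(chrom = "chr1", start = c(10e6, 55e6, 80e6),
                          end = c(10e6, 55e6, 80e6) + 200)
  res <- isochore_fractions(sites, iso)
  expect_equal(res$fractions[["L1"]], 0.5)
  expect_equal(res$fractions[["H3"]], 0.5)
  expect_equal(res$fractions[["L2"]], 0)
  expect_equal(sum(res$fractions), 1)
  expect_equal(res$n_unassigned, 1)
  expect_true(all(is.nan(isochore_fractions(sites[0, ], iso)$fractions)))
})

test_that("DE integration counts down/up genes and domain membership", {
  layout <- genome_layout("chr1", 100e6)
  dom <- domain_set(tibble::tibble(chrom = "chr1", start = 0, end = 1e6))
  genes <- toy_genes("chr1", start = (1:10) * 2e5, end = (1:10) * 2e5 + 5e4,
                     strand = rep("+", 10), ids = sprintf("g%03d", 1:10))
  expr <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:10),
    log2fc = c(rep(-1, 6), rep(-0.2, 2), rep(1, 2)),
    p_value = c(rep(0.01, 5), 0.2, 0.01, 0.01, 0.01, 0.01))
  res <- de_genes_in_domains(expr, genes, dom)
  expect_equal(res$n_down, 5)    # 6th down gene fails p
  expect_equal(res$n_up, 2)
  expect_equal(res$n_down_in_domains, 4)  # TSS 2e5..8e5 < 1e6; 1e6 is outside
  expect_equal(res$pct_down_in_domains, 100 * 4 / 5)
  # gene-body membership counts partial overlap
  dom2 <- domain_set(tibble::tibble(chrom = "chr1", start = 2.1e5, end = 2.2e5))
  expect_equal(de_genes_in_domains(expr, genes, dom2)$n_down_in_domains, 0)
  expect_equal(de_genes_in_domains(expr, genes, dom2,
                                   membership = "body")$n_down_in_domains, 1)
  # missing ids are warned and counted
  expr2 <- dplyr::bind_rows(expr, tibble::tibble(gene_id = "missing",
                                                 log2fc = -2, p_value = 0.001))
  expect_warning(res2 <- de_genes_in_domains(expr2, genes, dom), "missing")
  expect_equal(res2$n_missing, 1)
  expect_equal(res2$n_down, 5)
  # empty selection: percentage undefined
  quiet <- tibble::tibble(gene_id = "g001", log2fc = 0, p_value = 0.9)
  expect_true(is.nan(de_genes_in_domains(quiet, genes, dom)$pct_down_in_domains))
})
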