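# hadcall

Calling and characterizing megabase-scale **accessibility domains** from
differential ATAC-seq peak tables.

## The problem

Loss of the histone acetyltransferase HAT1 — which acetylates newly
synthesized histone H4 on K5/K12 during replication-coupled chromatin
assembly — causes large regions of heterochromatin to lose chromatin
accessibility. These HAT1-dependent accessibility domains (HADs) are
megabase-scale, AT-rich, gene-poor, and coincide to a striking degree with
lamin-associated domains (LADs) and with regions where H3K9me3 ChIP peak
density rises in the knockout. `hadcall` is for epigenomics analysts who
have a differential accessibility table (e.g. DiffBind/DESeq2 output over
MACS2 peaks, knockout vs wild type) and want to discover such domains and
quantify their genomic context, with every step seeded and testable.

## The method

Let peak *i* have midpoint $x_i$ and differential accessibility
$y_i = \log_2(\mathrm{KO}/\mathrm{WT})$. Working per chromosome with peaks
ordered by midpoint:

1. **Smoothing.** A centered sliding-window mean over $w = 25$ data
   points (edges truncated): $\bar y_i = \mathrm{mean}(y_{i-h}, \ldots,
   y_{i+h})$, $h = (w-1)/2$. Each smoothed point carries a *support
   interval*, the footprint from the first to the last peak in its window.
2. **Segmentation.** Points with $\bar y_i \le c$ are domain-supporting,
   with cutoff $c = -0.58 = \log_2(1/1.5)$ rounded to two decimals (a
   1.5-fold loss of accessibility). Scanning supporting points in order,
   consecutive points merge into one domain whenever the genomic gap
   between the current domain's footprint and the next point's support
   interval is at most $g = 1$ Mb — intervening above-cutoff points do not
   break a domain. The domain interval is the union span of its members'
   support intervals; domains on excluded chromosomes (chrY) are dropped.
3. **Characterization.** Size distribution and genome fraction; gene
   density by TSS containment; site annotation (promoter / exon / intron /
   downstream / distal intergenic, by midpoint with that precedence);
   isochore class composition (L1/L2/H1/H2/H3); per-Mb ChIP peak-density
   differencing between conditions; overlap with LAD sets; integration
   with differential expression. Significance of domain–track and
   domain–domain association uses a circular-rotation permutation null
   (all intervals on a chromosome shifted by one uniform offset with
   wrap-around, preserving sizes and spacings), with
   $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$.

A fully seeded synthetic-data generator (`sim_params()`,
`generate_truth()`, `simulate_*()`) produces toy genomes with LAD-like
domains, planted low-accessibility regions nested inside them, matched
ChIP/gene/expression/isochore data — so the whole pipeline is exercised
end to end without sequencing data.

## Worked example

Run the whole pipeline on the default synthetic genome (3 chromosomes of
100 Mb, ~30,000 differential peaks, 20 planted low-accessibility domains
nested in LAD-like regions):

```r
library(hadcall)
report <- run_pipeline(list(seed = 1L, simulation = TRUE))
print(report)
#> <hadcall_report>
#>   n_sites: 30556
#>   n_differential: 3908
#>   n_down: 3436
#>   fraction_down: 0.8792
#>   n_domains_raw: 20
#>   n_domains: 20
#>   genome_fraction: 0.3532
#>   fraction_1_5Mb: 0.45
#>   median_domain_size: 5173671
#>   gene_density_inside: 2.114
#>   gene_density_outside: 8.097
#>   feature_fractions: promoter=0.0187 exon=0.0294 intron=0.0371 downstream=0.00742 distal_intergenic=0.907
#>   isochore_fractions: L1=0.253 L2=0.622 H1=0.0885 H2=0.0353 H3=0.00102
#>   overlap_fraction_lads: 1
#>   jaccard_lads: 0.7118
#>   overlap_perm_p: 0.02
#>   density_difference: 8.19
#>   density_perm_p: 0.005
#>   n_down_de: 709
#>   n_up_de: 283
#>   n_down_de_in_domains: 41
#>   pct_down_de_in_domains: 5.783
```

Reading the report: of 30,556 simulated peaks, 3,908 pass the
differential cut (|log2FC| ≥ 1, *P* < 0.01) and 87.9% of those lose
accessibility; the caller finds all 20 planted domains (none on excluded
chromosomes), covering 35% of the toy genome with 45% of domains between
1 and 5 Mb; domains are gene-poor (2.1 vs 8.1 genes/Mb), sit in the
GC-poor isochores, all overlap a LAD-like domain, capture an 8.2 peaks/Mb
knockout gain in ChIP density (rotation *p* = 0.005), and contain only
5.8% of the 709 down-regulated genes. With real inputs, pass file paths
instead of a simulation block (see `?run_pipeline` and
`vignette("domain-calling")`); a thin command-line front-end lives at
`inst/cli/hadcall.R`.

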