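## Domain characterization: sizes, genome fraction, gene density,
## genomic-feature annotation of sites, isochore composition, and
## differential-expression integration. Membership is by midpoint (sites)
## or TSS (genes) containment, so every element is counted exactly once.

gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Domain size distribution
#'
#' @param domains A [domain_set()].
#' @return List with `sizes` (bp vector) and `fraction_in_range(lo, hi)`,
#'   a function returning the fraction of domains with lo <= size <= hi
#'   (NaN for an empty set).
#' @export
size_distribution <- function(domains) {
  sizes <- domains$end - domains$start
  list(
    sizes = sizes,
    fraction_in_range = function(lo, hi) {
      if (length(sizes) == 0) return(NaN)
      mean(sizes >= lo & sizes <= hi)
    }
  )
}

#' Fraction of the genome covered by a domain set
#'
#' @param domains A [domain_set()].
#' @param layout A [genome_layout()].
#' @param excluded_chromosomes Chromosomes excluded from both numerator and
#'   denominator.
#' @return Covered fraction in [0, 1].
#' @export
genome_fraction <- function(domains, layout, excluded_chromosomes = character()) {
  dom <- domains[!domains$chrom %in% excluded_chromosomes, ]
  total_bp(dom) / layout_total_bp(layout, excluded_chromosomes)
}

#' Gene density inside and outside a domain set
#'
#' A gene lies inside if its TSS falls within any domain. Densities are
#' gene counts per Mb of the respective territory.
#'
#' @param domains A [domain_set()].
#' @param genes Gene model tibble (needs `chrom`, `start`, `end`,
#'   `strand`).
#' @param layout A [genome_layout()].
#' @return List `inside`, `outside` (genes/Mb), `n_inside`, `n_outside`.
#' @export
gene_density <- function(domains, genes, layout) {
  inside <- points_in_intervals(genes$chrom, gene_tss(genes), domains)
  dom_bp <- total_bp(domains)
  out_bp <- layout_total_bp(layout) - dom_bp
  list(
    inside = if (dom_bp == 0) NaN else sum(inside) / (dom_bp / 1e6),
    outside = if (out_bp == 0) NaN else sum(!inside) / (out_bp / 1e6),
    n_inside = sum(inside),
    n_outside = sum(!inside)
  )
}

#' Annotate sites with genomic feature categories
#'
#' Each site is assigned, by its midpoint, exactly one of promoter, exon,
#' intron, downstream or distal_intergenic, with precedence in that order.
#' The promoter is `[TSS - promoter_upstream, TSS + promoter_downstream)`
#' oriented by strand; "downstream" extends `downstream_bp` past the gene's
#' 3' end; intron is any gene-body position that is neither promoter nor
#' exon. Ties across genes within the winning category are broken by
#' nearest TSS.
#'
#' @param sites Interval tibble (`chrom`, `start`, `end`).
#' @param genes Gene model tibble with `exons` list-column.
#' @param params An [analysis_params()].
#' @return List with `annotation` (per-site tibble adding `category` and
#'   `gene_id`) and `fractions` (named category fractions over all sites,
#'   summing to 1).
#' @export
annotate_site_features <- function(sites, genes, params = analysis_params()) {
  categories <- c("promoter", "exon", "intron", "downstream", "distal_intergenic")
  n <- nrow(sites)
  if (n == 0) {
    return(list(
      annotation = tibble::tibble(chrom = character(), start = numeric(),
                                  end = numeric(), category = character(),
                                  gene_id = character()),
      fractions = stats::setNames(rep(NaN, 5), categories)
    ))
  }
  mid <- (sites$start + sites$end) %/% 2
  mid_gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(mid + 1, mid + 1))
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  ## promoter window in 0-based half-open coords, strand-oriented
  prom_start <- ifelse(plus, tss - params$promoter_upstream,
                       tss - params$promoter_downstream + 1)
  prom_end <- ifelse(plus, tss + params$promoter_downstream,
                     tss + params$promoter_upstream + 1)
  down_start <- ifelse(plus, genes$end, genes$start - params$downstream_bp)
  down_end <- ifelse(plus, genes$end + params$downstream_bp, genes$start)
  gr_of <- function(s, e, gene_idx) {
    keep <- e > pmax(s, 0)
    s <- pmax(s[keep], 0)
    GenomicRanges::GRanges(genes$chrom[gene_idx][keep],
                           IRanges::IRanges(s + 1, e[keep]),
                           gene = gene_idx[keep])
  }
  gi <- seq_len(nrow(genes))
  ex <- dplyr::bind_rows(genes$exons)
  ex_gene <- rep(gi, vapply(genes$exons, nrow, integer(1)))
  feats <- list(
    promoter = gr_of(prom_start, prom_end, gi),
    exon = if (nrow(ex) > 0) {
      GenomicRanges::GRanges(genes$chrom[ex_gene],
                             IRanges::IRanges(ex$start + 1, ex$end),
                             gene = ex_gene)
    } else GenomicRanges::GRanges(),
    intron = gr_of(genes$start, genes$end, gi),  # gene body; losers of promoter/exon
    downstream = gr_of(down_start, down_end, gi)
  )
  category <- rep("distal_intergenic", n)
  gene_hit <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  for (cat in names(feats)) {
    if (!any(unassigned) || length(feats[[cat]]) == 0) next
    ov <- GenomicRanges::findOverlaps(mid_gr, feats[[cat]])
    q <- S4Vectors::queryHits(ov)
    keep <- unassigned[q]
    q <- q[keep]
    g <- S4Vectors::mcols(feats[[cat]])$gene[S4Vectors::subjectHits(ov)][keep]
    if (length(q) == 0) next
    ## nearest-TSS tie-break across genes
    d <- abs(mid[q] - tss[g])
    ord <- order(q, d)
    first <- !duplicated(q[ord])
    q1 <- q[ord][first]
    g1 <- g[ord][first]
    category[q1] <- cat
    gene_hit[q1] <- genes$gene_id[g1]
    unassigned[q1] <- FALSE
  }
  annotation <- tibble::tibble(chrom = sites$chrom, start = sites$start,
                               end = sites$end, category = category,
                               gene_id = gene_hit)
  fr <- vapply(categories, function(cc) mean(category == cc), numeric(1))
  list(annotation = annotation, fractions = fr)
}

#' Isochore class composition of a site set
#'
#' Each site is assigned the class of the isochore segment containing its
#' midpoint; sites falling in no segment are counted as unassigned.
#'
#' @param sites Interval tibble (`chrom`, `start`, `end`).
#' @param isochores Isochore map tibble (`chrom`, `start`, `end`, `class`).
#' @return List with `fractions` (named fractions over assigned sites for
#'   L1, L2, H1, H2, H3; NaN if none assigned), `n_assigned`,
#'   `n_unassigned`.
#' @export
isochore_fractions <- function(sites, isochores) {
  classes <- c("L1", "L2", "H1", "H2", "H3")
  if (nrow(sites) == 0) {
    return(list(fractions = stats::setNames(rep(NaN, 5), classes),
                n_assigned = 0L, n_unassigned = 0L))
  }
  mid <- (sites$start + sites$end) %/% 2
  assigned <- rep(NA_character_, nrow(sites))
  for (cl in classes) {
    seg <- isochores[isochores$class == cl, ]
    if (nrow(seg) == 0) next
    hit <- points_in_intervals(sites$chrom, mid, seg)
    assigned[hit & is.na(assigned)] <- cl
  }
  n_as <- sum(!is.na(assigned))
  fr <- if (n_as == 0) stats::setNames(rep(NaN, 5), classes) else {
    vapply(classes, function(cl) sum(assigned == cl, na.rm = TRUE) / n_as,
           numeric(1))
  }
  list(fractions = fr, n_assigned = n_as, n_unassigned = sum(is.na(assigned)))
}

#' Differential expression integrated with a domain set
#'
#' Down-regulated genes satisfy log2FC <= -log2(`de_fold_threshold`) with
#' p < `de_p_threshold`; up-regulated symmetrically. A gene lies in a
#' domain when its TSS does (`membership = "tss"`, default) or when its
#' body overlaps the domain set by at least 1 bp (`membership = "body"`).
#'
#' @param expression Expression tibble (`gene_id`, `log2fc`, `p_value`).
#' @param genes Gene model tibble.
#' @param domains A [domain_set()].
#' @param params An [analysis_params()].
#' @param membership `"tss"` or `"body"`.
#' @return List `n_down`, `n_up`, `n_down_in_domains`,
#'   `pct_down_in_domains` (percentage, NaN when `n_down` is 0),
#'   `n_missing` (expression gene ids absent from the gene model; warned).
#' @export
de_genes_in_domains <- function(expression, genes, domains,
                                params = analysis_params(),
                                membership = c("tss", "body")) {
  membership <- match.arg(membership)
  idx <- match(expression$gene_id, genes$gene_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    warning(n_missing, " expression gene id(s) missing from the gene model",
            call. = FALSE)
  }
  expr <- expression[!is.na(idx), ]
  g <- genes[idx[!is.na(idx)], ]
  thr <- log2(params$de_fold_threshold)
  down <- expr$log2fc <= -thr & expr$p_value < params$de_p_threshold
  up <- expr$log2fc >= thr & expr$p_value < params$de_p_threshold
  in_dom <- if (membership == "tss") {
    points_in_intervals(g$chrom, gene_tss(g), domains)
  } else {
    if (nrow(domains) == 0) rep(FALSE, nrow(g)) else {
      ov <- GenomicRanges::findOverlaps(as_gr0(g), as_gr0(domains))
      seq_len(nrow(g)) %in% S4Vectors::queryHits(ov)
    }
  }
  n_down <- sum(down)
  n_in <- sum(down & in_dom)
  list(
    n_down = n_down,
    n_up = sum(up),
    n_down_in_domains = n_in,
    pct_down_in_domains = if (n_down == 0) NaN else 100 * n_in / n_down,
    n_missing = n_missing
  )
}
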