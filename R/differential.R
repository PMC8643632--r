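#' Analysis parameters
#'
#' Central container for every tunable threshold of the pipeline, with the
#' defaults the domain analysis was designed around: differential sites are
#' |log2FC| >= 1 (inclusive) with raw P < 0.01 (strict); smoothing uses
#' 25-point windows; domains are called at a smoothed cutoff of -0.58 (the
#' log2 of a 1.5-fold change, rounded to two decimals) with a 1 Mb merge
#' gap; density bins are 1 Mb; differential expression uses a 1.5-fold
#' threshold at P < 0.05; promoters span +/- 3 kb of the TSS; chrY domains
#' are excluded.
#'
#' @param da_lfc_threshold Absolute log2FC threshold for differential-site
#'   selection (inclusive).
#' @param da_p_threshold P-value threshold for selection (strict `<`).
#' @param window_points Sliding-window size in data points (odd).
#' @param domain_cutoff Smoothed log2FC at or below which a point is
#'   domain-supporting (negative).
#' @param max_gap Largest genomic gap (bp) bridged when merging
#'   domain-supporting points.
#' @param density_bin Bin width (bp) for peak-density tracks.
#' @param de_fold_threshold Fold-change threshold for differential
#'   expression.
#' @param de_p_threshold P-value threshold for differential expression.
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS (bp), oriented by strand.
#' @param downstream_bp Extent (bp) of the "downstream" feature category
#'   past a gene's 3' end.
#' @param excluded_chromosomes Chromosomes whose domains are dropped.
#' @param use_fdr Use the FDR column instead of raw p for site selection.
#' @return A validated list of class `analysis_params`.
#' @export
analysis_params <- function(da_lfc_threshold = 1.0,
                            da_p_threshold = 0.01,
                            window_points = 25,
                            domain_cutoff = -0.58,
                            max_gap = 1e6,
                            density_bin = 1e6,
                            de_fold_threshold = 1.5,
                            de_p_threshold = 0.05,
                            promoter_upstream = 3000,
                            promoter_downstream = 3000,
                            downstream_bp = 3000,
                            excluded_chromosomes = "chrY",
                            use_fdr = FALSE) {
  p <- as.list(environment())
  if (p$da_lfc_threshold <= 0 || p$da_p_threshold <= 0 ||
      p$de_fold_threshold <= 1 || p$de_p_threshold <= 0 ||
      p$max_gap < 0 || p$density_bin <= 0) {
    stop("thresholds must be positive (fold threshold > 1)", call. = FALSE)
  }
  if (p$domain_cutoff >= 0) stop("domain_cutoff must be negative", call. = FALSE)
  if (p$window_points < 1 || p$window_points %% 2 == 0) {
    stop("window_points must be odd and >= 1", call. = FALSE)
  }
  class(p) <- "analysis_params"
  p
}

#' Select differentially accessible sites
#'
#' Keeps records with |log2FC| >= `da_lfc_threshold` and p <
#' `da_p_threshold` (raw p by default; the FDR column when
#' `use_fdr = TRUE`). Selection is idempotent.
#'
#' @param table Differential site tibble (`chrom`, `start`, `end`,
#'   `log2fc`, `p_value`, optional `fdr`).
#' @param params An [analysis_params()].
#' @return List with `selected` (the filtered table) and `summary`
#'   (`n_total` selected, `n_down`, `fraction_down`; `fraction_down` is NaN
#'   for an empty selection).
#' @export
select_differential_sites <- function(table, params = analysis_params()) {
  pcol <- if (isTRUE(params$use_fdr)) {
    if (!"fdr" %in% names(table) || all(is.na(table$fdr))) {
      stop("use_fdr = TRUE but the table has no fdr column", call. = FALSE)
    }
    table$fdr
  } else {
    table$p_value
  }
  keep <- abs(table$log2fc) >= params$da_lfc_threshold &
    pcol < params$da_p_threshold
  keep[is.na(keep)] <- FALSE
  selected <- table[keep, ]
  n <- nrow(selected)
  n_down <- sum(selected$log2fc < 0)
  list(
    selected = selected,
    summary = list(
      n_total = n,
      n_down = n_down,
      fraction_down = if (n == 0) NaN else n_down / n
    )
  )
}

#' Build the per-chromosome log2FC anchor track
#'
#' One point per record, anchored at the interval midpoint
#' (floor((start + end) / 2)); all records are used (selection is not
#' applied before smoothing). Points are sorted by anchor within each
#' chromosome, ties broken by start then end.
#'
#' @param table Differential site tibble.
#' @param layout Optional [genome_layout()] defining chromosome order.
#' @return Track tibble `chrom`, `anchor`, `value`, `src_start`, `src_end`.
#' @export
build_lfc_track <- function(table, layout = NULL) {
  validate_intervals(table, layout, what = "differential site")
  out <- tibble::tibble(
    chrom = table$chrom,
    anchor = (table$start + table$end) %/% 2,
    value = table$log2fc,
    src_start = table$start,
    src_end = table$end
  )
  key <- if (is.null(layout)) out$chrom else {
    factor(out$chrom, levels = c(layout$chrom, setdiff(unique(out$chrom), layout$chrom)))
  }
  out[order(key, out$anchor, out$src_start, out$src_end), ]
}
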