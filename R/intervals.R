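## Interval arithmetic on 0-based half-open coordinates. Set operations are
## delegated to IRanges/GenomicRanges behind these wrappers; conversion is
## start+1 on the way in, start-1 on the way out.

as_gr0 <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

from_gr0 <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Overlap in base pairs between two intervals
#'
#' Vectorized over rows: element i of the result is the overlap of the i-th
#' interval of `a` with the i-th of `b`. Intervals on different chromosomes
#' overlap by 0; abutting half-open intervals overlap by 0.
#'
#' @param a,b Data frames (recycled row-wise if one has a single row) with
#'   columns `chrom`, `start`, `end` in 0-based half-open coordinates.
#' @return Numeric vector of overlap widths in bp.
#' @examples
#' interval_overlap_bp(
#'   data.frame(chrom = "chr1", start = 0, end = 10),
#'   data.frame(chrom = "chr1", start = 5, end = 8)
#' )
#' @export
interval_overlap_bp <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), ]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), ]
  if (nrow(a) != nrow(b)) stop("a and b must have matching rows", call. = FALSE)
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  ov
}

## union (merge) of an interval set; returns disjoint sorted intervals
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  from_gr0(GenomicRanges::reduce(as_gr0(df)))
}

total_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  m <- merge_intervals(df)
  sum(m$end - m$start)
}

## base pairs shared by two interval sets
intersect_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(as_gr0(a)),
    GenomicRanges::reduce(as_gr0(b))
  )
  sum(as.numeric(GenomicRanges::width(gr)))
}

#' Construct a validated domain set
#'
#' A domain set is a sorted, per-chromosome non-overlapping collection of
#' intervals with optional per-domain support statistics, carrying a label
#' (e.g. "HAD", "LAD", "planted").
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and optionally
#'   `n_support` (count of contributing smoothed-track anchors) and
#'   `mean_value` (mean smoothed log2FC of those anchors).
#' @param label Single string naming the set.
#' @param layout Optional [genome_layout()] used for validation and ordering.
#' @return A tibble of class `domain_set` with attribute `label`.
#' @export
domain_set <- function(df, label = "domain", layout = NULL) {
  df <- tibble::as_tibble(df)
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("domain set needs chrom/start/end columns", call. = FALSE)
  }
  if (!"n_support" %in% names(df)) df$n_support <- NA_integer_
  if (!"mean_value" %in% names(df)) df$mean_value <- NA_real_
  df <- df[, c("chrom", "start", "end", "n_support", "mean_value")]
  validate_intervals(df, layout, what = "domain")
  df <- order_genomic(df, layout)
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] < df$end[-nrow(df)])) {
      stop("domains overlap within a chromosome", call. = FALSE)
    }
  }
  attr(df, "label") <- label
  class(df) <- unique(c("domain_set", class(df)))
  df
}

#' Label of a domain set
#' @param domains A [domain_set()].
#' @return The label string.
#' @export
domain_label <- function(domains) attr(domains, "label") %||% "domain"

`%||%` <- function(x, y) if (is.null(x)) y else x

## membership of points (chrom, pos) in an interval set; intervals need not
## be disjoint. Returns a logical vector.
points_in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  if (length(pos) == 0 || nrow(intervals) == 0) return(out)
  iv <- merge_intervals(intervals)
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    sub <- iv[iv$chrom == cc, ]
    if (nrow(sub) == 0) next
    idx <- findInterval(pos[sel], sub$start)
    out[sel] <- idx >= 1 & pos[sel] < sub$end[pmax(idx, 1)]
  }
  out
}

#' Circularly rotate a domain set along each chromosome
#'
#' Shifts every domain on a chromosome by one offset with wrap-around, the
#' permutation move behind the package's null models: interval sizes and
#' inter-interval spacings are preserved exactly. A domain crossing the
#' chromosome end is split into two pieces.
#'
#' @param domains A [domain_set()].
#' @param layout A [genome_layout()].
#' @param offsets Named numeric vector of per-chromosome offsets in bp
#'   (names are chromosome names; missing chromosomes get offset 0).
#' @return A rotated [domain_set()].
#' @export
rotate_domains <- function(domains, layout, offsets) {
  if (nrow(domains) == 0) return(domains)
  len <- chrom_length(layout, domains$chrom)
  off <- unname(offsets[domains$chrom])
  off[is.na(off)] <- 0
  s <- (domains$start + off) %% len
  e <- s + (domains$end - domains$start)
  keep <- tibble::tibble(chrom = domains$chrom, start = s, end = pmin(e, len))
  wrap <- e > len
  if (any(wrap)) {
    keep <- dplyr::bind_rows(
      keep,
      tibble::tibble(chrom = domains$chrom[wrap], start = 0, end = e[wrap] - len[wrap])
    )
    keep <- keep[keep$end > keep$start, ]
  }
  domain_set(keep, label = domain_label(domains), layout = layout)
}
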