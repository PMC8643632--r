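## The domain caller: centered sliding-window smoothing of the per-peak
## log2FC track, then segmentation by cutoff and genomic gap merging.

#' Sliding-window average of a log2FC track
#'
#' Centered mean over `window_points` data points with truncated edge
#' windows: point i on a chromosome with n points averages indices
#' max(1, i-h) .. min(n, i+h), h = (window_points - 1) / 2, so every input
#' point yields one output point and windows never span chromosomes. Each
#' smoothed point carries a support interval: the footprint from the first
#' to the last peak interval contributing to its window.
#'
#' @param track Track tibble from [build_lfc_track()].
#' @param window_points Odd window size in data points; default 25.
#' @param align `"center"` (default) or `"trailing"` (window ends at the
#'   current point).
#' @return Smoothed track tibble `chrom`, `anchor`, `smoothed`,
#'   `sup_start`, `sup_end`, with attribute `window_points`.
#' @export
sliding_window_average <- function(track, window_points = 25,
                                   align = c("center", "trailing")) {
  align <- match.arg(align)
  if (window_points < 1 || window_points %% 2 == 0) {
    stop("window_points must be odd and >= 1 (got ", window_points, ")",
         call. = FALSE)
  }
  h <- (window_points - 1) / 2
  pieces <- lapply(split(seq_len(nrow(track)), track$chrom), function(idx) {
    n <- length(idx)
    v <- track$value[idx]
    if (align == "center") {
      lo <- pmax(1L, seq_len(n) - h)
      hi <- pmin(n, seq_len(n) + h)
    } else {
      lo <- pmax(1L, seq_len(n) - (window_points - 1L))
      hi <- seq_len(n)
    }
    cs <- c(0, cumsum(v))
    sm <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    ss <- track$src_start[idx]
    se <- track$src_end[idx]
    tibble::tibble(
      chrom = track$chrom[idx],
      anchor = track$anchor[idx],
      smoothed = sm,
      sup_start = vapply(seq_len(n), function(i) min(ss[lo[i]:hi[i]]), numeric(1)),
      sup_end = vapply(seq_len(n), function(i) max(se[lo[i]:hi[i]]), numeric(1))
    )
  })
  out <- dplyr::bind_rows(pieces[unique(track$chrom)])
  attr(out, "window_points") <- window_points
  out
}

#' Call accessibility domains from a smoothed track
#'
#' Points with smoothed value at or below `cutoff` are domain-supporting.
#' Scanning each chromosome in anchor order, consecutive supporting points
#' are merged into one domain whenever the genomic gap between the end of
#' the current domain's footprint and the start of the next supporting
#' point's support interval is at most `max_gap` -- regardless of
#' intervening above-cutoff points, which neither break a domain nor
#' contribute to its statistics. A domain's interval is the union span of
#' its members' support intervals; an isolated supporting point yields a
#' domain covering its own support interval.
#'
#' @param smoothed Smoothed track from [sliding_window_average()].
#' @param cutoff Smoothed log2FC threshold (points <= cutoff are
#'   supporting); default -0.58, the log2 of a 1.5-fold change rounded to
#'   two decimals.
#' @param max_gap Largest bridged genomic gap in bp; default 1 Mb.
#' @param layout Optional [genome_layout()] for ordering/validation.
#' @param label Label for the resulting [domain_set()].
#' @return A [domain_set()] with `n_support` (member count) and
#'   `mean_value` (mean smoothed value of members) per domain.
#' @export
call_domains <- function(smoothed, cutoff = -0.58, max_gap = 1e6,
                         layout = NULL, label = "HAD") {
  rows <- list()
  for (cc in unique(smoothed$chrom)) {
    s <- smoothed[smoothed$chrom == cc, ]
    s <- s[order(s$anchor, s$sup_start), ]
    m <- which(s$smoothed <= cutoff)
    if (length(m) == 0) next
    cur_start <- s$sup_start[m[1]]
    cur_end <- s$sup_end[m[1]]
    vals <- s$smoothed[m[1]]
    flush <- function() {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        chrom = cc, start = cur_start, end = cur_end,
        n_support = length(vals), mean_value = mean(vals)
      )
    }
    for (j in m[-1]) {
      if (s$sup_start[j] - cur_end <= max_gap) {
        cur_start <- min(cur_start, s$sup_start[j])
        cur_end <- max(cur_end, s$sup_end[j])
        vals <- c(vals, s$smoothed[j])
      } else {
        flush()
        cur_start <- s$sup_start[j]
        cur_end <- s$sup_end[j]
        vals <- s$smoothed[j]
      }
    }
    flush()
  }
  if (length(rows) == 0) {
    return(domain_set(tibble::tibble(chrom = character(), start = numeric(),
                                     end = numeric()),
                      label = label, layout = layout))
  }
  domain_set(dplyr::bind_rows(rows), label = label, layout = layout)
}

#' Drop domains on excluded chromosomes
#'
#' @param domains A [domain_set()].
#' @param excluded Character vector of chromosome names (e.g. `"chrY"`).
#' @return The domain set without domains on excluded chromosomes; order
#'   preserved.
#' @export
exclude_chromosomes <- function(domains, excluded = "chrY") {
  out <- domains[!domains$chrom %in% excluded, ]
  attr(out, "label") <- domain_label(domains)
  class(out) <- unique(c("domain_set", class(out)))
  out
}
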