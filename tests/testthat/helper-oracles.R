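# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation they check.

toy_layout <- function(n = 2, len = 1e6) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

# brute-force centered sliding mean with truncated edges
oracle_sliding_mean <- function(values, window) {
  h <- (window - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i) {
    mean(values[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# brute-force domain merge: mark points <= cutoff, then connect every pair
# of marked points whose footprints are within max_gap (transitive closure
# via union-find), one chromosome at a time
oracle_call_domains <- function(smoothed, cutoff, max_gap) {
  out <- list()
  for (cc in unique(smoothed$chrom)) {
    s <- smoothed[smoothed$chrom == cc, ]
    s <- s[order(s$anchor, s$sup_start), ]
    m <- which(s$smoothed <= cutoff)
    if (length(m) == 0) next
    parent <- seq_along(m)
    root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(m)) {
      for (b in seq_along(m)) {
        if (a >= b) next
        i <- m[a]; j <- m[b]
        if (s$sup_start[j] - s$sup_end[i] <= max_gap) {
          parent[root(a)] <- root(b)
        }
      }
    }
    comp <- vapply(seq_along(m), root, integer(1))
    for (g in unique(comp)) {
      idx <- m[comp == g]
      out[[length(out) + 1]] <- data.frame(
        chrom = cc,
        start = min(s$sup_start[idx]),
        end = max(s$sup_end[idx]),
        n_support = length(idx),
        mean_value = mean(s$smoothed[idx])
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_support = integer(), mean_value = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# random smoothed-style track with monotone footprints (widths smaller than
# the minimum anchor spacing, so footprint order follows anchor order)
random_smoothed_track <- function(n_points, n_chroms = 2) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chroms)), n_points, replace = TRUE))
  pieces <- lapply(split(seq_len(n_points), chrom), function(idx) {
    k <- length(idx)
    anchor <- cumsum(sample(1000:200000, k, replace = TRUE))
    data.frame(
      chrom = chrom[idx],
      anchor = anchor,
      smoothed = stats::rnorm(k, -0.5, 0.5),
      sup_start = anchor - sample(50:400, k, replace = TRUE),
      sup_end = anchor + sample(50:400, k, replace = TRUE)
    )
  })
  do.call(rbind, pieces)
}

# per-base overlap oracle on small coordinate spans
oracle_overlap_fraction <- function(query, subject, min_bp = 1) {
  if (nrow(query) == 0) return(NaN)
  hits <- vapply(seq_len(nrow(query)), function(i) {
    bases <- seq(query$start[i], query$end[i] - 1)
    sub <- subject[subject$chrom == query$chrom[i], , drop = FALSE]
    covered <- rep(FALSE, length(bases))
    for (j in seq_len(nrow(sub))) {
      covered <- covered | (bases >= sub$start[j] & bases < sub$end[j])
    }
    sum(covered) >= min_bp
  }, logical(1))
  mean(hits)
}

oracle_interval_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  sum(seq(a$start, a$end - 1) %in% seq(b$start, b$end - 1))
}

# tiny gene model builder; exons as a list of c(start, end) pairs
toy_genes <- function(chrom, start, end, strand, exons = NULL, ids = NULL) {
  n <- length(start)
  tibble::tibble(
    gene_id = ids %||% sprintf("g%03d", seq_len(n)),
    chrom = chrom, start = start, end = end, strand = strand,
    exons = exons %||% replicate(n, tibble::tibble(start = numeric(),
                                                   end = numeric()),
                                 simplify = FALSE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
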