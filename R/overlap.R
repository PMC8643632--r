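## Domain-set versus domain-set comparison: element-wise overlap fraction,
## base-pair Jaccard, and circular-rotation permutation significance.

#' Fraction of query domains overlapping a subject set
#'
#' Subject domains are merged (union) first so overlapping subject
#' annotations are not double counted; each query domain's total overlap
#' with that union is computed and the domain counts as overlapping when
#' it reaches `min_bp`. Generally asymmetric in query and subject.
#'
#' @param query,subject [domain_set()]s (or interval tibbles) on a shared
#'   coordinate system.
#' @param min_bp Minimum overlap in bp for a query domain to count;
#'   default 1 (any overlap).
#' @return Fraction in [0, 1]; NaN for an empty query.
#' @export
overlap_fraction <- function(query, subject, min_bp = 1) {
  if (nrow(query) == 0) return(NaN)
  if (nrow(subject) == 0) return(0)
  qgr <- as_gr0(query)
  sgr <- GenomicRanges::reduce(as_gr0(subject))
  ov <- GenomicRanges::findOverlaps(qgr, sgr)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    qgr[S4Vectors::queryHits(ov)], sgr[S4Vectors::subjectHits(ov)]
  ))
  per_query <- rep(0, nrow(query))
  if (length(w) > 0) {
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    per_query[as.integer(names(agg))] <- as.numeric(agg)
  }
  mean(per_query >= min_bp)
}

#' Base-pair Jaccard index of two interval sets
#'
#' Intersection bp over union bp of the merged sets; symmetric.
#'
#' @param a,b [domain_set()]s or interval tibbles.
#' @return Value in [0, 1]; NaN when both sets are empty.
#' @export
basepair_jaccard <- function(a, b) {
  uni <- total_bp(dplyr::bind_rows(a[, c("chrom", "start", "end")],
                                   b[, c("chrom", "start", "end")]))
  if (uni == 0) return(NaN)
  intersect_bp(a, b) / uni
}

#' Permutation test for domain-set overlap
#'
#' The observed [overlap_fraction()] is compared with a null built by
#' circularly rotating the query set along each chromosome by independent
#' uniform offsets: `perm_p = (1 + #(null >= observed)) / (1 + n_perm)`,
#' one-sided. Rotation preserves the query's per-chromosome length and
#' spacing structure exactly.
#'
#' @param query,subject [domain_set()]s on the shared `layout`.
#' @param layout A [genome_layout()].
#' @param n_perm Number of rotations (>= 1); default 199.
#' @param seed Integer seed.
#' @param min_bp Passed to [overlap_fraction()].
#' @return List `observed`, `null_mean`, `null_sd`, `perm_p`, `null`.
#' @export
overlap_permutation_test <- function(query, subject, layout, n_perm = 199,
                                     seed = 1, min_bp = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  obs <- overlap_fraction(query, subject, min_bp)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(k) {
    offsets <- stats::setNames(floor(stats::runif(nrow(layout)) * layout$length),
                               layout$chrom)
    overlap_fraction(rotate_domains(query, layout, offsets), subject, min_bp)
  }, numeric(1))
  list(
    observed = obs,
    null_mean = mean(null),
    null_sd = stats::sd(null),
    perm_p = (1 + sum(null >= obs)) / (1 + n_perm),
    null = null
  )
}
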