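track_from_values <- function(values, anchors = NULL, chrom = "chr1",
                              half_width = 500) {
  anchors <- anchors %||% (seq_along(values) * 10000)
  tibble::tibble(chrom = chrom, anchor = anchors, value = values,
                 src_start = anchors - half_width, src_end = anchors + half_width)
}

test_that("sliding window average matches brute force, edges truncated", {
  trk <- track_from_values(c(1, 2, 3, 4, 5))
  sm <- sliding_window_average(trk, 3)
  expect_equal(sm$smoothed, c(1.5, 2, 3, 4, 4.5))

  const <- sliding_window_average(track_from_values(rep(2.5, 40)), 25)
  expect_equal(const$smoothed, rep(2.5, 40))

  set.seed(11)
  for (i in 1:100) {
    v <- stats::rnorm(sample(1:80, 1))
    w <- sample(c(1, 3, 5, 9, 25), 1)
    sm <- sliding_window_average(track_from_values(v), w)
    expect_equal(sm$smoothed, oracle_sliding_mean(v, w))
  }

  expect_error(sliding_window_average(trk, 4), "odd")
})

test_that("support intervals span the contributing peaks and windows never cross chromosomes", {
  trk <- dplyr::bind_rows(
    track_from_values(c(1, 2, 3), chrom = "chr1"),
    track_from_values(c(100, 200, 300), chrom = "chr2"))
  sm <- sliding_window_average(trk, 3)
  expect_equal(sm$smoothed[sm$chrom == "chr1"], c(1.5, 2, 2.5))
  expect_equal(sm$smoothed[sm$chrom == "chr2"], c(150, 200, 250))
  # middle point's support spans first to last peak of its window
  expect_equal(sm$sup_start[2], trk$src_start[1])
  expect_equal(sm$sup_end[2], trk$src_end[3])
  # anchor lies inside its support interval
  expect_true(all(sm$anchor >= sm$sup_start & sm$anchor < sm$sup_end))
})

test_that("domain calling merges through gaps and intervening high points", {
  # marked anchors at 1.0, 2.0, 4.0, 4.2, 8.0 Mb (support +/- 0.5 kb),
  # unmarked at 1.5 Mb; cutoff -0.58, gap 1 Mb -> 3 domains
  anchors <- c(1.0e6, 1.5e6, 2.0e6, 4.0e6, 4.2e6, 8.0e6)
  values <- c(-1, 0, -1, -0.8, -0.7, -0.9)
  sm <- tibble::tibble(chrom = "chr1", anchor = anchors, smoothed = values,
                       sup_start = anchors - 500, sup_end = anchors + 500)
  dom <- call_domains(sm, cutoff = -0.58, max_gap = 1e6)
  expect_equal(nrow(dom), 3)
  expect_equal(dom$start, c(0.9995e6, 3.9995e6, 7.9995e6))
  expect_equal(dom$end, c(2.0005e6, 4.2005e6, 8.0005e6))
  expect_equal(dom$n_support, c(2L, 2L, 1L))
  # unmarked point contributes to no mean
  expect_equal(dom$mean_value, c(-1, -0.75, -0.9))

  none <- call_domains(sm, cutoff = -2)
  expect_equal(nrow(none), 0)

  # ties included: smoothed == cutoff is marked
  tied <- tibble::tibble(chrom = "chr1", anchor = 100, smoothed = -0.58,
                         sup_start = 50, sup_end = 150)
  expect_equal(nrow(call_domains(tied, cutoff = -0.58)), 1)
})

test_that("domain calling equals the brute-force merge oracle on random tracks", {
  set.seed(42)
  for (i in 1:300) {
    sm <- random_smoothed_track(sample(1:50, 1))
    cutoff <- stats::runif(1, -1.2, 0)
    gap <- sample(c(1e4, 1e5, 5e5, 1e6), 1)
    got <- call_domains(sm, cutoff, gap)
    want <- oracle_call_domains(sm, cutoff, gap)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_support, want$n_support)
    expect_equal(got$mean_value, want$mean_value)
  }
})

test_that("called domains are sorted, disjoint, and respond monotonically to parameters", {
  set.seed(9)
  for (i in 1:25) {
    sm <- random_smoothed_track(50)
    dom <- call_domains(sm, -0.5, 2e5)
    by_chr <- split(dom, dom$chrom)
    for (d in by_chr) {
      if (nrow(d) > 1) {
        expect_true(all(diff(d$start) > 0))
        expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
      }
    }
    # lowering the cutoff never increases covered bp
    expect_lte(total_bp(call_domains(sm, -0.8, 2e5)), total_bp(dom))
    # increasing the gap never increases the number of domains
    expect_lte(nrow(call_domains(sm, -0.5, 8e5)), nrow(dom))
  }
})

test_that("chromosome exclusion drops exactly the named chromosomes", {
  dom <- domain_set(tibble::tibble(
    chrom = c("chr1", "chr2", "chrY"), start = c(0, 0, 0),
    end = c(100, 100, 100)), label = "HAD")
  kept <- exclude_chromosomes(dom, "chrY")
  expect_equal(kept$chrom, c("chr1", "chr2"))
  expect_equal(domain_label(kept), "HAD")
  expect_equal(nrow(exclude_chromosomes(dom, character())), 3)
  expect_equal(nrow(exclude_chromosomes(dom, c("chr1", "chr2", "chrY"))), 0)
})
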