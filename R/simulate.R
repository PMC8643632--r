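## Seeded synthetic-data generator. Emulates the statistical structure the
## domain analysis assumes: a multi-chromosome genome carrying LAD-like
## megabase domains, a subset of which contain planted low-accessibility
## regions where peak-level log2FC shifts negative; differential peaks
## sparser inside those gene-poor domains; ChIP peak sets whose per-Mb
## density rises inside planted domains in the knockout; genes depleted
## inside planted domains with differential-expression calls mostly outside.
##
## Every product is a pure function of (params, seed). One global seed
## spawns fixed per-stream sub-seeds: truth = seed + 1, differential peaks
## = seed + 2, ChIP WT/KO = seed + 3/4, genes & expression = seed + 5,
## isochores = seed + 6.

#' Simulation parameters
#'
#' Defaults describe a toy genome of 3 chromosomes x 100 Mb carrying 21
#' LAD-like domains of 5-9 Mb (real LADs run 0.1-10 Mb), 20 of which
#' contain one planted low-accessibility domain occupying 50-100% of the
#' LAD span. Differential peaks are placed by a renewal process with
#' exponential spacing, denser outside planted domains (7.5 kb vs 25 kb,
#' ~30,000 peaks genome-wide), with log2FC ~ N(0, 0.3) outside and
#' N(-1.5, 0.5) inside planted domains.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_lads_per_chrom LAD-like domains per chromosome.
#' @param lad_size_range Two-element bp range of LAD sizes (uniform).
#' @param lad_min_gap Minimum gap between consecutive LADs and to the
#'   chromosome ends (bp).
#' @param frac_lads_with_planted_domain Fraction of LADs receiving one
#'   planted low-accessibility domain.
#' @param domain_lfc_mean,domain_lfc_sd Normal log2FC model inside planted
#'   domains (mean negative: accessibility lost in the knockout).
#' @param background_lfc_mean,background_lfc_sd Normal log2FC model
#'   elsewhere.
#' @param peak_spacing_background,peak_spacing_in_domains Mean bp between
#'   differential-peak midpoints outside/inside planted domains (spacing is
#'   sparser inside, mirroring gene-poor AT-rich domains).
#' @param peak_width_range Uniform bp range of differential peak widths.
#' @param frac_sites_down_target Target fraction of selected differential
#'   sites that lose accessibility; isolated gained-accessibility peaks are
#'   planted among background peaks at an analytically calibrated rate to
#'   meet it in expectation.
#' @param chip_density_background ChIP peaks per Mb in either condition.
#' @param chip_density_gain_in_domains Additional KO peaks per Mb inside
#'   planted domains.
#' @param chip_peak_width Fixed ChIP peak width (bp).
#' @param gene_density_background,gene_density_in_domains Genes per Mb
#'   outside/inside planted domains.
#' @param gene_length_range Uniform bp range of gene lengths.
#' @param n_de_genes Number of differentially expressed genes.
#' @param frac_de_down Fraction of DE genes that are down-regulated
#'   (defaults to 709/992, the down:up split the generator emulates).
#' @param de_outside_weight Class-total odds of sampling DE genes outside
#'   versus inside planted domains (19 means 19:1, i.e. 5% expected inside).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_chroms = 3,
                       chrom_length = 100e6,
                       n_lads_per_chrom = 7,
                       lad_size_range = c(5e6, 9e6),
                       lad_min_gap = 3e6,
                       frac_lads_with_planted_domain = 20 / 21,
                       domain_lfc_mean = -1.5,
                       domain_lfc_sd = 0.5,
                       background_lfc_mean = 0,
                       background_lfc_sd = 0.3,
                       peak_spacing_background = 7500,
                       peak_spacing_in_domains = 25000,
                       peak_width_range = c(200, 500),
                       frac_sites_down_target = 0.88,
                       chip_density_background = 30,
                       chip_density_gain_in_domains = 10,
                       chip_peak_width = 500,
                       gene_density_background = 10,
                       gene_density_in_domains = 2,
                       gene_length_range = c(5e3, 5e4),
                       n_de_genes = 992,
                       frac_de_down = 709 / 992,
                       de_outside_weight = 19,
                       seed = 1) {
  p <- as.list(environment())
  fracs <- c(p$frac_lads_with_planted_domain, p$frac_sites_down_target,
             p$frac_de_down)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (p$peak_spacing_background <= 0 || p$peak_spacing_in_domains <= 0 ||
      p$chip_density_background <= 0 || p$gene_density_background <= 0) {
    stop("spacings and densities must be positive", call. = FALSE)
  }
  if (diff(p$lad_size_range) < 0 || diff(p$peak_width_range) < 0 ||
      diff(p$gene_length_range) < 0) {
    stop("ranges must be ordered (lo, hi)", call. = FALSE)
  }
  if (p$n_chroms < 1 || p$chrom_length <= 0) stop("invalid genome dimensions", call. = FALSE)
  p$seed <- as.integer(p$seed)
  class(p) <- "sim_params"
  p
}

## alternating planted / background segmentation of one chromosome
chrom_segments <- function(planted_chrom, L) {
  if (nrow(planted_chrom) == 0) {
    return(tibble::tibble(start = 0, end = L, in_planted = FALSE))
  }
  p <- planted_chrom[order(planted_chrom$start), ]
  bounds <- c(0, rbind(p$start, p$end), L)
  seg <- tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1])
  seg$in_planted <- rep(c(FALSE, TRUE), length.out = nrow(seg))
  seg[seg$end > seg$start, ]
}

#' Generate the synthetic ground truth: genome, LADs and planted domains
#'
#' LADs are placed without overlap (uniform sizes, at least `lad_min_gap`
#' apart and away from chromosome ends); a fraction of them receives one
#' planted low-accessibility domain occupying 50-100% of the LAD span,
#' positioned uniformly within it.
#'
#' @param params A [sim_params()].
#' @return A list of class `synthetic_truth`: `layout` ([genome_layout()]),
#'   `lads` and `planted` ([domain_set()]s, every planted domain nested in
#'   exactly one LAD), `params`.
#' @export
generate_truth <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  layout <- genome_layout(paste0("chr", seq_len(params$n_chroms)),
                          rep(params$chrom_length, params$n_chroms))
  n <- params$n_lads_per_chrom
  lads <- list()
  for (cc in layout$chrom) {
    L <- params$chrom_length
    sizes <- round(stats::runif(n, params$lad_size_range[1], params$lad_size_range[2]))
    free <- L - sum(sizes) - (n + 1) * params$lad_min_gap
    if (free < 0) {
      stop("LADs cannot fit on a ", L, " bp chromosome without overlap; ",
           "reduce n_lads_per_chrom or lad_size_range", call. = FALSE)
    }
    w <- diff(c(0, sort(stats::runif(n)), 1))
    gaps <- params$lad_min_gap + round(w * free)
    starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(sizes))[seq_len(n)]
    lads[[cc]] <- tibble::tibble(chrom = cc, start = starts, end = starts + sizes)
  }
  lads <- dplyr::bind_rows(lads)
  n_total <- nrow(lads)
  n_planted <- round(params$frac_lads_with_planted_domain * n_total)
  chosen <- sort(sample.int(n_total, n_planted))
  planted <- lads[chosen, ]
  lad_size <- planted$end - planted$start
  occ <- stats::runif(n_planted, 0.5, 1)
  p_size <- round(occ * lad_size)
  off <- floor(stats::runif(n_planted) * (lad_size - p_size + 1))
  planted$start <- planted$start + off
  planted$end <- planted$start + p_size
  out <- list(
    layout = layout,
    lads = domain_set(lads, label = "LAD", layout = layout),
    planted = domain_set(planted, label = "planted", layout = layout),
    params = params
  )
  class(out) <- "synthetic_truth"
  out
}

## renewal-process midpoints with exponential inter-arrival on [start, end)
renewal_points <- function(start, end, mean_spacing) {
  len <- end - start
  n_draw <- max(10L, ceiling(len / mean_spacing * 2 + 6 * sqrt(len / mean_spacing)))
  pts <- start + cumsum(stats::rexp(n_draw, rate = 1 / mean_spacing))
  while (length(pts) > 0 && pts[length(pts)] < end) {
    pts <- c(pts, pts[length(pts)] +
               cumsum(stats::rexp(n_draw, rate = 1 / mean_spacing)))
  }
  floor(pts[pts < end])
}

#' Simulate a differential accessibility peak table
#'
#' Peak midpoints follow a renewal process with exponential spacing (mean
#' `peak_spacing_background` outside planted domains,
#' `peak_spacing_in_domains` inside); widths are uniform in
#' `peak_width_range`. log2FC is drawn from the background normal model
#' outside planted domains and from the domain model inside; the p-value is
#' the two-sided normal tail probability of the drawn log2FC under the
#' background distribution, so planted peaks tend to small p and the
#' (log2FC, p) joint structure resembles a volcano plot. To reach the
#' configured down-fraction among selected sites, isolated
#' gained-accessibility peaks (log2FC ~ N(+|domain_lfc_mean|,
#' domain_lfc_sd)) are planted among background peaks at an analytically
#' calibrated count; the count is zero in the null configuration.
#'
#' @param truth A [generate_truth()] result.
#' @param params A [sim_params()]; defaults to `truth$params`.
#' @return Tibble `chrom`, `start`, `end`, `log2fc`, `p_value`, `fdr` (NA),
#'   plus the truth annotations `in_planted` and `planted_up`.
#' @export
simulate_differential_peaks <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(params$seed + 2L)
  rows <- list()
  for (cc in truth$layout$chrom) {
    L <- chrom_length(truth$layout, cc)
    segs <- chrom_segments(truth$planted[truth$planted$chrom == cc, ], L)
    for (i in seq_len(nrow(segs))) {
      spacing <- if (segs$in_planted[i]) params$peak_spacing_in_domains
                 else params$peak_spacing_background
      mids <- renewal_points(segs$start[i], segs$end[i], spacing)
      if (length(mids) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = cc, mid = mids, in_planted = segs$in_planted[i]
      )
    }
  }
  pk <- dplyr::bind_rows(rows)
  n <- nrow(pk)
  w <- floor(stats::runif(n, params$peak_width_range[1], params$peak_width_range[2] + 1))
  pk$start <- pmax(0, pk$mid - w %/% 2)
  pk$end <- pmin(chrom_length(truth$layout, pk$chrom), pk$start + w)
  mu_b <- params$background_lfc_mean
  sd_b <- params$background_lfc_sd
  pk$log2fc <- ifelse(pk$in_planted,
                      stats::rnorm(n, params$domain_lfc_mean, params$domain_lfc_sd),
                      stats::rnorm(n, mu_b, sd_b))
  ## calibrate planted-up count so E[down fraction among selected] hits the
  ## target under the default selection (|log2FC| >= 1, P < 0.01)
  pk$planted_up <- FALSE
  t_eff <- max(1.0, sd_b * stats::qnorm(1 - 0.01 / 2))
  n_in <- sum(pk$in_planted)
  n_bg <- n - n_in
  p_dn_dom <- stats::pnorm(-t_eff, params$domain_lfc_mean, params$domain_lfc_sd)
  p_tail_bg <- stats::pnorm(mu_b - t_eff, mu_b, sd_b)
  e_down <- n_in * p_dn_dom + n_bg * p_tail_bg
  f <- params$frac_sites_down_target
  if (f > 0 && f < 1 && e_down > 0) {
    p_up_shift <- stats::pnorm(-t_eff, -abs(params$domain_lfc_mean),
                               params$domain_lfc_sd)
    n_up <- max(0, round((e_down * (1 - f) / f - n_bg * p_tail_bg) / p_up_shift))
    n_up <- min(n_up, n_bg)
    if (n_up > 0) {
      idx <- sample(which(!pk$in_planted), n_up)
      pk$log2fc[idx] <- stats::rnorm(n_up, abs(params$domain_lfc_mean),
                                     params$domain_lfc_sd)
      pk$planted_up[idx] <- TRUE
    }
  }
  pk$p_value <- pmin(1, 2 * stats::pnorm(-abs((pk$log2fc - mu_b) / sd_b)))
  pk$fdr <- NA_real_
  pk <- pk[order(factor(pk$chrom, levels = truth$layout$chrom), pk$start, pk$end), ]
  pk <- pk[!duplicated(pk[, c("chrom", "start", "end")]), ]
  tibble::as_tibble(pk[, c("chrom", "start", "end", "log2fc", "p_value", "fdr",
                           "in_planted", "planted_up")])
}

#' Simulate a per-condition ChIP peak set
#'
#' Homogeneous Poisson placement at `chip_density_background` peaks/Mb
#' genome-wide in both conditions; the KO condition gains an extra
#' `chip_density_gain_in_domains` peaks/Mb inside planted domains. Peaks
#' have fixed width `chip_peak_width`. WT and KO use independent
#' sub-streams, so with zero gain the two conditions differ only by
#' sampling noise.
#'
#' @param truth A [generate_truth()] result.
#' @param params A [sim_params()]; defaults to `truth$params`.
#' @param condition `"WT"` or `"KO"`.
#' @return Peak tibble `chrom`, `start`, `end`, `score`.
#' @export
simulate_chip_peaks <- function(truth, params = truth$params,
                                condition = c("WT", "KO")) {
  stopifnot(inherits(truth, "synthetic_truth"))
  condition <- match.arg(condition)
  set.seed(params$seed + if (condition == "WT") 3L else 4L)
  half <- params$chip_peak_width %/% 2
  rows <- list()
  for (cc in truth$layout$chrom) {
    L <- chrom_length(truth$layout, cc)
    n_bg <- stats::rpois(1, L / 1e6 * params$chip_density_background)
    mids <- floor(stats::runif(n_bg) * L)
    if (condition == "KO" && params$chip_density_gain_in_domains > 0) {
      pl <- truth$planted[truth$planted$chrom == cc, ]
      for (i in seq_len(nrow(pl))) {
        sz <- pl$end[i] - pl$start[i]
        n_extra <- stats::rpois(1, sz / 1e6 * params$chip_density_gain_in_domains)
        mids <- c(mids, pl$start[i] + floor(stats::runif(n_extra) * sz))
      }
    }
    mids <- sort(mids)
    rows[[cc]] <- tibble::tibble(
      chrom = cc,
      start = pmax(0, mids - half),
      end = pmin(L, mids - half + params$chip_peak_width)
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- out[!duplicated(out[, c("chrom", "start", "end")]), ]
  out$score <- 0
  out
}

#' Simulate a gene model and matched expression table
#'
#' Gene starts are placed by Poisson sampling at
#' `gene_density_background` genes/Mb outside LAD-like domains and
#' `gene_density_in_domains` inside them: the LAD compartment as a whole is
#' gene-poor, and the planted low-accessibility domains it contains are
#' therefore gene-poor too. Genes
#' get uniform lengths, 2-8 exons and random strand. `n_de_genes` genes are
#' flagged differentially expressed with |log2FC| >= log2(1.5) and
#' p < 0.05; the DE sample is drawn with class-total odds
#' `de_outside_weight` : 1 for genes outside vs inside planted domains, so
#' with the default 19:1 an expected 5% of DE genes fall inside. Signs
#' follow `frac_de_down` (709:283 down:up by default), assigned
#' independently of location.
#'
#' @param truth A [generate_truth()] result.
#' @param params A [sim_params()]; defaults to `truth$params`.
#' @return List with `genes` (gene model tibble with `exons` list-column)
#'   and `expression` (tibble `gene_id`, `log2fc`, `p_value`, `de`,
#'   `direction`).
#' @export
simulate_genes_and_expression <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(params$seed + 5L)
  rows <- list()
  for (cc in truth$layout$chrom) {
    L <- chrom_length(truth$layout, cc)
    segs <- chrom_segments(truth$lads[truth$lads$chrom == cc, ], L)
    for (i in seq_len(nrow(segs))) {
      dens <- if (segs$in_planted[i]) params$gene_density_in_domains
              else params$gene_density_background
      n_g <- stats::rpois(1, (segs$end[i] - segs$start[i]) / 1e6 * dens)
      if (n_g == 0) next
      starts <- sort(floor(stats::runif(n_g, segs$start[i], segs$end[i])))
      rows[[length(rows) + 1]] <- tibble::tibble(chrom = cc, start = starts)
    }
  }
  genes <- dplyr::bind_rows(rows)
  n <- nrow(genes)
  len <- floor(stats::runif(n, params$gene_length_range[1],
                            params$gene_length_range[2] + 1))
  genes$end <- pmin(chrom_length(truth$layout, genes$chrom), genes$start + len)
  genes <- genes[genes$end - genes$start >= 1000, ]
  genes <- genes[!duplicated(genes[, c("chrom", "start")]), ]
  n <- nrow(genes)
  genes$strand <- sample(c("+", "-"), n, replace = TRUE)
  genes$gene_id <- sprintf("gene%05d", seq_len(n))
  genes$exons <- lapply(seq_len(n), function(i) {
    k <- sample(2:8, 1)
    b <- sort(sample.int(genes$end[i] - genes$start[i], 2 * k)) + genes$start[i] - 1
    tibble::tibble(start = b[seq(1, 2 * k, by = 2)], end = b[seq(2, 2 * k, by = 2)])
  })
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "exons")]

  if (params$n_de_genes > n) {
    stop("n_de_genes (", params$n_de_genes, ") exceeds simulated gene count (",
         n, ")", call. = FALSE)
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  inside <- points_in_intervals(genes$chrom, tss, truth$planted)
  p_in <- if (any(inside)) 1 / (1 + params$de_outside_weight) else 0
  n_de_in <- min(stats::rbinom(1, params$n_de_genes, p_in), sum(inside))
  n_de_out <- params$n_de_genes - n_de_in
  if (n_de_out > sum(!inside)) stop("not enough genes outside planted domains",
                                    call. = FALSE)
  de_idx <- c(sample(which(inside), n_de_in), sample(which(!inside), n_de_out))
  de <- logical(n); de[de_idx] <- TRUE
  n_down <- round(params$n_de_genes * params$frac_de_down)
  down_idx <- sample(de_idx, n_down)
  direction <- rep("none", n)
  direction[de_idx] <- "up"
  direction[down_idx] <- "down"

  thr <- log2(1.5)
  lfc <- stats::rnorm(n, 0, 0.25)
  pv <- stats::runif(n, 0.05, 1)
  n_up <- params$n_de_genes - n_down
  lfc[direction == "down"] <- -(thr + stats::rexp(n_down, rate = 2))
  lfc[direction == "up"] <- thr + stats::rexp(n_up, rate = 2)
  pv[de] <- stats::runif(params$n_de_genes, 1e-8, 0.05)
  expression <- tibble::tibble(gene_id = genes$gene_id, log2fc = lfc,
                               p_value = pv, de = de, direction = direction)
  list(genes = genes, expression = expression)
}

#' Simulate an isochore map
#'
#' Tiles every chromosome with segments of uniform length 0.3-3 Mb labeled
#' L1/L2/H1/H2/H3 from configured genome-wide proportions; the tiling
#' partitions each chromosome exactly. When `truth` is supplied, tiles
#' whose midpoint falls in a planted domain are reassigned to the GC-poor
#' classes L1/L2 with probability `bias` (planted domains emulate AT-rich
#' heterochromatin).
#'
#' @param layout A [genome_layout()].
#' @param seed Integer seed.
#' @param truth Optional [generate_truth()] result enabling the L1/L2 bias.
#' @param props Named class proportions (L1, L2, H1, H2, H3).
#' @param seg_range Uniform bp range of segment lengths.
#' @param bias Probability of reassigning a planted-domain tile to L1/L2.
#' @return Tibble `chrom`, `start`, `end`, `class`.
#' @export
simulate_isochores <- function(layout, seed = 1, truth = NULL,
                               props = c(L1 = 0.19, L2 = 0.37, H1 = 0.30,
                                         H2 = 0.11, H3 = 0.03),
                               seg_range = c(0.3e6, 3e6), bias = 0.9) {
  stopifnot(abs(sum(props) - 1) < 1e-8)
  set.seed(as.integer(seed) + 6L)
  rows <- list()
  for (i in seq_len(nrow(layout))) {
    L <- layout$length[i]
    lens <- numeric(0)
    while (sum(lens) < L) {
      lens <- c(lens, round(stats::runif(ceiling(L / mean(seg_range)) + 10,
                                         seg_range[1], seg_range[2])))
    }
    ends <- pmin(cumsum(lens), L)
    ends <- ends[ends <= L]
    if (length(ends) == 0 || ends[length(ends)] < L) ends <- c(ends, L)
    ends <- unique(ends)
    starts <- c(0, ends[-length(ends)])
    rows[[i]] <- tibble::tibble(chrom = layout$chrom[i], start = starts, end = ends)
  }
  iso <- dplyr::bind_rows(rows)
  iso$class <- sample(names(props), nrow(iso), replace = TRUE, prob = props)
  if (!is.null(truth)) {
    mid <- (iso$start + iso$end) %/% 2
    hit <- points_in_intervals(iso$chrom, mid, truth$planted)
    flip <- hit & stats::runif(nrow(iso)) < bias
    iso$class[flip] <- sample(c("L1", "L2"), sum(flip), replace = TRUE,
                              prob = props[c("L1", "L2")])
  }
  iso
}

#' Write every synthetic product to standard formats
#'
#' Convenience wrapper used by the pipeline's simulate stage: chrom sizes,
#' LAD/planted BED, differential table TSV, WT/KO narrowPeak, isochore BED,
#' gene GTF, expression TSV, plus a JSON echo of the parameters.
#'
#' @param truth A [generate_truth()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_inputs <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- truth$params
  peaks <- simulate_differential_peaks(truth, params)
  ge <- simulate_genes_and_expression(truth, params)
  iso <- simulate_isochores(truth$layout, params$seed, truth)
  paths <- c(
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    lads = file.path(dir, "lads.bed"),
    planted = file.path(dir, "planted.bed"),
    diff_table = file.path(dir, "differential_sites.tsv"),
    chip_wt = file.path(dir, "chip_WT.narrowPeak"),
    chip_ko = file.path(dir, "chip_KO.narrowPeak"),
    isochores = file.path(dir, "isochores.bed"),
    genes = file.path(dir, "genes.gtf"),
    expression = file.path(dir, "expression.tsv"),
    params = file.path(dir, "sim_params.json")
  )
  writeLines(sprintf("%s\t%d", truth$layout$chrom, as.integer(truth$layout$length)),
             paths["chrom_sizes"])
  write_domains(truth$lads, paths["lads"])
  write_domains(truth$planted, paths["planted"])
  write_diff_table(peaks, paths["diff_table"])
  write_narrowpeak(simulate_chip_peaks(truth, params, "WT"), paths["chip_wt"])
  write_narrowpeak(simulate_chip_peaks(truth, params, "KO"), paths["chip_ko"])
  write_isochore_bed(iso, paths["isochores"])
  write_gene_gtf(ge$genes, paths["genes"])
  write_expression_table(ge$expression, paths["expression"])
  jsonlite::write_json(unclass(params), paths["params"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
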