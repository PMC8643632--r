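## Orchestration: run the full synthetic-or-real analysis end to end,
## write every stage's artifact, and produce a summary report with the
## headline descriptors (site counts, down fraction, domain count, genome
## fraction, size fraction, LAD overlap, density association, DE
## integration).

#' Default pipeline configuration
#'
#' A single nested list drives [run_pipeline()]. `simulation` (a list of
#' [sim_params()] overrides, or `TRUE` for all defaults) and `inputs`
#' (paths to real files) are mutually exclusive ways to provide data;
#' `params` holds [analysis_params()] overrides; `stages` toggles the
#' optional analysis stages; `n_perm` sets both permutation tests; `seed`
#' seeds every source of randomness (no wall-clock seeding anywhere).
#'
#' @return The default configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_perm = 199L,
    output_dir = NULL,
    simulation = NULL,
    inputs = list(diff_table = NULL, chrom_sizes = NULL, lads = NULL,
                  lad_class = NULL, chip_wt = NULL, chip_ko = NULL,
                  isochores = NULL, genes_gtf = NULL, expression = NULL),
    params = list(),
    stages = list(annotate = TRUE, overlap = TRUE, density = TRUE,
                  expression = TRUE)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults from [default_config()], [analysis_params()] and
#' [sim_params()]; rejects unknown keys at any level.
#'
#' @param config A (possibly partial) configuration list, or a path to a
#'   YAML/JSON file containing one.
#' @return The fully resolved configuration (class `hadcall_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  tmpl <- default_config()
  unknown <- setdiff(names(config), names(tmpl))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_block <- function(block, allowed, name) {
    bad <- setdiff(names(block), allowed)
    if (length(bad) > 0) {
      stop("unknown config key(s) in ", name, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- utils::modifyList(tmpl, config, keep.null = TRUE)
  if (isTRUE(out$simulation)) out$simulation <- list()
  if (!is.null(out$simulation)) {
    check_block(out$simulation, setdiff(names(formals(sim_params)), "seed"),
                "simulation")
  }
  check_block(out$params, names(formals(analysis_params)), "params")
  check_block(out$inputs, names(tmpl$inputs), "inputs")
  check_block(out$stages, names(tmpl$stages), "stages")
  out$seed <- as.integer(out$seed)
  out$n_perm <- as.integer(out$n_perm)
  class(out) <- c("hadcall_config", "list")
  out
}

#' Run the full domain-calling pipeline
#'
#' Sequence: simulate (optional) -> select differential sites -> build the
#' log2FC track -> sliding-window smoothing -> domain calling -> chromosome
#' exclusion -> size/genome-fraction/gene-density/feature/isochore
#' annotation -> LAD overlap with permutation test -> ChIP peak-density
#' association -> differential-expression integration. Stages lacking
#' inputs can be switched off via `config$stages`; a requested stage with
#' missing inputs is an error naming the stage. With `output_dir` set,
#' every stage's product and the resolved configuration are written out,
#' so all report values are recomputable from the written files.
#'
#' @param config Configuration list or file; see [validate_config()].
#' @return A report list (class `hadcall_report`) with the resolved
#'   parameters and the headline quantities: `n_sites`, `n_differential`,
#'   `fraction_down`, `n_domains`, `genome_fraction`, `fraction_1_5Mb`,
#'   feature/isochore fractions, `overlap_fraction_lads` and its
#'   `overlap_perm_p`, `density_difference` and `density_perm_p`,
#'   `n_down_de`, `n_up_de`, `pct_down_de_in_domains`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  ap_over <- cfg$params
  ap <- do.call(analysis_params, ap_over)
  need <- function(x, stage) {
    if (is.null(x)) stop("missing input for stage '", stage, "'", call. = FALSE)
    x
  }

  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$simulation)) {
    sp <- do.call(sim_params, c(cfg$simulation, list(seed = cfg$seed)))
    truth <- generate_truth(sp)
    layout <- truth$layout
    diff_table <- simulate_differential_peaks(truth, sp)
    lads <- truth$lads
    chip_wt <- simulate_chip_peaks(truth, sp, "WT")
    chip_ko <- simulate_chip_peaks(truth, sp, "KO")
    ge <- simulate_genes_and_expression(truth, sp)
    genes <- ge$genes
    expression <- ge$expression
    isochores <- simulate_isochores(layout, sp$seed, truth)
    if (!is.null(out_dir)) write_synthetic_inputs(truth, file.path(out_dir, "inputs"))
  } else {
    layout <- read_chrom_sizes(need(cfg$inputs$chrom_sizes, "core"))
    diff_table <- read_diff_table(need(cfg$inputs$diff_table, "core"), layout)
    truth <- NULL
    lads <- if (!is.null(cfg$inputs$lads)) {
      d <- read_domains(cfg$inputs$lads, label = "LAD", layout = layout)
      d
    }
    chip_wt <- if (!is.null(cfg$inputs$chip_wt)) {
      read_intervals(cfg$inputs$chip_wt, "narrowPeak", layout)
    }
    chip_ko <- if (!is.null(cfg$inputs$chip_ko)) {
      read_intervals(cfg$inputs$chip_ko, "narrowPeak", layout)
    }
    genes <- if (!is.null(cfg$inputs$genes_gtf)) read_gtf_genes(cfg$inputs$genes_gtf)
    expression <- if (!is.null(cfg$inputs$expression)) {
      read_expression_table(cfg$inputs$expression)
    }
    isochores <- if (!is.null(cfg$inputs$isochores)) {
      read_isochore_bed(cfg$inputs$isochores, layout)
    }
  }

  ## core: selection, track, smoothing, calling
  sel <- select_differential_sites(diff_table, ap)
  track <- build_lfc_track(diff_table, layout)
  smoothed <- sliding_window_average(track, ap$window_points)
  domains_raw <- call_domains(smoothed, ap$domain_cutoff, ap$max_gap,
                              layout = layout)
  domains <- exclude_chromosomes(domains_raw, ap$excluded_chromosomes)

  report <- list(
    seed = cfg$seed,
    params = unclass(ap),
    n_sites = nrow(diff_table),
    n_differential = sel$summary$n_total,
    n_down = sel$summary$n_down,
    fraction_down = sel$summary$fraction_down,
    n_domains_raw = nrow(domains_raw),
    n_domains = nrow(domains)
  )

  if (isTRUE(cfg$stages$annotate)) {
    sd <- size_distribution(domains)
    report$genome_fraction <- genome_fraction(domains, layout,
                                              ap$excluded_chromosomes)
    report$fraction_1_5Mb <- sd$fraction_in_range(1e6, 5e6)
    report$median_domain_size <- if (length(sd$sizes)) stats::median(sd$sizes) else NaN
    if (!is.null(genes)) {
      gd <- gene_density(domains, genes, layout)
      report$gene_density_inside <- gd$inside
      report$gene_density_outside <- gd$outside
      feat <- annotate_site_features(sel$selected, genes, ap)
      report$feature_fractions <- as.list(feat$fractions)
    }
    if (!is.null(isochores)) {
      iso <- isochore_fractions(sel$selected, isochores)
      report$isochore_fractions <- as.list(iso$fractions)
    }
  }

  if (isTRUE(cfg$stages$overlap)) {
    lads_use <- need(lads, "overlap")
    report$overlap_fraction_lads <- overlap_fraction(domains, lads_use)
    report$jaccard_lads <- basepair_jaccard(domains, lads_use)
    ot <- overlap_permutation_test(domains, lads_use, layout,
                                   n_perm = cfg$n_perm, seed = cfg$seed + 7L)
    report$overlap_perm_p <- ot$perm_p
  }

  if (isTRUE(cfg$stages$density)) {
    cw <- need(chip_wt, "density")
    ck <- need(chip_ko, "density")
    delta <- density_difference(bin_peak_counts(cw, layout, ap$density_bin),
                                bin_peak_counts(ck, layout, ap$density_bin))
    da <- domain_density_association(delta, domains, layout,
                                     n_perm = cfg$n_perm, seed = cfg$seed + 8L)
    report$density_difference <- da$difference
    report$density_perm_p <- da$perm_p
  } else {
    delta <- NULL
  }

  if (isTRUE(cfg$stages$expression)) {
    expr_use <- need(expression, "expression")
    genes_use <- need(genes, "expression")
    de <- de_genes_in_domains(expr_use, genes_use, domains, ap)
    report$n_down_de <- de$n_down
    report$n_up_de <- de$n_up
    report$n_down_de_in_domains <- de$n_down_in_domains
    report$pct_down_de_in_domains <- de$pct_down_in_domains
  }

  if (!is.null(out_dir)) {
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.resolved.yaml"))
    write_diff_table(sel$selected, file.path(out_dir, "selected_sites.tsv"))
    write_domains(domains, file.path(out_dir, "domains.bed"))
    write_bedgraph(
      tibble::tibble(chrom = smoothed$chrom, start = smoothed$sup_start,
                     end = smoothed$sup_end, value = smoothed$smoothed),
      file.path(out_dir, "smoothed.bedGraph"))
    if (!is.null(delta)) {
      write_bedgraph(
        tibble::tibble(chrom = delta$chrom, start = delta$bin_start,
                       end = delta$bin_end, value = delta$delta),
        file.path(out_dir, "density_delta.bedGraph"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "string")
  }
  class(report) <- c("hadcall_report", "list")
  report
}

#' @export
print.hadcall_report <- function(x, ...) {
  fmt <- function(v) {
    if (is.numeric(v) && any(v != round(v))) signif(v, 4) else v
  }
  cat("<hadcall_report>\n")
  for (nm in setdiff(names(x), c("params", "seed"))) {
    v <- x[[nm]]
    if (is.list(v)) {
      cat("  ", nm, ": ", paste(names(v), signif(unlist(v), 3), sep = "=",
                                collapse = " "), "\n", sep = "")
    } else {
      cat("  ", nm, ": ", paste(fmt(v), collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}
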