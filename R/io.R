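## Readers and writers for the plain-text formats the pipeline touches.
## BED-family coordinates are taken as-is (0-based half-open); GTF (1-based
## inclusive) is converted at this boundary and nowhere else.

## read lines keeping original line numbers; drops '#' comments and blanks
read_table_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", txt)
  list(text = txt[keep], lineno = which(keep))
}

#' Read genomic intervals from BED3, BED6 or narrowPeak
#'
#' @param path Path to a tab-separated interval file; `#` comment lines are
#'   skipped. Coordinates are 0-based half-open as in the BED standard.
#' @param format One of `"BED3"`, `"BED6"`, `"narrowPeak"` (ENCODE
#'   10-field; column 10 is the summit offset, -1 meaning absent).
#' @param layout Optional [genome_layout()]; when supplied, intervals
#'   exceeding a chromosome length are rejected.
#' @return A tibble of peak records in file order: `chrom`, `start`, `end`,
#'   plus `name`, `score`, `strand` (BED6/narrowPeak) and `summit_offset`
#'   (narrowPeak).
#' @export
read_intervals <- function(path, format = c("BED3", "BED6", "narrowPeak"),
                           layout = NULL) {
  format <- match.arg(format)
  need <- switch(format, BED3 = 3L, BED6 = 6L, narrowPeak = 10L)
  lines <- read_table_lines(path)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < need)) {
    bad <- which(nf < need)[1]
    stop("malformed ", format, " line ", lines$lineno[bad], " in ", path,
         ": expected >= ", need, " fields, found ", nf[bad], call. = FALSE)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble::tibble(
    chrom = col(1),
    start = suppressWarnings(as.numeric(col(2))),
    end = suppressWarnings(as.numeric(col(3)))
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    stop("non-numeric coordinate at line ", lines$lineno[bad], " in ", path,
         call. = FALSE)
  }
  if (any(out$end <= out$start)) {
    bad <- which(out$end <= out$start)[1]
    stop("end <= start at line ", lines$lineno[bad], " in ", path, call. = FALSE)
  }
  if (format %in% c("BED6", "narrowPeak")) {
    out$name <- col(4)
    out$score <- suppressWarnings(as.numeric(col(5)))
    out$strand <- col(6)
  }
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.numeric(col(10)))
    summit[summit < 0] <- NA_real_
    if (any(!is.na(summit) & summit >= out$end - out$start)) {
      bad <- which(!is.na(summit) & summit >= out$end - out$start)[1]
      stop("summit offset outside peak at line ", lines$lineno[bad], " in ",
           path, call. = FALSE)
    }
    out$summit_offset <- summit
  }
  validate_intervals(out, layout, what = "interval")
  out
}

#' Write a domain set as BED6
#'
#' Emits one BED6 line per domain with the domain's `mean_value` in the
#' score column and the set label in the name column; starts with a header
#' comment. A write-then-read round trip returns identical intervals.
#'
#' @param domains A [domain_set()].
#' @param path Output path.
#' @export
write_domains <- function(domains, path) {
  lab <- domain_label(domains)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", lab, " domains: chrom start end name mean_value strand"), con)
  if (nrow(domains) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.",
                       domains$chrom, as.integer(domains$start),
                       as.integer(domains$end),
                       paste0(lab, "_", seq_len(nrow(domains))),
                       formatC(domains$mean_value, format = "g", digits = 8)),
               con)
  }
  invisible(path)
}

#' Read a domain set written by [write_domains()] (or any BED6)
#' @param path BED6 file; the score column is taken as `mean_value`.
#' @param label Label for the resulting set; defaults to "domain".
#' @param layout Optional [genome_layout()] for validation.
#' @return A [domain_set()].
#' @export
read_domains <- function(path, label = "domain", layout = NULL) {
  bed <- read_intervals(path, "BED6", layout)
  domain_set(
    tibble::tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                   n_support = NA_integer_, mean_value = bed$score),
    label = label, layout = layout
  )
}

## column-synonym lookup for tabular readers (case-insensitive)
match_column <- function(nms, synonyms, what, path, required = TRUE) {
  hit <- which(tolower(nms) %in% tolower(synonyms))
  if (length(hit) == 0) {
    if (required) stop("missing ", what, " column in ", path,
                       " (accepted: ", paste(synonyms, collapse = ", "), ")",
                       call. = FALSE)
    return(NA_integer_)
  }
  hit[1]
}

#' Read a differential accessibility peak table
#'
#' Tab-separated with a header. Column names are matched case-insensitively
#' with synonyms: chrom/seqnames/chr, start, end, log2FoldChange/log2fc/Fold,
#' pvalue/p_value/p.value, padj/FDR/qvalue (optional).
#'
#' @param path Path to the table.
#' @param layout Optional [genome_layout()] for validation.
#' @return Tibble with `chrom`, `start`, `end`, `log2fc`, `p_value`, `fdr`.
#' @export
read_diff_table <- function(path, layout = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  nms <- names(df)
  out <- tibble::tibble(
    chrom = as.character(df[[match_column(nms, c("chrom", "seqnames", "chr"), "chrom", path)]]),
    start = as.numeric(df[[match_column(nms, "start", "start", path)]]),
    end = as.numeric(df[[match_column(nms, "end", "end", path)]]),
    log2fc = as.numeric(df[[match_column(nms, c("log2FoldChange", "log2fc", "Fold", "lfc"), "log2 fold change", path)]]),
    p_value = as.numeric(df[[match_column(nms, c("pvalue", "p_value", "p.value", "p"), "p-value", path)]])
  )
  i <- match_column(nms, c("padj", "fdr", "qvalue"), "fdr", path, required = FALSE)
  out$fdr <- if (is.na(i)) NA_real_ else as.numeric(df[[i]])
  if (any(out$p_value <= 0 | out$p_value > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1] in ", path, call. = FALSE)
  }
  validate_intervals(out, layout, what = "differential site")
  out
}

#' Write a differential accessibility peak table
#' @param table Tibble as returned by [read_diff_table()].
#' @param path Output path.
#' @export
write_diff_table <- function(table, path) {
  out <- data.frame(chrom = table$chrom, start = table$start, end = table$end,
                    log2FoldChange = table$log2fc, pvalue = table$p_value)
  if ("fdr" %in% names(table) && !all(is.na(table$fdr))) out$padj <- table$fdr
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isochore map from BED
#'
#' BED6-style with the isochore class (L1, L2, H1, H2, H3) in the name
#' column.
#' @param path BED file path.
#' @param layout Optional [genome_layout()].
#' @return Tibble `chrom`, `start`, `end`, `class`.
#' @export
read_isochore_bed <- function(path, layout = NULL) {
  bed <- read_intervals(path, "BED6", layout)
  classes <- c("L1", "L2", "H1", "H2", "H3")
  if (!all(bed$name %in% classes)) {
    stop("isochore classes must be one of ", paste(classes, collapse = "/"),
         call. = FALSE)
  }
  tibble::tibble(chrom = bed$chrom, start = bed$start, end = bed$end,
                 class = bed$name)
}

#' Write an isochore map as BED6
#' @param isochores Tibble `chrom`, `start`, `end`, `class`.
#' @param path Output path.
#' @export
write_isochore_bed <- function(isochores, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", isochores$chrom,
                     as.integer(isochores$start), as.integer(isochores$end),
                     isochores$class),
             path)
  invisible(path)
}

#' Read a differential expression table
#'
#' Tab-separated with header columns gene_id (synonyms gene/id),
#' log2FoldChange (synonyms log2fc/Fold) and pvalue (synonyms
#' p_value/p.value).
#' @param path Path to the table.
#' @return Tibble `gene_id`, `log2fc`, `p_value`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  nms <- names(df)
  tibble::tibble(
    gene_id = as.character(df[[match_column(nms, c("gene_id", "gene", "id"), "gene id", path)]]),
    log2fc = as.numeric(df[[match_column(nms, c("log2FoldChange", "log2fc", "Fold", "lfc"), "log2 fold change", path)]]),
    p_value = as.numeric(df[[match_column(nms, c("pvalue", "p_value", "p.value", "p"), "p-value", path)]])
  )
}

#' Write an expression table
#' @param expression Tibble `gene_id`, `log2fc`, `p_value`.
#' @param path Output path.
#' @export
write_expression_table <- function(expression, path) {
  utils::write.table(
    data.frame(gene_id = expression$gene_id,
               log2FoldChange = expression$log2fc,
               pvalue = expression$p_value),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene model from GTF
#'
#' Uses `gene` and `exon` features and the `gene_id` attribute; 1-based
#' inclusive GTF coordinates are converted to the package's 0-based
#' half-open convention here.
#'
#' @param path GTF file path.
#' @return Gene model tibble: `gene_id`, `chrom`, `start`, `end`, `strand`
#'   and a list-column `exons` of per-gene exon tibbles (`start`, `end`,
#'   sorted, non-overlapping).
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  df <- tibble::tibble(
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  )
  genes <- df[df$type == "gene", ]
  exons <- df[df$type == "exon", ]
  if (nrow(genes) == 0) stop("no gene features in ", path, call. = FALSE)
  ex_split <- split(exons[, c("start", "end")], exons$gene_id)
  genes$exons <- lapply(genes$gene_id, function(g) {
    e <- ex_split[[g]]
    if (is.null(e)) return(tibble::tibble(start = numeric(), end = numeric()))
    tibble::as_tibble(e[order(e$start), ])
  })
  genes[, c("gene_id", "chrom", "start", "end", "strand", "exons")]
}

#' Write a gene model as GTF
#' @param genes Gene model tibble as from [read_gtf_genes()].
#' @param path Output path.
#' @export
write_gene_gtf <- function(genes, path) {
  n_ex <- vapply(genes$exons, nrow, integer(1))
  ex <- dplyr::bind_rows(genes$exons)
  gr <- GenomicRanges::GRanges(
    seqnames = c(genes$chrom, rep(genes$chrom, n_ex)),
    ranges = IRanges::IRanges(
      start = c(genes$start, ex$start) + 1,
      end = c(genes$end, ex$end)
    ),
    strand = c(genes$strand, rep(genes$strand, n_ex)),
    type = c(rep("gene", nrow(genes)), rep("exon", sum(n_ex))),
    gene_id = c(genes$gene_id, rep(genes$gene_id, n_ex)),
    source = "hadcall"
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write peaks as ENCODE narrowPeak
#' @param peaks Tibble with `chrom`, `start`, `end` and optional `score`,
#'   `summit_offset`.
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  summit <- if ("summit_offset" %in% names(peaks)) peaks$summit_offset else NA
  summit[is.na(summit)] <- -1
  writeLines(sprintf("%s\t%d\t%d\tpeak_%d\t%s\t.\t0\t-1\t-1\t%d",
                     peaks$chrom, as.integer(peaks$start), as.integer(peaks$end),
                     seq_len(nrow(peaks)), formatC(score, format = "g"),
                     as.integer(summit)),
             path)
  invisible(path)
}

#' Write a per-position track as bedGraph
#' @param df Tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column.
#' @export
write_bedgraph <- function(df, path, value = "value") {
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                     as.integer(df$end),
                     formatC(df[[value]], format = "g", digits = 8)),
             path)
  invisible(path)
}
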