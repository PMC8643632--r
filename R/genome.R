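#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that
#' defines the coordinate space for every other object in the package. All
#' coordinates are 0-based, half-open (BED-native); 1-based formats (GTF)
#' are converted at the reader boundary.
#'
#' @param chrom Character vector of unique chromosome names. Order is
#'   preserved and defines genome-wide ordering.
#' @param length Positive chromosome lengths in base pairs.
#' @return A tibble of class `genome_layout` with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(100e6, 80e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(chrom)) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  out <- tibble::tibble(chrom = chrom, length = length)
  class(out) <- c("genome_layout", class(out))
  out
}

#' Read a genome layout from a chrom-sizes file
#'
#' Two tab-separated columns: chromosome name, length. Lines starting with
#' `#` are ignored.
#'
#' @param path Path to a chrom-sizes text file.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_table_lines(path)
  fields <- strsplit(lines$text, "\t", fixed = TRUE)
  bad <- which(vapply(fields, base::length, integer(1)) < 2L)
  if (base::length(bad) > 0) {
    stop("malformed chrom-sizes line ", lines$lineno[bad[1]], " in ", path,
         call. = FALSE)
  }
  genome_layout(
    vapply(fields, `[[`, character(1), 1L),
    as.numeric(vapply(fields, `[[`, character(1), 2L))
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", nrow(x), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp\n", sep = "")
  NextMethod()
}

## total length of the non-excluded part of a layout
layout_total_bp <- function(layout, excluded_chromosomes = character()) {
  sum(layout$length[!layout$chrom %in% excluded_chromosomes])
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  layout$length[i]
}

## Validate a table of 0-based half-open intervals, optionally against a
## layout. Used by readers (validation on) and constructors.
validate_intervals <- function(df, layout = NULL, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$end <= df$start)) {
    bad <- which(df$start < 0 | df$end <= df$start)[1]
    stop(what, " ", bad, " invalid: need 0 <= start < end (got [",
         df$start[bad], ",", df$end[bad], "))", call. = FALSE)
  }
  if (!is.null(layout)) {
    len <- chrom_length(layout, df$chrom)
    if (any(df$end > len)) {
      bad <- which(df$end > len)[1]
      stop(what, " ", bad, " on ", df$chrom[bad], " exceeds chromosome length ",
           len[bad], call. = FALSE)
    }
  }
  invisible(df)
}

## order rows genome-wide: by layout chromosome order when given, else by
## chromosome name, then start, then end
order_genomic <- function(df, layout = NULL) {
  key <- if (is.null(layout)) df$chrom else {
    factor(df$chrom, levels = c(layout$chrom, setdiff(unique(df$chrom), layout$chrom)))
  }
  df[order(key, df$start, df$end), , drop = FALSE]
}
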