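# Readers/writers for the plain-text formats consumed by the pipeline and the
# in-memory domain types shared by all downstream steps. Coordinates are
# 0-based, half-open throughout (BED convention).

#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals (`chrom`, `start`, `end`,
#' optional `summit`, `read_count`, `name`) sorted by (chrom, start, end) with
#' duplicate (chrom, start, end) triples removed. Coordinates are 0-based,
#' half-open.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer start (inclusive) and end (exclusive) positions;
#'   `0 <= start < end` is required.
#' @param summit Optional integer summit positions with
#'   `start <= summit < end`; `NA` where unknown.
#' @param read_count Optional non-negative per-peak read counts; `NA` where
#'   unknown.
#' @param name Optional peak identifiers.
#' @param sample_label Free-text label for the sample the peaks came from.
#' @return A `peak_set` (data frame) with attribute `sample_label`.
#' @export
peak_set <- function(chrom, start, end, summit = NA, read_count = NA,
                     name = NA, sample_label = "") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    summit = rep_len(as.numeric(summit), n),
    read_count = rep_len(as.numeric(read_count), n),
    name = rep_len(as.character(name), n),
    stringsAsFactors = FALSE
  )
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("invalid peak interval (need 0 <= start < end) at row ", bad[1])
  }
  bad <- which(!is.na(df$summit) &
                 !(df$summit >= df$start & df$summit < df$end))
  if (length(bad)) {
    stop("summit outside [start, end) at row ", bad[1])
  }
  if (any(!is.na(df$read_count) & df$read_count < 0)) {
    stop("read_count must be non-negative")
  }
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_label") <- sample_label
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Peak set '", attr(x, "sample_label"), "': ", nrow(x), " peaks on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  print(head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Read peaks from a BED3+ file
#'
#' Columns: chrom, start, end, then optionally 4 = name, 5 = score
#' (interpreted as the peak's read count), 6 = strand (ignored), 7 = summit
#' offset relative to `start`. Lines are de-duplicated on
#' (chrom, start, end) and sorted.
#'
#' @param path Path to a tab-separated BED file.
#' @param sample_label Label stored on the returned set.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, sample_label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", which(nf < 3L)[1], ": fewer than 3 BED fields")
  }
  get_col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else NA_character_
  }, character(1))
  chrom <- get_col(1L)
  start <- suppressWarnings(as.numeric(get_col(2L)))
  end <- suppressWarnings(as.numeric(get_col(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) stop("line ", bad[1], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    stop("line ", bad[1], ": invalid interval (start >= end or start < 0)")
  }
  name <- get_col(4L)
  score <- suppressWarnings(as.numeric(get_col(5L)))
  offset <- suppressWarnings(as.numeric(get_col(7L)))
  summit <- ifelse(is.na(offset), NA_real_, start + offset)
  peak_set(chrom, start, end, summit = summit, read_count = score,
           name = name, sample_label = sample_label)
}

#' Write peaks to a BED file
#'
#' Inverse of [read_peaks()]: columns chrom, start, end, name, score
#' (read count), strand placeholder, summit offset. Round-trips coordinates
#' and counts exactly.
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @export
write_peaks <- function(x, path) {
  fmt_num <- function(v) ifelse(is.na(v), ".", format(v, scientific = FALSE,
                                                      trim = TRUE))
  out <- paste(x$chrom,
               format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE),
               ifelse(is.na(x$name), ".", x$name),
               fmt_num(x$read_count),
               ".",
               fmt_num(ifelse(is.na(x$summit), NA, x$summit - x$start)),
               sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read strand-aware intervals (e.g. sequencing reads) from BED
#'
#' Minimal BED3/BED6 reader for read placements; strand defaults to `+` when
#' absent. Intervals are not de-duplicated (reads may stack).
#'
#' @param path Path to a BED file.
#' @return Data frame with columns chrom, start, end, strand.
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("line ", which(lengths(fields) < 3L)[1], ": fewer than 3 BED fields")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- as.numeric(vapply(fields, `[[`, character(1), 2L))
  end <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "+"
  }, character(1))
  if (any(is.na(start) | is.na(end) | start >= end)) {
    stop("invalid interval coordinates in ", path)
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation (refFlat-like table)
#'
#' Expects a tab-separated table with columns name, chrom, strand, txStart,
#' txEnd, exonStarts, exonEnds (the last two comma-separated lists). The TSS
#' is `txStart` on the + strand and `txEnd - 1` on the - strand. Duplicate
#' gene symbols are collapsed to the longest transcript so that every symbol
#' has a single deterministic TSS.
#'
#' Gene symbols are case-folded to upper case in the `symbol` column; all set
#' operations downstream use that canonical case.
#'
#' @param path Path to the annotation table (a header line starting with
#'   `#` or `name` is skipped).
#' @return A `gene_annotation` data frame with list-columns `exon_starts`,
#'   `exon_ends`, a computed `tss` column and attribute `universe_size`.
#' @export
read_gene_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  lines <- lines[!grepl("^name\t", lines)]
  if (!length(lines)) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 7L)) {
    stop("line ", which(lengths(fields) < 7L)[1],
         ": annotation needs 7 columns")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  parse_list <- function(s) as.numeric(strsplit(sub(",$", "", s), ",")[[1]])
  gene_annotation(
    name = col(1L), chrom = col(2L), strand = col(3L),
    tx_start = as.numeric(col(4L)), tx_end = as.numeric(col(5L)),
    exon_starts = lapply(col(6L), parse_list),
    exon_ends = lapply(col(7L), parse_list)
  )
}

#' Construct a gene annotation
#'
#' @param name Gene symbols.
#' @param chrom,strand,tx_start,tx_end Per-gene location; strand in `+`/`-`;
#'   coordinates 0-based half-open.
#' @param exon_starts,exon_ends Lists of numeric vectors (parallel, sorted,
#'   non-overlapping, contained in the transcript).
#' @return A `gene_annotation` data frame; see [read_gene_annotation()].
#' @export
gene_annotation <- function(name, chrom, strand, tx_start, tx_end,
                            exon_starts = NULL, exon_ends = NULL) {
  n <- length(name)
  if (is.null(exon_starts)) exon_starts <- as.list(tx_start)
  if (is.null(exon_ends)) exon_ends <- as.list(tx_end)
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(tx_start >= tx_end)) stop("tx_start must be < tx_end")
  for (i in seq_len(n)) {
    es <- exon_starts[[i]]; ee <- exon_ends[[i]]
    if (length(es) != length(ee)) {
      stop("gene ", name[i], ": exon start/end lists of unequal length")
    }
    if (any(es >= ee) || is.unsorted(es) ||
        (length(es) > 1L && any(es[-1] < ee[-length(ee)])) ||
        es[1] < tx_start[i] || ee[length(ee)] > tx_end[i]) {
      stop("gene ", name[i], ": malformed exon blocks")
    }
  }
  df <- data.frame(name = as.character(name), chrom = as.character(chrom),
                   strand = strand, tx_start = as.numeric(tx_start),
                   tx_end = as.numeric(tx_end), stringsAsFactors = FALSE)
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  df$symbol <- toupper(df$name)
  # de-duplication policy: one representative transcript (the longest) per
  # symbol, so nearest-gene queries have a single deterministic TSS
  if (anyDuplicated(df$symbol)) {
    len <- df$tx_end - df$tx_start
    ord <- order(df$symbol, -len, df$chrom, df$tx_start)
    df <- df[ord, , drop = FALSE]
    dropped <- duplicated(df$symbol)
    if (any(dropped)) {
      message(sum(dropped), " duplicate gene symbol(s) collapsed to the ",
              "longest transcript")
    }
    df <- df[!dropped, , drop = FALSE]
  }
  df$tss <- ifelse(df$strand == "+", df$tx_start, df$tx_end - 1)
  ord <- order(df$chrom, df$tx_start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "universe_size") <- length(unique(df$symbol))
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write a gene annotation back to the refFlat-like format
#' @param x A `gene_annotation`.
#' @param path Output path.
#' @export
write_gene_annotation <- function(x, path) {
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  out <- paste(x$name, x$chrom, x$strand, fmt(x$tx_start), fmt(x$tx_end),
               vapply(x$exon_starts, function(v) paste0(paste(fmt(v),
                 collapse = ","), ","), character(1)),
               vapply(x$exon_ends, function(v) paste0(paste(fmt(v),
                 collapse = ","), ","), character(1)),
               sep = "\t")
  writeLines(c("#name\tchrom\tstrand\ttxStart\ttxEnd\texonStarts\texonEnds",
               out), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then one or more gene symbols, all
#' tab-separated. Symbols are upper-cased and de-duplicated.
#'
#' @param path Path to a GMT file.
#' @return A named list of `gene_set` objects (each a list with `name` and
#'   `genes`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character()))
  }
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line ", i, ": fewer than 3 fields")
    gene_set(f[1], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Construct a gene set
#' @param name Signature identifier.
#' @param genes Character vector of gene symbols (upper-cased, de-duplicated).
#' @return A `gene_set` list.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Write gene sets to GMT
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  out <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(out, path)
  invisible(path)
}

#' Construct an expression matrix
#'
#' @param values Numeric matrix of log2-scale intensities, genes in rows
#'   (rownames = symbols), samples in columns (colnames = sample names).
#' @param group Character vector of condition labels (e.g. `"wt"`/`"ko"`),
#'   one per column or named by sample.
#' @return An `expression_matrix`: the matrix with a `group` attribute.
#' @export
expression_matrix <- function(values, group) {
  values <- as.matrix(values)
  if (!is.null(names(group))) {
    if (!all(colnames(values) %in% names(group))) {
      stop("sample(s) missing from group map: ",
           paste(setdiff(colnames(values), names(group)), collapse = ", "))
    }
    group <- unname(group[colnames(values)])
  }
  if (length(group) != ncol(values)) {
    stop("group labels must match the number of samples")
  }
  rownames(values) <- toupper(rownames(values))
  attr(values, "group") <- as.character(group)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  g <- table(attr(x, "group"))
  cat("Expression matrix: ", nrow(x), " genes x ", ncol(x), " samples (",
      paste(names(g), g, sep = ":", collapse = ", "), "), log2 scale\n",
      sep = "")
  invisible(x)
}

#' Read a log2 expression matrix from TSV
#'
#' First column = gene symbol, header = sample names. Rows containing any
#' non-numeric or missing value are dropped with a message.
#'
#' @param path Path to the TSV file.
#' @param group_map Named character vector mapping every sample name in the
#'   header to a condition label.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, group_map) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column")
  samples <- colnames(tab)[-1]
  missing <- setdiff(samples, names(group_map))
  if (length(missing)) {
    stop("sample(s) absent from group map: ", paste(missing, collapse = ", "))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1, drop = FALSE])),
           nrow = nrow(tab), dimnames = list(tab[[1]], samples))
  )
  keep <- complete.cases(vals)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing or non-numeric values dropped")
  }
  expression_matrix(vals[keep, , drop = FALSE], group_map[samples])
}

# shared TSV writer: data frame + '#'-prefixed comment lines recording the
# parameters that produced the table
write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
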