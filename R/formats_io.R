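# Readers and writers for every external file the pipeline touches.
#
# All genomic intervals are held internally as 0-based half-open [start, end),
# the native BED convention. GTF (1-based inclusive) is converted once, at the
# boundary, so downstream window arithmetic uses a single convention.

## ---- peaks ------------------------------------------------------------

#' Construct a validated peak table
#'
#' A peak is one CLIP binding site of one RBP: chromosome, 0-based half-open
#' interval, strand and a per-peak binding p-value (the "CLIP signal").
#'
#' @param rbp_id,chrom,start,end,strand,binding_p vectors of equal length.
#' @return a `data.frame` of class `rbp_peaks` with those six columns.
#' @export
peak_table <- function(rbp_id, chrom, start, end, strand = ".", binding_p) {
  df <- data.frame(
    rbp_id = as.character(rbp_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand), binding_p = as.numeric(binding_p),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
  class(df) <- c("rbp_peaks", "data.frame")
  df
}

validate_peaks <- function(df) {
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop(sprintf("malformed peak coordinates (start >= end) at row(s): %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(df$binding_p > 0 & df$binding_p <= 1))
  if (length(bad)) {
    stop(sprintf("binding p-value outside (0, 1] at row(s): %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(df$chrom))) stop("empty chromosome name", call. = FALSE)
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  invisible(df)
}

#' Read CLIP peaks from a BED-like file
#'
#' Expects a tab-separated BED-like file with at least five columns:
#' chrom, start, end, name, score/p-value (and optionally strand). CLIPdb
#' exports differ in which column carries the binding p-value and whether it
#' is raw or -log10-transformed, so both are configurable.
#'
#' @param path file path.
#' @param rbp_id RBP identifier to stamp on every peak; defaults to the file
#'   name without extension.
#' @param p_value_column 1-based column index holding the binding p-value.
#' @param p_dialect `"raw"` (p in (0,1]) or `"minus_log10"` (column holds
#'   -log10(p), converted on read).
#' @return a peak table (see [peak_table()]); coordinates are kept 0-based
#'   half-open as in BED. Rows failing validation raise an error naming the
#'   offending line numbers.
#' @export
read_peaks <- function(path, rbp_id = NULL, p_value_column = 5L,
                       p_dialect = c("raw", "minus_log10")) {
  p_dialect <- match.arg(p_dialect)
  if (is.null(rbp_id)) rbp_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) NULL
  )
  if (is.null(raw) || nrow(raw) == 0L) {
    return(peak_table(character(), character(), integer(), integer(),
                      character(), numeric()))
  }
  if (ncol(raw) < max(5L, p_value_column)) {
    stop(sprintf("'%s': expected >= %d tab-separated columns, found %d",
                 path, max(5L, p_value_column), ncol(raw)), call. = FALSE)
  }
  pval <- suppressWarnings(as.numeric(raw[[p_value_column]]))
  bad <- which(is.na(pval))
  if (length(bad)) {
    stop(sprintf("'%s': p-value column %d not numeric at line(s): %s",
                 path, p_value_column, paste(head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  if (p_dialect == "minus_log10") pval <- 10^(-pval)
  strand <- if (ncol(raw) >= 6L) as.character(raw[[6L]]) else "."
  strand[!strand %in% c("+", "-")] <- "."
  start <- suppressWarnings(as.integer(raw[[2L]]))
  end <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop(sprintf("'%s': malformed coordinates (start >= end or non-integer) at line(s): %s",
                 path, paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(pval > 0 & pval <= 1))
  if (length(bad)) {
    stop(sprintf("'%s': binding p-value outside (0, 1] at line(s): %s",
                 path, paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  peak_table(rbp_id, as.character(raw[[1L]]), start, end, strand, pval)
}

## ---- annotation -------------------------------------------------------

#' Construct a validated transcript annotation
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `biotype`, `chrom`, `strand`.
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @return list of class `rbp_annotation` with elements `transcripts`
#'   (gaining `length`, `span_start`, `span_end` columns) and `exons`
#'   (sorted by transcript and start).
#' @export
annotation_table <- function(transcripts, exons) {
  stopifnot(all(c("transcript_id", "gene_id", "biotype", "chrom", "strand")
                %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  assert_unique(transcripts$transcript_id, "transcript ids")
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("transcript strand must be '+' or '-'", call. = FALSE)
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) stop("exon with start >= end", call. = FALSE)
  missing_ex <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(missing_ex)) {
    stop(sprintf("transcript(s) without exons: %s",
                 paste(head(missing_ex, 5L), collapse = ", ")), call. = FALSE)
  }
  # overlapping exons within one transcript are an annotation defect
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tx in names(by_tx)) {
    idx <- by_tx[[tx]]
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] < e[-length(e)])) {
        stop(sprintf("overlapping exons within transcript '%s'", tx),
             call. = FALSE)
      }
    }
  }
  len <- vapply(by_tx, function(i) sum(exons$end[i] - exons$start[i]), 0)
  sp_s <- vapply(by_tx, function(i) min(exons$start[i]), 0)
  sp_e <- vapply(by_tx, function(i) max(exons$end[i]), 0)
  ord <- match(transcripts$transcript_id, names(by_tx))
  transcripts$length <- as.integer(len[ord])
  transcripts$span_start <- as.integer(sp_s[ord])
  transcripts$span_end <- as.integer(sp_e[ord])
  rownames(transcripts) <- NULL
  rownames(exons) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "rbp_annotation")
}

#' Read transcript annotation from a GTF file
#'
#' Groups exon features per transcript, converting GTF 1-based inclusive
#' coordinates to the internal 0-based half-open convention, and computes
#' transcript length as the sum of exon lengths. Biotype is taken from the
#' `transcript_biotype` attribute when present, else `gene_biotype`, else
#' `biotype`; unknown biotype strings pass through verbatim. Transcripts
#' announced by a `transcript` feature but carrying no exon rows are skipped
#' with a warning; overlapping exons within one transcript are an error.
#'
#' @param path GTF file path.
#' @return an `rbp_annotation` (see [annotation_table()]).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  is_exon <- as.character(gr$type) == "exon"
  if (!any(is_exon)) stop(sprintf("'%s': no exon features", path), call. = FALSE)
  biotype_of <- function(i) {
    for (key in c("transcript_biotype", "gene_biotype", "biotype")) {
      if (key %in% names(md)) {
        v <- as.character(md[[key]][i])
        if (!all(is.na(v))) return(v)
      }
    }
    rep(NA_character_, length(i))
  }
  exi <- which(is_exon)
  tx_id <- as.character(md$transcript_id[exi])
  if ("transcript_id" %in% names(md)) {
    announced <- unique(as.character(md$transcript_id[!is_exon]))
    announced <- announced[!is.na(announced)]
    orphan <- setdiff(announced, unique(tx_id))
    if (length(orphan)) {
      warning(sprintf("skipping %d transcript(s) with zero exon rows: %s",
                      length(orphan), paste(head(orphan, 5L), collapse = ", ")),
              call. = FALSE)
    }
  }
  exons <- data.frame(
    transcript_id = tx_id,
    start = GenomicRanges::start(gr)[exi] - 1L, # GTF 1-based incl -> 0-based half-open
    end = GenomicRanges::end(gr)[exi],
    stringsAsFactors = FALSE
  )
  first <- !duplicated(tx_id)
  transcripts <- data.frame(
    transcript_id = tx_id[first],
    gene_id = as.character(md$gene_id[exi][first]),
    biotype = biotype_of(exi[first]),
    chrom = as.character(GenomicRanges::seqnames(gr))[exi][first],
    strand = as.character(GenomicRanges::strand(gr))[exi][first],
    stringsAsFactors = FALSE
  )
  annotation_table(transcripts, exons)
}

## ---- expression matrices ----------------------------------------------

#' Construct a validated expression matrix
#'
#' @param values numeric matrix, rows are transcripts or genes, columns are
#'   tissues/conditions; non-negative.
#' @param level `"transcript"` or `"protein"`.
#' @return the matrix with unique dimnames and a `level` attribute, class
#'   `rbp_expr`.
#' @export
expression_matrix <- function(values, level = c("transcript", "protein")) {
  level <- match.arg(level)
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) > 0L && is.null(rownames(values))) {
    stop("expression matrix needs row names", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character()
  if (is.null(colnames(values))) {
    stop("expression matrix needs column (tissue) names", call. = FALSE)
  }
  assert_unique(rownames(values), "expression row ids")
  assert_unique(colnames(values), "tissue ids")
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative expression value", call. = FALSE)
  }
  structure(values, level = level, class = c("rbp_expr", class(values)))
}

#' Read an expression matrix from TSV
#'
#' First column holds row ids, header row holds tissue ids, body is numeric
#' and non-negative.
#'
#' @inheritParams expression_matrix
#' @param path TSV file path.
#' @export
read_expression <- function(path, level = c("transcript", "protein")) {
  level <- match.arg(level)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop(sprintf("'%s': empty table", path), call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, level)
}

#' Write an expression matrix to TSV
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- edge lists --------------------------------------------------------

#' Read an undirected edge list from TSV (two columns of node ids)
#'
#' Self-loops are dropped and duplicate edges (in either orientation)
#' deduplicated, with a warning when anything was removed.
#' @param path TSV path, no header required.
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  edge_list(df[[1L]], df[[2L]])
}

#' Construct a normalized undirected edge list
#' @param from,to character vectors of node ids.
#' @return data.frame of class `rbp_edges` with columns `from`, `to`,
#'   `from <= to` lexicographically, deduplicated, no self-loops.
#' @export
edge_list <- function(from, to) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- a != b
  n_self <- sum(!keep)
  key <- paste(a[keep], b[keep], sep = "\r")
  dup <- duplicated(key)
  if (n_self || any(dup)) {
    warning(sprintf("edge list normalized: %d self-loop(s), %d duplicate(s) removed",
                    n_self, sum(dup)), call. = FALSE)
  }
  structure(data.frame(from = a[keep][!dup], to = b[keep][!dup],
                       stringsAsFactors = FALSE),
            class = c("rbp_edges", "data.frame"))
}

#' Write an edge list to TSV
#' @param x edge list.
#' @param path output path.
#' @export
write_edge_list <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## ---- tabular outputs ---------------------------------------------------

#' Write/read a generic result table (network, classification, features)
#'
#' Plain TSV with header; `read_result_table(write_result_table(x)) == x`
#' column-for-column for the supported atomic types.
#' @param x data.frame.
#' @param path file path.
#' @export
write_result_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
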