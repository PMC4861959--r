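# RBP -> target-transcript network construction.
#
# A transcript is a target of an RBP iff at least one of the RBP's peaks
# shares >= 1 base with a window of +/- `flank` bp around any of the
# transcript's exonic start or end coordinates. The default flank of 300 bp
# reflects the typical distance of RBP binding sites from splice sites.

#' Boundary windows around exon starts and ends
#'
#' For each exon `[s, e)` (0-based half-open) two windows are produced:
#' `[max(0, s - flank), s + flank + 1)` around the start coordinate and
#' `[max(0, e - 1 - flank), e + flank)` around the last exonic base. Windows
#' may overlap each other and the exon body; they are clipped at the
#' chromosome origin.
#'
#' @param annotation an `rbp_annotation`.
#' @param flank non-negative integer flank size in bp (default 300).
#' @param transcript_id optional subset of transcript ids.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `transcript_id`, `boundary_kind` (`"exon_start"` / `"exon_end"`).
#' @export
boundary_windows <- function(annotation, flank = 300L, transcript_id = NULL) {
  stopifnot(inherits(annotation, "rbp_annotation"), flank >= 0)
  flank <- as.integer(flank)
  ex <- annotation$exons
  if (!is.null(transcript_id)) {
    ex <- ex[ex$transcript_id %in% transcript_id, , drop = FALSE]
  }
  tx <- annotation$transcripts
  m <- match(ex$transcript_id, tx$transcript_id)
  win <- data.frame(
    chrom = rep(tx$chrom[m], 2L),
    start = c(pmax(0L, ex$start - flank), pmax(0L, ex$end - 1L - flank)),
    end = c(ex$start + flank + 1L, ex$end + flank),
    strand = rep(tx$strand[m], 2L),
    transcript_id = rep(ex$transcript_id, 2L),
    boundary_kind = rep(c("exon_start", "exon_end"), each = nrow(ex)),
    stringsAsFactors = FALSE
  )
  rownames(win) <- NULL
  win
}

#' Map peaks to target transcripts
#'
#' @param peaks a peak table (see [peak_table()]).
#' @param annotation an `rbp_annotation`.
#' @param flank window half-width in bp.
#' @param respect_strand require peak and transcript strand to agree
#'   (peaks with strand `"."` match either strand). Off by default: CLIP
#'   peak strand annotation is frequently absent or unreliable.
#' @param exclude_self drop targets whose gene encodes the RBP itself;
#'   requires `rbp_gene`.
#' @param rbp_gene named character vector mapping rbp_id -> gene_id (only
#'   used when `exclude_self = TRUE`).
#' @return an object of class `rbp_network`: list with
#'   * `rbps`: all RBP ids seen in `peaks` (targets may be empty),
#'   * `targets`: named list rbp_id -> character vector of transcript ids,
#'   * `support`: data.frame (rbp_id, transcript_id, chrom, peak_start,
#'     peak_end, binding_p) with one row per supporting peak/target pair.
#' @export
map_targets <- function(peaks, annotation, flank = 300L,
                        respect_strand = FALSE, exclude_self = FALSE,
                        rbp_gene = NULL) {
  stopifnot(inherits(annotation, "rbp_annotation"))
  rbps <- unique(peaks$rbp_id)
  chroms <- unique(annotation$transcripts$chrom)
  off <- !(peaks$chrom %in% chroms)
  if (any(off)) {
    warning(sprintf("%d peak(s) on chromosome(s) absent from annotation ignored",
                    sum(off)), call. = FALSE)
    peaks <- peaks[!off, , drop = FALSE]
  }
  win <- boundary_windows(annotation, flank)
  support <- if (nrow(peaks) == 0L || nrow(win) == 0L) {
    data.frame(rbp_id = character(), transcript_id = character(),
               chrom = character(), peak_start = integer(),
               peak_end = integer(), binding_p = numeric(),
               stringsAsFactors = FALSE)
  } else {
    pk_gr <- GenomicRanges::GRanges(
      peaks$chrom,
      IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
      strand = ifelse(peaks$strand == ".", "*", peaks$strand)
    )
    win_gr <- GenomicRanges::GRanges(
      win$chrom,
      IRanges::IRanges(start = win$start + 1L, end = win$end),
      strand = win$strand
    )
    hits <- GenomicRanges::findOverlaps(pk_gr, win_gr,
                                        ignore.strand = !respect_strand)
    pi <- S4Vectors::queryHits(hits)
    ti <- win$transcript_id[S4Vectors::subjectHits(hits)]
    dup <- duplicated(paste(peaks$rbp_id[pi], ti, pi, sep = "\r"))
    pi <- pi[!dup]; ti <- ti[!dup]
    data.frame(rbp_id = peaks$rbp_id[pi], transcript_id = ti,
               chrom = peaks$chrom[pi], peak_start = peaks$start[pi],
               peak_end = peaks$end[pi], binding_p = peaks$binding_p[pi],
               stringsAsFactors = FALSE)
  }
  if (exclude_self) {
    if (is.null(rbp_gene)) {
      stop("exclude_self = TRUE requires 'rbp_gene'", call. = FALSE)
    }
    tx <- annotation$transcripts
    self_gene <- rbp_gene[support$rbp_id]
    tgt_gene <- tx$gene_id[match(support$transcript_id, tx$transcript_id)]
    support <- support[is.na(self_gene) | self_gene != tgt_gene, , drop = FALSE]
  }
  targets <- lapply(setNames(rbps, rbps), function(r) {
    sort(unique(support$transcript_id[support$rbp_id == r]))
  })
  structure(list(rbps = rbps, targets = targets, support = support),
            class = "rbp_network")
}

#' Per-RBP target counts and the union of unique targets
#'
#' @param net an `rbp_network`.
#' @return list with `table` (data.frame rbp_id, n_targets) and
#'   `union_targets` (number of unique transcripts targeted by any RBP).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "rbp_network"))
  tab <- data.frame(
    rbp_id = net$rbps,
    n_targets = vapply(net$targets[net$rbps], length, 0L),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab,
       union_targets = length(unique(unlist(net$targets, use.names = FALSE))))
}

#' Flatten a network to its edge table (rbp_id, transcript_id, n peaks)
#' @param net an `rbp_network`.
#' @return data.frame with one row per RBP-target pair.
#' @export
network_edges <- function(net) {
  s <- net$support
  if (nrow(s) == 0L) {
    return(data.frame(rbp_id = character(), transcript_id = character(),
                      n_supporting_peaks = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_supporting_peaks = s$binding_p),
                          by = list(rbp_id = s$rbp_id,
                                    transcript_id = s$transcript_id),
                          FUN = length)
  agg <- agg[order(agg$rbp_id, agg$transcript_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Rebuild an `rbp_network` from an edge table written by [network_edges()]
#'
#' Support-level peak detail (positions, p-values) is not recoverable from
#' the edge table; `support` carries NA placeholders.
#' @param edges data.frame with columns rbp_id, transcript_id.
#' @param rbps optional full RBP id set (to preserve zero-target RBPs).
#' @export
network_from_edges <- function(edges, rbps = NULL) {
  rbps <- rbps %||% unique(edges$rbp_id)
  targets <- lapply(setNames(rbps, rbps), function(r) {
    sort(unique(edges$transcript_id[edges$rbp_id == r]))
  })
  n <- nrow(edges)
  support <- data.frame(rbp_id = edges$rbp_id,
                        transcript_id = edges$transcript_id,
                        chrom = rep(NA_character_, n),
                        peak_start = rep(NA_integer_, n),
                        peak_end = rep(NA_integer_, n),
                        binding_p = rep(NA_real_, n),
                        stringsAsFactors = FALSE)
  structure(list(rbps = rbps, targets = targets, support = support),
            class = "rbp_network")
}
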