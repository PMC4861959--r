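# Protein-interaction network centralities and the sync / non-sync
# comparison. "Sync" RBPs carry the same significant label (SC at both
# levels, or SIC at both levels) in the transcript-level and protein-level
# classifications; the hypothesis tested is that sync RBPs sit more
# centrally in the protein-interaction network.

#' Split RBPs into sync and non-sync sets from two classifications
#'
#' @param class_rna,class_protein results of [run_level()] at the transcript
#'   and protein level (or their `table` data.frames).
#' @return list: `sync` and `non_sync` character vectors partitioning the
#'   RBPs classified at both levels.
#' @export
sync_partition <- function(class_rna, class_protein) {
  tab <- function(x) if (inherits(x, "rbp_classification")) x$table else x
  a <- tab(class_rna); b <- tab(class_protein)
  shared <- intersect(a$rbp_id, b$rbp_id)
  if (!length(shared)) stop("no RBP classified at both levels", call. = FALSE)
  la <- a$label[match(shared, a$rbp_id)]
  lb <- b$label[match(shared, b$rbp_id)]
  sync <- shared[(la == "SC" & lb == "SC") | (la == "SIC" & lb == "SIC")]
  list(sync = sync, non_sync = setdiff(shared, sync))
}

#' Closeness and betweenness centrality of an undirected graph
#'
#' Closeness uses the classical definition with the Wasserman-Faust
#' component scaling so disconnected graphs are handled:
#' `closeness(v) = (k / sum d(v,u)) * (k / (n - 1))` where `k` is the number
#' of nodes reachable from `v` and the sum runs over them; an isolated node
#' scores 0. With `harmonic = TRUE` the harmonic alternative
#' `sum(1 / d(v,u)) / (n - 1)` is used instead. Betweenness is the standard
#' shortest-path count (each unordered pair counted once), reported
#' unnormalized with a normalized column alongside. Self-loops and duplicate
#' edges are normalized away by [edge_list()] before this point.
#'
#' @param edges an edge list ([edge_list()]).
#' @param nodes optional node universe including isolated nodes.
#' @param harmonic use harmonic closeness instead of the classical scaled
#'   definition.
#' @return data.frame of class columns `node`, `closeness`, `betweenness`,
#'   `betweenness_normalized`, `component_size`.
#' @export
centralities <- function(edges, nodes = NULL, harmonic = FALSE) {
  nodes <- unique(c(nodes %||% character(), edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  n <- length(nodes)
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  closeness <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    k <- length(reach)
    if (k == 0L) return(0)
    if (harmonic) sum(1 / reach) / (n - 1) else (k / sum(reach)) * (k / (n - 1))
  }, 0)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  norm <- if (n > 2L) btw / ((n - 1) * (n - 2) / 2) else btw * 0
  out <- data.frame(
    node = nodes,
    closeness = closeness,
    betweenness = unname(btw[nodes]),
    betweenness_normalized = unname(norm[nodes]),
    component_size = comp$csize[comp$membership[nodes]],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Compare a centrality measure between two node groups
#'
#' Two-sided Wilcoxon rank-sum test (exact when sample sizes permit and
#' there are no ties, matching `stats::wilcox.test` defaults) plus the sign
#' of the median difference.
#'
#' @param cent centrality table from [centralities()].
#' @param group1,group2 character vectors of node ids (e.g. sync / non-sync
#'   RBPs); both must contain at least 2 nodes present in `cent`.
#' @param measure column of `cent` to compare.
#' @return list: `p`, `direction` (+1 when `group1` median higher, -1 lower,
#'   0 equal), `median_group1`, `median_group2`, `n1`, `n2`.
#' @export
compare_groups <- function(cent, group1, group2, measure = "closeness") {
  stopifnot(measure %in% names(cent))
  v1 <- cent[[measure]][cent$node %in% group1]
  v2 <- cent[[measure]][cent$node %in% group2]
  if (length(v1) < 2L || length(v2) < 2L) {
    stop(sprintf("both groups need >= 2 nodes with centralities (have %d, %d)",
                 length(v1), length(v2)), call. = FALSE)
  }
  p <- suppressWarnings(
    wilcox.test(v1, v2, alternative = "two.sided")$p.value
  )
  m1 <- median(v1); m2 <- median(v2)
  list(p = p, direction = sign(m1 - m2),
       median_group1 = m1, median_group2 = m2,
       n1 = length(v1), n2 = length(v2))
}
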