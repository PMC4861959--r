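# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive, transparent algorithms and share no code with
# the package internals they check.

# all-pairs peak/window overlap by direct arithmetic: transcript T is a
# target of RBP R iff some peak of R shares >= 1 base with the window
# [max(0, b - flank), b + flank + 1) around some exon boundary base b of T
brute_force_targets <- function(peaks, annotation, flank = 300L) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  out <- list()
  for (r in unique(peaks$rbp_id)) {
    pk <- peaks[peaks$rbp_id == r, , drop = FALSE]
    hits <- character()
    for (ti in seq_len(nrow(tx))) {
      t_id <- tx$transcript_id[ti]
      exs <- ex[ex$transcript_id == t_id, , drop = FALSE]
      boundaries <- c(exs$start, exs$end - 1L) # boundary bases, 0-based
      found <- FALSE
      for (pi in seq_len(nrow(pk))) {
        if (pk$chrom[pi] != tx$chrom[ti]) next
        for (b in boundaries) {
          ws <- max(0L, b - flank); we <- b + flank + 1L
          if (pk$start[pi] < we && pk$end[pi] > ws) { found <- TRUE; break }
        }
        if (found) break
      }
      if (found) hits <- c(hits, t_id)
    }
    out[[r]] <- sort(hits)
  }
  out
}

# random peak/annotation instance for the overlap equivalence property
random_overlap_instance <- function(n_peaks = 50L, n_transcripts = 20L) {
  chroms <- c("c1", "c2")
  tx <- list(); exn <- list()
  for (i in seq_len(n_transcripts)) {
    n_ex <- sample(1:4, 1L)
    starts <- sort(sample(0:20000, n_ex))
    lens <- sample(10:400, n_ex, replace = TRUE)
    # keep exons non-overlapping by spacing them out
    starts <- starts + cumsum(rep(500L, n_ex)) - 500L
    tx[[i]] <- data.frame(transcript_id = paste0("t", i),
                          gene_id = paste0("g", i), biotype = "protein_coding",
                          chrom = sample(chroms, 1L),
                          strand = sample(c("+", "-"), 1L))
    exn[[i]] <- data.frame(transcript_id = paste0("t", i),
                           start = starts, end = starts + lens)
  }
  ann <- annotation_table(do.call(rbind, tx), do.call(rbind, exn))
  n_rbps <- sample(2:4, 1L)
  starts <- sample(0:25000, n_peaks, replace = TRUE)
  pk <- peak_table(
    rbp_id = paste0("R", sample(n_rbps, n_peaks, replace = TRUE)),
    chrom = sample(chroms, n_peaks, replace = TRUE),
    start = starts, end = starts + sample(10:200, n_peaks, replace = TRUE),
    strand = sample(c("+", "-", "."), n_peaks, replace = TRUE),
    binding_p = runif(n_peaks, 1e-6, 0.05)
  )
  list(peaks = pk, annotation = ann)
}

# all-pairs BFS centrality oracle: adjacency-list BFS per source with
# shortest-path counting, then the pair-combination identity for betweenness
bfs_centrality_oracle <- function(edges, nodes) {
  nodes <- unique(c(nodes, edges$from, edges$to))
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- idx[[edges$from[k]]]; b <- idx[[edges$to[k]]]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, n, n); S <- matrix(0, n, n) # distances, path counts
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- rep(0, n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) sig[w] <- sig[w] + sig[v]
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist; S[s, ] <- sig
  }
  closeness <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]; d <- d[is.finite(d)]
    if (!length(d)) return(0)
    (length(d) / sum(d)) * (length(d) / (n - 1))
  }, 0)
  betweenness <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || is.infinite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t]) {
        tot <- tot + S[s, v] * S[v, t] / S[s, t]
      }
    }
    tot
  }, 0)
  data.frame(node = nodes, closeness = closeness, betweenness = betweenness,
             stringsAsFactors = FALSE)
}

# random connected-ish graph for centrality properties
random_edge_list <- function(n_nodes = 20L, extra = 15L) {
  nodes <- paste0("n", seq_len(n_nodes))
  from <- nodes[vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 1L)]
  to <- nodes[2:n_nodes]
  a <- sample(nodes, extra, replace = TRUE)
  b <- sample(nodes, extra, replace = TRUE)
  keep <- a != b
  suppressWarnings(edge_list(c(from, a[keep]), c(to, b[keep])))
}

# tiny annotation fixture used across io/classifier tests
tiny_annotation <- function() {
  tx <- data.frame(
    transcript_id = c("tA1", "tA2", "tB1", "tL1"),
    gene_id = c("gA", "gA", "gB", "gA"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA"),
    chrom = "c1", strand = c("+", "+", "-", "+"),
    stringsAsFactors = FALSE
  )
  exn <- data.frame(
    transcript_id = c("tA1", "tA1", "tA2", "tB1", "tL1"),
    start = c(1000L, 2000L, 1000L, 5000L, 9000L),
    end = c(1200L, 2300L, 1500L, 5600L, 9400L),
    stringsAsFactors = FALSE
  )
  annotation_table(tx, exn)
}

# small expression matrix with named rows over k tissues
tiny_expr <- function(rows, k = 6L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rexp(length(rows) * k), nrow = length(rows),
                dimnames = list(rows, paste0("ts", seq_len(k))))
    expression_matrix(m, "transcript")
  })
}
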