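# PPI centralities and the sync/non-sync comparison.

test_that("closeness and betweenness match hand-enumerated small graphs", {
  # path a - b - c
  path <- edge_list(c("a", "b"), c("b", "c"))
  cent <- centralities(path)
  b <- cent[cent$node == "b", ]
  expect_equal(b$betweenness, 1)
  expect_equal(b$closeness, 1)
  a <- cent[cent$node == "a", ]
  expect_equal(a$betweenness, 0)
  expect_equal(a$closeness, (2 / 3) * (2 / 2))

  # star: center lies on every leaf pair's only path
  star <- edge_list(rep("c0", 4), paste0("l", 1:4))
  cs <- centralities(star)
  expect_equal(cs$betweenness[cs$node == "c0"], choose(4, 2))
  expect_equal(cs$closeness[cs$node == "c0"], 1)

  # complete graph K4: everything adjacent, no intermediaries
  k4 <- t(utils::combn(paste0("v", 1:4), 2))
  ck <- centralities(edge_list(k4[, 1], k4[, 2]))
  expect_equal(ck$betweenness, rep(0, 4))
  expect_equal(ck$closeness, rep(1, 4))

  # isolated node scores closeness 0
  iso <- centralities(path, nodes = c("a", "b", "c", "z"))
  expect_equal(iso$closeness[iso$node == "z"], 0)
  expect_equal(iso$component_size[iso$node == "z"], 1)
})

test_that("centralities equal the all-pairs BFS oracle on random graphs", {
  withr::with_seed(42, {
    for (i in 1:15) {
      e <- random_edge_list(n_nodes = sample(5:30, 1L),
                            extra = sample(0:25, 1L))
      cent <- centralities(e)
      oracle <- bfs_centrality_oracle(e, cent$node)
      m <- match(cent$node, oracle$node)
      expect_equal(cent$closeness, oracle$closeness[m])
      expect_equal(cent$betweenness, oracle$betweenness[m])
    }
  })
})

test_that("closeness is relabelling-invariant and monotone in added edges", {
  withr::with_seed(19, {
    for (i in 1:5) {
      e <- random_edge_list(n_nodes = 15L, extra = 10L)
      cent <- centralities(e)
      # relabel nodes with a random permutation
      perm <- setNames(sample(paste0("m", seq_along(unique(c(e$from, e$to))))),
                       unique(c(e$from, e$to)))
      e2 <- suppressWarnings(edge_list(perm[e$from], perm[e$to]))
      cent2 <- centralities(e2)
      expect_equal(sort(cent2$closeness), sort(cent$closeness))

      # adding one edge never decreases any node's closeness
      nodes <- unique(c(e$from, e$to))
      pair <- sample(nodes, 2L)
      e3 <- suppressWarnings(edge_list(c(e$from, pair[1]), c(e$to, pair[2])))
      cent3 <- centralities(e3)
      m <- match(cent$node, cent3$node)
      expect_true(all(cent3$closeness[m] >= cent$closeness - 1e-12))
    }
  })
})

test_that("sync partition keeps only same-direction significant pairs", {
  mk <- function(ids, labels) data.frame(rbp_id = ids, label = labels,
                                         stringsAsFactors = FALSE)
  rna <- mk(c("R1", "R2", "R3", "R4"), c("SC", "SC", "SIC", "NSC"))
  prot <- mk(c("R1", "R2", "R3", "R4"), c("SC", "SIC", "SIC", "NSC"))
  sp <- sync_partition(rna, prot)
  expect_setequal(sp$sync, c("R1", "R3"))
  expect_setequal(sp$non_sync, c("R2", "R4"))
  # a planted 6 + 6 cohort gives exactly 12 sync RBPs
  ids <- sprintf("R%02d", 1:60)
  lab_rna <- c(rep("SC", 20), rep("SIC", 20), rep("NSC", 20))
  lab_prot <- lab_rna
  lab_prot[7:20] <- "SIC"; lab_prot[27:40] <- "SC"
  sp2 <- sync_partition(mk(ids, lab_rna), mk(ids, lab_prot))
  expect_length(sp2$sync, 12L)
  expect_error(sync_partition(mk("R1", "SC"), mk("R2", "SC")), "no RBP")
})

test_that("group comparison is symmetric and exact under complete separation", {
  withr::with_seed(3, {
    vals <- c(sort(runif(48, 0, 0.4)), sort(runif(12, 0.5, 1)))
    cent <- data.frame(node = paste0("n", 1:60), closeness = vals,
                       stringsAsFactors = FALSE)
    low <- paste0("n", 1:48)
    high <- paste0("n", 49:60)
    res <- compare_groups(cent, high, low, "closeness")
    # all 12 high values beat all 48 low values: exact two-sided tail
    expect_equal(res$p, 2 / choose(60, 12))
    expect_equal(res$direction, 1)
    swap <- compare_groups(cent, low, high, "closeness")
    expect_equal(swap$p, res$p)
    expect_equal(swap$direction, -1)

    same <- compare_groups(cent, low, low, "closeness")
    expect_gt(same$p, 0.99)
    expect_error(compare_groups(cent, "n1", low), ">= 2 nodes")
  })
})

test_that("planted PPI core elevates sync RBP closeness", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- synth_config(seed = s, n_rbps = 24L, n_transcripts = 100L,
                        targets_per_rbp = c(1L, 2L), n_other_proteins = 80L)
    a <- generate_annotation(cfg)
    p <- generate_peaks(cfg, a$annotation, a$truth)
    g <- generate_ppi(cfg, p$truth)
    cent <- centralities(g$ppi, nodes = g$truth$rbps$gene_id)
    sync <- g$truth$rbps$gene_id[g$truth$rbps$sync]
    non <- setdiff(g$truth$rbps$gene_id, sync)
    med <- function(ids) median(cent$closeness[cent$node %in% ids])
    if (med(sync) > med(non)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
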