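# Peak-to-target mapping around exon boundary windows.

single_exon_annotation <- function(start, end, strand = "+") {
  annotation_table(
    data.frame(transcript_id = "T1", gene_id = "G1",
               biotype = "protein_coding", chrom = "c1", strand = strand,
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "T1", start = start, end = end)
  )
}

test_that("boundary windows follow the +/- flank formula with origin clipping", {
  ann <- single_exon_annotation(1000L, 1200L)
  w <- boundary_windows(ann, flank = 300L)
  ws <- w[w$boundary_kind == "exon_start", ]
  we <- w[w$boundary_kind == "exon_end", ]
  expect_equal(c(ws$start, ws$end), c(700L, 1301L))
  expect_equal(c(we$start, we$end), c(899L, 1500L))

  w0 <- boundary_windows(ann, flank = 0L)
  expect_equal(w0$start, c(1000L, 1199L))
  expect_equal(w0$end, c(1001L, 1200L))

  wc <- boundary_windows(single_exon_annotation(100L, 150L), flank = 300L)
  expect_equal(wc$start[wc$boundary_kind == "exon_start"], 0L)
  expect_equal(wc$end[wc$boundary_kind == "exon_start"], 401L)
})

test_that("map_targets matches the hand-computed window overlap examples", {
  ann <- single_exon_annotation(1000L, 1200L)
  inside <- peak_table("R1", "c1", 750L, 780L, "+", 0.01)
  outside <- peak_table("R1", "c1", 650L, 690L, "+", 0.01)
  expect_equal(map_targets(inside, ann)$targets$R1, "T1")
  expect_equal(map_targets(outside, ann)$targets$R1, character())
})

test_that("RBPs whose peaks all miss the annotation keep an empty target set", {
  ann <- single_exon_annotation(1000L, 1200L)
  pk <- peak_table("R9", "chrUnknown", 10L, 40L, ".", 0.01)
  expect_warning(net <- map_targets(pk, ann), "absent from annotation")
  expect_equal(net$targets$R9, character())
  expect_equal(network_summary(net)$table$n_targets, 0L)
})

test_that("map_targets equals the brute-force all-pairs overlap oracle", {
  withr::with_seed(101, {
    for (i in 1:30) {
      inst <- random_overlap_instance(n_peaks = sample(10:80, 1L),
                                      n_transcripts = sample(5:25, 1L))
      net <- suppressWarnings(
        map_targets(inst$peaks, inst$annotation, flank = 300L))
      oracle <- brute_force_targets(inst$peaks, inst$annotation, flank = 300L)
      for (r in names(oracle)) {
        expect_identical(net$targets[[r]], oracle[[r]])
      }
    }
  })
})

test_that("targets grow monotonically in the flank size", {
  withr::with_seed(7, {
    for (i in 1:10) {
      inst <- random_overlap_instance(n_peaks = 40L, n_transcripts = 12L)
      prev <- NULL
      for (flank in c(0L, 50L, 300L, 1000L)) {
        net <- suppressWarnings(
          map_targets(inst$peaks, inst$annotation, flank = flank))
        if (!is.null(prev)) {
          for (r in names(net$targets)) {
            expect_true(all(prev[[r]] %in% net$targets[[r]]))
          }
        }
        prev <- net$targets
      }
    }
  })
})

test_that("a peak beyond 2*flank of every boundary never creates a target", {
  ann <- single_exon_annotation(5000L, 5400L)
  flank <- 300L
  far <- peak_table("R1", "c1", 5400L + 2L * flank + 1L,
                    5400L + 2L * flank + 40L, ".", 0.01)
  expect_equal(map_targets(far, ann, flank = flank)$targets$R1, character())
})

test_that("network_summary does set arithmetic and matches planted counts", {
  edges <- data.frame(rbp_id = c("R1", "R1", "R2", "R2"),
                      transcript_id = c("T1", "T2", "T2", "T3"))
  net <- network_from_edges(edges)
  s <- network_summary(net)
  expect_equal(s$table$n_targets, c(2L, 2L))
  expect_equal(s$union_targets, 3L)
  expect_equal(network_summary(network_from_edges(edges[0, ], rbps = "R1"))$union_targets, 0L)

  cfg <- synth_config(seed = 5, n_rbps = 3L, n_transcripts = 120L,
                      targets_per_rbp = c(7L, 7L), n_other_proteins = 20L)
  ds <- generate_dataset(cfg)
  net <- map_targets(ds$peaks, ds$annotation, flank = cfg$flank)
  s <- network_summary(net)
  expect_equal(s$table$n_targets, rep(7L, 3L))
})

test_that("exclude_self drops the RBP gene's own transcripts", {
  ann <- annotation_table(
    data.frame(transcript_id = c("T1", "T2"), gene_id = c("R1", "G2"),
               biotype = "protein_coding", chrom = "c1", strand = "+",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = c("T1", "T2"), start = c(1000L, 1000L),
               end = c(1200L, 1300L))
  )
  pk <- peak_table("R1", "c1", 990L, 1020L, "+", 0.01)
  net <- map_targets(pk, ann)
  expect_setequal(net$targets$R1, c("T1", "T2"))
  net2 <- map_targets(pk, ann, exclude_self = TRUE,
                      rbp_gene = c(R1 = "R1"))
  expect_equal(net2$targets$R1, "T2")
})
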