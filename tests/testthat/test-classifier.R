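# Representative selection, Spearman profiles, partitioning and the
# SC/SIC/NSC rank-sum classification.

test_that("select_representative filters to protein_coding then takes argmax", {
  ann <- tiny_annotation() # gA: tA1, tA2 (protein_coding), tL1 (lincRNA)
  m <- rbind(tA1 = rep(5, 4), tA2 = rep(8, 4), tL1 = rep(20, 4))
  colnames(m) <- paste0("ts", 1:4)
  expr <- expression_matrix(m, "transcript")
  expect_equal(select_representative("gA", ann, expr), "tA2")

  expect_equal(select_representative("gB", ann,
                                     tiny_expr("tB1", k = 4)), "tB1")

  m2 <- rbind(tA1 = rep(8, 4), tA2 = rep(8, 4))
  colnames(m2) <- paste0("ts", 1:4)
  expect_equal(select_representative("gA", ann,
                                     expression_matrix(m2, "transcript")),
               "tA1")
  expect_warning(
    expect_true(is.na(select_representative("gB", ann,
                                            tiny_expr("tA1", k = 4)))),
    "no protein_coding")
})

test_that("spearman_profile matches the rank-difference formula exactly", {
  x <- as.numeric(1:16)
  Y <- rbind(same = x, rev = rev(x))
  rho <- spearman_profile(x, Y)
  expect_equal(unname(rho["same"]), 1)
  expect_equal(unname(rho["rev"]), -1)

  # hand computation: d = x_rank - y_rank = (−1,1,−1,1,0), sum d^2 = 4,
  # rho = 1 − 6*4 / (5*24) = 0.8
  x5 <- c(1, 2, 3, 4, 5)
  rho5 <- spearman_profile(x5, rbind(h = c(2, 1, 4, 3, 5)))
  expect_equal(unname(rho5["h"]), 0.8)
})

test_that("spearman_profile excludes constant and under-paired rows with reasons", {
  x <- c(1, 2, 3, 4, 5)
  Y <- rbind(const = rep(2, 5), ok = c(5, 4, 3, 2, 1))
  rho <- spearman_profile(x, Y)
  expect_equal(names(rho), "ok")
  expect_equal(attr(rho, "excluded")$id, "const")

  Yna <- rbind(gap = c(1, NA, NA, NA, 2), ok = c(5, 4, 3, 2, 1))
  rho <- spearman_profile(x, Yna)
  expect_equal(names(rho), "ok")
  expect_match(attr(rho, "excluded")$reason, "fewer than 3")
})

test_that("partition draws reproducible matched controls of the right shape", {
  net <- network_from_edges(data.frame(
    rbp_id = "R1", transcript_id = paste0("T", 1:10)))
  expr <- tiny_expr(paste0("T", 1:110), k = 4)
  p1 <- partition("R1", net, expr, n_reps = 20L, seed = 3L)
  expect_length(p1$targets, 10L)
  expect_length(p1$control_all, 100L)
  expect_length(p1$control_matched, 20L)
  for (s in p1$control_matched) {
    expect_length(s, 10L)
    expect_false(anyDuplicated(s) > 0)
    expect_true(all(s %in% p1$control_all))
    expect_length(intersect(s, p1$targets), 0L)
  }
  p2 <- partition("R1", net, expr, n_reps = 20L, seed = 3L)
  expect_identical(p1$control_matched, p2$control_matched)

  # boundary: pool exactly as large as the target set
  expr20 <- tiny_expr(paste0("T", 1:20), k = 4)
  pb <- partition("R1", net, expr20, n_reps = 3L, seed = 1L)
  for (s in pb$control_matched) expect_setequal(s, pb$control_all)

  # 10 targets but only 2 expressed non-targets: matched draw impossible
  expect_error(partition("R1", net, tiny_expr(paste0("T", 1:12), k = 4)),
               "matched sampling impossible")
})

test_that("classify applies the rank-sum direction rule and its anti-symmetry", {
  withr::with_seed(11, {
    same <- rnorm(50, 0, 0.2)
    expect_equal(classify(same, same)$label, "NSC")
    expect_gt(classify(same, same)$p, 0.9)

    ctrl <- rnorm(100, 0, 0.2)
    up <- rnorm(100, 0.4, 0.2)
    down <- rnorm(100, -0.4, 0.2)
    expect_equal(classify(up, ctrl)$label, "SC")
    expect_equal(classify(down, ctrl)$label, "SIC")
    # swapping the vectors maps SC <-> SIC
    expect_equal(classify(ctrl, up)$label, "SIC")
    expect_equal(classify(ctrl, down)$label, "SC")
    expect_equal(classify(up, ctrl)$p, classify(ctrl, up)$p)
  })
  res <- classify(c(0.1), c(0.2, 0.3))
  expect_equal(res$label, "NSC")
  expect_true(res$insufficient_data)
})

test_that("rho, p and labels are invariant to strictly increasing transforms", {
  cfg <- synth_config(seed = 9, n_rbps = 6L, n_transcripts = 300L,
                      targets_per_rbp = c(20L, 25L), n_other_proteins = 20L)
  ds <- generate_dataset(cfg)
  net <- map_targets(ds$peaks, ds$annotation)
  rbps <- ds$truth$rbps$rbp_id
  base <- run_level(rbps, net, ds$annotation, ds$expr_rna,
                    n_reps = 5L, seed = 2L)
  transformed <- expression_matrix(ds$expr_rna^3 + 1, "transcript")
  alt <- run_level(rbps, net, ds$annotation, transformed,
                   n_reps = 5L, seed = 2L)
  expect_equal(base$table$label, alt$table$label)
  expect_equal(base$table$p_vs_all, alt$table$p_vs_all)
  expect_equal(base$table$median_target_rho, alt$table$median_target_rho)
})

test_that("run_level at protein level uses shared tissues and reports skips", {
  cfg <- synth_config(seed = 21, n_rbps = 8L, n_transcripts = 400L,
                      targets_per_rbp = c(25L, 30L), n_other_proteins = 20L)
  ds <- generate_dataset(cfg)
  net <- map_targets(ds$peaks, ds$annotation)
  rbps <- ds$truth$rbps$rbp_id
  # drop one RBP's protein row: it must be skipped, not fail
  prot <- ds$expr_protein[rownames(ds$expr_protein) != "RBP03", , drop = FALSE]
  cl <- run_level(rbps, net, ds$annotation, ds$expr_rna,
                  expression_matrix(prot, "protein"),
                  level = "protein", n_reps = 5L, seed = 2L)
  expect_true("RBP03" %in% cl$skipped$id)
  expect_equal(nrow(cl$table), 7L)
  # too few shared tissues aborts
  prot2 <- ds$expr_protein[, 1:2, drop = FALSE]
  expect_error(run_level(rbps, net, ds$annotation, ds$expr_rna,
                         expression_matrix(prot2, "protein"),
                         level = "protein", n_reps = 5L, seed = 2L),
               "shared")
})

test_that("class percentages reproduce their counts arithmetically", {
  h <- class_percentages(36, 11, 13)
  expect_equal(h$n, 60)
  expect_equal(round(h$pct_significant, 2), 78.33)
  expect_equal(h$pct_sc, 60)
  p <- class_percentages(3, 2, 5)
  expect_equal(p$pct_significant, 50)
})
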