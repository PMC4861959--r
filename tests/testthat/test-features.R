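# Feature tables (RBP-centric and transcript-centric) and the three
# feature-selection procedures.

# small planted-network fixture shared by the table tests
feature_fixture <- function(seed = 13) {
  cfg <- synth_config(seed = seed, n_rbps = 5L, n_transcripts = 300L,
                      targets_per_rbp = c(20L, 25L), n_other_proteins = 30L)
  ds <- generate_dataset(cfg)
  net <- map_targets(ds$peaks, ds$annotation)
  cl <- run_level(ds$truth$rbps$rbp_id, net, ds$annotation, ds$expr_rna,
                  n_reps = 5L, seed = 2L)
  list(ds = ds, net = net, cl = cl)
}

test_that("rbp_feature_table has exactly the nine predictors plus response", {
  fx <- feature_fixture()
  rft <- rbp_feature_table(fx$net, fx$ds$annotation, fx$cl, fx$ds$expr_rna,
                           fx$ds$expr_protein, fx$ds$ppi,
                           fx$ds$domain_counts)
  expect_identical(names(rft),
                   c("rbp_id", "response", "n_targets", "median_clip_p",
                     "n_rna_binding_domains", "n_ppi_partners",
                     "n_protein_coding_transcripts", "n_annotated_transcripts",
                     "selected_transcript_length", "median_boundary_distance",
                     "mrna_protein_corr"))
  expect_equal(rft$n_targets,
               unname(vapply(fx$net$targets[rft$rbp_id], length, 0L)))
  expect_true(all(rft$response >= -1 & rft$response <= 1))
  expect_true(all(rft$mrna_protein_corr >= -1 & rft$mrna_protein_corr <= 1))
})

test_that("PPI degree, odd-count clip median and missing-entry flags are right", {
  fx <- feature_fixture()
  # overwrite with a hand-built PPI: R has partners A and B; A-B is not R's
  rbps <- fx$ds$truth$rbps$rbp_id
  ppi <- edge_list(c(rbps[1], rbps[1], "A"), c("A", "B", "B"))
  dom <- fx$ds$domain_counts[-2] # RBP 2 has no domain entry
  rft <- rbp_feature_table(fx$net, fx$ds$annotation, fx$cl, fx$ds$expr_rna,
                           fx$ds$expr_protein, ppi, dom)
  expect_equal(rft$n_ppi_partners[rft$rbp_id == rbps[1]], 2L)
  expect_equal(rft$n_ppi_partners[rft$rbp_id == rbps[2]], 0L)
  expect_equal(rft$n_rna_binding_domains[rft$rbp_id == rbps[2]], 0L)
  flags <- attr(rft, "flags")
  expect_true(any(flags$rbp_id == rbps[2] &
                    flags$feature == "n_rna_binding_domains"))

  # odd-count median of binding p-values over one RBP's supporting peaks
  sup <- fx$net$support[fx$net$support$rbp_id == rbps[1], ]
  expect_equal(rft$median_clip_p[rft$rbp_id == rbps[1]],
               median(sup$binding_p))
})

test_that("transcript-centric distances are strand-aware genomic-end offsets", {
  ann <- annotation_table(
    data.frame(transcript_id = c("Tp", "Tm"), gene_id = c("Gp", "Gm"),
               biotype = "protein_coding", chrom = "c1",
               strand = c("+", "-"), stringsAsFactors = FALSE),
    data.frame(transcript_id = c("Tp", "Tm"), start = c(1000L, 1000L),
               end = c(2000L, 2000L))
  )
  # peaks at start 1200 inside the exon-start windows of both transcripts
  pk <- peak_table(c("R1", "R1"), "c1", c(1200L, 1200L), c(1230L, 1230L),
                   ".", c(0.01, 0.01))
  net <- map_targets(pk, ann)
  # hand-made classification carrying a rho for both pairs
  cl <- structure(list(
    rho_long = data.frame(rbp_id = "R1", transcript_id = c("Tp", "Tm"),
                          rho = c(0.5, -0.2), stringsAsFactors = FALSE)
  ), class = "rbp_classification")
  tft <- transcript_feature_table(net, ann, cl)
  expect_identical(names(tft),
                   c("rbp_id", "transcript_id", "response", "clip_p",
                     "dist_5prime", "dist_3prime", "transcript_length",
                     "transcript_type"))
  plus <- tft[tft$transcript_id == "Tp", ]
  minus <- tft[tft$transcript_id == "Tm", ]
  expect_equal(plus$dist_5prime, 200L)
  expect_equal(plus$dist_3prime, 799L)
  # strand reflection swaps the two distances
  expect_equal(minus$dist_5prime, 799L)
  expect_equal(minus$dist_3prime, 200L)

  # peak starting exactly at the transcript start has dist_5prime 0
  pk0 <- peak_table("R1", "c1", 1000L, 1030L, ".", 0.01)
  net0 <- map_targets(pk0, ann)
  cl0 <- structure(list(
    rho_long = data.frame(rbp_id = "R1", transcript_id = "Tp", rho = 0.1,
                          stringsAsFactors = FALSE)
  ), class = "rbp_classification")
  tft0 <- transcript_feature_table(net0, ann, cl0)
  expect_equal(tft0$dist_5prime[tft0$transcript_id == "Tp"], 0L)
})

test_that("the best-p peak is used when several peaks support one pair", {
  ann <- annotation_table(
    data.frame(transcript_id = "T1", gene_id = "G1",
               biotype = "protein_coding", chrom = "c1", strand = "+",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "T1", start = 1000L, end = 2000L)
  )
  pk <- peak_table(c("R1", "R1"), "c1", c(1100L, 1900L), c(1130L, 1930L),
                   "+", c(0.04, 1e-6))
  net <- map_targets(pk, ann)
  cl <- structure(list(
    rho_long = data.frame(rbp_id = "R1", transcript_id = "T1", rho = 0.3,
                          stringsAsFactors = FALSE)
  ), class = "rbp_classification")
  tft <- transcript_feature_table(net, ann, cl)
  expect_equal(tft$clip_p, 1e-6)
  expect_equal(tft$dist_5prime, 900L)
})

test_that("fit_multivariate recovers exact fits and flags rank deficiency", {
  d <- data.frame(y = 3 + 2 * (1:10), x = 1:10)
  fit <- suppressWarnings(fit_multivariate(d, "y", "x")) # perfect fit
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-8)

  withr::with_seed(5, {
    n <- 500
    d2 <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d2$y <- d2$x1 + rnorm(n, 0, 0.1)
    fit2 <- fit_multivariate(d2, "y", c("x1", "x2"))
    expect_lt(fit2$feature_p[["x1"]], 1e-6)
    expect_gt(fit2$feature_p[["x2"]], 0.05)
    expect_identical(fit2$selected, "x1")

    # collinear design errors with the offending column named
    d2$x3 <- 2 * d2$x1
    expect_error(fit_multivariate(d2, "y", c("x1", "x3")),
                 "rank-deficient.*x3")
  })

  # constant response: no predictor explains anything
  d3 <- data.frame(y = rep(1, 20), x = rnorm(20))
  fit3 <- suppressWarnings(fit_multivariate(d3, "y", "x")) # zero-variance y
  expect_gt(fit3$feature_p[["x"]], 0.99)
})

test_that("stepwise drops the null predictor, keeps the strong one, and is
           order-invariant", {
  withr::with_seed(8, {
    n <- 400
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- d$x1 + rnorm(n, 0, 0.3)
    fit <- fit_stepwise(d, "y", c("x1", "x2", "x3"))
    expect_identical(fit$selected, "x1")
    fit_rev <- fit_stepwise(d, "y", c("x3", "x2", "x1"))
    expect_identical(fit_rev$selected, fit$selected)
    expect_equal(fit_rev$coefficients, fit$coefficients)

    # a lone significant predictor is a fixed point
    fit1 <- fit_stepwise(d, "y", "x1")
    expect_identical(fit1$selected, "x1")

    # all-null fit usually collapses to the intercept (this seed does)
    d$y2 <- rnorm(n)
    fit0 <- fit_stepwise(d, "y2", c("x1", "x2", "x3"))
    expect_length(fit0$selected, 0L)
    expect_length(coef(fit0$fit), 1L)
  })
})

test_that("elastic net matches OLS as lambda -> 0 and shrinks to zero for
           large lambda", {
  withr::with_seed(17, {
    n <- 200
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 1.5 * d$x1 - d$x2 + rnorm(n, 0, 0.5)
    # OLS on standardized predictors, centered response
    xs <- scale(as.matrix(d[, c("x1", "x2", "x3")]))
    ys <- d$y - mean(d$y)
    beta_ols <- coef(lm(ys ~ xs - 1))
    en0 <- fit_elastic_net(d, "y", c("x1", "x2", "x3"),
                           l1_ratio = 0.5, lambda = 1e-8)
    expect_equal(unname(en0$coefficients), unname(beta_ols),
                 tolerance = 1e-6)
    en_big <- fit_elastic_net(d, "y", c("x1", "x2", "x3"),
                              l1_ratio = 0.5, lambda = 1e6)
    expect_equal(unname(en_big$coefficients), rep(0, 3))
    expect_length(en_big$selected, 0L)
  })
})

test_that("cross-validated elastic net recovers a sparse truth", {
  withr::with_seed(23, {
    n <- 300
    p <- 10
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", 1:p)))
    y <- 2 * X[, 1] - 2 * X[, 5] + rnorm(n, 0, 0.5)
    d <- data.frame(y = y, X)
    en <- fit_elastic_net(d, "y", paste0("x", 1:p), k_folds = 5L, seed = 4L)
    expect_true(all(c("x1", "x5") %in% en$selected))
    # determinism under the same seed
    en2 <- fit_elastic_net(d, "y", paste0("x", 1:p), k_folds = 5L, seed = 4L)
    expect_identical(en$coefficients, en2$coefficients)
  })
})

test_that("per-RBP transcript models skip small RBPs and summarize medians", {
  fx <- feature_fixture(seed = 31)
  tft <- transcript_feature_table(fx$net, fx$ds$annotation, fx$cl)
  # add a tiny RBP that cannot support a fit
  tiny <- tft[1:3, ]
  tiny$rbp_id <- "Rtiny"
  prm <- per_rbp_transcript_models(rbind(tft, tiny))
  expect_true("Rtiny" %in% prm$skipped$rbp_id)
  expect_false("Rtiny" %in% rownames(prm$neg_log10_p))
  expect_identical(colnames(prm$neg_log10_p),
                   c("clip_p", "dist_5prime", "dist_3prime",
                     "transcript_length", "transcript_type"))
  expect_true(all(prm$fraction_significant >= 0 &
                    prm$fraction_significant <= 1, na.rm = TRUE))

  bio <- biotype_effect_summary(data.frame(
    rbp_id = "R1",
    transcript_type = c("pc", "pc", "lnc"),
    response = c(0.5, 0.6, -0.1)
  ))
  expect_equal(bio$median_rho[bio$transcript_type == "pc"], 0.55)
  expect_equal(bio$median_rho[bio$transcript_type == "lnc"], -0.1)
})
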