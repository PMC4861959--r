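# End-to-end orchestration: build-network -> classify (both levels) ->
# feature modelling -> centrality, from a directory of input files to a
# directory of TSV outputs plus a machine-readable run manifest.

pipeline_defaults <- function() {
  list(flank = 300L, alpha = 0.05, n_reps = 100L, seed = 1L,
       p_value_column = 5L, p_dialect = "raw",
       respect_strand = FALSE, exclude_self = FALSE,
       model_methods = c("multivariate", "stepwise", "elastic_net"))
}

#' Run the whole pipeline over a directory of input files
#'
#' Expects the layout written by [write_synthetic_dataset()] (or equivalent
#' real inputs): `annotation.gtf`, `peaks/<rbp_id>.bed`,
#' `expression_rna.tsv`, optionally `expression_protein.tsv`, `ppi.tsv`,
#' `domain_counts.tsv`. RBP ids are taken from the peak file names and are
#' assumed to be gene ids of the annotation.
#'
#' Stages: (1) peak-to-target network; (2) transcript-level SC/SIC/NSC
#' classification; (3) protein-level classification (skipped with a warning
#' when the protein matrix is absent); (4) RBP-centric and
#' transcript-centric feature tables and models; (5) sync/non-sync PPI
#' centrality comparison (needs both classifications). All randomness is
#' governed by `config$seed`; a second run with the same config and inputs
#' is byte-identical. With `resume = TRUE`, stages whose outputs already
#' exist under a matching config hash are skipped.
#'
#' @param input_dir directory of input files.
#' @param out_dir output directory (created).
#' @param config named list overriding entries of the default config
#'   (`flank = 300`, `alpha = 0.05`, `n_reps = 100`, `seed = 1`,
#'   `p_value_column = 5`, `p_dialect = "raw"`, `respect_strand = FALSE`,
#'   `exclude_self = FALSE`, `model_methods`).
#' @param resume skip stages whose outputs exist under the same config.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(input_dir, out_dir, config = list(), resume = FALSE) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  cfg_hash <- digest_string(cfg_json)

  in_files <- list(
    annotation = file.path(input_dir, "annotation.gtf"),
    expr_rna = file.path(input_dir, "expression_rna.tsv"),
    expr_protein = file.path(input_dir, "expression_protein.tsv"),
    ppi = file.path(input_dir, "ppi.tsv"),
    domains = file.path(input_dir, "domain_counts.tsv")
  )
  peak_files <- sort(list.files(file.path(input_dir, "peaks"),
                                pattern = "\\.bed$", full.names = TRUE))
  if (!length(peak_files)) stop("no peak files under ", input_dir, call. = FALSE)
  for (f in c(in_files$annotation, in_files$expr_rna)) {
    if (!file.exists(f)) stop("missing required input: ", f, call. = FALSE)
  }
  has_protein <- file.exists(in_files$expr_protein)
  if (!has_protein) {
    warning("no protein expression matrix; running transcript level only",
            call. = FALSE)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  } else NULL
  can_resume <- !is.null(old_manifest) &&
    identical(old_manifest$config_hash, cfg_hash)
  stage_done <- function(outputs) {
    can_resume && all(file.exists(file.path(out_dir, outputs)))
  }

  stages <- list()
  log_stage <- function(name, outputs, info = list()) {
    stages[[name]] <<- c(list(outputs = outputs), info)
  }

  annotation <- read_annotation(in_files$annotation)
  expr_rna <- read_expression(in_files$expr_rna, "transcript")
  expr_protein <- if (has_protein) {
    read_expression(in_files$expr_protein, "protein")
  } else NULL
  peaks <- do.call(rbind, lapply(peak_files, function(f) {
    read_peaks(f, p_value_column = cfg$p_value_column,
               p_dialect = cfg$p_dialect)
  }))
  rbps <- sort(unique(peaks$rbp_id))
  rbp_gene <- setNames(rbps, rbps)

  # -- stage 1: network ----------------------------------------------------
  net <- map_targets(peaks, annotation, flank = cfg$flank,
                     respect_strand = cfg$respect_strand,
                     exclude_self = cfg$exclude_self,
                     rbp_gene = if (cfg$exclude_self) rbp_gene else NULL)
  if (!stage_done(c("network.tsv", "network_summary.tsv"))) {
    write_result_table(network_edges(net), file.path(out_dir, "network.tsv"))
    ns <- network_summary(net)
    write_result_table(ns$table, file.path(out_dir, "network_summary.tsv"))
  }
  ns <- network_summary(net)
  log_stage("network", c("network.tsv", "network_summary.tsv"),
            list(n_rbps = length(rbps), n_edges = nrow(network_edges(net)),
                 union_targets = ns$union_targets))

  # -- stage 2/3: classification -------------------------------------------
  class_rna <- run_level(rbps, net, annotation, expr_rna,
                         level = "transcript", rbp_gene = rbp_gene,
                         alpha = cfg$alpha, n_reps = cfg$n_reps,
                         seed = cfg$seed)
  if (!stage_done(c("class_rna.tsv", "rho_rna.tsv"))) {
    write_result_table(class_rna$table, file.path(out_dir, "class_rna.tsv"))
    write_result_table(class_rna$rho_long, file.path(out_dir, "rho_rna.tsv"))
  }
  log_stage("classify_rna", c("class_rna.tsv", "rho_rna.tsv"),
            list(n_classified = nrow(class_rna$table),
                 n_skipped = nrow(class_rna$skipped),
                 labels = as.list(table(class_rna$table$label))))

  class_protein <- NULL
  if (has_protein) {
    class_protein <- run_level(rbps, net, annotation, expr_rna, expr_protein,
                               level = "protein", rbp_gene = rbp_gene,
                               alpha = cfg$alpha, n_reps = cfg$n_reps,
                               seed = cfg$seed)
    if (!stage_done(c("class_protein.tsv", "rho_protein.tsv"))) {
      write_result_table(class_protein$table,
                         file.path(out_dir, "class_protein.tsv"))
      write_result_table(class_protein$rho_long,
                         file.path(out_dir, "rho_protein.tsv"))
    }
    log_stage("classify_protein", c("class_protein.tsv", "rho_protein.tsv"),
              list(n_classified = nrow(class_protein$table),
                   n_skipped = nrow(class_protein$skipped),
                   labels = as.list(table(class_protein$table$label))))
  }

  # -- stage 4: feature modelling -------------------------------------------
  ppi <- if (file.exists(in_files$ppi)) read_edge_list(in_files$ppi) else NULL
  domain_counts <- if (file.exists(in_files$domains)) {
    d <- read_result_table(in_files$domains)
    setNames(as.integer(d[[2L]]), d[[1L]])
  } else setNames(integer(), character())
  if (!is.null(ppi)) {
    rft <- rbp_feature_table(net, annotation, class_rna, expr_rna,
                             expr_protein, ppi, domain_counts, rbp_gene)
    write_result_table(rft, file.path(out_dir, "rbp_features.tsv"))
    fits <- list()
    if ("multivariate" %in% cfg$model_methods) {
      fits$multivariate <- tryCatch(
        fit_multivariate(rft, "response", rbp_feature_cols, alpha = cfg$alpha),
        error = function(e) NULL)
    }
    if ("stepwise" %in% cfg$model_methods) {
      fits$stepwise <- tryCatch(
        fit_stepwise(rft, "response", rbp_feature_cols,
                     alpha_stay = cfg$alpha),
        error = function(e) NULL)
    }
    if ("elastic_net" %in% cfg$model_methods) {
      fits$elastic_net <- tryCatch(
        fit_elastic_net(rft, "response", rbp_feature_cols, seed = cfg$seed),
        error = function(e) NULL)
    }
    ms <- model_summary_table(fits)
    write_result_table(ms, file.path(out_dir, "rbp_model_summary.tsv"))
    tft <- transcript_feature_table(net, annotation, class_rna)
    write_result_table(tft, file.path(out_dir, "transcript_features.tsv"))
    prm <- per_rbp_transcript_models(tft, methods = "multivariate",
                                     alpha = cfg$alpha, seed = cfg$seed)
    sig <- data.frame(rbp_id = rownames(prm$neg_log10_p),
                      prm$neg_log10_p, check.names = FALSE)
    write_result_table(sig, file.path(out_dir,
                                      "transcript_model_significance.tsv"))
    write_result_table(
      data.frame(feature = names(prm$fraction_significant),
                 fraction_significant = unname(prm$fraction_significant)),
      file.path(out_dir, "transcript_feature_fractions.tsv"))
    write_result_table(biotype_effect_summary(tft),
                       file.path(out_dir, "biotype_summary.tsv"))
    log_stage("features",
              c("rbp_features.tsv", "rbp_model_summary.tsv",
                "transcript_features.tsv",
                "transcript_model_significance.tsv",
                "transcript_feature_fractions.tsv", "biotype_summary.tsv"),
              list(n_rbp_rows = nrow(rft), n_pair_rows = nrow(tft),
                   n_models_fitted = length(prm$fits)))
  }

  # -- stage 5: centrality ---------------------------------------------------
  if (!is.null(ppi) && !is.null(class_protein)) {
    sp <- sync_partition(class_rna, class_protein)
    cent <- centralities(ppi, nodes = unname(rbp_gene))
    write_result_table(cent, file.path(out_dir, "centrality.tsv"))
    cmp <- lapply(c("closeness", "betweenness"), function(m) {
      res <- tryCatch(
        compare_groups(cent, rbp_gene[sp$sync], rbp_gene[sp$non_sync], m),
        error = function(e) list(p = NA_real_, direction = NA_real_,
                                 median_group1 = NA_real_,
                                 median_group2 = NA_real_,
                                 n1 = length(sp$sync), n2 = length(sp$non_sync)))
      data.frame(measure = m, p = res$p, direction = res$direction,
                 median_sync = res$median_group1,
                 median_non_sync = res$median_group2,
                 n_sync = res$n1, n_non_sync = res$n2)
    })
    write_result_table(do.call(rbind, cmp),
                       file.path(out_dir, "sync_comparison.tsv"))
    log_stage("centrality", c("centrality.tsv", "sync_comparison.tsv"),
              list(n_sync = length(sp$sync), n_non_sync = length(sp$non_sync)))
  }

  out_files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rbpregulon")),
    r_version = R.version.string,
    config = cfg, config_hash = cfg_hash, seed = cfg$seed,
    inputs = as.list(tools::md5sum(c(unlist(in_files[file.exists(unlist(in_files))]),
                                     peak_files))),
    outputs = as.list(tools::md5sum(file.path(out_dir, out_files))),
    stages = stages
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of a string, via the file-based tools::md5sum
digest_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

# tidy coefficient / p-value / selection summary across model fits
model_summary_table <- function(fits) {
  rows <- lapply(names(fits), function(m) {
    f <- fits[[m]]
    if (is.null(f)) return(NULL)
    feats <- if (!is.null(f$feature_p)) names(f$feature_p) else f$selected
    if (!length(feats)) return(data.frame(
      method = m, feature = NA_character_, p = NA_real_,
      selected = FALSE, stringsAsFactors = FALSE))
    data.frame(method = m, feature = feats,
               p = if (!is.null(f$feature_p)) unname(f$feature_p) else NA_real_,
               selected = feats %in% f$selected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out %||% data.frame()
}
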