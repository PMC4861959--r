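# Feature tables and feature-selection models explaining the observed
# RBP-target co-expression, at two levels:
#  * RBP-centric: one row per RBP, response = median target rho, nine
#    predictors describing the RBP, its binding signal and its annotation.
#  * transcript-centric: one row per RBP-target pair, response = the pair's
#    rho, five predictors describing the binding site and the transcript.

## ---- feature tables -----------------------------------------------------

rbp_feature_cols <- c("n_targets", "median_clip_p", "n_rna_binding_domains",
                      "n_ppi_partners", "n_protein_coding_transcripts",
                      "n_annotated_transcripts", "selected_transcript_length",
                      "median_boundary_distance", "mrna_protein_corr")

transcript_feature_cols <- c("clip_p", "dist_5prime", "dist_3prime",
                             "transcript_length", "transcript_type")

#' RBP-centric feature table
#'
#' One row per classified RBP. The response is the median Spearman rho of
#' the RBP with its targets; the nine predictors are the target count, the
#' median binding p-value of target-supporting peaks ("CLIP signal"), the
#' number of RNA-binding domains, the PPI degree, the counts of
#' protein-coding and of all annotated transcripts of the RBP gene, the
#' length of the representative protein-coding transcript, the median over
#' target-supporting peaks of the distance from the peak start to the
#' closest genomic end of the target transcript, and the Spearman
#' correlation between the RBP's mRNA and protein profiles over shared
#' tissues.
#'
#' RBPs missing a domain-count or PPI entry get 0 for that feature;
#' RBPs without a protein row get `mrna_protein_corr = 0`. These
#' imputations keep the design full-rank and are flagged in the `flags`
#' attribute (data.frame rbp_id, feature) rather than silently NA.
#'
#' @param net an `rbp_network` with peak-level support.
#' @param annotation an `rbp_annotation`.
#' @param classification result of [run_level()] at the level whose response
#'   is wanted.
#' @param expr_rna transcript-level expression matrix.
#' @param expr_protein protein matrix or NULL.
#' @param ppi an edge list ([edge_list()]).
#' @param domain_counts named integer vector rbp_id -> number of RNA-binding
#'   domains.
#' @param rbp_gene named character vector rbp_id -> gene_id (default
#'   identity).
#' @return data.frame with columns `rbp_id`, `response`, and the nine
#'   predictors, `flags` attribute listing imputed cells.
#' @export
rbp_feature_table <- function(net, annotation, classification, expr_rna,
                              expr_protein = NULL, ppi, domain_counts,
                              rbp_gene = NULL) {
  stopifnot(inherits(classification, "rbp_classification"))
  recs <- classification$records
  rbps <- names(recs)
  rbp_gene <- rbp_gene %||% setNames(rbps, rbps)
  tx <- annotation$transcripts
  deg <- table(c(ppi$from, ppi$to))
  flags <- list()
  flag <- function(r, feature) flags[[length(flags) + 1L]] <<-
    data.frame(rbp_id = r, feature = feature, stringsAsFactors = FALSE)
  shared <- if (!is.null(expr_protein)) {
    intersect(colnames(expr_protein), colnames(expr_rna))
  } else character()

  rows <- lapply(rbps, function(r) {
    z <- recs[[r]]
    gene <- unname(rbp_gene[r])
    sup <- net$support[net$support$rbp_id == r, , drop = FALSE]
    n_dom <- domain_counts[r]
    if (is.na(n_dom)) { n_dom <- 0L; flag(r, "n_rna_binding_domains") }
    n_ppi <- deg[r]
    if (is.na(n_ppi)) { n_ppi <- 0L; flag(r, "n_ppi_partners") }
    gene_tx <- tx[tx$gene_id == gene, , drop = FALSE]
    rep_len <- tx$length[match(z$representative_id, tx$transcript_id)]
    # distance from each supporting peak start to the closest genomic end of
    # its target transcript
    m <- match(sup$transcript_id, tx$transcript_id)
    bd <- pmin(abs(sup$peak_start - tx$span_start[m]),
               abs(sup$peak_start - (tx$span_end[m] - 1L)))
    mp_corr <- 0
    if (!is.null(expr_protein) && length(shared) >= 3L) {
      ids_p <- rownames(expr_protein)
      iso <- ids_p[ids_p == gene | startsWith(ids_p, paste0(gene, "."))]
      if (length(iso) && !is.na(z$representative_id) &&
          z$representative_id %in% rownames(expr_rna)) {
        pvec <- apply(expr_protein[iso, shared, drop = FALSE], 2L, max)
        rvec <- expr_rna[z$representative_id, shared]
        mp <- suppressWarnings(cor(rvec, pvec, method = "spearman"))
        if (is.na(mp)) flag(r, "mrna_protein_corr") else mp_corr <- mp
      } else flag(r, "mrna_protein_corr")
    } else flag(r, "mrna_protein_corr")
    data.frame(
      rbp_id = r,
      response = z$median_target_rho,
      n_targets = length(net$targets[[r]] %||% character()),
      median_clip_p = if (nrow(sup)) median(sup$binding_p) else NA_real_,
      n_rna_binding_domains = as.integer(n_dom),
      n_ppi_partners = as.integer(n_ppi),
      n_protein_coding_transcripts = sum(gene_tx$biotype == "protein_coding"),
      n_annotated_transcripts = nrow(gene_tx),
      selected_transcript_length = if (length(rep_len)) rep_len else NA_integer_,
      median_boundary_distance = if (length(bd)) median(bd) else NA_real_,
      mrna_protein_corr = mp_corr,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "flags") <- if (length(flags)) {
    do.call(rbind, c(flags, list(make.row.names = FALSE)))
  } else data.frame(rbp_id = character(), feature = character())
  out
}

#' Transcript-centric feature table
#'
#' One row per RBP-target pair with an expression-backed rho. When several
#' peaks support one pair, the peak with the smallest binding p-value is
#' used (ties broken by genomic start). Distances run from the peak start to
#' the strand-aware transcript ends in genomic space: the 5' end is the
#' genomic span start on the + strand and the last spanned base on the -
#' strand.
#'
#' @param net an `rbp_network` with peak-level support.
#' @param annotation an `rbp_annotation`.
#' @param classification result of [run_level()]; its `rho_long` supplies
#'   the per-pair response.
#' @return data.frame with columns `rbp_id`, `transcript_id`, `response`,
#'   `clip_p`, `dist_5prime`, `dist_3prime`, `transcript_length`,
#'   `transcript_type`; attribute `n_excluded` counts pairs without a rho.
#' @export
transcript_feature_table <- function(net, annotation, classification) {
  stopifnot(inherits(classification, "rbp_classification"))
  rho <- classification$rho_long
  sup <- net$support
  key_s <- paste(sup$rbp_id, sup$transcript_id, sep = "\r")
  key_r <- paste(rho$rbp_id, rho$transcript_id, sep = "\r")
  n_excluded <- length(setdiff(unique(key_s), key_r))
  # best peak per pair: smallest binding p, then smallest start
  ord <- order(key_s, sup$binding_p, sup$peak_start)
  sup <- sup[ord, , drop = FALSE]
  best <- sup[!duplicated(paste(sup$rbp_id, sup$transcript_id, sep = "\r")), ,
              drop = FALSE]
  key_b <- paste(best$rbp_id, best$transcript_id, sep = "\r")
  m <- match(key_r, key_b)
  keep <- !is.na(m)
  rho <- rho[keep, , drop = FALSE]
  best <- best[m[keep], , drop = FALSE]
  tx <- annotation$transcripts
  ti <- match(rho$transcript_id, tx$transcript_id)
  left <- best$peak_start - tx$span_start[ti]
  right <- (tx$span_end[ti] - 1L) - best$peak_start
  plus <- tx$strand[ti] == "+"
  out <- data.frame(
    rbp_id = rho$rbp_id, transcript_id = rho$transcript_id,
    response = rho$rho,
    clip_p = best$binding_p,
    dist_5prime = ifelse(plus, left, right),
    dist_3prime = ifelse(plus, right, left),
    transcript_length = tx$length[ti],
    transcript_type = tx$biotype[ti],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

## ---- model fitting ------------------------------------------------------

# design-matrix helper: expands factors against a reference level and maps
# each column back to its originating feature
build_design <- function(table, response, predictors) {
  stopifnot(response %in% names(table), all(predictors %in% names(table)))
  df <- table[, c(response, predictors), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  for (p in predictors) if (is.character(df[[p]])) df[[p]] <- factor(df[[p]])
  rhs <- if (length(predictors)) {
    paste(sprintf("`%s`", predictors), collapse = " + ")
  } else "1"
  form <- as.formula(paste(response, "~", rhs))
  mm <- model.matrix(form, data = df)
  assign <- attr(mm, "assign")
  feature_of <- c("(Intercept)", predictors)[assign + 1L]
  list(df = df, formula = form, x = mm[, -1L, drop = FALSE],
       y = df[[response]], feature_of = feature_of[-1L])
}

# one p-value per feature from per-coefficient p-values: numeric features
# keep their coefficient p; a categorical feature takes the minimum of its
# BH-adjusted contrast p-values
feature_p_values <- function(coef_p, feature_of) {
  vapply(unique(feature_of), function(f) {
    ps <- coef_p[feature_of == f]
    ps <- ps[!is.na(ps)]
    if (!length(ps)) return(NA_real_)
    if (length(ps) == 1L) ps else min(p.adjust(ps, method = "BH"))
  }, 0)
}

#' Full multivariate linear regression
#'
#' Ordinary least squares of the response on all predictors, with two-sided
#' t-test p-values per coefficient. Categorical predictors are expanded to
#' indicator contrasts against a reference level; the feature-level p of a
#' categorical predictor is the minimum of its BH-adjusted contrast
#' p-values. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param table data.frame of response + predictors.
#' @param response name of the response column.
#' @param predictors names of predictor columns.
#' @param alpha significance threshold defining the `selected` set.
#' @return list of class `rbp_model_fit`: `method`, `coefficients`,
#'   `p_values` (per coefficient), `feature_p` (per feature),
#'   `neg_log10_p` (per feature), `selected`, `n`, `fit` (the `lm` object).
#' @export
fit_multivariate <- function(table, response, predictors, alpha = 0.05) {
  d <- build_design(table, response, predictors)
  if (nrow(d$df) <= ncol(d$x) + 1L) {
    stop(sprintf("need more rows (%d) than coefficients (%d)",
                 nrow(d$df), ncol(d$x) + 1L), call. = FALSE)
  }
  fit <- lm(d$formula, data = d$df)
  if (anyNA(coef(fit))) {
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coef_p <- sm[-1L, "Pr(>|t|)"]
  # a constant response carries no association with any predictor; the
  # t statistics are 0/0 there, so the p-values are pinned at 1
  if (stats::var(d$y) < .Machine$double.eps * max(1, mean(d$y)^2)) {
    coef_p[] <- 1
  }
  fp <- feature_p_values(coef_p, d$feature_of)
  structure(list(
    method = "multivariate",
    coefficients = coef(fit),
    p_values = coef_p,
    feature_p = fp,
    neg_log10_p = -log10(fp),
    selected = names(fp)[!is.na(fp) & fp < alpha],
    n = nrow(d$df), fit = fit
  ), class = "rbp_model_fit")
}

#' Backward stepwise elimination on p-values
#'
#' Starting from the full OLS fit, repeatedly drops the single feature with
#' the largest marginal p-value (single-term F test, which equals the
#' coefficient t-test for one-column features) while that p-value is at or
#' above `alpha_stay`; stops when every remaining feature is below the
#' threshold or none remain. Ties break alphabetically so the path is
#' deterministic and invariant to the predictor column order.
#'
#' @inheritParams fit_multivariate
#' @param alpha_stay p-value a feature must beat to stay in the model.
#' @return an `rbp_model_fit`; `selected` holds the surviving features (may
#'   be empty, in which case the intercept-only fit is returned).
#' @export
fit_stepwise <- function(table, response, predictors, alpha_stay = 0.05) {
  current <- sort(predictors)
  first <- TRUE
  repeat {
    d <- build_design(table, response, current)
    if (first && nrow(d$df) <= ncol(d$x) + 1L) {
      stop(sprintf("need more rows (%d) than coefficients (%d)",
                   nrow(d$df), ncol(d$x) + 1L), call. = FALSE)
    }
    first <- FALSE
    fit <- lm(d$formula, data = d$df)
    if (!length(current)) break
    dr <- drop1(fit, test = "F")
    terms <- rownames(dr)[-1L]
    pvals <- dr[["Pr(>F)"]][-1L]
    # strip backtick quoting applied in the formula
    terms <- gsub("`", "", terms)
    ord <- order(-pvals, terms)
    worst <- ord[1L]
    if (is.na(pvals[worst]) || pvals[worst] >= alpha_stay) {
      if (is.na(pvals[worst])) {
        stop(sprintf("rank-deficient design; collinear term '%s'", terms[worst]),
             call. = FALSE)
      }
      current <- setdiff(current, terms[worst])
    } else break
  }
  if (length(current)) {
    d <- build_design(table, response, current)
    fit <- lm(d$formula, data = d$df)
    sm <- summary(fit)$coefficients
    coef_p <- sm[-1L, "Pr(>|t|)"]
    fp <- feature_p_values(coef_p, d$feature_of)
    cf <- coef(fit)
  } else {
    d <- list(df = table[complete.cases(table[, c(response, predictors)]), ,
                         drop = FALSE])
    fit <- lm(as.formula(paste(response, "~ 1")), data = d$df)
    coef_p <- setNames(numeric(), character())
    fp <- setNames(numeric(), character())
    cf <- coef(fit)
  }
  structure(list(
    method = "stepwise",
    coefficients = cf,
    p_values = coef_p,
    feature_p = fp,
    neg_log10_p = -log10(fp),
    selected = sort(current),
    n = nrow(d$df), fit = fit
  ), class = "rbp_model_fit")
}

#' Elastic-net regression with cross-validated hyperparameters
#'
#' Predictors are standardized to zero mean and unit variance and the
#' response centered before penalization. The mixing parameter `l1_ratio`
#' (glmnet's `alpha`; 0 = ridge, 1 = lasso) and the penalty `lambda` are
#' chosen by k-fold cross-validated mean squared error over the supplied
#' grids, with fold assignment fixed by `seed`. Selected features are those
#' with a nonzero coefficient at the chosen pair. Passing scalar `l1_ratio`
#' and `lambda` skips cross-validation and fits that point exactly.
#'
#' @inheritParams fit_multivariate
#' @param l1_ratio grid of mixing values in `[0, 1]`.
#' @param lambda optional penalty grid; default lets glmnet build its path.
#' @param k_folds folds for cross-validation (reduced with a warning when
#'   there are fewer rows than folds).
#' @param seed integer seed fixing the fold assignment.
#' @return an `rbp_model_fit` with `coefficients` on the standardized scale,
#'   `selected` (nonzero features) and `hyperparameters`
#'   (list `l1_ratio`, `lambda`). Penalized fits carry no p-values.
#' @export
fit_elastic_net <- function(table, response, predictors,
                            l1_ratio = c(0, 0.25, 0.5, 0.75, 1),
                            lambda = NULL, k_folds = 10L, seed = 1L) {
  d <- build_design(table, response, predictors)
  x <- scale(d$x)
  sds <- attr(x, "scaled:scale")
  if (any(sds == 0)) {
    stop(sprintf("constant predictor column(s): %s",
                 paste(colnames(d$x)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  y <- d$y - mean(d$y)
  n <- nrow(x)
  fixed <- length(l1_ratio) == 1L && length(lambda) == 1L
  if (fixed) {
    # pad the path below the requested lambda so glmnet converges cleanly
    lam_seq <- sort(unique(c(lambda, lambda * c(64, 16, 4))), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, alpha = l1_ratio, lambda = lam_seq,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14, maxit = 1e6)
    beta <- suppressWarnings(
      as.numeric(coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                      alpha = l1_ratio, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14,
                      maxit = 1e6))[-1L])
    best <- list(l1_ratio = l1_ratio, lambda = lambda)
  } else {
    if (n < k_folds) {
      warning(sprintf("only %d rows; reducing folds from %d to %d",
                      n, k_folds, max(3L, n)), call. = FALSE)
      k_folds <- max(3L, min(n, k_folds))
    }
    foldid <- withr::with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
    cvs <- lapply(l1_ratio, function(a) {
      glmnet::cv.glmnet(x, y, alpha = a, lambda = lambda, foldid = foldid,
                        standardize = FALSE, intercept = FALSE)
    })
    cvm_min <- vapply(cvs, function(cv) min(cv$cvm), 0)
    bi <- which.min(cvm_min)
    cv <- cvs[[bi]]
    best <- list(l1_ratio = l1_ratio[bi], lambda = cv$lambda.min)
    beta <- as.numeric(coef(cv, s = "lambda.min"))[-1L]
  }
  names(beta) <- colnames(d$x)
  nz_features <- unique(d$feature_of[beta != 0])
  structure(list(
    method = "elastic_net",
    coefficients = beta,
    p_values = NULL,
    feature_p = NULL,
    neg_log10_p = NULL,
    selected = sort(nz_features),
    hyperparameters = best,
    n = n, fit = NULL
  ), class = "rbp_model_fit")
}

## ---- per-RBP transcript-centric models ----------------------------------

#' Fit transcript-centric models per RBP and summarize feature significance
#'
#' For each RBP with at least `p + 2` expression-backed target pairs (p =
#' number of predictors) the multivariate model (and optionally stepwise and
#' elastic net) is fitted on its pairs. Biotype levels observed only once
#' within an RBP are merged into `"other"` before contrasts; if the merged
#' factor is left with a single level the transcript_type feature is dropped
#' for that RBP (its p is NA).
#'
#' @param tft transcript-centric feature table ([transcript_feature_table()]).
#' @param methods subset of `c("multivariate", "stepwise", "elastic_net")`.
#' @param alpha significance threshold for the per-feature fractions.
#' @param seed seed for elastic-net folds.
#' @return list: `fits` (rbp -> method -> `rbp_model_fit`), `neg_log10_p`
#'   (matrix RBP x feature, from the multivariate fits), `fraction_significant`
#'   (named vector: share of fitted RBPs with feature p < alpha),
#'   `skipped` (data.frame rbp_id, reason).
#' @export
per_rbp_transcript_models <- function(tft, methods = "multivariate",
                                      alpha = 0.05, seed = 1L) {
  predictors <- transcript_feature_cols
  rbps <- unique(tft$rbp_id)
  fits <- list()
  skipped <- list()
  pmat <- matrix(NA_real_, nrow = 0L, ncol = length(predictors),
                 dimnames = list(NULL, predictors))
  for (r in rbps) {
    sub <- tft[tft$rbp_id == r, , drop = FALSE]
    # merge singleton biotype levels so contrasts are estimable
    cnt <- table(sub$transcript_type)
    singles <- names(cnt)[cnt < 2L]
    sub$transcript_type[sub$transcript_type %in% singles] <- "other"
    preds <- predictors
    if (length(unique(sub$transcript_type)) < 2L) {
      preds <- setdiff(preds, "transcript_type")
    }
    # drop constant numeric predictors (inestimable for this RBP)
    for (p in setdiff(preds, "transcript_type")) {
      if (length(unique(sub[[p]])) < 2L) preds <- setdiff(preds, p)
    }
    need <- ncol(model.matrix(~ ., sub[, preds, drop = FALSE])) + 1L
    if (nrow(sub) < max(need, length(predictors) + 2L)) {
      skipped[[r]] <- data.frame(rbp_id = r, reason = "too few target pairs",
                                 stringsAsFactors = FALSE)
      next
    }
    fr <- list()
    if ("multivariate" %in% methods) {
      fr$multivariate <- tryCatch(
        fit_multivariate(sub, "response", preds, alpha = alpha),
        error = function(e) NULL)
    }
    if ("stepwise" %in% methods) {
      fr$stepwise <- tryCatch(
        fit_stepwise(sub, "response", preds, alpha_stay = alpha),
        error = function(e) NULL)
    }
    if ("elastic_net" %in% methods) {
      fr$elastic_net <- tryCatch(
        fit_elastic_net(sub, "response", preds, seed = seed),
        error = function(e) NULL)
    }
    if (is.null(fr$multivariate) && "multivariate" %in% methods) {
      skipped[[r]] <- data.frame(rbp_id = r, reason = "model fit failed",
                                 stringsAsFactors = FALSE)
      next
    }
    fits[[r]] <- fr
    row <- setNames(rep(NA_real_, length(predictors)), predictors)
    if (!is.null(fr$multivariate)) {
      fp <- fr$multivariate$feature_p
      row[names(fp)] <- -log10(fp)
    }
    pmat <- rbind(pmat, row)
    rownames(pmat)[nrow(pmat)] <- r
  }
  frac <- vapply(predictors, function(f) {
    col <- pmat[, f]
    if (!nrow(pmat)) return(NA_real_)
    mean(!is.na(col) & col > -log10(alpha))
  }, 0)
  list(fits = fits, neg_log10_p = pmat, fraction_significant = frac,
       skipped = if (length(skipped)) {
         do.call(rbind, c(skipped, list(make.row.names = FALSE)))
       } else data.frame(rbp_id = character(), reason = character()))
}

#' Median response per transcript biotype per RBP
#'
#' @param tft transcript-centric feature table.
#' @return data.frame rbp_id, transcript_type, median_rho, n_pairs.
#' @export
biotype_effect_summary <- function(tft) {
  agg <- stats::aggregate(list(median_rho = tft$response),
                          by = list(rbp_id = tft$rbp_id,
                                    transcript_type = tft$transcript_type),
                          FUN = median)
  cnt <- stats::aggregate(list(n_pairs = tft$response),
                          by = list(rbp_id = tft$rbp_id,
                                    transcript_type = tft$transcript_type),
                          FUN = length)
  out <- merge(agg, cnt, by = c("rbp_id", "transcript_type"))
  out <- out[order(out$rbp_id, out$transcript_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
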