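# SC / SIC / NSC classification of RBPs from tissue co-expression.
#
# For each RBP, Spearman correlations are computed between the RBP's
# expression profile (a representative protein-coding transcript at the
# transcript level; the protein row at the protein level) and every target
# and non-target transcript across tissues. The target rho distribution is
# compared against the control distribution with a two-sample Wilcoxon
# rank-sum test; direction is decided by the medians.

#' Pick the representative protein-coding transcript of a gene
#'
#' The representative is the protein_coding transcript of the gene with the
#' highest mean expression across all tissues; ties break lexicographically
#' by transcript id so the choice is deterministic.
#'
#' @param gene_id gene identifier.
#' @param annotation an `rbp_annotation`.
#' @param expr transcript-level expression matrix.
#' @return a transcript id, or `NA_character_` (with a warning) when the
#'   gene has no protein_coding transcript with an expression row.
#' @export
select_representative <- function(gene_id, annotation, expr) {
  tx <- annotation$transcripts
  cand <- tx$transcript_id[tx$gene_id == gene_id & tx$biotype == "protein_coding"]
  cand <- intersect(cand, rownames(expr))
  if (!length(cand)) {
    warning(sprintf("gene '%s': no protein_coding transcript with expression; unusable at transcript level",
                    gene_id), call. = FALSE)
    return(NA_character_)
  }
  mu <- rowMeans(expr[cand, , drop = FALSE])
  cand <- sort(cand) # lexicographic tie-break
  mu <- mu[cand]
  cand[which.max(mu)]
}

#' Spearman correlation of one profile against each row of a matrix
#'
#' Average ranks are used for ties. Rows with fewer than 3 complete pairs
#' against `x`, or that are constant after pairing, have no defined rank
#' correlation; they are excluded and reported via the `excluded` attribute.
#'
#' @param x numeric vector over tissues.
#' @param Y numeric matrix with `ncol(Y) == length(x)`, rownames required.
#' @return named numeric vector of rho in `[-1, 1]` for usable rows, with
#'   attribute `excluded`: data.frame(id, reason).
#' @export
spearman_profile <- function(x, Y) {
  stopifnot(is.matrix(Y), ncol(Y) == length(x), !is.null(rownames(Y)))
  if (nrow(Y) == 0L) {
    out <- setNames(numeric(), character())
    attr(out, "excluded") <- data.frame(id = character(), reason = character())
    return(out)
  }
  # fast path: no missing values anywhere; rank once per row, then one
  # vectorized Pearson-on-ranks computation
  if (!anyNA(x) && !anyNA(Y) && length(unique(x)) >= 2L && length(x) >= 3L) {
    rx <- rank(x)
    R <- t(apply(Y, 1L, rank))
    const <- apply(R, 1L, function(z) all(z == z[1L]))
    rxc <- rx - mean(rx)
    Rc <- R - rowMeans(R)
    num <- as.numeric(Rc %*% rxc)
    den <- sqrt(rowSums(Rc^2) * sum(rxc^2))
    rho <- ifelse(const, NA_real_, num / den)
    usable <- !const
    out <- setNames(rho[usable], rownames(Y)[usable])
    attr(out, "excluded") <- data.frame(
      id = rownames(Y)[!usable],
      reason = rep("constant profile", sum(!usable)),
      stringsAsFactors = FALSE)
    return(out)
  }
  ok_x <- !is.na(x)
  rho <- rep(NA_real_, nrow(Y))
  reason <- rep(NA_character_, nrow(Y))
  for (i in seq_len(nrow(Y))) {
    yi <- Y[i, ]
    keep <- ok_x & !is.na(yi)
    if (sum(keep) < 3L) {
      reason[i] <- "fewer than 3 paired tissues"
      next
    }
    xv <- x[keep]; yv <- yi[keep]
    if (length(unique(yv)) < 2L || length(unique(xv)) < 2L) {
      reason[i] <- "constant profile"
      next
    }
    rho[i] <- cor(rank(xv), rank(yv), method = "pearson")
  }
  usable <- is.na(reason)
  out <- setNames(rho[usable], rownames(Y)[usable])
  attr(out, "excluded") <- data.frame(id = rownames(Y)[!usable],
                                      reason = reason[!usable],
                                      stringsAsFactors = FALSE)
  out
}

#' Partition expressed transcripts into target / control sets for one RBP
#'
#' Targets are the RBP's network targets restricted to rows of the
#' expression matrix; `control_all` is every other expressed transcript.
#' `n_reps` matched control samples of size `|targets|` are drawn from
#' `control_all` without replacement, using a random stream derived
#' deterministically from `(seed, rbp_id)`.
#'
#' @param rbp_id RBP identifier.
#' @param net an `rbp_network`.
#' @param expr expression matrix whose rows define "expressed".
#' @param n_reps number of matched control samples (default 100).
#' @param seed master integer seed.
#' @param exclude_ids ids removed from both targets and controls (e.g. the
#'   RBP's own representative transcript).
#' @return list of class `rbp_partition`: `rbp_id`, `targets`,
#'   `control_all`, `control_matched` (list of `n_reps` character vectors).
#' @export
partition <- function(rbp_id, net, expr, n_reps = 100L, seed = 1L,
                      exclude_ids = character()) {
  expressed <- setdiff(rownames(expr), exclude_ids)
  targets <- intersect(net$targets[[rbp_id]] %||% character(), expressed)
  control_all <- setdiff(expressed, targets)
  if (length(control_all) < length(targets)) {
    stop(sprintf("RBP '%s': control pool (%d) smaller than target set (%d); matched sampling impossible",
                 rbp_id, length(control_all), length(targets)), call. = FALSE)
  }
  matched <- withr::with_seed(derive_seed(seed, rbp_id), {
    lapply(seq_len(n_reps), function(i) {
      sample(control_all, length(targets), replace = FALSE)
    })
  })
  structure(list(rbp_id = rbp_id, targets = targets,
                 control_all = control_all, control_matched = matched),
            class = "rbp_partition")
}

#' Classify one target-vs-control comparison as SC, SIC or NSC
#'
#' Two-sided two-sample Wilcoxon rank-sum (Mann-Whitney) test with normal
#' approximation and tie correction. The compared vectors are unpaired and
#' typically of unequal length, so the rank-sum (not signed-rank) variant is
#' the applicable one. Label is SC when `p < alpha` and the target median
#' rho exceeds the control median, SIC when it is lower, NSC otherwise.
#'
#' @param rho_targets,rho_controls numeric vectors of Spearman rho.
#' @param alpha significance threshold (default 0.05).
#' @return list: `p`, `label`, `median_targets`, `median_controls`,
#'   `insufficient_data` flag.
#' @export
classify <- function(rho_targets, rho_controls, alpha = 0.05) {
  rho_targets <- rho_targets[!is.na(rho_targets)]
  rho_controls <- rho_controls[!is.na(rho_controls)]
  if (length(rho_targets) < 2L || length(rho_controls) < 2L) {
    return(list(p = NA_real_, label = "NSC",
                median_targets = median(rho_targets),
                median_controls = median(rho_controls),
                insufficient_data = TRUE))
  }
  p <- suppressWarnings(
    wilcox.test(rho_targets, rho_controls, alternative = "two.sided",
                exact = FALSE, correct = TRUE)$p.value
  )
  mt <- median(rho_targets); mc <- median(rho_controls)
  label <- if (!is.na(p) && p < alpha) {
    if (mt > mc) "SC" else if (mt < mc) "SIC" else "NSC"
  } else "NSC"
  list(p = p, label = label, median_targets = mt, median_controls = mc,
       insufficient_data = FALSE)
}

#' Run the SC/SIC/NSC classification for a cohort of RBPs at one level
#'
#' At the transcript level the RBP profile is the expression of its
#' representative protein-coding transcript. At the protein level the RBP
#' profile is its gene's row in the protein matrix (per-tissue maximum when
#' several isoform rows exist); target and control profiles come from the
#' RNA matrix restricted to the tissues shared by both matrices. RBPs
#' without a protein row are skipped and reported.
#'
#' The final label is taken against `control_all`; the `n_reps`
#' matched-control p-values are summarized by their median and the fraction
#' of matched comparisons agreeing with the final label is reported.
#'
#' @param rbps character vector of RBP ids.
#' @param net an `rbp_network`.
#' @param annotation an `rbp_annotation`.
#' @param expr_rna transcript-level expression matrix.
#' @param expr_protein protein-level expression matrix (gene x tissue), only
#'   for `level = "protein"`.
#' @param level `"transcript"` or `"protein"`.
#' @param rbp_gene named character vector rbp_id -> gene_id; defaults to the
#'   identity (RBP ids are gene ids).
#' @param alpha significance threshold.
#' @param n_reps matched-control resamples.
#' @param seed master seed for the matched sampling.
#' @return list of class `rbp_classification`: `records` (one per usable
#'   RBP), `table` (tidy per-RBP summary with BH-adjusted p column),
#'   `rho_long` (per RBP-target pair rho, for downstream modelling),
#'   `skipped` (data.frame id, reason), `level`, `alpha`.
#' @export
run_level <- function(rbps, net, annotation, expr_rna, expr_protein = NULL,
                      level = c("transcript", "protein"),
                      rbp_gene = NULL, alpha = 0.05, n_reps = 100L, seed = 1L) {
  level <- match.arg(level)
  rbp_gene <- rbp_gene %||% setNames(rbps, rbps)
  if (level == "protein") {
    if (is.null(expr_protein)) stop("protein level requires 'expr_protein'",
                                    call. = FALSE)
    shared <- intersect(colnames(expr_protein), colnames(expr_rna))
    if (length(shared) < 3L) {
      stop(sprintf("only %d tissue(s) shared between RNA and protein matrices; need >= 3",
                   length(shared)), call. = FALSE)
    }
    rna <- expr_rna[, shared, drop = FALSE]
  } else {
    rna <- expr_rna
  }
  records <- list()
  skipped <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  rho_long <- list()
  for (r in rbps) {
    gene <- unname(rbp_gene[r])
    if (level == "transcript") {
      rep_id <- suppressWarnings(select_representative(gene, annotation, rna))
      if (is.na(rep_id)) {
        skipped <- rbind(skipped, data.frame(
          id = r, reason = "no expressed protein_coding transcript"))
        next
      }
      x <- rna[rep_id, ]
      exclude <- rep_id
    } else {
      tx <- annotation$transcripts
      ids_p <- rownames(expr_protein)
      iso <- ids_p[ids_p == gene | startsWith(ids_p, paste0(gene, "."))]
      if (!length(iso)) {
        skipped <- rbind(skipped, data.frame(
          id = r, reason = "no protein expression row"))
        next
      }
      prot <- expr_protein[iso, shared, drop = FALSE]
      x <- apply(prot, 2L, max) # isoform rows collapsed by per-tissue max
      rep_id <- gene
      exclude <- tx$transcript_id[tx$gene_id == gene]
    }
    part <- partition(r, net, rna, n_reps = n_reps, seed = seed,
                      exclude_ids = exclude)
    rho_t <- spearman_profile(x, rna[part$targets, , drop = FALSE])
    rho_c <- spearman_profile(x, rna[part$control_all, , drop = FALSE])
    res_all <- classify(rho_t, rho_c, alpha)
    matched <- lapply(part$control_matched, function(ids) {
      classify(rho_t, rho_c[intersect(ids, names(rho_c))], alpha)
    })
    p_matched <- vapply(matched, `[[`, 0, "p")
    lab_matched <- vapply(matched, `[[`, "", "label")
    records[[r]] <- list(
      rbp_id = r, level = level, representative_id = rep_id,
      rho_targets = rho_t, rho_control_all = rho_c,
      p_vs_all = res_all$p, p_vs_matched = p_matched,
      p_matched_summary = median(p_matched, na.rm = TRUE),
      matched_agreement = mean(lab_matched == res_all$label, na.rm = TRUE),
      label = res_all$label,
      median_target_rho = res_all$median_targets,
      median_control_rho = res_all$median_controls,
      insufficient_data = res_all$insufficient_data, alpha = alpha
    )
    if (length(rho_t)) {
      rho_long[[r]] <- data.frame(rbp_id = r, transcript_id = names(rho_t),
                                  rho = unname(rho_t), stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(records)) {
    d <- do.call(rbind, lapply(records, function(z) data.frame(
      rbp_id = z$rbp_id, level = z$level,
      representative_id = z$representative_id,
      n_targets = length(z$rho_targets),
      median_target_rho = z$median_target_rho,
      median_control_rho = z$median_control_rho,
      p_vs_all = z$p_vs_all, p_matched_summary = z$p_matched_summary,
      matched_agreement = z$matched_agreement,
      label = z$label, stringsAsFactors = FALSE)))
    d$p_adj_bh <- p.adjust(d$p_vs_all, method = "BH")
    rownames(d) <- NULL
    d
  } else {
    data.frame()
  }
  structure(list(records = records, table = tab,
                 rho_long = if (length(rho_long)) {
                   do.call(rbind, c(rho_long, list(make.row.names = FALSE)))
                 } else data.frame(),
                 skipped = skipped, level = level, alpha = alpha),
            class = "rbp_classification")
}

#' Class percentages from SC/SIC/NSC counts
#'
#' Turns raw class counts into the percentages used to summarize a cohort:
#' the share of each class and the share of RBPs with any significant
#' association (SC + SIC).
#'
#' @param sc,sic,nsc non-negative integer counts.
#' @return list: `n`, `pct_sc`, `pct_sic`, `pct_nsc`, `pct_significant`.
#' @export
class_percentages <- function(sc, sic, nsc) {
  n <- sc + sic + nsc
  stopifnot(n > 0)
  list(n = n,
       pct_sc = 100 * sc / n,
       pct_sic = 100 * sic / n,
       pct_nsc = 100 * nsc / n,
       pct_significant = 100 * (sc + sic) / n)
}
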