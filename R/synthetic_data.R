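# Synthetic fixtures with planted structure.
#
# Emulates the shape of the real inputs (exon-structured annotation, CLIP
# peak files, transcript x tissue TPM matrix, gene x tissue protein matrix,
# PPI edge list, RNA-binding-domain counts) with the facts recorded in a
# truth object so every pipeline stage can be verified against construction:
# which transcripts are targets of which RBP, which SC/SIC/NSC label was
# planted at each level, and which RBPs sit in the dense PPI core.
#
# Correlation is planted on a latent Gaussian scale via the rank (copula)
# coupling: the Pearson coefficient used on the latent scale is
# 2*sin(pi*rho_s/6), so the population Spearman correlation equals the
# requested effect_rho; the monotone exp() map to TPM-like values leaves
# Spearman untouched.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the emulated study conditions: 60 RBPs profiled across
#' 16 tissues at the transcript level and 9 of those tissues at the protein
#' level, 50-80 planted targets per RBP, a planted rank correlation of 0.7
#' for significant classes, and RNA/protein label assignments that yield 12
#' "sync" RBPs (6 SC/SC and 6 SIC/SIC).
#'
#' @param seed master integer seed; every generator op derives its own
#'   stream from it.
#' @param n_rbps number of RBPs.
#' @param n_transcripts number of non-RBP transcripts (targets are drawn
#'   from these; the rest form the control pool).
#' @param n_tissues_rna,n_tissues_protein tissue counts; protein tissues are
#'   the first `n_tissues_protein` RNA tissues.
#' @param effect_rho planted |Spearman| for SC/SIC classes, in (0, 1).
#' @param targets_per_rbp integer range (min, max) of planted targets.
#' @param peaks_per_target integer range of supporting peaks per planted
#'   pair.
#' @param n_decoy_peaks decoy peaks per RBP, placed > 2*flank away from
#'   every exon boundary.
#' @param flank window half-width the peaks are planted against.
#' @param n_sync number of planted sync RBPs per direction (6 means 6 SC/SC
#'   plus 6 SIC/SIC).
#' @param biotype_distribution named probabilities for non-RBP transcript
#'   biotypes.
#' @param n_other_proteins non-RBP nodes in the synthetic PPI graph.
#' @param plant_ppi_core plant a dense core that sync RBPs attach to, so
#'   their closeness is elevated by construction.
#' @param label_mix_rna named proportions of SC/SIC/NSC at the RNA level.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_rbps = 60L, n_transcripts = 5000L,
                         n_tissues_rna = 16L, n_tissues_protein = 9L,
                         effect_rho = 0.7, targets_per_rbp = c(50L, 80L),
                         peaks_per_target = c(1L, 3L), n_decoy_peaks = 20L,
                         flank = 300L, n_sync = 6L,
                         biotype_distribution = c(protein_coding = 0.55,
                                                  processed_transcript = 0.2,
                                                  lincRNA = 0.15, miRNA = 0.1),
                         n_other_proteins = 200L, plant_ppi_core = TRUE,
                         label_mix_rna = c(SC = 1/3, SIC = 1/3, NSC = 1/3)) {
  stopifnot(effect_rho > 0, effect_rho < 1,
            n_tissues_protein <= n_tissues_rna, n_tissues_protein >= 3L,
            length(targets_per_rbp) == 2L,
            targets_per_rbp[1] <= targets_per_rbp[2])
  if (n_rbps * targets_per_rbp[2] > n_transcripts) {
    stop("n_transcripts too small for the requested targets_per_rbp range",
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_rbps = as.integer(n_rbps),
    n_transcripts = as.integer(n_transcripts),
    n_tissues_rna = as.integer(n_tissues_rna),
    n_tissues_protein = as.integer(n_tissues_protein),
    effect_rho = effect_rho,
    targets_per_rbp = as.integer(targets_per_rbp),
    peaks_per_target = as.integer(peaks_per_target),
    n_decoy_peaks = as.integer(n_decoy_peaks),
    flank = as.integer(flank), n_sync = as.integer(n_sync),
    biotype_distribution = biotype_distribution / sum(biotype_distribution),
    n_other_proteins = as.integer(n_other_proteins),
    plant_ppi_core = isTRUE(plant_ppi_core),
    label_mix_rna = label_mix_rna / sum(label_mix_rna)
  ), class = "synth_config")
}

# planted label assignment: RNA labels follow label_mix_rna in blocks;
# protein labels keep the first n_sync SC and n_sync SIC RBPs in sync and
# flip the direction of the remaining significant RBPs
plant_labels <- function(cfg) {
  n <- cfg$n_rbps
  counts <- diff(round(cumsum(c(0, cfg$label_mix_rna)) * n))
  label_rna <- rep(names(cfg$label_mix_rna), counts)
  length(label_rna) <- n
  label_rna[is.na(label_rna)] <- "NSC"
  label_protein <- label_rna
  is_sc <- which(label_rna == "SC"); is_sic <- which(label_rna == "SIC")
  flip_sc <- is_sc[-seq_len(min(cfg$n_sync, length(is_sc)))]
  flip_sic <- is_sic[-seq_len(min(cfg$n_sync, length(is_sic)))]
  label_protein[flip_sc] <- "SIC"
  label_protein[flip_sic] <- "SC"
  data.frame(
    rbp_id = sprintf("RBP%02d", seq_len(n)),
    gene_id = sprintf("RBP%02d", seq_len(n)),
    label_rna = label_rna, label_protein = label_protein,
    sync = label_rna == label_protein & label_rna != "NSC",
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic transcript annotation
#'
#' Lays genes on four chromosomes as non-overlapping loci separated by gaps
#' of at least 3 kb (comfortably more than twice the default flank, so peaks
#' planted at one locus can never reach another locus's windows). Each RBP
#' gene gets 1-3 transcripts, always including a protein-coding one; every
#' non-RBP gene carries one transcript with 1-10 exons and a biotype drawn
#' from `biotype_distribution` (miRNA transcripts are single-exon).
#'
#' @param cfg a `synth_config`.
#' @return list: `annotation` (an `rbp_annotation`), `truth` (list with
#'   `rbps` label table, `rbp_representative` planted carrier transcript per
#'   RBP, `target_candidates` non-RBP transcript ids).
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$seed, "annotation"), {
    rbps <- plant_labels(cfg)
    chroms <- paste0("chr", 1:4)
    tx_rows <- list(); ex_rows <- list()
    cursor <- setNames(rep(1000L, length(chroms)), chroms)
    add_transcript <- function(tx_id, gene_id, biotype, chrom, strand,
                               n_exons) {
      exon_len <- sample(100:500, n_exons, replace = TRUE)
      intron_len <- if (n_exons > 1L) sample(800:2000, n_exons - 1L,
                                             replace = TRUE) else integer()
      s <- cursor[[chrom]]
      starts <- s + cumsum(c(0L, exon_len[-n_exons] + intron_len))
      ends <- starts + exon_len
      cursor[[chrom]] <<- max(ends) + sample(3000:5000, 1L)
      tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
        transcript_id = tx_id, gene_id = gene_id, biotype = biotype,
        chrom = chrom, strand = strand, stringsAsFactors = FALSE)
      ex_rows[[length(ex_rows) + 1L]] <<- data.frame(
        transcript_id = tx_id, start = as.integer(starts),
        end = as.integer(ends), stringsAsFactors = FALSE)
    }
    rep_tx <- character(nrow(rbps))
    for (i in seq_len(nrow(rbps))) {
      chrom <- sample(chroms, 1L)
      n_iso <- sample(1:3, 1L)
      for (j in seq_len(n_iso)) {
        bt <- if (j == 1L) "protein_coding" else
          sample(c("protein_coding", "processed_transcript"), 1L)
        add_transcript(sprintf("%s.t%d", rbps$gene_id[i], j), rbps$gene_id[i],
                       bt, chrom, sample(c("+", "-"), 1L), sample(2:8, 1L))
      }
      rep_tx[i] <- sprintf("%s.t1", rbps$gene_id[i])
    }
    bts <- sample(names(cfg$biotype_distribution), cfg$n_transcripts,
                  replace = TRUE, prob = cfg$biotype_distribution)
    for (i in seq_len(cfg$n_transcripts)) {
      n_ex <- if (bts[i] == "miRNA") 1L else sample(1:10, 1L)
      add_transcript(sprintf("T%06d", i), sprintf("G%06d", i), bts[i],
                     sample(chroms, 1L), sample(c("+", "-"), 1L), n_ex)
    }
    ann <- annotation_table(do.call(rbind, tx_rows), do.call(rbind, ex_rows))
    list(annotation = ann,
         truth = list(rbps = rbps,
                      rbp_representative = setNames(rep_tx, rbps$rbp_id),
                      target_candidates = sprintf("T%06d",
                                                  seq_len(cfg$n_transcripts))))
  })
}

#' Generate synthetic CLIP peaks
#'
#' Draws each RBP's planted target set (disjoint across RBPs so every
#' planted correlation is unambiguous), places 1-3 supporting peaks per
#' planted pair inside a randomly chosen boundary window of the target, and
#' adds decoy peaks in inter-locus gaps, more than `2 * flank` away from
#' every exon boundary. Binding p-values are drawn log-uniformly from
#' [1e-10, 0.05].
#'
#' @param cfg a `synth_config`.
#' @param annotation the annotation from [generate_annotation()].
#' @param truth its truth list; extended with `targets` (named list) on
#'   return.
#' @return list: `peaks` (a peak table), `truth` (with planted `targets`).
#' @export
generate_peaks <- function(cfg, annotation, truth) {
  withr::with_seed(derive_seed(cfg$seed, "peaks"), {
    rbps <- truth$rbps$rbp_id
    pool <- truth$target_candidates
    k <- sample_range(cfg$targets_per_rbp, length(rbps))
    if (sum(k) > length(pool)) {
      stop("target candidate pool exhausted; increase n_transcripts",
           call. = FALSE)
    }
    picks <- if (sum(k)) sample(pool, sum(k)) else character()
    targets <- split(picks, factor(rep(seq_along(rbps), k),
                                   levels = seq_along(rbps)))
    names(targets) <- rbps
    targets <- lapply(targets, function(x) sort(as.character(x)))
    ex <- annotation$exons
    tx <- annotation$transcripts
    # inter-locus gap midpoints per chromosome, for decoys
    gap_mid <- do.call(rbind, lapply(split(tx, tx$chrom), function(d) {
      sp <- d[order(d$span_start), c("span_start", "span_end")]
      lo <- c(head(sp$span_end, -1L))
      hi <- c(sp$span_start[-1L])
      ok <- hi - lo > 4L * cfg$flank + 200L
      data.frame(chrom = d$chrom[1L], mid = as.integer((lo[ok] + hi[ok]) / 2),
                 stringsAsFactors = FALSE)
    }))
    rows <- list()
    for (r in rbps) {
      for (t in targets[[r]]) {
        exs <- ex[ex$transcript_id == t, , drop = FALSE]
        n_pk <- sample_range(cfg$peaks_per_target, 1L)
        for (j in seq_len(n_pk)) {
          ei <- sample(nrow(exs), 1L)
          boundary <- if (runif(1) < 0.5) exs$start[ei] else exs$end[ei] - 1L
          w <- sample(20:60, 1L)
          s <- max(0L, boundary - cfg$flank +
                     sample.int(2L * cfg$flank - w, 1L) - 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            rbp_id = r, chrom = tx$chrom[match(t, tx$transcript_id)],
            start = s, end = s + w,
            strand = tx$strand[match(t, tx$transcript_id)],
            binding_p = 10^runif(1, -10, log10(0.05)),
            stringsAsFactors = FALSE)
        }
      }
      if (cfg$n_decoy_peaks > 0L && nrow(gap_mid)) {
        gi <- sample(nrow(gap_mid), cfg$n_decoy_peaks, replace = TRUE)
        w <- sample(20:60, cfg$n_decoy_peaks, replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          rbp_id = r, chrom = gap_mid$chrom[gi],
          start = gap_mid$mid[gi] - as.integer(w / 2),
          end = gap_mid$mid[gi] - as.integer(w / 2) + w,
          strand = ".",
          binding_p = 10^runif(cfg$n_decoy_peaks, -10, log10(0.05)),
          stringsAsFactors = FALSE)
      }
    }
    pk <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    truth$targets <- targets
    list(peaks = peak_table(pk$rbp_id, pk$chrom, pk$start, pk$end, pk$strand,
                            pk$binding_p),
         truth = truth)
  })
}

#' Generate synthetic expression with planted rank correlation
#'
#' Each RBP gets a latent Gaussian RNA profile `r` over the tissues; its
#' planted targets share a common factor `g` which equals `+r` for SC RBPs,
#' `-r` for SIC RBPs, and an independent profile for NSC RBPs. Each target
#' is coupled to `g` with latent Pearson `2*sin(pi*effect_rho/6)` so its
#' population Spearman against the RBP profile is `+/- effect_rho` (0 for
#' NSC and for all non-targets). The protein profile of each RBP is coupled
#' to `g` over the first `n_tissues_protein` tissues with the sign of the
#' planted protein label, so protein-level labels can differ from RNA-level
#' ones. All values are mapped through `exp()` to positive TPM-like units;
#' the planted RBP representative transcript gets a +2 latent mean shift so
#' it is the gene's highest-expressed protein-coding isoform.
#'
#' @param cfg a `synth_config`.
#' @param annotation annotation from [generate_annotation()].
#' @param truth truth list after [generate_peaks()] (needs `targets`).
#' @return list: `expr_rna` (transcript x tissue), `expr_protein`
#'   (RBP gene x tissue).
#' @export
generate_expression <- function(cfg, annotation, truth) {
  withr::with_seed(derive_seed(cfg$seed, "expression"), {
    tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues_rna))
    prot_tissues <- tissues[seq_len(cfg$n_tissues_protein)]
    rho_lat <- 2 * sin(pi * cfg$effect_rho / 6)
    tx_ids <- annotation$transcripts$transcript_id
    nt <- cfg$n_tissues_rna
    lat <- matrix(rnorm(length(tx_ids) * nt), nrow = length(tx_ids),
                  dimnames = list(tx_ids, tissues))
    prot <- matrix(NA_real_, nrow = nrow(truth$rbps),
                   ncol = cfg$n_tissues_protein,
                   dimnames = list(truth$rbps$gene_id, prot_tissues))
    sign_of <- c(SC = 1, SIC = -1, NSC = 0)
    for (i in seq_len(nrow(truth$rbps))) {
      r_id <- truth$rbps$rbp_id[i]
      rep_tx <- truth$rbp_representative[[r_id]]
      r <- rnorm(nt)
      lat[rep_tx, ] <- r + 2 # mean shift marks the representative isoform
      s_t <- sign_of[[truth$rbps$label_rna[i]]]
      s_p <- sign_of[[truth$rbps$label_protein[i]]]
      # a factor shared by the targets exists only when some level carries a
      # planted signal; doubly-NSC RBPs get mutually independent targets so
      # their correlations with the RBP are a clean null (a shared factor
      # would shift all target rhos by its chance correlation with the RBP)
      g <- if (s_t != 0) s_t * r else if (s_p != 0) rnorm(nt) else NULL
      for (t in truth$targets[[r_id]]) {
        lat[t, ] <- if (is.null(g)) rnorm(nt) else {
          rho_lat * g + sqrt(1 - rho_lat^2) * rnorm(nt)
        }
      }
      g9 <- if (is.null(g)) NULL else g[seq_len(cfg$n_tissues_protein)]
      p <- if (s_p != 0) {
        s_p * (rho_lat * g9 +
                 sqrt(1 - rho_lat^2) * rnorm(cfg$n_tissues_protein))
      } else rnorm(cfg$n_tissues_protein)
      prot[truth$rbps$gene_id[i], ] <- p
    }
    list(expr_rna = expression_matrix(exp(1 + lat), "transcript"),
         expr_protein = expression_matrix(exp(1 + prot), "protein"))
  })
}

#' Generate a synthetic protein-interaction network
#'
#' Builds a connected random graph over all RBP genes plus
#' `n_other_proteins` background proteins (a random spanning tree plus
#' random extra edges). With `plant_ppi_core = TRUE` a dense core of hub
#' proteins is added, fully connected internally, and every sync RBP is
#' wired to all hubs while non-sync RBPs keep only their sparse background
#' attachment - elevating the closeness of sync RBPs by construction.
#'
#' @param cfg a `synth_config`.
#' @param truth truth list (needs `rbps` with the `sync` column).
#' @return list: `ppi` (an edge list), `truth` (with `ppi_core` node ids).
#' @export
generate_ppi <- function(cfg, truth) {
  withr::with_seed(derive_seed(cfg$seed, "ppi"), {
    others <- sprintf("P%04d", seq_len(cfg$n_other_proteins))
    nodes <- c(truth$rbps$gene_id, others)
    n <- length(nodes)
    # random spanning tree keeps everything in one component
    perm <- sample(nodes)
    from <- perm[vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L)]
    to <- perm[2:n]
    extra <- matrix(sample(nodes, 2L * n, replace = TRUE), ncol = 2L)
    extra <- extra[extra[, 1L] != extra[, 2L], , drop = FALSE]
    ef <- c(from, extra[, 1L]); et <- c(to, extra[, 2L])
    core <- character()
    if (cfg$plant_ppi_core) {
      core <- sample(others, 8L)
      cc <- t(utils::combn(core, 2L))
      sync_genes <- truth$rbps$gene_id[truth$rbps$sync]
      ef <- c(ef, cc[, 1L], rep(sync_genes, each = length(core)))
      et <- c(et, cc[, 2L], rep(core, times = length(sync_genes)))
    }
    truth$ppi_core <- core
    list(ppi = suppressWarnings(edge_list(ef, et)), truth = truth)
  })
}

#' Generate RNA-binding-domain counts per RBP
#'
#' @param cfg a `synth_config`.
#' @param truth truth list.
#' @return named integer vector rbp_id -> domain count (1-14).
#' @export
generate_domain_counts <- function(cfg, truth) {
  withr::with_seed(derive_seed(cfg$seed, "domains"), {
    setNames(sample(1:14, nrow(truth$rbps), replace = TRUE),
             truth$rbps$rbp_id)
  })
}

#' Generate the complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_annotation()], [generate_peaks()],
#' [generate_expression()], [generate_ppi()] and [generate_domain_counts()].
#'
#' @param cfg a `synth_config`.
#' @return list of class `synth_dataset`: `cfg`, `annotation`, `peaks`,
#'   `expr_rna`, `expr_protein`, `ppi`, `domain_counts`, `truth`,
#'   `rbp_gene` (identity map rbp_id -> gene_id).
#' @export
generate_dataset <- function(cfg = synth_config()) {
  a <- generate_annotation(cfg)
  p <- generate_peaks(cfg, a$annotation, a$truth)
  e <- generate_expression(cfg, a$annotation, p$truth)
  g <- generate_ppi(cfg, p$truth)
  dc <- generate_domain_counts(cfg, g$truth)
  structure(list(
    cfg = cfg, annotation = a$annotation, peaks = p$peaks,
    expr_rna = e$expr_rna, expr_protein = e$expr_protein,
    ppi = g$ppi, domain_counts = dc, truth = g$truth,
    rbp_gene = setNames(g$truth$rbps$gene_id, g$truth$rbps$rbp_id)
  ), class = "synth_dataset")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits a GTF (1-based inclusive coordinates), one BED6 peak file per RBP
#' (raw binding p in column 5), the two expression TSVs, the PPI edge list,
#' the domain-count TSV and the truth tables. Output is byte-deterministic
#' for a given dataset.
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named character vector of written paths.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "annotation.gtf"))
  tx <- ds$annotation$transcripts
  ex <- ds$annotation$exons
  m <- match(ex$transcript_id, tx$transcript_id)
  attr_str <- sprintf(
    'gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    tx$gene_id[m], ex$transcript_id, tx$biotype[m])
  gtf <- sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
                 tx$chrom[m], ex$start + 1L, ex$end, tx$strand[m], attr_str)
  writeLines(gtf, paths[["annotation"]])
  for (r in unique(ds$peaks$rbp_id)) {
    pk <- ds$peaks[ds$peaks$rbp_id == r, , drop = FALSE]
    path <- file.path(dir, "peaks", paste0(r, ".bed"))
    writeLines(sprintf("%s\t%d\t%d\t%s_pk%d\t%.8g\t%s", pk$chrom, pk$start,
                       pk$end, r, seq_len(nrow(pk)), pk$binding_p, pk$strand),
               path)
    paths[[paste0("peaks_", r)]] <- path
  }
  paths[["expr_rna"]] <- write_expression(ds$expr_rna,
                                          file.path(dir, "expression_rna.tsv"))
  paths[["expr_protein"]] <- write_expression(
    ds$expr_protein, file.path(dir, "expression_protein.tsv"))
  paths[["ppi"]] <- write_edge_list(ds$ppi, file.path(dir, "ppi.tsv"))
  paths[["domains"]] <- write_result_table(
    data.frame(rbp_id = names(ds$domain_counts),
               n_rna_binding_domains = unname(ds$domain_counts)),
    file.path(dir, "domain_counts.tsv"))
  paths[["truth_rbps"]] <- write_result_table(ds$truth$rbps,
                                              file.path(dir, "truth_rbps.tsv"))
  tgt <- data.frame(
    rbp_id = rep(names(ds$truth$targets),
                 vapply(ds$truth$targets, length, 0L)),
    transcript_id = unlist(ds$truth$targets, use.names = FALSE))
  paths[["truth_targets"]] <- write_result_table(
    tgt, file.path(dir, "truth_targets.tsv"))
  invisible(paths)
}
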