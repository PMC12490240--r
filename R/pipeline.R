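# End-to-end composition of the analysis stages on one cohort, plus
# recovery evaluation against the planted ground truth.

#' Default ligand-receptor pair panel
#'
#' A small curated panel of immune costimulation/coinhibition pairs
#' relevant to lymphoma-microenvironment crosstalk; subunits of a complex
#' are joined by `+`.
#'
#' @return data.frame with `pair`, `ligand`, `receptor`, `annotation`.
#' @export
default_lr_pairs <- function() {
  data.frame(
    pair = c("CD70_CD27"),
    ligand = c("CD70"),
    receptor = c("CD27"),
    annotation = c("costimulation"),
    stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates a cohort from `config`, then runs malignant-cell
#' identification (QC, clustering, typing, BCR, expression CNV,
#' classification), CNV segment detection and WGS concordance,
#' between-sample similarity of malignant subcluster composition,
#' per-sample consensus NMF programs with meta-program construction,
#' ligand-receptor permutation tests, the somatic-variant filter cascade,
#' CCF clustering and clone-tree enumeration with fishplot export.
#'
#' @param config a [sim_config()].
#' @param seed analysis seed (the cohort uses `config$seed`).
#' @param outdir optional output directory for result tables.
#' @param nmf_k_range,nmf_restarts,nmf_genes consensus-NMF scale for the
#'   per-sample program search.
#' @param n_perm permutations for the ligand-receptor tests.
#' @return list of class `mcl_pipeline` with components `cohort`,
#'   `malignant`, `cnv_segments`, `wgs_concordance`, `similarity`,
#'   `programs`, `meta_programs`, `interactions`, `variants`, `clones`,
#'   `trees`, `fishplot`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, outdir = NULL,
                         nmf_k_range = 2:5, nmf_restarts = 8,
                         nmf_genes = 200, n_perm = 1000) {
  cohort <- generate_cohort(config)
  mal <- identify_malignant(cohort$expression$matrix,
                            cohort$bcr$rearrangements, seed = seed)
  labels <- mal$cell_labels
  is_mal <- labels$label == "malignant"

  # expression-inferred CNV segments of the malignant compartment,
  # checked against the bulk WGS segment table
  segs <- detect_cnv_segments(mal$cnv_profile, cells = which(is_mal))
  conc <- concordance_with_wgs(mal$cnv_profile,
                               cohort$variants$wgs_segments,
                               cells = which(is_mal))

  # similarity between samples over malignant subclusters
  sim <- NULL
  if (sum(is_mal) > 10 && length(unique(labels$sample[is_mal])) > 1) {
    sim <- similarity_matrix(labels$b_subcluster[is_mal],
                             labels$sample[is_mal])
  }

  # per-sample consensus NMF on malignant cells over the most variable
  # genes
  programs <- list(); prog_sets <- list()
  norm <- mal$norm
  for (s in unique(labels$sample)) {
    idx <- which(is_mal & labels$sample == s)
    if (length(idx) < max(nmf_k_range) * 5) next
    m <- as.matrix(norm[idx, , drop = FALSE])
    vars <- matrixStats::colVars(m)
    top <- order(vars, decreasing = TRUE)[seq_len(min(nmf_genes, ncol(m)))]
    x <- nmf_input(m[, top, drop = FALSE])
    cn <- run_consensus_nmf(x, k_range = nmf_k_range,
                            n_restarts = nmf_restarts,
                            seed = derive_seed(seed, 20L) + match(
                              s, unique(labels$sample)),
                            max_iter = 100)
    k_star <- select_k(cn)
    programs[[s]] <- list(nmf = cn, k = k_star)
    tg <- cn$by_k[[as.character(k_star)]]$top_genes
    names(tg) <- sprintf("%s_P%d", s, seq_along(tg))
    prog_sets <- c(prog_sets, tg)
  }
  meta <- if (length(prog_sets) >= 2) build_meta_programs(prog_sets)
          else NULL

  # ligand-receptor tests between malignant cells and the microenvironment
  inter <- NULL
  types <- labels$label
  types[types %in% c("ambiguous", "doublet", "normal")] <- NA
  ok <- !is.na(types)
  if (any(ok) && "malignant" %in% types[ok]) {
    inter <- score_interactions(
      norm[ok, , drop = FALSE], mal$qc_matrix$counts[ok, , drop = FALSE],
      types[ok], default_lr_pairs(),
      senders = "malignant",
      receivers = intersect(c("T", "NK", "myeloid"), unique(types[ok])),
      n_perm = n_perm, seed = derive_seed(seed, 30L))
  }

  # somatic-variant cascade
  cons <- consensus_calls(cohort$variants$caller_tables)
  cons <- germline_panel_filter(cons, cohort$variants$panel,
                                n_panel = config$n_panel)
  pair <- c(config$sample_ids[1],
            config$sample_ids[length(config$sample_ids)])
  cons <- rescue_paired(cons, cohort$variants$pileup, pair)
  cons <- gene_level_filters(cons, data.frame(
    gene = config$genes$symbol, chrom = config$genes$chrom,
    start = config$genes$start, gdi = config$genes$gdi,
    fpkm = config$genes$fpkm, stringsAsFactors = FALSE))

  # CCF clustering over the retained variant keys, using the pileup as
  # the per-sample read-count source
  keys <- unique(cons$variants$key)
  pu <- cohort$variants$pileup
  pu <- pu[pu$key %in% keys, , drop = FALSE]
  clones <- NULL; trees <- NULL; fish <- NULL
  if (length(unique(pu$key)) >= 2) {
    alt <- tapply(pu$alt_count, list(pu$key, pu$sample), sum)
    dep <- tapply(pu$depth, list(pu$key, pu$sample), sum)
    clones <- cluster_ccf(alt, dep, purity = config$purity,
                          k_max = min(6, nrow(alt) - 1),
                          seed = derive_seed(seed, 40L))
    if (clones$k <= 8) {
      trees <- enumerate_trees(clones)
      if (length(trees$trees) > 0) {
        fish <- export_fishplot(trees$trees[[1]], clones$ccf,
                                timepoints = colnames(clones$ccf))
      }
    }
  }

  out <- structure(list(cohort = cohort, malignant = mal,
                        cnv_segments = segs, wgs_concordance = conc,
                        similarity = sim, programs = programs,
                        meta_programs = meta, interactions = inter,
                        variants = cons, clones = clones, trees = trees,
                        fishplot = fish, seed = seed),
                   class = "mcl_pipeline")
  if (!is.null(outdir)) write_pipeline(out, outdir)
  out
}

#' Write pipeline result tables
#'
#' @param result an `mcl_pipeline` object.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(result$malignant$cell_labels, "cell_labels.tsv")
  wt(result$malignant$evidence[, setdiff(names(result$malignant$evidence),
                                         "doublet")], "cluster_evidence.tsv")
  wt(result$cnv_segments, "cnv_segments.tsv")
  if (!is.null(result$similarity)) {
    si <- as.data.frame(result$similarity$si)
    si <- cbind(sample = rownames(si), si)
    wt(si, "similarity_index.tsv")
  }
  if (!is.null(result$variants)) wt(result$variants$variants,
                                    "variants_filtered.tsv")
  if (!is.null(result$clones)) {
    cc <- as.data.frame(result$clones$ccf)
    cc <- cbind(clone = rownames(cc), cc, size = result$clones$size)
    wt(cc, "clone_ccf.tsv")
  }
  if (!is.null(result$trees) && length(result$trees$trees)) {
    writeLines(tree_newick(result$trees$trees[[1]]),
               file.path(outdir, "clone_tree.nwk"))
  }
  if (!is.null(result$fishplot)) wt(result$fishplot, "fishplot.tsv")
  if (!is.null(result$interactions)) wt(result$interactions,
                                        "interactions.tsv")
  invisible(outdir)
}

#' Evaluate pipeline recovery against the planted truth
#'
#' @param result an `mcl_pipeline` object.
#' @return list of recovery metrics: `malignant_f1` (cell-level F1 of the
#'   malignant label), `malignant_precision`, `malignant_recall`,
#'   `clonotype_accuracy` (fraction of captured malignant cells assigned
#'   their planted clonotype key), `cnv_precision`/`cnv_recall`
#'   (segment-level), `wgs_concordance`, `ccf_mae` (mean absolute error
#'   of recovered cluster CCFs over variants and samples), `n_clones`,
#'   `tree_match` (1 when a unique surviving topology equals the planted
#'   tree), `si_first_last`, `variant_precision`/`variant_recall` of the
#'   filter cascade.
#' @export
evaluate_recovery <- function(result) {
  stopifnot(inherits(result, "mcl_pipeline"))
  cohort <- result$cohort
  config <- cohort$config
  labels <- result$malignant$cell_labels
  meta <- result$malignant$qc_matrix$cell_meta
  truth_mal <- meta$true_type == "malignantB" & meta$qc_class == "ok"
  pred_mal <- labels$label == "malignant"
  tp <- sum(truth_mal & pred_mal)
  prec <- if (sum(pred_mal)) tp / sum(pred_mal) else NA_real_
  rec <- if (sum(truth_mal)) tp / sum(truth_mal) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else 0

  # clonotype recovery: captured malignant cells must carry their planted
  # clonotype key
  ct_acc <- NA_real_
  if (!is.null(result$malignant$clonotypes)) {
    ca <- result$malignant$clonotypes$cell_assignment
    expected <- vapply(config$clonotypes, function(ct)
      paste(ct$heavy_v, ct$heavy_j, ct$heavy_cdr3, ct$light_v,
            ct$light_j, ct$light_cdr3, sep = "|"), "")
    idx <- match(ca$cell_id, meta$barcode)
    truth_ct <- meta$true_clonotype[idx]
    sel <- !is.na(truth_ct)
    if (any(sel))
      ct_acc <- mean(ca$clonotype[sel] == expected[truth_ct[sel]])
  }

  # planted-segment recovery (direction + overlap)
  planted <- lapply(config$cnv_segments, function(seg) {
    g <- config$genes[seg$genes, ]
    list(chrom = seg$chrom, start = min(g$start), end = max(g$start),
         direction = if (seg$ratio > 1) "gain" else "loss")
  })
  det <- result$cnv_segments
  match_planted <- function(d) {
    any(vapply(planted, function(p)
      p$chrom == d$chrom && p$direction == d$direction &&
        p$start <= d$end && p$end >= d$start, TRUE))
  }
  cnv_prec <- if (nrow(det)) mean(vapply(seq_len(nrow(det)), function(i)
    match_planted(det[i, ]), TRUE)) else NA_real_
  cnv_rec <- mean(vapply(planted, function(p) {
    any(det$chrom == p$chrom & det$direction == p$direction &
          det$start <= p$end & det$end >= p$start)
  }, TRUE))

  # CCF error: per retained true variant, compare its recovered cluster
  # CCF with the planted clone CCF
  ccf_mae <- NA_real_; tree_match <- 0; n_clones <- NA_integer_
  vt <- cohort$variants$truth$variants
  if (!is.null(result$clones)) {
    cl <- result$clones
    n_clones <- cl$k
    keys <- rownames(cl$ccf)  # none: assignment indexed by pileup keys
    pu <- cohort$variants$pileup
    pu_keys <- sort(unique(pu$key[pu$key %in%
                                    result$variants$variants$key]))
    est_ccf <- cl$ccf[cl$assignment, , drop = FALSE]
    rownames(est_ccf) <- pu_keys
    idx <- match(vt$key, pu_keys)
    sel <- !is.na(idx)
    if (any(sel)) {
      true_ccf <- config$clone_ccf[vt$clone[sel], , drop = FALSE]
      est <- est_ccf[idx[sel], colnames(cl$ccf) %in% config$sample_ids,
                     drop = FALSE]
      est <- est[, match(config$sample_ids, colnames(est)), drop = FALSE]
      ccf_mae <- mean(abs(est - true_ccf))
    }
    if (!is.null(result$trees) && length(result$trees$trees) == 1) {
      # map recovered clusters to planted clones by nearest CCF profile
      d <- as.matrix(dist(rbind(cl$ccf, config$clone_ccf)))
      k <- cl$k; nk <- nrow(config$clone_ccf)
      if (k == nk) {
        cross <- d[seq_len(k), k + seq_len(nk), drop = FALSE]
        map <- apply(cross, 1, which.min)
        if (length(unique(map)) == k) {
          rec_parent <- result$trees$trees[[1]]
          mapped <- integer(nk)
          for (v in seq_len(k)) {
            p <- rec_parent[v]
            mapped[map[v]] <- if (p == 0) 0L else map[p]
          }
          true_parent <- ifelse(is.na(config$clone_parent), 0L,
                                config$clone_parent)
          tree_match <- as.integer(all(mapped == true_parent))
        }
      }
    }
  }

  # variant-cascade precision/recall against planted somatic truth
  final_keys <- unique(result$variants$variants$key)
  true_keys <- vt$key
  vp <- if (length(final_keys)) mean(final_keys %in% true_keys) else NA
  vr <- mean(true_keys %in% final_keys)

  si_fl <- if (!is.null(result$similarity)) {
    n <- nrow(result$similarity$si)
    result$similarity$si[1, n]
  } else NA_real_

  list(malignant_f1 = f1, malignant_precision = prec,
       malignant_recall = rec, clonotype_accuracy = ct_acc,
       cnv_precision = cnv_prec, cnv_recall = cnv_rec,
       wgs_concordance = result$wgs_concordance,
       ccf_mae = ccf_mae, n_clones = n_clones, tree_match = tree_match,
       si_first_last = si_fl,
       variant_precision = vp, variant_recall = vr)
}

#' Consensus-NMF model-selection experiment on planted-program data
#'
#' For each seed, simulates a count matrix with `k_true` planted programs
#' ([simulate_programs()]), runs consensus NMF over `k_range` and records
#' whether the cophenetic rule selects `k_true`.
#'
#' @param n_seeds number of independent simulations (default 10).
#' @param k_true planted number of programs (default 3).
#' @param k_range candidate K values (default 2:5).
#' @param n_cells,n_genes simulated matrix size.
#' @param n_restarts consensus restarts (default 8).
#' @param seed base seed.
#' @return list with `selected` (per-seed K*), `n_correct`.
#' @export
nmf_k_experiment <- function(n_seeds = 10, k_true = 3, k_range = 2:5,
                             n_cells = 240, n_genes = 300,
                             n_restarts = 8, seed = 1L) {
  selected <- integer(n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- simulate_programs(n_cells, n_genes, k = k_true,
                             seed = derive_seed(seed, 500L + i))
    x <- nmf_input(normalize_log(Matrix::Matrix(sim$counts,
                                                sparse = TRUE)))
    cn <- run_consensus_nmf(x, k_range = k_range, n_restarts = n_restarts,
                            seed = derive_seed(seed, 600L + i),
                            max_iter = 100)
    selected[i] <- suppressWarnings(select_k(cn))
  }
  list(selected = selected, n_correct = sum(selected == k_true))
}
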