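# Multi-criteria malignant B-cell classification: clonal BCR, light-chain
# ratio consistency, CCND1 overexpression, and confirmatory CNV evidence.

#' Default thresholds for B-cluster classification
#'
#' All thresholds are package defaults operationalizing qualitative
#' criteria: `bcr_fraction` (dominant-clonotype fraction among a cluster's
#' BCR-assigned cells), `ratio_shift` and `ratio_sd` (light-chain-ratio
#' consistency: |mean - 0.5| >= shift and SD <= sd), `ccnd1_lfc` (log2
#' fold-change vs the normal-B reference), `cnv_quantile` (the reference
#' quantile a malignant cluster's median CNV score must exceed).
#'
#' @return named list of thresholds.
#' @export
malignant_thresholds <- function() {
  list(bcr_fraction = 0.5, ratio_shift = 0.3, ratio_sd = 0.15,
       ccnd1_lfc = 1, cnv_quantile = 0.95)
}

#' Flag T/B doublet clusters
#'
#' A cluster is flagged as a T+B doublet cluster when both its B-marker
#' (CD19, MS4A1, CD79A) and T-marker (CD3E, CD4, CD8A) scores exceed the
#' cohort medians. A cluster's score is the median over its cells of the
#' mean log-normalized marker expression; each marker set's cohort median
#' is taken over the cells outside that set's own lineage (B markers over
#' non-B cells, T markers over non-T cells), i.e. a doublet cluster
#' expresses each lineage's markers above the background of cells that do
#' not belong to that lineage. The anchors are carried in the evidence
#' table's `b_median`/`t_median` attributes.
#'
#' @param evidence data.frame with per-cluster `b_score` and `t_score`
#'   columns and `b_median`/`t_median` attributes (see
#'   [compute_cluster_evidence()]).
#' @return logical vector, one flag per cluster.
#' @export
flag_doublets <- function(evidence) {
  assert_that(all(c("b_score", "t_score") %in% names(evidence)),
              "evidence must carry b_score/t_score marker columns")
  b_med <- attr(evidence, "b_median")
  t_med <- attr(evidence, "t_median")
  assert_that(!is.null(b_med) && !is.null(t_med),
              "evidence must carry cohort b_median/t_median attributes")
  evidence$b_score > b_med & evidence$t_score > t_med
}

#' Classify B-cell clusters as malignant, normal or ambiguous
#'
#' A cluster is malignant when all primary channels agree: dominant
#' clonotype fraction >= `bcr_fraction` (skipped in three-channel mode
#' when no BCR data is available), light-chain-ratio consistency
#' (|mean - 0.5| >= `ratio_shift` and SD <= `ratio_sd`), and CCND1 log2
#' fold change >= `ccnd1_lfc` against the normal-B reference. The CNV
#' channel (median CNV score above the reference quantile) is
#' confirmatory only: when the primary channels all agree but the CNV
#' channel disagrees the cluster is demoted to ambiguous; CNV evidence
#' never promotes a cluster. A cluster with no positive primary channel
#' is normal; anything else is ambiguous. Doublet-flagged clusters are
#' labeled `doublet`.
#'
#' @param evidence output of [compute_cluster_evidence()].
#' @param thresholds see [malignant_thresholds()].
#' @param use_cnv logical; disable to skip the confirmatory CNV channel.
#' @return character vector of labels per cluster
#'   (`malignant`/`normal`/`ambiguous`/`doublet`).
#' @export
classify_b_clusters <- function(evidence,
                                thresholds = malignant_thresholds(),
                                use_cnv = TRUE) {
  th <- utils::modifyList(malignant_thresholds(), as.list(thresholds))
  has_bcr <- !is.null(evidence$dom_frac) && !all(is.na(evidence$dom_frac))
  if (!has_bcr)
    message("no BCR evidence available; three-channel mode")
  n <- nrow(evidence)
  bcr_pos <- if (has_bcr) !is.na(evidence$dom_frac) &
    evidence$dom_frac >= th$bcr_fraction else rep(NA, n)
  light_pos <- !is.na(evidence$ratio_mean) &
    abs(evidence$ratio_mean - 0.5) >= th$ratio_shift &
    !is.na(evidence$ratio_sd) & evidence$ratio_sd <= th$ratio_sd
  ccnd1_pos <- !is.na(evidence$ccnd1_lfc) &
    evidence$ccnd1_lfc >= th$ccnd1_lfc
  cnv_pos <- !is.na(evidence$cnv_median) &
    evidence$cnv_median > evidence$cnv_ref_quantile
  primary <- light_pos & ccnd1_pos & (if (has_bcr) bcr_pos else TRUE)
  # CNV is confirmatory only: it can demote a malignant call, but a
  # cluster with no positive primary channel is normal regardless of it
  any_pos <- light_pos | ccnd1_pos |
    (if (has_bcr) bcr_pos %in% TRUE else FALSE)
  label <- ifelse(primary & (!use_cnv | cnv_pos), "malignant",
                  ifelse(!any_pos, "normal", "ambiguous"))
  if (!is.null(evidence$doublet) && any(evidence$doublet))
    label[evidence$doublet] <- "doublet"
  label
}

#' Compute per-cluster evidence for malignant-cell classification
#'
#' @param norm cells x genes normalized matrix of the full dataset.
#' @param counts the matching [cell_matrix()] (raw counts, for the
#'   light-chain ratio).
#' @param b_cells integer indices (rows of `norm`) of the B compartment.
#' @param b_cluster integer subcluster labels for `b_cells`.
#' @param bcr a `clonotype_set` (see [assign_clonotypes()]) or `NULL`.
#' @param cnv_scores named per-cell CNV scores for (at least) the B cells.
#' @param normal_ref indices (rows of `norm`) of normal-B reference cells.
#' @param major_type optional per-cell major-type labels over the rows of
#'   `norm`; used for the doublet-score cohort anchors (falling back to
#'   overall per-cell medians when absent).
#' @param cnv_quantile reference quantile for the CNV channel.
#' @return data.frame with one row per B subcluster and the evidence
#'   channels used by [classify_b_clusters()]; carries `b_median` /
#'   `t_median` attributes for [flag_doublets()].
#' @export
compute_cluster_evidence <- function(norm, counts, b_cells, b_cluster,
                                     bcr = NULL, cnv_scores = NULL,
                                     normal_ref = NULL, major_type = NULL,
                                     cnv_quantile = 0.95) {
  b_markers <- c("CD19", "MS4A1", "CD79A")
  t_markers <- c("CD3E", "CD4", "CD8A")
  bm <- intersect(b_markers, colnames(norm))
  tm <- intersect(t_markers, colnames(norm))
  assert_that(length(bm) > 0 && length(tm) > 0,
              "doublet marker genes absent from the matrix")
  b_score_cell <- Matrix::rowMeans(norm[, bm, drop = FALSE])
  t_score_cell <- Matrix::rowMeans(norm[, tm, drop = FALSE])

  ratio_cell <- light_chain_ratio_matrix(counts)
  ccnd1 <- if ("CCND1" %in% colnames(norm))
    as.numeric(norm[, "CCND1"]) else rep(NA_real_, nrow(norm))
  ref_ccnd1 <- if (!is.null(normal_ref) && length(normal_ref))
    mean(expm1(ccnd1[normal_ref])) else NA_real_
  ref_q <- if (!is.null(cnv_scores) && !is.null(normal_ref) &&
               length(normal_ref)) {
    ref_sc <- cnv_scores[rownames(norm)[normal_ref]]
    quantile(ref_sc, cnv_quantile, na.rm = TRUE, names = FALSE)
  } else NA_real_

  cl <- sort(unique(b_cluster))
  rows <- lapply(cl, function(g) {
    idx <- b_cells[b_cluster == g]
    bc <- rownames(norm)[idx]
    dom_frac <- NA_real_
    dom_clonotype <- NA_character_
    if (!is.null(bcr)) {
      ca <- bcr$cell_assignment
      in_cl <- ca[ca$cell_id %in% bc, , drop = FALSE]
      if (nrow(in_cl) > 0) {
        dom <- in_cl[in_cl$status == "clonal", , drop = FALSE]
        if (nrow(dom) > 0) {
          tab <- sort(table(dom$clonotype), decreasing = TRUE)
          dom_clonotype <- names(tab)[1]
          dom_frac <- tab[[1]] / nrow(in_cl)
        } else dom_frac <- 0
      }
    }
    rat <- ratio_cell[idx]
    rat <- rat[!is.na(rat)]
    ccnd1_lfc <- if (!is.na(ref_ccnd1))
      log2((mean(expm1(ccnd1[idx])) + 1) / (ref_ccnd1 + 1)) else NA_real_
    cnv_med <- if (!is.null(cnv_scores))
      median(cnv_scores[bc], na.rm = TRUE) else NA_real_
    data.frame(cluster = g, n_cells = length(idx),
               dom_frac = dom_frac, dom_clonotype = dom_clonotype,
               ratio_mean = if (length(rat)) mean(rat) else NA_real_,
               ratio_sd = if (length(rat) > 1) sd(rat) else 0,
               ccnd1_lfc = ccnd1_lfc,
               cnv_median = cnv_med, cnv_ref_quantile = ref_q,
               b_score = median(b_score_cell[idx]),
               t_score = median(t_score_cell[idx]),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (!is.null(major_type)) {
    attr(ev, "b_median") <- median(b_score_cell[major_type != "B"])
    attr(ev, "t_median") <- median(t_score_cell[major_type != "T"])
  } else {
    attr(ev, "b_median") <- median(b_score_cell)
    attr(ev, "t_median") <- median(t_score_cell)
  }
  ev
}

#' Identify malignant B cells in a cohort
#'
#' End-to-end composition: QC, normalization, clustering, major-type
#' annotation, B-compartment subclustering, BCR clonotype dominance,
#' expression-inferred CNV scoring against a non-B reference, per-cluster
#' evidence, doublet flagging and cluster classification. Non-B-compartment
#' cells keep their major type as the label.
#'
#' @param x a raw [cell_matrix()] (QC is applied internally).
#' @param rearrangements optional AIRR-style rearrangement data.frame.
#' @param resolution clustering resolution for the major clustering.
#' @param subcluster_resolution resolution for the patient-specific
#'   B-compartment reclustering (default 1.0, finer than the major
#'   clustering so that small normal-B populations separate).
#' @param seed integer seed.
#' @param thresholds see [malignant_thresholds()].
#' @param cnv_window smoothing window for [infer_cnv_profile()].
#' @return list of class `malignant_call`: `cell_labels` (per QC-passing
#'   cell: barcode, sample, major type, B subcluster, label), `evidence`
#'   (per B subcluster), `qc_matrix`, `clusters`, `types`, `clonotypes`,
#'   `cnv_profile`.
#' @export
identify_malignant <- function(x, rearrangements = NULL, resolution = 0.6,
                               subcluster_resolution = 1.0, seed = 1L,
                               thresholds = malignant_thresholds(),
                               cnv_window = 51) {
  xq <- apply_qc(x)
  norm <- normalize_log(xq)
  clusters <- cluster_cells(norm, resolution = resolution, seed = seed,
                            sample = xq$cell_meta$sample)
  types <- annotate_major_types(norm, clusters)
  is_b <- types$cell_type == "B"
  b_cells <- which(is_b)
  assert_that(length(b_cells) >= 10, "too few B cells to classify")

  sub <- cluster_cells(norm[b_cells, , drop = FALSE],
                       resolution = subcluster_resolution,
                       seed = derive_seed(seed, 7L))
  b_cluster <- sub$label

  bcr <- NULL
  if (!is.null(rearrangements)) {
    paired <- filter_rearrangements(rearrangements)
    paired <- paired[paired$cell_id %in% rownames(norm), , drop = FALSE]
    if (nrow(paired) > 0) bcr <- assign_clonotypes(paired)
  }

  # provisional normal-B reference: subclusters without a dominant
  # clonotype (or, lacking BCR, with an inconsistent light-chain ratio)
  ev0 <- compute_cluster_evidence(norm, xq, b_cells, b_cluster, bcr,
                                  cnv_scores = NULL, normal_ref = NULL)
  if (!all(is.na(ev0$dom_frac))) {
    normal_cl <- ev0$cluster[!is.na(ev0$dom_frac) &
                               ev0$dom_frac < thresholds$bcr_fraction]
  } else {
    normal_cl <- ev0$cluster[is.na(ev0$ratio_mean) |
                               abs(ev0$ratio_mean - 0.5) <
                                 thresholds$ratio_shift]
  }
  normal_ref <- b_cells[b_cluster %in% normal_cl]
  if (length(normal_ref) < 3 && !is.null(bcr)) {
    # fallback: individual B cells whose clonotype is polyclonal
    poly <- bcr$cell_assignment$cell_id[
      bcr$cell_assignment$status == "polyclonal"]
    normal_ref <- b_cells[rownames(norm)[b_cells] %in% poly]
  }
  assert_that(length(normal_ref) >= 3,
              "no normal-B reference cells identified")

  # expression CNV against the normal-B reference (lineage-matched, so
  # cell-type signature differences do not mimic copy-number change)
  profile <- infer_cnv_profile(norm, reference_cells = normal_ref,
                               gene_meta = xq$gene_meta,
                               window = cnv_window)
  scores <- cnv_score(profile)

  ev <- compute_cluster_evidence(norm, xq, b_cells, b_cluster, bcr,
                                 cnv_scores = scores,
                                 normal_ref = normal_ref,
                                 major_type = types$cell_type,
                                 cnv_quantile = thresholds$cnv_quantile)
  ev$doublet <- flag_doublets(ev)
  label_cl <- classify_b_clusters(ev, thresholds)
  ev$label <- label_cl

  cell_labels <- data.frame(
    barcode = xq$cell_meta$barcode, sample = xq$cell_meta$sample,
    major_type = types$cell_type,
    b_subcluster = NA_integer_, label = types$cell_type,
    stringsAsFactors = FALSE)
  cell_labels$b_subcluster[b_cells] <- b_cluster
  cell_labels$label[b_cells] <-
    label_cl[match(b_cluster, ev$cluster)]

  structure(list(cell_labels = cell_labels, evidence = ev,
                 qc_matrix = xq, clusters = clusters, types = types,
                 clonotypes = bcr, cnv_profile = profile,
                 cnv_scores = scores, normal_ref = normal_ref,
                 b_cells = b_cells, norm = norm),
            class = "malignant_call")
}

#' @export
print.malignant_call <- function(x, ...) {
  tab <- table(x$cell_labels$label)
  cat("<malignant_call>\n")
  print(tab)
  invisible(x)
}
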