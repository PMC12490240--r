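# QC filtering, normalization, clustering, cell-type annotation and
# rank-sum differential expression.

#' Default marker sets for major cell types
#'
#' Canonical markers: B (CD19, MS4A1, CD79A), T (CD3D, CD3E, CD3G),
#' NK (XCL2, NKG7, GNLY), myeloid (CD68, CD33, CST3) and erythrocyte
#' (HBQ1, HBM, GYPA).
#'
#' @return named list of character vectors.
#' @export
default_marker_sets <- function() {
  list(B = c("CD19", "MS4A1", "CD79A"),
       T = c("CD3D", "CD3E", "CD3G"),
       NK = c("XCL2", "NKG7", "GNLY"),
       myeloid = c("CD68", "CD33", "CST3"),
       erythrocyte = c("HBQ1", "HBM", "GYPA"))
}

#' Apply quality-control filters
#'
#' Removes genes detected in fewer than `min_cells_per_gene` cells, then
#' cells failing any of: at least `min_genes` and at most `max_genes`
#' detected genes, at most `max_counts` total counts, at most `max_pct_mito`
#' percent mitochondrial counts, at least `min_pct_ribo` percent ribosomal
#' counts. Gene and cell filters are iterated to a fixed point so that the
#' operation is idempotent: the returned matrix satisfies both filters
#' simultaneously.
#'
#' @param x a [cell_matrix()].
#' @param min_genes,max_genes detected-gene bounds per cell (inclusive
#'   keep: a cell with exactly `min_genes` detected genes is retained).
#' @param max_counts maximum total counts per cell (inclusive keep).
#' @param max_pct_mito maximum mitochondrial percentage (cells strictly
#'   above are removed).
#' @param min_pct_ribo minimum ribosomal percentage (cells strictly below
#'   are removed).
#' @param min_cells_per_gene minimum number of cells a gene must be
#'   detected in.
#' @return the filtered [cell_matrix()]. Warns (does not error) when the
#'   result is empty.
#' @export
apply_qc <- function(x, min_genes = 500, max_genes = 5000,
                     max_counts = 40000, max_pct_mito = 20,
                     min_pct_ribo = 5, min_cells_per_gene = 3) {
  stopifnot(inherits(x, "cell_matrix"))
  assert_that(!is.null(x$gene_meta$mito) && !is.null(x$gene_meta$ribo),
              "gene_meta must carry mito/ribo flags")
  repeat {
    n_before <- dim(x)
    keep_g <- Matrix::colSums(x$counts > 0) >= min_cells_per_gene
    x <- subset_cells(x, genes = keep_g)
    cm <- x$cell_meta
    keep_c <- cm$n_genes_detected >= min_genes &
      cm$n_genes_detected <= max_genes &
      cm$total_counts <= max_counts &
      cm$pct_mito <= max_pct_mito &
      cm$pct_ribo >= min_pct_ribo
    x <- subset_cells(x, cells = keep_c)
    if (all(dim(x) == n_before) || any(dim(x) == 0)) break
  }
  if (nrow(x$counts) == 0) warning("QC removed every cell")
  x
}

#' Library-size log-normalization
#'
#' value = log1p(count / cell_total * scale). Cells with zero total counts
#' pass through as all-zero rows with a warning. The zero pattern of the
#' counts is preserved.
#'
#' @param x a [cell_matrix()] or a cells x genes matrix.
#' @param scale library-size scale factor (default 10,000).
#' @return sparse cells x genes matrix of normalized values.
#' @export
normalize_log <- function(x, scale = 1e4) {
  cm <- if (inherits(x, "cell_matrix")) x$counts else
    as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
  tot <- Matrix::rowSums(cm)
  if (any(tot == 0)) warning("cells with zero total counts pass through")
  fac <- ifelse(tot > 0, scale / tot, 0)
  out <- Matrix::Diagonal(x = fac) %*% cm
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(cm)
  as(out, "CsparseMatrix")
}

# Top principal components of the gene-scaled normalized matrix.
.pca_embed <- function(norm, n_pcs = 30, seed = 0L) {
  m <- as.matrix(norm)
  mu <- colMeans(m)
  sdv <- matrixStats::colSds(m)
  keep <- sdv > 0
  if (!any(keep)) return(matrix(0, nrow(m), 1,
                                dimnames = list(rownames(norm), NULL)))
  m <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  m[m > 10] <- 10
  n_pcs <- min(n_pcs, nrow(m) - 1L, ncol(m) - 1L)
  if (n_pcs < 2) return(m[, seq_len(max(1, ncol(m))), drop = FALSE])
  pc <- with_seed(seed, irlba::irlba(m, nv = n_pcs, nu = n_pcs))
  emb <- pc$u %*% diag(pc$d, n_pcs, n_pcs)
  rownames(emb) <- rownames(norm)
  emb
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds an SNN graph on the top principal components (default 30, fewer
#' when rank-limited) of the gene-scaled normalized matrix and optimizes
#' modularity (Louvain) at the given resolution. Labels are dense from 0
#' and ordered by decreasing cluster size; the result is deterministic
#' given `seed`.
#'
#' @param norm cells x genes normalized matrix (see [normalize_log()]).
#' @param resolution modularity resolution (> 0), default 0.6.
#' @param seed integer seed.
#' @param n_pcs number of principal components (default 30).
#' @param k neighbors for the SNN graph.
#' @return a list of class `cluster_assignment`: `label` (integer vector,
#'   0-based), `resolution`, `seed`, `sizes`, `fractions` (per-sample
#'   fractional abundance when `sample` supplied).
#' @param sample optional per-cell sample ids for fractional abundances.
#' @export
cluster_cells <- function(norm, resolution = 0.6, seed = 1L, n_pcs = 30,
                          k = 20, sample = NULL) {
  assert_that(resolution > 0, "resolution must be > 0")
  assert_that(nrow(norm) >= 2, "need at least 2 cells")
  emb <- .pca_embed(norm, n_pcs, seed = derive_seed(seed, 1L))
  if (all(dist(emb[seq_len(min(50, nrow(emb))), , drop = FALSE]) < 1e-12)) {
    # degenerate: identical cells form a single cluster
    lab <- rep(0L, nrow(norm))
  } else {
    g <- scran::buildSNNGraph(t(emb), k = min(k, nrow(emb) - 1L), d = NA)
    comm <- with_seed(derive_seed(seed, 2L),
                      igraph::cluster_louvain(g, resolution = resolution))
    lab <- as.integer(igraph::membership(comm))
    ord <- order(tabulate(lab), decreasing = TRUE)
    lab <- match(lab, ord) - 1L
  }
  sizes <- table(lab)
  fractions <- NULL
  if (!is.null(sample)) {
    tab <- table(sample, lab)
    fractions <- sweep(tab, 1, rowSums(tab), "/")
  }
  structure(list(label = lab, resolution = resolution, seed = seed,
                 sizes = as.integer(sizes),
                 fractions = fractions),
            class = "cluster_assignment")
}

#' Annotate clusters with major cell types
#'
#' Scores each cluster for each marker set as the mean (over the set's
#' genes) of the cluster's mean z-scaled expression; assigns the argmax
#' type. Exact ties are broken by the fixed order of `marker_sets` with a
#' warning.
#'
#' @param norm cells x genes normalized matrix with gene symbols as
#'   column names.
#' @param clusters a `cluster_assignment` or integer label vector.
#' @param marker_sets named list of marker gene vectors
#'   (default [default_marker_sets()]).
#' @return a list of class `cell_type_call`: `cluster_type` (named
#'   character vector per cluster), `scores` (clusters x types matrix),
#'   `cell_type` (per-cell type).
#' @export
annotate_major_types <- function(norm, clusters,
                                 marker_sets = default_marker_sets()) {
  lab <- if (inherits(clusters, "cluster_assignment")) clusters$label
         else as.integer(clusters)
  present <- lapply(marker_sets, intersect, colnames(norm))
  assert_that(any(lengths(present) > 0),
              "no marker gene present in the matrix")
  m <- as.matrix(norm[, unique(unlist(present)), drop = FALSE])
  mu <- colMeans(m)
  sdv <- matrixStats::colSds(m)
  z <- sweep(sweep(m, 2, mu), 2, pmax(sdv, 1e-12), "/")
  cl <- sort(unique(lab))
  scores <- matrix(NA_real_, length(cl), length(marker_sets),
                   dimnames = list(as.character(cl), names(marker_sets)))
  for (i in seq_along(cl)) {
    zi <- z[lab == cl[i], , drop = FALSE]
    for (t in names(marker_sets)) {
      gs <- present[[t]]
      scores[i, t] <- if (length(gs)) mean(zi[, gs]) else -Inf
    }
  }
  best <- apply(scores, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1)
      warning("tied marker scores; first type in fixed order used")
    w[1]
  })
  cluster_type <- setNames(names(marker_sets)[best], as.character(cl))
  structure(list(cluster_type = cluster_type, scores = scores,
                 cell_type = unname(cluster_type[as.character(lab)])),
            class = "cell_type_call")
}

#' Rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalized values with
#' Benjamini-Hochberg adjustment. The log2 fold change compares group
#' means of de-logged normalized expression (with a pseudocount of 1).
#' Rows are sorted by adjusted p, then by decreasing absolute fold change.
#'
#' @param norm cells x genes normalized matrix.
#' @param group_a,group_b index vectors (logical or integer) over cells;
#'   each group must contain at least 3 cells.
#' @return data.frame with `gene`, `lfc`, `p`, `adj_p`.
#' @export
differential_expression <- function(norm, group_a, group_b) {
  a <- as.matrix(norm[group_a, , drop = FALSE])
  b <- as.matrix(norm[group_b, , drop = FALSE])
  assert_that(nrow(a) >= 3 && nrow(b) >= 3,
              "each group needs at least 3 cells")
  n_genes <- ncol(a)
  p <- numeric(n_genes)
  for (j in seq_len(n_genes)) {
    if (all(a[, j] == a[1, j]) && all(b[, j] == a[1, j])) {
      p[j] <- 1
    } else {
      p[j] <- suppressWarnings(
        wilcox.test(a[, j], b[, j], exact = FALSE)$p.value)
    }
  }
  lfc <- log2((colMeans(expm1(a)) + 1) / (colMeans(expm1(b)) + 1))
  out <- data.frame(gene = colnames(norm) %||% seq_len(n_genes),
                    lfc = lfc, p = p, adj_p = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$adj_p, -abs(out$lfc)), , drop = FALSE]
}
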