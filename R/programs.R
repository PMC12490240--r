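# Per-sample consensus NMF expression programs, cophenetic K selection,
# meta-program construction from shared top genes, and meta-program
# scoring with paired-sample comparison.

# Multiplicative-update NMF (Frobenius objective): X (cells x genes,
# non-negative) ~ W (cells x k) %*% H (k x genes).
.nmf_fit <- function(x, k, max_iter = 150, tol = 1e-5) {
  n <- nrow(x); m <- ncol(x)
  w <- matrix(runif(n * k, 0.1, 1), n, k)
  h <- matrix(runif(k * m, 0.1, 1), k, m)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, x) / pmax(crossprod(w) %*% h, 1e-12))
    w <- w * (x %*% t(h) / pmax(w %*% tcrossprod(h), 1e-12))
    if (it %% 10 == 0) {
      err <- sum((x - w %*% h)^2)
      if (abs(err_prev - err) < tol * max(err_prev, 1e-12)) break
      err_prev <- err
    }
  }
  # scale programs so H rows have unit L2 norm (gene scores comparable)
  nrm <- sqrt(rowSums(h^2))
  nrm[nrm == 0] <- 1
  list(w = sweep(w, 2, nrm, "*"), h = sweep(h, 1, nrm, "/"),
       error = sum((x - w %*% h)^2))
}

#' Prepare a non-negative NMF input from normalized expression
#'
#' Genes are z-scaled across cells and negative values are clipped at 0,
#' so programs capture above-average expression.
#'
#' @param norm cells x genes normalized matrix.
#' @return dense non-negative cells x genes matrix (zero-variance genes
#'   dropped).
#' @export
nmf_input <- function(norm) {
  m <- as.matrix(norm)
  sdv <- matrixStats::colSds(m)
  keep <- sdv > 0
  m <- m[, keep, drop = FALSE]
  z <- sweep(sweep(m, 2, colMeans(m)), 2, sdv[keep], "/")
  z[z < 0] <- 0
  z
}

#' Consensus non-negative matrix factorization over a range of K
#'
#' For each K in `k_range`, runs `n_restarts` random-initialization NMF
#' fits. The cell x cell consensus matrix holds the fraction of restarts
#' co-assigning two cells to the same maximum-usage program; the
#' cophenetic coefficient is the correlation between consensus distances
#' (1 - consensus) and the cophenetic distances of their average-linkage
#' dendrogram. Programs for each K are reported from the restart with the
#' lowest reconstruction error.
#'
#' @param x non-negative cells x genes matrix (see [nmf_input()]).
#' @param k_range integer vector of K values (default 2:10). K values
#'   exceeding the number of cells are skipped with a warning.
#' @param n_restarts random restarts per K (default 20).
#' @param seed integer seed.
#' @param n_top_genes genes reported per program (default 30).
#' @param max_iter NMF iterations per restart.
#' @return list of class `consensus_nmf`: per-K entries with `programs`
#'   (list of per-program top genes + full gene scores), `usage`
#'   (cells x K), `consensus`, `cophenetic`, `error`; plus `cophenetic`
#'   (named vector over K) at the top level.
#' @export
run_consensus_nmf <- function(x, k_range = 2:10, n_restarts = 20,
                              seed = 1L, n_top_genes = 30,
                              max_iter = 150) {
  x <- as.matrix(x)
  assert_that(min(x) >= 0, "NMF input must be non-negative")
  k_range <- sort(unique(as.integer(k_range)))
  skip <- k_range > nrow(x)
  if (any(skip)) {
    warning("K values exceeding the number of cells skipped")
    k_range <- k_range[!skip]
  }
  res <- list()
  coph <- setNames(numeric(length(k_range)), as.character(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    best <- NULL
    consensus <- matrix(0, nrow(x), nrow(x))
    for (r in seq_len(n_restarts)) {
      fit <- with_seed(derive_seed(seed, 1000L * k + r), .nmf_fit(
        x, k, max_iter = max_iter))
      assign <- max.col(fit$w, ties.method = "first")
      co <- outer(assign, assign, "==")
      consensus <- consensus + co
      if (is.null(best) || fit$error < best$error) best <- fit
    }
    consensus <- consensus / n_restarts
    d <- as.dist(1 - consensus)
    hc <- hclust(d, method = "average")
    cc <- suppressWarnings(cor(cophenetic(hc), d))
    if (is.na(cc)) cc <- 1  # degenerate: all distances equal
    top <- lapply(seq_len(k), function(j) {
      ord <- order(best$h[j, ], decreasing = TRUE)
      colnames(x)[head(ord, min(n_top_genes, ncol(x)))]
    })
    res[[as.character(k)]] <- list(
      k = k, usage = best$w, gene_scores = best$h,
      top_genes = top, consensus = consensus, cophenetic = cc,
      error = best$error)
    coph[as.character(k)] <- cc
  }
  structure(list(by_k = res, cophenetic = coph, k_range = k_range,
                 seed = seed, n_restarts = n_restarts),
            class = "consensus_nmf")
}

#' Select the number of programs from the cophenetic profile
#'
#' K* is the smallest K in the range whose cophenetic coefficient is
#' strictly greater than the next K's (the K just before the first
#' decrease). When the profile never decreases, the largest K is returned
#' with a warning.
#'
#' @param cophenetic named numeric vector of cophenetic coefficients over
#'   a contiguous K range (or a `consensus_nmf` object).
#' @return the selected integer K*.
#' @export
select_k <- function(cophenetic) {
  if (inherits(cophenetic, "consensus_nmf"))
    cophenetic <- cophenetic$cophenetic
  assert_that(length(cophenetic) >= 2,
              "need cophenetic coefficients for at least 2 K values")
  ks <- as.integer(names(cophenetic))
  ord <- order(ks)
  ks <- ks[ord]; cc <- unname(cophenetic[ord])
  for (i in seq_len(length(ks) - 1)) {
    if (cc[i] > cc[i + 1]) return(ks[i])
  }
  warning("cophenetic coefficient never decreases; largest K returned")
  ks[length(ks)]
}

#' Group programs across samples into meta-programs
#'
#' Similarity between two programs is the number of shared top genes;
#' distance is `n_top - shared`. Programs are average-linkage
#' hierarchically clustered and the tree is cut at `cut_height`
#' (default `n_top - 3`, i.e. programs sharing at least 3 genes can
#' merge).
#'
#' @param programs list of character vectors of top genes (one per
#'   program, across all samples); names identify the programs.
#' @param cut_height dendrogram cut height (default `n_top - 3`).
#' @param n_top nominal top-gene count (default 30).
#' @return list of class `meta_programs`: `membership` (named integer
#'   vector program -> meta-program), `consensus_genes` (per meta-program:
#'   genes appearing in at least half of the member programs, always a
#'   subset of the union of member top genes), `shared` (the similarity
#'   matrix).
#' @export
build_meta_programs <- function(programs, cut_height = NULL, n_top = 30) {
  assert_that(length(programs) >= 2, "need at least 2 programs")
  if (is.null(names(programs)))
    names(programs) <- sprintf("program%03d", seq_along(programs))
  if (is.null(cut_height)) cut_height <- n_top - 3
  np <- length(programs)
  shared <- matrix(0, np, np,
                   dimnames = list(names(programs), names(programs)))
  for (i in seq_len(np)) for (j in seq_len(np))
    shared[i, j] <- length(intersect(programs[[i]], programs[[j]]))
  d <- as.dist(n_top - shared)
  if (np == 2) {
    membership <- if (d[1] <= cut_height) c(1L, 1L) else c(1L, 2L)
    names(membership) <- names(programs)
  } else {
    hc <- hclust(d, method = "average")
    membership <- cutree(hc, h = cut_height)
  }
  consensus <- lapply(sort(unique(membership)), function(m) {
    mem <- programs[membership == m]
    genes <- unlist(mem)
    tab <- table(genes)
    out <- names(tab)[tab >= ceiling(length(mem) / 2)]
    if (!length(out)) out <- names(sort(tab, decreasing = TRUE))[1]
    out
  })
  names(consensus) <- paste0("MP", sort(unique(membership)))
  structure(list(membership = membership, consensus_genes = consensus,
                 shared = shared, cut_height = cut_height, n_top = n_top),
            class = "meta_programs")
}

#' Score cells for a meta-program gene set
#'
#' The per-cell score is the mean normalized expression over the gene set.
#'
#' @param norm cells x genes normalized matrix.
#' @param gene_set character vector of genes; must intersect the matrix.
#' @return numeric per-cell scores.
#' @export
score_meta_program <- function(norm, gene_set) {
  gs <- intersect(gene_set, colnames(norm))
  assert_that(length(gs) > 0, "gene set disjoint from the matrix")
  as.numeric(Matrix::rowMeans(norm[, gs, drop = FALSE]))
}

#' Paired comparison of meta-program expression between two samples
#'
#' Compares per-gene sample means of the meta-program's genes with a
#' two-sided Wilcoxon signed-rank test and reports the mean difference
#' (sample B minus sample A).
#'
#' @param norm_a,norm_b cells x genes normalized matrices for the two
#'   samples (same gene space).
#' @param gene_set meta-program gene set.
#' @return list with `delta` (mean B - A over the set), `p` (signed-rank
#'   p-value), `n_genes`.
#' @export
compare_paired <- function(norm_a, norm_b, gene_set) {
  gs <- intersect(gene_set, intersect(colnames(norm_a), colnames(norm_b)))
  assert_that(length(gs) > 0, "gene set disjoint from the matrices")
  mu_a <- Matrix::colMeans(norm_a[, gs, drop = FALSE])
  mu_b <- Matrix::colMeans(norm_b[, gs, drop = FALSE])
  diffs <- mu_b - mu_a
  p <- if (all(diffs == 0)) 1 else
    suppressWarnings(wilcox.test(mu_b, mu_a, paired = TRUE,
                                 exact = FALSE)$p.value)
  list(delta = mean(diffs), p = p, n_genes = length(gs))
}
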