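# Cancer-cell-fraction estimation, multi-sample binomial-mixture clone
# clustering with BIC model selection, exhaustive sum-rule clone-tree
# enumeration, and fishplot-ready export.

#' Cancer cell fraction from VAF, purity and local copy number
#'
#' ccf = vaf * (purity * copy_number + (1 - purity) * 2) /
#' (purity * multiplicity), clipped to `[0, 1]`.
#'
#' @param vaf variant allele frequency in `[0, 1]`.
#' @param purity tumor purity in `(0, 1]`.
#' @param copy_number local total copy number in the tumor (>= 1).
#' @param multiplicity mutation copies per tumor cell (>= 1, default 1).
#' @return ccf in `[0, 1]` (vectorized).
#' @export
compute_ccf <- function(vaf, purity, copy_number = 2, multiplicity = 1) {
  assert_that(all(purity > 0 & purity <= 1),
              "purity must lie in (0, 1]")
  assert_that(all(vaf >= 0 & vaf <= 1), "vaf must lie in [0, 1]")
  assert_that(all(copy_number >= 1), "copy_number must be >= 1")
  assert_that(all(multiplicity >= 1), "multiplicity must be >= 1")
  ccf <- vaf * (purity * copy_number + (1 - purity) * 2) /
    (purity * multiplicity)
  pmin(pmax(ccf, 0), 1)
}

#' Estimate mutation multiplicity
#'
#' round(vaf * copy_number / purity) clipped to `[1, copy_number]`.
#'
#' @inheritParams compute_ccf
#' @return integer multiplicity estimate.
#' @export
estimate_multiplicity <- function(vaf, purity, copy_number = 2) {
  m <- round(vaf * copy_number / purity)
  pmin(pmax(m, 1), copy_number)
}

# Expected VAF for a clipped candidate CCF.
.vaf_factor <- function(purity, copy_number, multiplicity) {
  purity * multiplicity / (purity * copy_number + (1 - purity) * 2)
}

#' Cluster variants into clones by a multi-sample binomial mixture
#'
#' Variants share a cluster when their per-sample cancer cell fractions
#' coincide. Emissions are binomial: for variant i in cluster k and
#' sample s, `alt[i,s] ~ Binomial(depth[i,s], phi[k,s] * f[i,s])` with
#' `f` the purity/copy-number VAF factor of [compute_ccf()]. Fitted by EM
#' with kmeans-on-naive-CCF initialization plus random restarts; the
#' number of clusters is chosen by BIC over `1..k_max`. Deterministic
#' given `seed`.
#'
#' @param alt,depth variants x samples matrices of alt and total read
#'   counts.
#' @param purity per-sample purity vector.
#' @param copy_number variants x samples matrix (or scalar) of local copy
#'   number (default 2).
#' @param multiplicity scalar or matrix (default 1).
#' @param k_max largest number of clusters tried (default 6).
#' @param n_restarts random EM restarts per K beyond the kmeans start.
#' @param seed integer seed.
#' @param max_iter,tol EM controls.
#' @return list of class `clone_clusters`: `assignment` (per-variant
#'   cluster), `ccf` (clusters x samples), `size`, `k`, `bic` (per K),
#'   `loglik`, `loglik_trace` (of the winning fit).
#' @export
cluster_ccf <- function(alt, depth, purity, copy_number = 2,
                        multiplicity = 1, k_max = 6, n_restarts = 5,
                        seed = 1L, max_iter = 200, tol = 1e-8) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt); s <- ncol(alt)
  assert_that(n >= 2, "need at least 2 variants")
  assert_that(length(purity) == s, "purity must match the sample axis")
  fac <- .vaf_factor(matrix(purity, n, s, byrow = TRUE),
                     copy_number, multiplicity)
  naive <- pmin(pmax(ifelse(depth > 0, alt / depth, NA) / fac, 0), 1)
  naive[is.na(naive)] <- 0

  loglik_fun <- function(phi, gamma = NULL) {
    # phi: k x s; returns per-variant-per-cluster log-likelihood matrix
    k <- nrow(phi)
    ll <- matrix(0, n, k)
    for (j in seq_len(k)) {
      p <- sweep(fac, 2, rep(1, s), "*") *
        matrix(phi[j, ], n, s, byrow = TRUE)
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      ll[, j] <- rowSums(dbinom(alt, depth, p, log = TRUE))
    }
    ll
  }

  run_em <- function(phi0, pi0) {
    k <- nrow(phi0)
    phi <- phi0; pival <- pi0
    trace <- numeric(0)
    ll_total <- -Inf
    for (it in seq_len(max_iter)) {
      ll <- loglik_fun(phi)
      ll_w <- sweep(ll, 2, log(pmax(pival, 1e-12)), "+")
      m <- matrixStats::rowMaxs(ll_w)
      lse <- m + log(rowSums(exp(ll_w - m)))
      new_total <- sum(lse)
      gamma <- exp(ll_w - lse)
      pival <- colMeans(gamma)
      for (j in seq_len(k)) {
        num <- colSums(gamma[, j] * alt)
        den <- colSums(gamma[, j] * depth * fac)
        phi[j, ] <- pmin(pmax(num / pmax(den, 1e-12), 0), 1)
      }
      trace <- c(trace, new_total)
      if (is.finite(ll_total) && abs(new_total - ll_total) <
            tol * (abs(ll_total) + 1)) {
        ll_total <- new_total
        break
      }
      ll_total <- new_total
    }
    list(phi = phi, pi = pival, loglik = ll_total, trace = trace,
         gamma = gamma)
  }

  fits <- list()
  bic <- setNames(numeric(k_max), as.character(seq_len(k_max)))
  for (k in seq_len(k_max)) {
    starts <- list()
    if (k == 1) {
      starts[[1]] <- list(phi = matrix(colMeans(naive), 1, s),
                          pi = 1)
    } else {
      km <- tryCatch(
        with_seed(derive_seed(seed, 300L + k),
                  kmeans(naive, centers = min(k, n), nstart = 5)),
        error = function(e) NULL)
      phi0 <- if (is.null(km)) {
        with_seed(derive_seed(seed, 300L + k), matrix(runif(k * s), k, s))
      } else km$centers
      if (nrow(phi0) < k)
        phi0 <- rbind(phi0, matrix(runif((k - nrow(phi0)) * s), ncol = s))
      starts[[1]] <- list(phi = pmin(pmax(phi0, 0.01), 1),
                          pi = rep(1 / k, k))
      for (r in seq_len(n_restarts)) {
        starts[[r + 1]] <- with_seed(derive_seed(seed, 400L + 10L * k + r),
          list(phi = matrix(runif(k * s), k, s), pi = rep(1 / k, k)))
      }
    }
    best <- NULL
    for (st in starts) {
      fit <- run_em(st$phi, st$pi)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    n_par <- k * s + (k - 1)
    bic[k] <- -2 * best$loglik + n_par * log(n)
    fits[[k]] <- best
  }
  k_star <- as.integer(which.min(bic))
  fit <- fits[[k_star]]
  assign <- max.col(fit$gamma, ties.method = "first")
  # drop empty clusters and relabel by decreasing mean CCF in sample 1
  used <- sort(unique(assign))
  phi <- fit$phi[used, , drop = FALSE]
  assign <- match(assign, used)
  ord <- order(phi[, 1], decreasing = TRUE)
  phi <- phi[ord, , drop = FALSE]
  assign <- match(assign, ord)
  rownames(phi) <- paste0("clone", seq_len(nrow(phi)))
  colnames(phi) <- colnames(alt) %||% paste0("S", seq_len(s))
  structure(list(assignment = assign, ccf = phi,
                 size = tabulate(assign, nrow(phi)),
                 k = nrow(phi), bic = bic, loglik = fit$loglik,
                 loglik_trace = fit$trace),
            class = "clone_clusters")
}

# Is parent vector (root has parent 0) a tree rooted at `root`?
.is_tree <- function(parent, root) {
  k <- length(parent)
  for (v in seq_len(k)) {
    seen <- logical(k)
    u <- v
    while (u != root) {
      if (seen[u]) return(FALSE)
      seen[u] <- TRUE
      u <- parent[u]
      if (u == 0L) return(FALSE)
    }
  }
  TRUE
}

# Sum-rule validity and slack of one parent vector given ccf (k x s).
# Comparisons carry a fixed 1e-9 numerical guard so that boundary cases
# (sums landing exactly on epsilon) do not depend on floating-point
# formulation.
.tree_check <- function(parent, ccf, epsilon) {
  k <- nrow(ccf)
  tol <- 1e-9
  ok <- TRUE
  slack <- 0
  for (v in seq_len(k)) {
    ch <- which(parent == v)
    if (length(ch)) {
      deficit <- ccf[v, ] - colSums(ccf[ch, , drop = FALSE])
      if (any(deficit < -epsilon - tol)) ok <- FALSE
      slack <- slack + sum(pmax(deficit, 0))
    }
    if (parent[v] != 0L) {
      if (any(ccf[v, ] > ccf[parent[v], ] + epsilon + tol)) ok <- FALSE
    }
  }
  list(ok = ok, slack = slack)
}

#' Enumerate clone trees satisfying the sum rule
#'
#' Exhaustively enumerates rooted trees over the clusters (root = founder
#' = the cluster with the highest mean CCF in the earliest sample, ties
#' broken by cluster size) and keeps those where, in every sample, each
#' node's CCF plus `epsilon` is at least the sum of its children's CCFs
#' and no child exceeds its parent's CCF by more than `epsilon`.
#' Survivors are ranked by ascending total residual slack (the unexplained
#' CCF summed over internal nodes and samples), so the tightest-fitting
#' topology ranks first.
#'
#' @param clusters a `clone_clusters` object or a clusters x samples CCF
#'   matrix.
#' @param epsilon sum-rule tolerance (default 0.05).
#' @param sizes optional cluster sizes for the founder tie-break.
#' @param max_clusters enumeration guard (default 10).
#' @return list of class `clone_trees`: `trees` (list of parent vectors,
#'   root entry 0), `slack` (per tree), `founder`, `ccf`; empty `trees`
#'   with a `violations` report when nothing is valid.
#' @export
enumerate_trees <- function(clusters, epsilon = 0.05, sizes = NULL,
                            max_clusters = 10) {
  ccf <- if (inherits(clusters, "clone_clusters")) clusters$ccf
         else as.matrix(clusters)
  if (is.null(sizes) && inherits(clusters, "clone_clusters"))
    sizes <- clusters$size
  k <- nrow(ccf)
  assert_that(k <= max_clusters,
              "too many clusters for exhaustive enumeration")
  if (is.null(sizes)) sizes <- rep(1L, k)
  founder <- order(-ccf[, 1], -sizes)[1]
  if (k == 1) {
    return(structure(list(trees = list(setNames(0L, rownames(ccf))),
                          slack = 0, founder = founder, ccf = ccf),
                     class = "clone_trees"))
  }
  others <- setdiff(seq_len(k), founder)
  choices <- rep(list(seq_len(k)), length(others))
  grid <- do.call(expand.grid, choices)
  trees <- list(); slack <- numeric(0)
  violations <- 0L
  for (r in seq_len(nrow(grid))) {
    parent <- integer(k)
    parent[others] <- unlist(grid[r, ])
    if (any(parent[others] == others)) next
    if (!.is_tree(parent, founder)) next
    chk <- .tree_check(parent, ccf, epsilon)
    if (chk$ok) {
      names(parent) <- rownames(ccf)
      trees[[length(trees) + 1]] <- parent
      slack <- c(slack, chk$slack)
    } else {
      violations <- violations + 1L
    }
  }
  ord <- order(slack)
  structure(list(trees = trees[ord], slack = slack[ord],
                 founder = founder, ccf = ccf,
                 n_invalid = violations),
            class = "clone_trees")
}

#' @export
print.clone_trees <- function(x, ...) {
  cat(sprintf("<clone_trees> %d valid topolog%s over %d clone(s)\n",
              length(x$trees), if (length(x$trees) == 1) "y" else "ies",
              nrow(x$ccf)))
  invisible(x)
}

#' Render a clone tree as a Newick-like string
#'
#' @param parent named parent vector (root entry 0).
#' @return a Newick string.
#' @export
tree_newick <- function(parent) {
  labs <- names(parent) %||% as.character(seq_along(parent))
  build <- function(v) {
    ch <- which(parent == v)
    if (!length(ch)) return(labs[v])
    paste0("(", paste(vapply(ch, build, ""), collapse = ","), ")", labs[v])
  }
  paste0(build(which(parent == 0L)), ";")
}

#' Export nested clone fractions for a fish plot
#'
#' For each timepoint and clone the exported fraction is the clone's CCF
#' (which, by the sum rule, already includes all descendants). The table
#' is validated against the sum rule at tolerance `epsilon`.
#'
#' @param parent named parent vector (root entry 0).
#' @param ccf clones x timepoints CCF matrix.
#' @param timepoints optional timepoint labels.
#' @param epsilon tolerance (default 0.05).
#' @return data.frame with `clone`, `parent`, one column per timepoint
#'   (nested fractions in percent).
#' @export
export_fishplot <- function(parent, ccf, timepoints = NULL,
                            epsilon = 0.05) {
  ccf <- as.matrix(ccf)
  k <- nrow(ccf)
  chk <- .tree_check(parent, ccf, epsilon)
  assert_that(chk$ok, "clone fractions violate the sum rule beyond epsilon")
  if (is.null(timepoints))
    timepoints <- colnames(ccf) %||% paste0("T", seq_len(ncol(ccf)))
  out <- data.frame(clone = rownames(ccf) %||% paste0("clone", seq_len(k)),
                    parent = ifelse(parent == 0L, "0",
                                    (rownames(ccf) %||%
                                       paste0("clone", seq_len(k)))[parent]),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(ccf))) out[[timepoints[j]]] <- 100 * ccf[, j]
  out
}
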