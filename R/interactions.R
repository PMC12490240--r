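# Ligand-receptor interaction scoring between annotated cell types with a
# label-permutation null, and the downstream significance/expression
# filters.

#' Ligand-receptor mean statistic and expressed fractions
#'
#' The statistic is the average of the mean ligand expression in the
#' sender type and the mean receptor expression in the receiver type.
#' For multi-subunit complexes, a complex's per-type expression is the
#' minimum over subunit means, and the expressed fraction is the minimum
#' over subunits of the fraction of cells with a raw count above 0.
#'
#' @param norm cells x genes normalized matrix.
#' @param counts cells x genes raw counts (for expressed fractions); may
#'   be the same matrix when raw counts are unavailable.
#' @param types per-cell type labels.
#' @param ligand,receptor character vectors of subunit gene symbols.
#' @param sender,receiver type labels (must occur in `types`).
#' @return list with `statistic`, `ligand_mean`, `receptor_mean`,
#'   `ligand_fraction`, `receptor_fraction`; `NULL` when any component
#'   gene is absent from the matrix (the pair is skipped with a message).
#' @export
lr_statistic <- function(norm, counts, types, ligand, receptor,
                         sender, receiver) {
  assert_that(sender %in% types, "sender type absent")
  assert_that(receiver %in% types, "receiver type absent")
  if (!all(c(ligand, receptor) %in% colnames(norm))) {
    message("pair skipped: component gene(s) absent from the matrix")
    return(NULL)
  }
  s_idx <- which(types == sender)
  r_idx <- which(types == receiver)
  lig_mean <- min(Matrix::colMeans(norm[s_idx, ligand, drop = FALSE]))
  rec_mean <- min(Matrix::colMeans(norm[r_idx, receptor, drop = FALSE]))
  lig_frac <- min(Matrix::colMeans(counts[s_idx, ligand, drop = FALSE] > 0))
  rec_frac <- min(Matrix::colMeans(counts[r_idx, receptor, drop = FALSE] > 0))
  list(statistic = (lig_mean + rec_mean) / 2,
       ligand_mean = lig_mean, receptor_mean = rec_mean,
       ligand_fraction = lig_frac, receptor_fraction = rec_frac)
}

#' Permutation test for a ligand-receptor interaction
#'
#' The null distribution shuffles the cell-type labels across all cells;
#' p = (1 + number of null statistics >= observed) / (1 + n_perm), so p
#' is never 0. Deterministic given `seed`.
#'
#' @inheritParams lr_statistic
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return list with `p`, `observed`, and the `lr_statistic` components.
#' @export
permutation_test <- function(norm, counts, types, ligand, receptor,
                             sender, receiver, n_perm = 1000, seed = 1L) {
  assert_that(n_perm >= 100, "need at least 100 permutations")
  obs <- lr_statistic(norm, counts, types, ligand, receptor,
                      sender, receiver)
  if (is.null(obs)) return(NULL)
  lig <- as.matrix(norm[, ligand, drop = FALSE])
  rec <- as.matrix(norm[, receptor, drop = FALSE])
  n <- length(types)
  null_stat <- with_seed(derive_seed(seed, 11L), vapply(
    seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      s_idx <- perm[types == sender]
      r_idx <- perm[types == receiver]
      (min(colMeans(lig[s_idx, , drop = FALSE])) +
         min(colMeans(rec[r_idx, , drop = FALSE]))) / 2
    }, 0))
  p <- (1 + sum(null_stat >= obs$statistic)) / (1 + n_perm)
  c(list(p = p, observed = obs$statistic), obs[-1])
}

#' Score a panel of ligand-receptor pairs between type pairs
#'
#' @param norm,counts,types as in [lr_statistic()].
#' @param pairs data.frame with columns `pair`, `ligand`, `receptor`
#'   (subunits separated by `+`), and optionally `annotation`.
#' @param senders,receivers type labels to cross (defaults: all types).
#' @param n_perm,seed permutation controls.
#' @return data.frame with one row per (pair, sender, receiver):
#'   statistic, p, expressed fractions, annotation.
#' @export
score_interactions <- function(norm, counts, types, pairs,
                               senders = NULL, receivers = NULL,
                               n_perm = 1000, seed = 1L) {
  senders <- senders %||% sort(unique(types))
  receivers <- receivers %||% sort(unique(types))
  out <- NULL
  for (i in seq_len(nrow(pairs))) {
    lig <- strsplit(pairs$ligand[i], "+", fixed = TRUE)[[1]]
    rec <- strsplit(pairs$receptor[i], "+", fixed = TRUE)[[1]]
    for (s in senders) for (r in receivers) {
      if (s == r) next
      res <- permutation_test(norm, counts, types, lig, rec, s, r,
                              n_perm = n_perm,
                              seed = derive_seed(seed, 17L * i) + i)
      if (is.null(res)) next
      out <- rbind(out, data.frame(
        pair = pairs$pair[i], sender = s, receiver = r,
        statistic = res$observed, p = res$p,
        ligand_fraction = res$ligand_fraction,
        receptor_fraction = res$receptor_fraction,
        annotation = pairs$annotation[i] %||% NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Filter interaction results to the reported set
#'
#' Keeps interactions with p < `max_p` (default 0.05), both expressed
#' fractions > `min_fraction` (default 0.10), and the pair present on a
#' curated immune-related list. An empty curated list filters on p and
#' fractions only, with a warning.
#'
#' @param results output of [score_interactions()].
#' @param curated character vector of curated pair ids (matching
#'   `results$pair`).
#' @param max_p,min_fraction thresholds (0.05; 0.10; both strict).
#' @return the filtered results data.frame.
#' @export
filter_interactions <- function(results, curated = character(),
                                max_p = 0.05, min_fraction = 0.10) {
  keep <- results$p < max_p &
    results$ligand_fraction > min_fraction &
    results$receptor_fraction > min_fraction
  if (length(curated) == 0) {
    warning("empty curated list; filtering on p and fractions only")
  } else {
    keep <- keep & results$pair %in% curated
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
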