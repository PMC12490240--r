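# Between-sample similarity index from shared-subcluster composition.

#' Composition vectors over a joint clustering
#'
#' Fractional abundance of each transcriptional subcluster per sample,
#' from a joint (pooled) clustering of the samples being compared.
#'
#' @param cluster per-cell cluster labels.
#' @param sample per-cell sample ids.
#' @return samples x clusters matrix of fractions (rows sum to 1).
#' @export
composition_vectors <- function(cluster, sample) {
  tab <- table(sample, cluster)
  sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
}

#' Similarity index between two composition vectors
#'
#' SI = sum over subclusters of the minimum fractional abundance between
#' the two samples; 1 means identical composition, 0 disjoint.
#'
#' @param a,b non-negative composition vectors over the same subcluster
#'   index set, each summing to 1 (within 1e-6).
#' @return SI in `[0, 1]`.
#' @export
similarity_index <- function(a, b) {
  assert_that(length(a) == length(b),
              "composition vectors must share the subcluster index set")
  if (!is.null(names(a)) && !is.null(names(b)))
    assert_that(all(names(a) == names(b)),
                "composition vectors must share the subcluster index set")
  assert_that(all(a >= 0) && all(b >= 0), "fractions must be non-negative")
  assert_that(abs(sum(a) - 1) < 1e-6 && abs(sum(b) - 1) < 1e-6,
              "fractions must sum to 1")
  sum(pmin(a, b))
}

#' Classify a similarity index into the published bands
#'
#' Below 0.35 is low, above 0.67 high, otherwise intermediate (both edges
#' strict, so 0.35 and 0.67 themselves are intermediate).
#'
#' @param si similarity index in `[0, 1]` (vectorized).
#' @return character vector of `low`/`intermediate`/`high`.
#' @export
classify_si <- function(si) {
  assert_that(all(si >= 0 & si <= 1), "SI must lie in [0,1]")
  ifelse(si < 0.35, "low", ifelse(si > 0.67, "high", "intermediate"))
}

#' Pairwise similarity matrix for a set of samples
#'
#' @param cluster,sample per-cell joint cluster labels and sample ids.
#' @return list with `si` (symmetric sample x sample matrix) and `band`
#'   (matching band labels).
#' @export
similarity_matrix <- function(cluster, sample) {
  comp <- composition_vectors(cluster, sample)
  n <- nrow(comp)
  si <- matrix(1, n, n, dimnames = list(rownames(comp), rownames(comp)))
  for (i in seq_len(n)) for (j in seq_len(n))
    si[i, j] <- similarity_index(comp[i, ], comp[j, ])
  band <- matrix(classify_si(si), n, n, dimnames = dimnames(si))
  list(si = si, band = band, composition = comp)
}
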