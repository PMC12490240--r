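# Clonotype assignment, dominance calling, somatic hypermutation counting
# against the germline IGHV, and the kappa/lambda light-chain ratio.

#' Filter AIRR-style rearrangements to paired-chain cells
#'
#' Keeps contigs flagged productive, complete (full length) and
#' high-confidence, then keeps cells with exactly one retained heavy (IGH)
#' and exactly one retained light (IGK or IGL) chain. Cells with two
#' retained productive heavy chains are ambiguous and excluded. Rows with a
#' malformed locus are rejected (their count is reported via a message).
#'
#' @param rearr data.frame with columns `cell_id`, `locus`, `v_call`,
#'   `j_call`, `cdr3_aa`, `sequence`, `productive`, `complete_vdj`,
#'   `high_confidence` (and optionally `sample`).
#' @return data.frame with one row per retained cell: `cell_id`, `sample`,
#'   heavy_* and light_* columns.
#' @export
filter_rearrangements <- function(rearr) {
  if (is.null(rearr) || nrow(rearr) == 0) {
    return(data.frame(cell_id = character(), sample = character(),
                      heavy_v = character(), heavy_j = character(),
                      heavy_cdr3 = character(), heavy_sequence = character(),
                      light_locus = character(), light_v = character(),
                      light_j = character(), light_cdr3 = character(),
                      stringsAsFactors = FALSE))
  }
  bad_locus <- !(rearr$locus %in% c("IGH", "IGK", "IGL"))
  if (any(bad_locus))
    message(sum(bad_locus), " rearrangement row(s) with malformed locus rejected")
  r <- rearr[!bad_locus &
               rearr$productive & rearr$complete_vdj &
               rearr$high_confidence, , drop = FALSE]
  if (nrow(r) == 0) return(filter_rearrangements(NULL))
  if (is.null(r$sample)) r$sample <- "sample1"
  heavy <- r[r$locus == "IGH", , drop = FALSE]
  light <- r[r$locus %in% c("IGK", "IGL"), , drop = FALSE]
  h1 <- names(which(table(heavy$cell_id) == 1))
  l1 <- names(which(table(light$cell_id) == 1))
  keep <- intersect(h1, l1)
  heavy <- heavy[match(keep, heavy$cell_id), , drop = FALSE]
  light <- light[match(keep, light$cell_id), , drop = FALSE]
  out <- data.frame(cell_id = keep, sample = heavy$sample,
                    heavy_v = heavy$v_call, heavy_j = heavy$j_call,
                    heavy_cdr3 = heavy$cdr3_aa,
                    heavy_sequence = heavy$sequence,
                    light_locus = light$locus, light_v = light$v_call,
                    light_j = light$j_call, light_cdr3 = light$cdr3_aa,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign clonotypes and call per-sample dominance
#'
#' Cells are grouped by exact match on the six-field key (heavy V, heavy J,
#' heavy CDR3 peptide, light V, light J, light CDR3 peptide). A clonotype
#' is dominant in a sample when its fraction of that sample's BCR-assigned
#' cells is strictly greater than `dominance_threshold` (default 0.05);
#' cells of non-dominant clonotypes are polyclonal. The denominator is the
#' number of BCR-assigned cells by default; supply `cells_per_sample` to
#' use total cell counts instead.
#'
#' @param paired output of [filter_rearrangements()].
#' @param cells_per_sample optional named vector of total cells per sample
#'   used as the dominance denominator instead of BCR-assigned cells.
#' @param dominance_threshold strict dominance threshold (default 0.05).
#' @return list of class `clonotype_set`: `clonotypes` (data.frame with
#'   key, per-sample counts/fractions/dominance), `cell_assignment`
#'   (per-cell clonotype key and dominance flag).
#' @export
assign_clonotypes <- function(paired, cells_per_sample = NULL,
                              dominance_threshold = 0.05) {
  key <- paste(paired$heavy_v, paired$heavy_j, paired$heavy_cdr3,
               paired$light_v, paired$light_j, paired$light_cdr3,
               sep = "|")
  samples <- unique(paired$sample)
  denom <- vapply(samples, function(s) {
    if (!is.null(cells_per_sample)) as.numeric(cells_per_sample[[s]])
    else sum(paired$sample == s)
  }, 0)
  names(denom) <- samples
  ukey <- unique(key)
  counts <- table(factor(key, levels = ukey),
                  factor(paired$sample, levels = samples))
  fracs <- sweep(unclass(counts), 2, pmax(denom[samples], 1), "/")
  fracs[, denom[samples] == 0] <- 0
  dom <- fracs > dominance_threshold
  tab <- data.frame(key = ukey, n_cells = as.integer(rowSums(counts)),
                    stringsAsFactors = FALSE)
  for (s in samples) {
    tab[[paste0("n_", s)]] <- as.integer(counts[, s])
    tab[[paste0("frac_", s)]] <- fracs[, s]
    tab[[paste0("dominant_", s)]] <- dom[, s]
  }
  tab$dominant <- rowSums(dom) > 0
  cell_assignment <- data.frame(
    cell_id = paired$cell_id, sample = paired$sample, clonotype = key,
    dominant_in_sample = dom[cbind(match(key, ukey),
                                   match(paired$sample, samples))],
    stringsAsFactors = FALSE)
  cell_assignment$status <- ifelse(cell_assignment$dominant_in_sample,
                                   "clonal", "polyclonal")
  structure(list(clonotypes = tab, cell_assignment = cell_assignment,
                 dominance_threshold = dominance_threshold),
            class = "clonotype_set")
}

#' Count somatic hypermutations against a germline IGHV
#'
#' Position-wise comparison of the observed IGHV nucleotide sequence with
#' the germline. Positions where either sequence is `N` are excluded from
#' both the mismatch count and the compared length. When lengths differ,
#' the shorter sequence is slid gap-free along the longer one and the
#' offset maximizing identity is used; only the overlapping window is
#' compared.
#'
#' @param observed,germline uppercase ACGTN nucleotide strings.
#' @return list with `shm_count` and `shm_rate` (count / compared length).
#' @export
count_shm <- function(observed, germline) {
  assert_that(is.character(observed) && nzchar(observed),
              "observed sequence must be a non-empty string")
  assert_that(is.character(germline) && nzchar(germline),
              "germline sequence must be a non-empty string")
  a <- strsplit(observed, "")[[1]]
  b <- strsplit(germline, "")[[1]]
  if (length(a) != length(b)) {
    if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
    best <- c(mis = Inf, cmp = 1)
    for (off in 0:(length(b) - length(a))) {
      w <- b[(off + 1):(off + length(a))]
      valid <- a != "N" & w != "N"
      mis <- sum(a[valid] != w[valid])
      if (mis < best["mis"]) best <- c(mis = mis, cmp = sum(valid))
    }
    return(list(shm_count = as.integer(best[["mis"]]),
                shm_rate = best[["mis"]] / best[["cmp"]]))
  }
  valid <- a != "N" & b != "N"
  cnt <- sum(a[valid] != b[valid])
  list(shm_count = as.integer(cnt), shm_rate = cnt / sum(valid))
}

#' Kappa/lambda light-chain ratio
#'
#' ratio = IGKC / (IGKC + max over present IGLC genes). Values near 1
#' indicate kappa restriction, near 0 lambda restriction. When IGKC and
#' every IGLC value are zero the ratio is undefined and `NA` is returned.
#'
#' @param igkc numeric vector (per cell or per cluster) of IGKC expression.
#' @param iglc matrix or vector of IGLC1..IGLC7 expression (columns =
#'   IGLC genes when a matrix; missing genes are simply absent).
#' @return numeric vector of ratios in `[0, 1]` with `NA` where undefined.
#' @export
light_chain_ratio <- function(igkc, iglc) {
  iglc <- as.matrix(iglc)
  if (nrow(iglc) != length(igkc) && ncol(iglc) == length(igkc))
    iglc <- t(iglc)
  max_l <- if (ncol(iglc) == 0) rep(0, length(igkc))
           else matrixStats::rowMaxs(iglc)
  denom <- igkc + max_l
  ifelse(denom > 0, igkc / denom, NA_real_)
}

#' Per-cell light-chain ratio from a count matrix
#'
#' Convenience wrapper extracting IGKC and IGLC1..IGLC7 columns by symbol.
#' Raw counts are used; at cluster level, counts are summed within the
#' cluster before the ratio is taken.
#'
#' @param x a [cell_matrix()] or counts matrix with gene-symbol colnames.
#' @param cluster optional per-cell cluster labels: when given, returns
#'   one ratio per cluster from summed counts.
#' @return numeric vector of ratios (per cell, or per cluster).
#' @export
light_chain_ratio_matrix <- function(x, cluster = NULL) {
  cm <- if (inherits(x, "cell_matrix")) x$counts else x
  iglc_genes <- intersect(paste0("IGLC", 1:7), colnames(cm))
  assert_that("IGKC" %in% colnames(cm), "IGKC not found in matrix")
  igkc <- as.numeric(cm[, "IGKC"])
  iglc <- as.matrix(cm[, iglc_genes, drop = FALSE])
  if (is.null(cluster)) return(light_chain_ratio(igkc, iglc))
  cl <- sort(unique(cluster))
  igkc_c <- vapply(cl, function(g) sum(igkc[cluster == g]), 0)
  iglc_c <- t(vapply(cl, function(g)
    colSums(iglc[cluster == g, , drop = FALSE]),
    numeric(ncol(iglc))))
  setNames(light_chain_ratio(igkc_c, iglc_c), as.character(cl))
}
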