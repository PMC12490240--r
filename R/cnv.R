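# Reference-relative copy-number inference from expression along genome
# order, the per-cell CNV score, segment detection, and concordance with
# bulk WGS segments.

.chrom_order <- function(chrom) {
  lev <- unique(chrom)
  num <- suppressWarnings(as.integer(sub("^chr", "", lev)))
  lev[order(is.na(num), num, lev)]
}

#' Infer a per-cell relative copy-number profile from expression
#'
#' For every gene the reference mean (over `reference_cells`, in log
#' space) is subtracted; residuals are clipped at plus/minus 3 reference
#' standard deviations (pooled over genes), smoothed along genome order by
#' a centered moving average of `window` genes within each chromosome
#' (shrinking at chromosome edges), re-centered per cell at its median,
#' and exponentiated to a ratio around 1.0. Immunoglobulin genes are
#' excluded before smoothing (clonal immunoglobulin expression mimics
#' copy-number change); genes without a chromosome/start annotation are
#' excluded with a warning.
#'
#' @param norm cells x genes normalized (log) matrix.
#' @param reference_cells index vector over rows of `norm` defining the
#'   diploid reference (at least 2 cells).
#' @param gene_meta data.frame with `symbol`, `chrom`, `start` and
#'   (optionally) `immunoglobulin` for the columns of `norm`.
#' @param window odd moving-average width in genes (default 51);
#'   `window = 1` disables smoothing.
#' @param denoise when `TRUE` (default), smoothed residuals within
#'   `noise_mult` standard deviations of the reference cells' own smoothed
#'   residuals are set to 0 (ratio 1), so that only departures exceeding
#'   the reference noise floor remain — the analogue of inferCNV's
#'   denoising step. Set `FALSE` for raw smoothed ratios.
#' @param noise_mult multiplier on the reference smoothed-residual SD
#'   (default 1.5).
#' @return list of class `cnv_profile`: `ratio` (cells x genes matrix of
#'   smoothed ratios, genes in genome order), `gene_meta` (reordered),
#'   `window`, `reference_cells`.
#' @export
infer_cnv_profile <- function(norm, reference_cells, gene_meta,
                              window = 51, denoise = TRUE,
                              noise_mult = 1.5) {
  assert_that(window >= 1 && window %% 2 == 1, "window must be odd, >= 1")
  ref_idx <- seq_len(nrow(norm))[reference_cells]
  assert_that(length(ref_idx) >= 2, "need at least 2 reference cells")
  g <- gene_meta
  unplaced <- is.na(g$chrom) | is.na(g$start)
  if (any(unplaced)) warning(sum(unplaced), " unplaced gene(s) excluded")
  ig <- if (!is.null(g$immunoglobulin)) g$immunoglobulin else
    startsWith(g$symbol, "IGK") | startsWith(g$symbol, "IGL") |
    startsWith(g$symbol, "IGH")
  keep <- !unplaced & !ig
  g <- g[keep, , drop = FALSE]
  m <- as.matrix(norm[, keep, drop = FALSE])
  ord <- order(match(g$chrom, .chrom_order(g$chrom)), g$start)
  g <- g[ord, , drop = FALSE]
  m <- m[, ord, drop = FALSE]

  ref_mean <- colMeans(m[ref_idx, , drop = FALSE])
  ref_sd <- matrixStats::colSds(m[ref_idx, , drop = FALSE])
  clip <- 3 * mean(ref_sd)
  rel <- sweep(m, 2, ref_mean)
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip

  if (window > 1) {
    idx_by_chrom <- split(seq_len(ncol(rel)), g$chrom)[
      .chrom_order(g$chrom)]
    half <- (window - 1) / 2
    for (idx in idx_by_chrom) {
      sub <- rel[, idx, drop = FALSE]
      cs <- cbind(0, t(apply(sub, 1, cumsum)))
      n <- length(idx)
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      rel[, idx] <- (cs[, hi + 1L, drop = FALSE] -
                       cs[, lo, drop = FALSE]) /
        rep(hi - lo + 1L, each = nrow(rel))
    }
  }
  rel <- rel - matrixStats::rowMedians(rel)
  if (denoise) {
    ref_noise <- sd(rel[ref_idx, , drop = FALSE])
    rel[abs(rel) <= noise_mult * ref_noise] <- 0
  }
  ratio <- exp(rel)
  dimnames(ratio) <- list(rownames(norm), g$symbol)
  structure(list(ratio = ratio, gene_meta = g, window = window,
                 reference_cells = ref_idx),
            class = "cnv_profile")
}

#' Per-cell CNV score
#'
#' Counts, per cell, the genes whose smoothed relative copy value falls
#' strictly below `lower` (default 0.95) or strictly above `upper`
#' (default 1.05), genome-wide or restricted to a genomic region.
#'
#' @param profile a `cnv_profile` from [infer_cnv_profile()].
#' @param region optional list/vector with `chrom`, `start`, `end`
#'   (1-based inclusive) restricting the count.
#' @param lower,upper the copy-ratio band (defaults 0.95 and 1.05).
#' @return named integer vector of per-cell scores.
#' @export
cnv_score <- function(profile, region = NULL, lower = 0.95, upper = 1.05) {
  stopifnot(inherits(profile, "cnv_profile"))
  r <- profile$ratio
  if (!is.null(region)) {
    g <- profile$gene_meta
    sel <- g$chrom == region[["chrom"]] &
      g$start >= as.numeric(region[["start"]]) &
      g$start <= as.numeric(region[["end"]])
    if (!any(sel)) {
      warning("region contains no genes; score is 0")
      return(setNames(rep(0L, nrow(r)), rownames(r)))
    }
    r <- r[, sel, drop = FALSE]
  }
  setNames(as.integer(rowSums(r < lower | r > upper)), rownames(r))
}

#' Detect copy-number segments from a profile
#'
#' Calls a gain/loss per gene when at least `cell_fraction` of the cells
#' fall outside the score band in the same direction (a true copy-number
#' change shifts the bulk of the tumor cells, whereas subpopulation
#' expression differences shift only a minority), then reports maximal
#' runs of at least `min_genes` consecutive same-direction genes within a
#' chromosome.
#'
#' @param profile a `cnv_profile`.
#' @param cells index over profile rows to average (default all).
#' @param min_genes minimum run length (default 30).
#' @param cell_fraction minimum fraction of cells out of band per gene
#'   (default 0.5).
#' @param lower,upper the copy-ratio band.
#' @return data.frame with `chrom`, `start`, `end`, `n_genes`,
#'   `direction`, `mean_ratio`.
#' @export
detect_cnv_segments <- function(profile, cells = NULL, min_genes = 30,
                                cell_fraction = 0.5,
                                lower = 0.95, upper = 1.05) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (is.null(cells)) cells <- seq_len(nrow(profile$ratio))
  r <- profile$ratio[cells, , drop = FALSE]
  mean_ratio <- colMeans(r)
  frac_gain <- colMeans(r > upper)
  frac_loss <- colMeans(r < lower)
  dir <- ifelse(frac_gain >= cell_fraction, 1L,
                ifelse(frac_loss >= cell_fraction, -1L, 0L))
  g <- profile$gene_meta
  out <- NULL
  for (ch in .chrom_order(g$chrom)) {
    idx <- which(g$chrom == ch)
    r <- rle(dir[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0L || r$lengths[j] < min_genes) next
      gi <- idx[starts[j]:ends[j]]
      out <- rbind(out, data.frame(
        chrom = ch, start = min(g$start[gi]), end = max(g$start[gi]),
        n_genes = length(gi),
        direction = if (r$values[j] > 0) "gain" else "loss",
        mean_ratio = mean(mean_ratio[gi]), stringsAsFactors = FALSE))
    }
  }
  out %||% data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_genes = integer(),
                      direction = character(), mean_ratio = numeric(),
                      stringsAsFactors = FALSE)
}

#' Concordance between an expression-inferred profile and bulk WGS CNVs
#'
#' Per gene, the expression direction call (gain/neutral/loss from the
#' 0.95/1.05 ratio band applied to the mean profile over `cells`) is
#' compared with the WGS call (amplified at >= 2.3 copies, deleted at
#' <= 1.7) of the segment covering the gene. Concordance is the fraction
#' of agreeing genes among genes covered by any non-neutral WGS segment.
#'
#' @param profile a `cnv_profile`.
#' @param wgs_segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and `copy_number`.
#' @param cells index over profile rows to average (default all).
#' @param lower,upper expression ratio band.
#' @param amp_cn,del_cn WGS copy-number thresholds (2.3 and 1.7).
#' @return concordance fraction in `[0, 1]`, or `NA` when no gene is
#'   covered by a non-neutral WGS segment.
#' @export
concordance_with_wgs <- function(profile, wgs_segments, cells = NULL,
                                 lower = 0.95, upper = 1.05,
                                 amp_cn = 2.3, del_cn = 1.7) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (is.null(cells)) cells <- seq_len(nrow(profile$ratio))
  mean_ratio <- colMeans(profile$ratio[cells, , drop = FALSE])
  g <- profile$gene_meta
  expr_call <- ifelse(mean_ratio > upper, 1L,
                      ifelse(mean_ratio < lower, -1L, 0L))
  wgs_call <- rep(NA_integer_, nrow(g))
  for (i in seq_len(nrow(wgs_segments))) {
    seg <- wgs_segments[i, ]
    cov <- g$chrom == seg$chrom & g$start >= seg$start & g$start <= seg$end
    call <- if (seg$copy_number >= amp_cn) 1L
            else if (seg$copy_number <= del_cn) -1L else 0L
    wgs_call[cov] <- call
  }
  sel <- !is.na(wgs_call) & wgs_call != 0L
  if (!any(sel)) return(NA_real_)
  mean(expr_call[sel] == wgs_call[sel])
}
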