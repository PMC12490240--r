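make_profile <- function(ratio, chrom = NULL, start = NULL) {
  g <- data.frame(symbol = colnames(ratio) %||%
                    sprintf("g%03d", seq_len(ncol(ratio))),
                  chrom = chrom %||% "chr1",
                  start = start %||% seq_len(ncol(ratio)) * 1000)
  structure(list(ratio = ratio, gene_meta = g, window = 1,
                 reference_cells = 1L), class = "cnv_profile")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("CNV score counts genes outside the 0.95/1.05 band exactly", {
  r <- matrix(1, 3, 50)
  expect_identical(unname(cnv_score(make_profile(r))), rep(0L, 3))
  r[1, 1:10] <- 0.90
  expect_identical(unname(cnv_score(make_profile(r))), c(10L, 0L, 0L))
  # boundary values are inside the closed band
  r[2, 1:5] <- 0.95; r[2, 6:10] <- 1.05
  expect_identical(unname(cnv_score(make_profile(r)))[2], 0L)
  # adding one more out-of-band gene never decreases the score
  r2 <- r; r2[1, 11] <- 1.2
  expect_gte(cnv_score(make_profile(r2))[1], cnv_score(make_profile(r))[1])
  # region restriction
  p <- make_profile(r)
  sc <- cnv_score(p, region = list(chrom = "chr1", start = 1, end = 5000))
  expect_identical(unname(sc[1]), 5L)
  expect_warning(cnv_score(p, region = list(chrom = "chr9", start = 1,
                                            end = 10)), "no genes")
})

test_that("reference cells profile to flat ratios near 1", {
  set.seed(5)
  counts <- matrix(rpois(200 * 400, 4), 200, 400)
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  g <- data.frame(symbol = sprintf("g%03d", 1:400),
                  chrom = rep(c("chr1", "chr2"), each = 200),
                  start = rep(seq_len(200) * 1000, 2))
  p <- infer_cnv_profile(norm, reference_cells = 1:100, gene_meta = g)
  ref_mean <- colMeans(p$ratio[1:100, ])
  expect_true(all(abs(ref_mean - 1) <= 0.02))
})

test_that("window 1 without denoising reduces to per-gene ratios", {
  set.seed(6)
  counts <- matrix(rpois(60 * 100, 5), 60, 100)
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  g <- data.frame(symbol = sprintf("g%03d", 1:100), chrom = "chr1",
                  start = seq_len(100) * 1000)
  p <- infer_cnv_profile(norm, 1:30, g, window = 1, denoise = FALSE)
  # manual recomputation of the per-gene (unsmoothed) ratio
  m <- as.matrix(norm)
  rel <- sweep(m, 2, colMeans(m[1:30, ]))
  clip <- 3 * mean(matrixStats::colSds(m[1:30, ]))
  rel <- pmin(pmax(rel, -clip), clip)
  rel <- rel - matrixStats::rowMedians(rel)
  expect_equal(unname(p$ratio), unname(exp(rel)), tolerance = 1e-12)
})

test_that("a planted gain is recovered cell-wise and segment-wise", {
  co <- tiny_cohort()
  mal <- tiny_malignant()
  meta <- mal$qc_matrix$cell_meta
  p <- mal$cnv_profile
  cfg <- co$config
  seg <- cfg$cnv_segments[[1]]  # the 2x gain
  seg_syms <- cfg$genes$symbol[seg$genes]
  in_seg <- colnames(p$ratio) %in% seg_syms
  other_seg <- cfg$genes$symbol[cfg$cnv_segments[[2]]$genes]
  outside <- !(colnames(p$ratio) %in% c(seg_syms, other_seg))
  is_mal <- meta$true_type == "malignantB" & meta$qc_class == "ok"
  inside_mean <- rowMeans(p$ratio[is_mal, in_seg, drop = FALSE])
  outside_mean <- rowMeans(p$ratio[is_mal, outside, drop = FALSE])
  expect_gte(mean(inside_mean > 1.05), 0.90)
  expect_gte(mean(outside_mean > 0.95 & outside_mean < 1.05), 0.90)
  # segment detection finds both planted segments with matching direction
  det <- detect_cnv_segments(p, cells = which(is_mal))
  expect_identical(nrow(det), 2L)
  expect_setequal(det$direction, c("gain", "loss"))
})

test_that("profiles are invariant to input gene permutation", {
  set.seed(8)
  counts <- matrix(rpois(40 * 80, 5), 40, 80)
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  g <- data.frame(symbol = sprintf("g%03d", 1:80), chrom = "chr1",
                  start = seq_len(80) * 1000)
  colnames(norm) <- g$symbol
  p1 <- infer_cnv_profile(norm, 1:20, g)
  perm <- sample(80)
  p2 <- infer_cnv_profile(norm[, perm], 1:20, g[perm, ])
  expect_equal(p1$ratio, p2$ratio)
})

test_that("immunoglobulin genes are excluded from profiles", {
  set.seed(9)
  counts <- matrix(rpois(30 * 50, 5), 30, 50)
  g <- data.frame(symbol = c("IGKC", sprintf("g%02d", 2:50)),
                  chrom = "chr2", start = seq_len(50) * 1000)
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  colnames(norm) <- g$symbol
  p <- infer_cnv_profile(norm, 1:10, g)
  expect_false("IGKC" %in% colnames(p$ratio))
})

test_that("WGS concordance is 1 for matching maps and 0 for inverted", {
  r <- matrix(1, 2, 100)
  r[, 11:30] <- 1.5
  r[, 61:80] <- 0.6
  p <- make_profile(r)
  wgs <- data.frame(chrom = "chr1",
                    start = c(11000, 61000), end = c(30000, 80000),
                    copy_number = c(4, 1))
  expect_equal(concordance_with_wgs(p, wgs), 1)
  wgs_inv <- transform(wgs, copy_number = c(1, 4))
  expect_equal(concordance_with_wgs(p, wgs_inv), 0)
  # no non-neutral overlap -> missing value
  wgs_neutral <- transform(wgs, copy_number = 2)
  expect_true(is.na(concordance_with_wgs(p, wgs_neutral)))
})

test_that("malignant CNV scores exceed normal-B scores across seeds", {
  higher <- 0L
  for (s in 1:10) {
    cfg <- sim_config(n_samples = 1, n_cells = 260, n_genes = 900,
                      cnv_segments = list(list(
                        chrom = "chr1", genes = 30:140, ratio = 1.5,
                        clones = 1:4)),
                      seed = 700 + s)
    ex <- generate_expression(cfg)
    xq <- apply_qc(ex$matrix)
    norm <- normalize_log(xq)
    meta <- xq$cell_meta
    nb <- which(meta$true_type == "normalB" & meta$qc_class == "ok")
    malc <- which(meta$true_type == "malignantB" & meta$qc_class == "ok")
    p <- infer_cnv_profile(norm, nb, xq$gene_meta)
    sc <- cnv_score(p)
    if (mean(sc[malc]) > mean(sc[nb])) higher <- higher + 1L
  }
  expect_identical(higher, 10L)
})
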