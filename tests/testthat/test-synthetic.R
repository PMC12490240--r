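test_that("generation is deterministic given config and seed", {
  cfg <- sim_config(n_samples = 1, n_cells = 120, n_genes = 600, seed = 9)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(generate_bcr(cfg)$rearrangements,
                   generate_bcr(cfg)$rearrangements)
  va <- generate_variant_tables(cfg)
  vb <- generate_variant_tables(cfg)
  expect_identical(va$caller_tables, vb$caller_tables)
  expect_identical(va$panel, vb$panel)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(mixture = c(malignantB = 0.5, normalB = 0.5,
                                      T = 0.5, NK = 0, myeloid = 0)),
               "sum to 1")
  expect_error(sim_config(ccnd1_fold = 0.5), "ccnd1_fold")
  expect_error(sim_config(n_genes = 600, cnv_segments = list(
    list(chrom = "chr1", genes = 500:900, ratio = 2, clones = 1:4))),
    "CNV segment span")
  expect_error(sim_config(clone_ccf = rbind(c(1, 1, 1), c(0.8, 0.8, 0.8),
                                            c(0.1, 0.1, 0.1),
                                            c(0.5, 0.5, 0.5))),
               "sum rule")
})

test_that("null configuration leaves CCND1 exchangeable between B subsets", {
  rejections <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_samples = 1, n_cells = 250, n_genes = 600,
                      ccnd1_fold = 1, cnv_segments = list(),
                      qc_noise = c(low_gene = 0, high_mito = 0,
                                   doublet = 0), seed = 100 + s)
    ex <- generate_expression(cfg)
    meta <- ex$matrix$cell_meta
    ccnd1 <- as.numeric(ex$matrix$counts[, "CCND1"])
    p <- wilcox.test(ccnd1[meta$true_type == "malignantB"],
                     ccnd1[meta$true_type == "normalB"],
                     exact = FALSE)$p.value
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("a planted 2x segment doubles summed malignant expression", {
  cfg <- sim_config(n_samples = 1, n_cells = 600, n_genes = 1500,
                    cnv_segments = list(list(chrom = "chr1",
                                             genes = 300:499, ratio = 2,
                                             clones = 1:4)),
                    seed = 21)
  ex <- generate_expression(cfg)
  meta <- ex$matrix$cell_meta
  seg <- 300:499
  # library-size factors share one distribution across cell types, so raw
  # mean segment sums compare directly
  segsum <- Matrix::rowSums(ex$matrix$counts[, seg])
  mal <- meta$true_type == "malignantB" & meta$qc_class == "ok"
  nb <- meta$true_type == "normalB" & meta$qc_class == "ok"
  ratio <- mean(segsum[mal]) / mean(segsum[nb])
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
})

test_that("CCND1 overexpression matches the configured fold", {
  ex <- tiny_cohort()$expression
  meta <- ex$matrix$cell_meta
  mal <- meta$true_type == "malignantB" & meta$qc_class == "ok"
  nb <- meta$true_type == "normalB" & meta$qc_class == "ok"
  fold <- mean(ex$matrix$counts[mal, "CCND1"]) /
    mean(ex$matrix$counts[nb, "CCND1"])
  expect_gt(fold, 4 * 0.8)
  expect_lt(fold, 4 * 1.25)
})

test_that("simulated counts match negative-binomial moments", {
  m <- simulate_homogeneous(800, 60, dispersion = 2, seed = 4)
  mu <- colMeans(m)
  v <- apply(m, 2, var)
  expected <- mu + mu^2 / 2
  rel_err <- abs(v - expected) / expected
  expect_lt(median(rel_err), 0.2)
})

test_that("clonotype cell counts follow binomial sampling", {
  cfg <- sim_config(
    n_samples = 1, n_cells = 1000, n_genes = 600,
    mixture = c(malignantB = 1, normalB = 0, T = 0, NK = 0, myeloid = 0),
    clone_parent = c(NA, 1L), clone_ccf = rbind(1, 0.66),
    clone_clonotype = c(1L, 2L),
    qc_noise = c(low_gene = 0, high_mito = 0, doublet = 0),
    bcr_capture = 1, seed = 31)
  bcr <- generate_bcr(cfg)
  n_ct1 <- sum(bcr$truth$true_clonotype == 1, na.rm = TRUE)
  # clonotype 1 holds the founder's exclusive fraction 0.34 of 1000 cells
  sigma <- sqrt(1000 * 0.34 * 0.66)
  expect_gt(n_ct1, 340 - 4 * sigma)
  expect_lt(n_ct1, 340 + 4 * sigma)
})

test_that("planted SHM counts are recovered from generated sequences", {
  co <- tiny_cohort()
  bcr <- co$bcr
  cfg <- co$config
  for (j in seq_along(cfg$clonotypes)) {
    cells <- bcr$truth$barcode[!is.na(bcr$truth$true_clonotype) &
                                 bcr$truth$true_clonotype == j]
    row <- bcr$rearrangements[bcr$rearrangements$cell_id == cells[1] &
                                bcr$rearrangements$locus == "IGH", ]
    res <- count_shm(row$sequence, bcr$germline_ighv)
    expect_identical(res$shm_count, cfg$clonotypes[[j]]$shm)
    if (cfg$clonotypes[[j]]$shm == 0)
      expect_identical(row$sequence, bcr$germline_ighv)
  }
})

test_that("polyclonal background clonotype keys are pairwise distinct", {
  co <- tiny_cohort()
  r <- co$bcr$rearrangements
  bg_cells <- co$bcr$truth$barcode[is.na(co$bcr$truth$true_clonotype)]
  h <- r[r$locus == "IGH" & r$cell_id %in% bg_cells, ]
  keys <- paste(h$v_call, h$j_call, h$cdr3_aa)
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("perfect callers reproduce the planted variant truth", {
  cfg <- sim_config(n_samples = 1, n_cells = 50, n_genes = 600,
                    clone_parent = c(NA), clone_ccf = cbind(1),
                    clone_clonotype = 1L, purity = 1,
                    caller_sensitivity = rep(1, 5),
                    caller_fp_rate = rep(0, 5),
                    n_artifacts = 0, n_weak_artifacts = 0, seed = 8)
  v <- generate_variant_tables(cfg)
  for (tab in v$caller_tables) {
    keys <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
    expect_setequal(keys, v$truth$variants$key)
  }
})

test_that("simulated VAF matches the binomial expectation", {
  cfg <- sim_config(n_samples = 1, n_cells = 50, n_genes = 1200,
                    clone_parent = c(NA), clone_ccf = cbind(1),
                    clone_clonotype = 1L, purity = 0.5, depth = 500,
                    n_variants_per_clone = 40,
                    n_artifacts = 0, n_weak_artifacts = 0, seed = 12)
  v <- generate_variant_tables(cfg)
  # clonal variant, purity 0.5, CN 2, multiplicity 1 -> expected VAF 0.25
  vaf <- v$pileup$alt_count / v$pileup$depth
  expect_lt(abs(mean(vaf) - 0.25), 0.01)
})

test_that("planted panel artifacts appear in the configured panel counts", {
  co <- tiny_cohort()
  art <- co$variants$truth$artifacts
  panel <- co$variants$panel
  hit <- table(paste(panel$chrom, panel$pos, panel$ref, panel$alt,
                     sep = ":"))
  expect_identical(as.integer(hit[art$key]), as.integer(art$n_panel_hit))
})

test_that("cohort files round-trip through plain-text serialization", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_samples = 1, n_cells = 80, n_genes = 600, seed = 13)
  co <- generate_cohort(cfg, outdir = dir)
  expect_true(file.exists(file.path(dir, "S01", "matrix.mtx")))
  back <- read_10x(file.path(dir, "S01"))
  expect_equal(as.matrix(back$counts),
               as.matrix(co$expression$matrix$counts),
               ignore_attr = TRUE)
  expect_identical(back$cell_meta$true_type,
                   co$expression$matrix$cell_meta$true_type)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$variants$key, co$variants$truth$variants$key)
})
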