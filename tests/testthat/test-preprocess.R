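test_that("QC cell filters apply the stated thresholds at the boundary", {
  x <- qc_matrix_fixture(detect = c(489, 490, 520))
  # +10 ribosomal genes and +1 of their overlap are detected as well:
  # cells detect `detect` + 10 ribo columns (first cells already count
  # column overlap), so compute detection from the object itself
  q <- apply_qc(x)
  det <- x$cell_meta$n_genes_detected[1:2]
  expect_true(det[1] < 500 && det[2] >= 500)
  expect_false(x$cell_meta$barcode[1] %in% q$cell_meta$barcode)
  expect_true(x$cell_meta$barcode[2] %in% q$cell_meta$barcode)
})

test_that("QC removes high-mitochondrial cells above 20 percent", {
  # two cells with identical detection; mito fractions ~25% and ~15%
  x <- qc_matrix_fixture(detect = c(550, 550),
                         mito_counts = c(60, 25), ribo_counts = 30)
  pct <- x$cell_meta$pct_mito[1:2]
  expect_gt(pct[1], 20)
  expect_lt(pct[2], 20)
  q <- apply_qc(x)
  expect_false(x$cell_meta$barcode[1] %in% q$cell_meta$barcode)
  expect_true(x$cell_meta$barcode[2] %in% q$cell_meta$barcode)
})

test_that("QC on an empty matrix returns an empty matrix without error", {
  g <- data.frame(symbol = c("A", "MT-1", "RPL1"), chrom = "chr1",
                  start = 1:3)
  x <- cell_matrix(matrix(0, 0, 3),
                   cell_meta = data.frame(sample = character(),
                                          barcode = character()),
                   gene_meta = g)
  expect_warning(q <- apply_qc(x), "every cell")
  expect_identical(nrow(q$counts), 0L)
})

test_that("apply_qc is idempotent", {
  q1 <- apply_qc(tiny_cohort()$expression$matrix)
  q2 <- apply_qc(q1)
  expect_identical(q1$counts, q2$counts)
})

test_that("log-normalization follows the scaled log1p contract", {
  counts <- rbind(c(10, 9990, 0), c(0, 0, 0), c(4, 16, 0))
  x <- cell_matrix(counts,
                   cell_meta = data.frame(sample = "s",
                                          barcode = c("a", "b", "c")),
                   gene_meta = data.frame(symbol = c("G1", "G2", "G3"),
                                          chrom = "chr1", start = 1:3))
  expect_warning(norm <- normalize_log(x), "zero total")
  expect_equal(norm[1, 1], log1p(10))
  expect_true(all(norm[2, ] == 0))
  # scale invariance: doubling all counts of a cell leaves its row fixed
  x2 <- cell_matrix(counts * 2, x$cell_meta, x$gene_meta)
  expect_warning(norm2 <- normalize_log(x2), "zero total")
  expect_equal(as.matrix(norm2), as.matrix(norm))
  # zero pattern preserved
  expect_identical(unname(as.matrix(norm) == 0), counts == 0)
})

test_that("clustering separates planted populations and is deterministic", {
  set.seed(42)
  n <- 120
  counts <- matrix(rpois(2 * n * 200, 2), 2 * n, 200)
  counts[1:n, 1:50] <- matrix(rpois(n * 50, 16), n, 50)  # fold 8
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  cl <- cluster_cells(norm, resolution = 0.6, seed = 1)
  expect_identical(length(unique(cl$label)), 2L)
  truth <- rep(c(0, 1), each = n)
  purity <- max(mean(cl$label == truth), mean(cl$label != truth))
  expect_gte(purity, 0.99)
  cl2 <- cluster_cells(norm, resolution = 0.6, seed = 1)
  expect_identical(cl$label, cl2$label)
  expect_error(cluster_cells(norm, resolution = 0), "resolution")
})

test_that("identical cells collapse to one cluster", {
  norm <- Matrix::Matrix(matrix(1, 60, 30), sparse = TRUE)
  cl <- cluster_cells(norm, resolution = 0.6, seed = 1)
  expect_identical(unique(cl$label), 0L)
})

test_that("marker-based annotation assigns the expected types", {
  syms <- c("CD3D", "CD3E", "CD3G", "CD19", "MS4A1", "CD79A", "OTHER")
  norm <- matrix(0.01, 40, 7, dimnames = list(NULL, syms))
  norm[1:20, 1:3] <- 3   # T cluster
  norm[21:40, 4:6] <- 3  # B cluster
  lab <- rep(c(0L, 1L), each = 20)
  call <- annotate_major_types(norm, lab)
  expect_identical(unname(call$cluster_type[["0"]]), "T")
  expect_identical(unname(call$cluster_type[["1"]]), "B")
  # exact ties fall back to the first type in fixed order, with warning
  tie <- matrix(1, 10, 7, dimnames = list(NULL, syms))
  expect_warning(res <- annotate_major_types(tie, rep(0L, 10)), "tie")
  expect_identical(unname(res$cluster_type[["0"]]),
                   names(default_marker_sets())[1])
  expect_error(annotate_major_types(
    matrix(1, 5, 2, dimnames = list(NULL, c("X", "Y"))), rep(0L, 5)),
    "marker")
})

test_that("cell typing on the synthetic cohort recovers planted types", {
  mal <- tiny_malignant()
  meta <- mal$qc_matrix$cell_meta
  truth <- meta$true_type
  truth[truth %in% c("malignantB", "normalB")] <- "B"
  ok <- meta$qc_class == "ok"
  expect_gte(mean(mal$types$cell_type[ok] == truth[ok]), 0.95)
})

test_that("differential expression flags an exclusive gene first", {
  set.seed(7)
  counts <- matrix(rpois(60 * 50, 3), 60, 50,
                   dimnames = list(NULL, sprintf("g%02d", 1:50)))
  counts[1:30, 1] <- rpois(30, 20)
  counts[31:60, 1] <- 0
  norm <- normalize_log(Matrix::Matrix(counts, sparse = TRUE))
  de <- differential_expression(norm, 1:30, 31:60)
  expect_identical(de$gene[1], "g01")
  expect_identical(min(de$p), de$p[de$gene == "g01"])
  # BH adjustment is monotone non-decreasing in p-rank
  ord <- order(de$p)
  expect_true(all(diff(de$adj_p[ord]) >= -1e-12))
  expect_error(differential_expression(norm, 1:2, 31:60), "at least 3")
})
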