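make_row <- function(cell, locus, v = "V1", j = "J1", cdr3 = "CARX",
                     seq = "ACGT", productive = TRUE, complete = TRUE,
                     confident = TRUE, sample = "s1") {
  data.frame(cell_id = cell, sample = sample, locus = locus, v_call = v,
             j_call = j, cdr3_aa = cdr3, sequence = seq,
             productive = productive, complete_vdj = complete,
             high_confidence = confident, stringsAsFactors = FALSE)
}

test_that("rearrangement filtering enforces flags and chain pairing", {
  rows <- rbind(
    make_row("c1", "IGH"), make_row("c1", "IGK"),       # kept
    make_row("c2", "IGH"),                              # heavy only
    make_row("c3", "IGH", productive = FALSE),
    make_row("c3", "IGK"),                              # failed heavy flag
    make_row("c4", "IGH"), make_row("c4", "IGH", v = "V9"),
    make_row("c4", "IGK"),                              # two heavies
    make_row("c5", "IGH"), make_row("c5", "IGL"))       # kept (lambda)
  out <- filter_rearrangements(rows)
  expect_setequal(out$cell_id, c("c1", "c5"))
  expect_identical(out$light_locus[out$cell_id == "c5"], "IGL")
  # malformed locus rejected with a message, not an error
  bad <- rbind(make_row("c6", "TRB"), make_row("c7", "IGH"),
               make_row("c7", "IGK"))
  expect_message(out2 <- filter_rearrangements(bad), "malformed")
  expect_identical(out2$cell_id, "c7")
  expect_identical(nrow(filter_rearrangements(rows[0, ])), 0L)
})

test_that("dominance is strict at 5 percent of BCR-assigned cells", {
  paired <- do.call(rbind, lapply(1:100, function(i) {
    key_cdr3 <- if (i <= 6) "CARSHARED" else if (i <= 11) "CARSECOND"
                else sprintf("CARBG%03d", i)
    data.frame(cell_id = sprintf("c%03d", i), sample = "s1",
               heavy_v = "V1", heavy_j = "J1", heavy_cdr3 = key_cdr3,
               heavy_sequence = "", light_locus = "IGK", light_v = "LV",
               light_j = "LJ", light_cdr3 = "CQQ",
               stringsAsFactors = FALSE)
  }))
  ct <- assign_clonotypes(paired)
  tab <- ct$clonotypes
  shared <- tab[grep("CARSHARED", tab$key), ]
  second <- tab[grep("CARSECOND", tab$key), ]
  expect_identical(shared$n_s1, 6L)
  expect_true(shared$dominant_s1)     # 6% > 5%
  expect_identical(second$n_s1, 5L)
  expect_false(second$dominant_s1)    # exactly 5% is not dominant
  expect_true(all(tab$frac_s1 >= 0 & tab$frac_s1 <= 1))
  expect_lte(sum(tab$frac_s1), 1 + 1e-9)
  # polyclonal status for non-dominant cells
  ca <- ct$cell_assignment
  expect_identical(unique(ca$status[ca$cell_id == "c010"]), "polyclonal")
  expect_identical(unique(ca$status[ca$cell_id == "c001"]), "clonal")
})

test_that("alternative denominator uses total cells per sample", {
  paired <- do.call(rbind, lapply(1:10, function(i)
    data.frame(cell_id = sprintf("c%d", i), sample = "s1", heavy_v = "V",
               heavy_j = "J", heavy_cdr3 = "CARS", heavy_sequence = "",
               light_locus = "IGK", light_v = "LV", light_j = "LJ",
               light_cdr3 = "CQQ", stringsAsFactors = FALSE)))
  # 10/10 of assigned cells but 10/500 of all cells
  ct <- assign_clonotypes(paired, cells_per_sample = c(s1 = 500))
  expect_false(ct$clonotypes$dominant_s1)
  expect_true(assign_clonotypes(paired)$clonotypes$dominant_s1)
})

test_that("SHM counting is exact, rate-correct and handles length offsets", {
  s <- strrep("ACGT", 75)  # 300 nt
  expect_identical(count_shm(s, s), list(shm_count = 0L, shm_rate = 0))
  mut <- s
  substr(mut, 10, 10) <- "T"; substr(mut, 200, 200) <- "A"
  res <- count_shm(mut, s)
  expect_identical(res$shm_count, 2L)
  expect_equal(res$shm_rate, 2 / 300, tolerance = 1e-9)
  # symmetry for equal lengths
  expect_identical(count_shm(s, mut)$shm_count, 2L)
  # N positions are excluded from count and compared length
  n_seq <- s
  substr(n_seq, 1, 1) <- "N"
  expect_identical(count_shm(n_seq, mut)$shm_count, 2L)
  expect_equal(count_shm(n_seq, mut)$shm_rate, 2 / 299, tolerance = 1e-9)
  # sliding gap-free alignment when lengths differ: observed contig with
  # 10 extra leading bases aligns back with 0 mismatches
  longer <- paste0("GGGGGGGGGG", s)
  expect_identical(count_shm(s, longer)$shm_count, 0L)
  expect_error(count_shm("", s), "non-empty")
})

test_that("light-chain ratio follows the IGKC/(IGKC+max IGLC) formula", {
  expect_equal(light_chain_ratio(9, matrix(c(1, 0.5), 1)), 0.9)
  expect_equal(light_chain_ratio(0, matrix(4, 1)), 0)
  expect_true(is.na(light_chain_ratio(0, matrix(0, 1))))
  # vectorized over cells, max over IGLC columns
  iglc <- rbind(c(1, 3), c(0, 0))
  expect_equal(light_chain_ratio(c(9, 0), iglc), c(0.75, NA))
})

test_that("matrix ratio extracts immunoglobulin genes and aggregates", {
  counts <- matrix(0, 4, 3,
                   dimnames = list(NULL, c("IGKC", "IGLC2", "G1")))
  counts[1, ] <- c(9, 1, 5)
  counts[2, ] <- c(0, 4, 5)
  counts[3, ] <- c(0, 0, 5)
  counts[4, ] <- c(3, 1, 5)
  x <- cell_matrix(counts,
                   data.frame(sample = "s", barcode = paste0("c", 1:4)),
                   data.frame(symbol = colnames(counts), chrom = "chr2",
                              start = 1:3))
  r <- light_chain_ratio_matrix(x)
  expect_equal(unname(r), c(0.9, 0, NA, 0.75))
  # cluster level: counts summed before the ratio
  rc <- light_chain_ratio_matrix(x, cluster = c(1, 1, 2, 2))
  expect_equal(unname(rc), c(9 / 14, 3 / 4))
})

test_that("planted clonotype fractions are recovered within binomial error", {
  co <- tiny_cohort()
  paired <- filter_rearrangements(co$bcr$rearrangements)
  ct <- assign_clonotypes(paired)
  cfg <- co$config
  expected_keys <- vapply(cfg$clonotypes, function(c)
    paste(c$heavy_v, c$heavy_j, c$heavy_cdr3, c$light_v, c$light_j,
          c$light_cdr3, sep = "|"), "")
  ca <- ct$cell_assignment
  truth <- co$bcr$truth
  idx <- match(ca$cell_id, truth$barcode)
  sel <- !is.na(truth$true_clonotype[idx])
  expect_gte(mean(ca$clonotype[sel] ==
                    expected_keys[truth$true_clonotype[idx][sel]]), 0.999)
})
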