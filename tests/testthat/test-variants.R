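caller_fixture <- function() {
  mk <- function(caller, keys) {
    f <- do.call(rbind, c(lapply(keys, function(k) strsplit(k, ":")[[1]]),
                          list(matrix(character(), 0, 4))))
    data.frame(patient = rep("P1", nrow(f)), sample = rep("T1", nrow(f)),
               chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 3],
               alt = f[, 4], caller = rep(caller, nrow(f)),
               vaf = rep(0.3, nrow(f)), depth = rep(100L, nrow(f)),
               stringsAsFactors = FALSE)
  }
  list(c1 = mk("c1", c("chr1:100:A:T", "chr2:200:C:G", "chr3:300:G:A")),
       c2 = mk("c2", c("chr1:100:A:T", "chr2:200:C:G")),
       c3 = mk("c3", c("chr1:100:A:T", "chr9:900:T:C")),
       c4 = mk("c4", character(0)),
       c5 = mk("c5", character(0)))
}

test_that("consensus retains variants called by at least two callers", {
  cons <- consensus_calls(caller_fixture())
  expect_setequal(cons$variants$key, c("chr1:100:A:T", "chr2:200:C:G"))
  expect_identical(cons$variants$n_callers[
    cons$variants$key == "chr1:100:A:T"], 3L)
  # singletons chr3/chr9 dropped
  expect_false("chr3:300:G:A" %in% cons$variants$key)
  # empty tables give an empty consensus
  empty <- lapply(caller_fixture(), function(t) t[0, ])
  expect_identical(nrow(consensus_calls(empty)$variants), 0L)
  # duplicated keys inside one caller are deduplicated with a warning
  dup <- caller_fixture()
  dup$c1 <- rbind(dup$c1, dup$c1[1, ])
  expect_warning(consensus_calls(dup), "deduplicated")
})

panel_fixture <- function(n_hit, key = "chr1:100:A:T") {
  f <- strsplit(key, ":")[[1]]
  data.frame(chrom = f[1], pos = as.integer(f[2]), ref = f[3],
             alt = f[4], panel_sample = sprintf("G%02d", seq_len(n_hit)),
             vaf = 0.4, depth = 80L, stringsAsFactors = FALSE)
}

test_that("germline panel filter drops variants in >=3 of 10 samples", {
  cons <- consensus_calls(caller_fixture())
  kept2 <- germline_panel_filter(cons, panel_fixture(2), n_panel = 10)
  expect_true("chr1:100:A:T" %in% kept2$variants$key)
  drop4 <- germline_panel_filter(cons, panel_fixture(4), n_panel = 10)
  expect_false("chr1:100:A:T" %in% drop4$variants$key)
  # the parenthetical 3-of-10 resolution: exactly 3 hits drop by default
  drop3 <- germline_panel_filter(cons, panel_fixture(3), n_panel = 10)
  expect_false("chr1:100:A:T" %in% drop3$variants$key)
  # strict >30% keeps exactly 30%
  strict3 <- germline_panel_filter(cons, panel_fixture(3), n_panel = 10,
                                   strict = TRUE)
  expect_true("chr1:100:A:T" %in% strict3$variants$key)
  expect_warning(unchanged <- germline_panel_filter(cons, NULL),
                 "empty germline panel")
  expect_identical(unchanged$variants, cons$variants)
})

test_that("paired rescue follows the coverage and alt-read rules", {
  tabs <- caller_fixture()
  # make chr2 variant relapse-only by renaming samples
  tabs <- lapply(tabs, function(t) t)
  tabs$c1$sample <- c("P", "R", "P")
  tabs$c2$sample <- c("P", "R")
  tabs$c3$sample <- c("P", "P")
  cons <- consensus_calls(tabs)
  pileup <- data.frame(
    key = c("chr2:200:C:G", "chr1:100:A:T"),
    sample = c("P", "R"),
    depth = c(2L, 30L), alt_count = c(0L, 0L),
    stringsAsFactors = FALSE)
  out <- rescue_paired(cons, pileup, c("P", "R"))
  v <- out$variants
  # partner has only 2 reads: fails the >2 rule -> unassessable
  expect_identical(v$pair_status[v$key == "chr2:200:C:G"], "unassessable")
  # partner well covered with 0 alt -> confirmed primary-specific
  expect_identical(v$pair_status[v$key == "chr1:100:A:T"],
                   "primary_specific")
  # partner with alt reads -> re-labeled shared
  pileup2 <- transform(pileup, alt_count = c(0L, 4L))
  out2 <- rescue_paired(cons, pileup2, c("P", "R"))
  expect_identical(
    out2$variants$pair_status[out2$variants$key == "chr1:100:A:T"],
    "shared")
  # missing pileup -> unassessable, never dropped
  out3 <- rescue_paired(cons, pileup[0, ], c("P", "R"))
  expect_identical(nrow(out3$variants), nrow(cons$variants))
  expect_true(all(out3$variants$pair_status == "unassessable"))
})

test_that("gene-level filters apply GDI and FPKM rules with ATM exempt", {
  v <- data.frame(patient = "P1", sample = "T1",
                  chrom = paste0("chr", 1:5), pos = 1:5 * 100,
                  ref = "A", alt = "T",
                  key = sprintf("chr%d:%d:A:T", 1:5, 1:5 * 100),
                  callers = "c1,c2", n_callers = 2L, vaf = 0.3,
                  depth = 100L,
                  gene = c("HIGHGDI", "ATM", "LOWEXPR", "OK", "MISSING"),
                  stringsAsFactors = FALSE)
  set <- mclevo:::.new_consensus(v)
  ann <- data.frame(gene = c("HIGHGDI", "ATM", "LOWEXPR", "OK"),
                    chrom = paste0("chr", 1:4), start = 1:4 * 100 - 10,
                    gdi = c(2500, 2500, 100, 100),
                    fpkm = c(5, 5, 0.4, 0.5), stringsAsFactors = FALSE)
  out <- gene_level_filters(set, ann)
  kept <- out$variants$gene
  expect_false("HIGHGDI" %in% kept)  # GDI 2500 > 2000
  expect_true("ATM" %in% kept)       # explicit exception
  expect_false("LOWEXPR" %in% kept)  # FPKM 0.4 < 0.5
  expect_true("OK" %in% kept)        # FPKM 0.5 kept (strict <)
  expect_true("MISSING" %in% kept)   # unannotated kept and flagged
  expect_true(out$variants$unannotated[out$variants$gene == "MISSING"])
})

test_that("recurrence rule reports two-patient or known genes", {
  sets <- list(A = c("ATM", "UNIQ1", "KNOWN1"),
               B = c("ATM", "UNIQ2"))
  rep <- recurrence_annotation(sets, known_genes = c("KNOWN1", "KNOWN9"))
  get <- function(g) rep$reportable[rep$gene == g]
  expect_true(get("ATM"))     # two patients
  expect_true(get("KNOWN1"))  # one patient but previously reported
  expect_false(get("UNIQ1"))  # one patient, not known
  # empty known list: only the two-patient rule applies
  rep2 <- recurrence_annotation(sets)
  expect_false(rep2$reportable[rep2$gene == "KNOWN1"])
})

test_that("CNV segment classification uses inclusive 2.3/1.7 thresholds", {
  seg <- data.frame(chrom = c("chr1", "chr2", "chr3", "chr14"),
                    start = c(1, 1, 1, 1), end = c(10, 10, 10, 10),
                    copy_number = c(2.3, 1.7, 2.0, 5))
  out <- classify_cnv_segments(seg)
  expect_identical(out$class, c("amplified", "deleted", "neutral",
                                "amplified"))
  ig <- data.frame(chrom = "chr14", start = 5, end = 20)
  out2 <- classify_cnv_segments(seg, ig_loci = ig)
  expect_false("chr14" %in% out2$chrom)
  expect_error(classify_cnv_segments(
    data.frame(chrom = "chr1", start = 10, end = 1, copy_number = 2)),
    "inverted")
  # BED conversion shifts starts to 1-based
  expect_identical(bed_to_1based(
    data.frame(chrom = "chr14", start = 4L, end = 20L))$start, 5L)
})

test_that("the cascade is replayable and never adds variants", {
  co <- tiny_cohort()
  cons0 <- consensus_calls(co$variants$caller_tables)
  cons1 <- germline_panel_filter(cons0, co$variants$panel, n_panel = 10)
  cons2 <- rescue_paired(cons1, co$variants$pileup, c("S01", "S02"))
  ann <- data.frame(gene = co$config$genes$symbol,
                    chrom = co$config$genes$chrom,
                    start = co$config$genes$start,
                    gdi = co$config$genes$gdi,
                    fpkm = co$config$genes$fpkm)
  cons3 <- gene_level_filters(cons2, ann)
  # monotone: every stage's key set is contained in the previous one
  trail <- cons3$trail
  for (i in seq_along(trail)[-1]) {
    expect_true(all(trail[[i]] %in% trail[[i - 1]]))
  }
  # replaying the recorded trail reproduces the final key set
  replayed <- replay_trail(cons3)
  expect_setequal(replayed$key, cons3$variants$key)
})

test_that("the full cascade reaches high precision and recall", {
  co <- tiny_cohort()
  cons <- consensus_calls(co$variants$caller_tables)
  cons <- germline_panel_filter(cons, co$variants$panel, n_panel = 10)
  ann <- data.frame(gene = co$config$genes$symbol,
                    chrom = co$config$genes$chrom,
                    start = co$config$genes$start,
                    gdi = co$config$genes$gdi,
                    fpkm = co$config$genes$fpkm)
  cons <- gene_level_filters(cons, ann)
  truth <- co$variants$truth$variants$key
  final <- unique(cons$variants$key)
  expect_gte(mean(final %in% truth), 0.9)  # precision
  expect_gte(mean(truth %in% final), 0.9)  # recall
})
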