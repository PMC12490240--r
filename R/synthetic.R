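# Synthetic MCL cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: multi-sample longitudinal cohorts whose malignant B cells carry
# clonal BCRs with light-chain restriction, CCND1 overexpression, planted
# copy-number segments acting multiplicatively on expression, a clone tree
# with per-sample cancer cell fractions, and multi-caller somatic variant
# tables with caller-specific error profiles and a germline panel.

# A synthetic germline IGHV nucleotide reference (300 nt). This is not a
# database allele: it is a fixed synthetic stand-in against which planted
# somatic hypermutations are counted.
SYNTHETIC_GERMLINE_IGHV <- paste0(
  "CAGGTGCAGCTGGTGGAGTCTGGGGGAGGCGTGGTCCAGCCTGGGAGGTCCCTGAGACTC",
  "TCCTGTGCAGCGTCTGGATTCACCTTCAGTAGCTATGGCATGCACTGGGTCCGCCAGGCT",
  "CCAGGCAAGGGGCTGGAGTGGGTGGCAGTTATATGGTATGATGGAAGTAATAAATACTAT",
  "GCAGACTCCGTGAAGGGCCGATTCACCATCTCCAGAGACAATTCCAAGAACACGCTGTAT",
  "CTGCAAATGAACAGCCTGAGAGCCGAGGACACGGCTGTGTATTACTGTGCGAGAGATCGG")

.sim_types <- c("malignantB", "normalB", "T", "NK", "myeloid")

# Relative numbers of genes per autosome (coarsely genome-like so that
# multi-hundred-gene segments fit on the larger chromosomes).
.chrom_weights <- c(200, 130, 110, 80, 90, 100, 95, 75, 80, 75, 130, 105,
                    35, 65, 65, 85, 120, 30, 140, 55, 25, 50)

#' Build a simulation configuration
#'
#' Returns a fully-specified configuration for the synthetic cohort
#' generators. All random quantities fixed at configuration time (baseline
#' gene means, gene damage index, bulk FPKM, signature/program gene sets)
#' are drawn deterministically from `seed`, so a config is a pure function
#' of its arguments.
#'
#' Defaults describe the study conditions the package is validated under:
#' three longitudinal samples of 2,000 cells over 2,000 genes, two dominant
#' malignant clonotypes (0 and 2 somatic hypermutations against the stored
#' germline IGHV), two planted copy-number segments, four-fold CCND1
#' overexpression in malignant cells, kappa light-chain restriction, a
#' four-clone tree with per-sample cancer cell fractions, purity around
#' 0.7, sequencing depth 200, and five variant callers at 0.9 sensitivity
#' with a false-positive rate of 1e-6 per base.
#'
#' @param n_samples number of longitudinal samples (timepoints).
#' @param n_cells cells per sample.
#' @param n_genes number of genes (including mitochondrial/ribosomal
#'   pseudo-gene groups and canonical marker symbols).
#' @param mixture named proportions over cell types
#'   (`malignantB`, `normalB`, `T`, `NK`, `myeloid`); must sum to 1.
#' @param dispersion negative-binomial size parameter shared by all genes.
#' @param ccnd1_fold fold-change (>= 1) applied to CCND1 in malignant cells
#'   relative to the normal-B baseline.
#' @param sig_fold fold-change applied to each cell type's signature genes.
#' @param program_fold fold-change applied to a malignant cell's active
#'   expression-program genes.
#' @param clone_parent integer parent vector over clones (`NA` for the
#'   founder).
#' @param clone_ccf clones x samples matrix of cancer cell fractions; must
#'   satisfy the tree sum rule in every sample.
#' @param clone_clonotype integer mapping clone -> clonotype index.
#' @param clonotypes list of clonotype descriptions; see defaults for the
#'   expected fields (`v_call`/`j_call`/`cdr3_aa` per chain, `shm`,
#'   `light_chain`).
#' @param cnv_segments list of planted segments, each with fields `chrom`,
#'   `genes` (global gene indices), `ratio` (multiplicative copy ratio) and
#'   `clones` (which clones carry it). `NULL` selects two default segments
#'   (a 2.0x gain of 120 genes on chr1 and a 0.5x loss of 100 genes on
#'   chr19) carried by all clones. An empty `list()` plants none.
#' @param purity per-sample tumor purity for the bulk WGS layer.
#' @param depth mean sequencing depth of the bulk WGS layer.
#' @param n_variants_per_clone somatic variants planted per clone.
#' @param caller_names names of the simulated variant callers.
#' @param caller_sensitivity per-caller detection probability for a true
#'   variant present in a sample.
#' @param caller_fp_rate per-caller false positives per base per sample.
#' @param n_panel number of germline panel samples.
#' @param n_artifacts systematic artifacts planted in >30% of the panel
#'   (all callers report them; the panel filter must remove them).
#' @param n_weak_artifacts artifacts present in fewer than 30% of panel
#'   samples (the panel filter must keep them).
#' @param qc_noise named fractions of planted QC-failing cells
#'   (`low_gene`, `high_mito`, `doublet`).
#' @param bcr_capture fraction of B cells with recovered BCR contigs.
#' @param kappa_fraction_normal fraction of normal B cells that are
#'   kappa-restricted (the rest are lambda).
#' @param seed integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 3,
                       n_cells = 2000,
                       n_genes = 2000,
                       mixture = c(malignantB = 0.48, normalB = 0.06,
                                   T = 0.28, NK = 0.10, myeloid = 0.08),
                       dispersion = 2,
                       ccnd1_fold = 4,
                       sig_fold = 8,
                       program_fold = 3,
                       clone_parent = c(NA, 1L, 2L, 1L),
                       clone_ccf = NULL,
                       clone_clonotype = c(1L, 1L, 2L, 2L),
                       clonotypes = NULL,
                       cnv_segments = NULL,
                       purity = NULL,
                       depth = 200,
                       n_variants_per_clone = 10,
                       caller_names = c("lancet", "strelka2", "muse",
                                        "mutect2", "somaticsniper"),
                       caller_sensitivity = rep(0.9, 5),
                       caller_fp_rate = rep(1e-6, 5),
                       n_panel = 10,
                       n_artifacts = 5,
                       n_weak_artifacts = 2,
                       qc_noise = c(low_gene = 0.02, high_mito = 0.02,
                                    doublet = 0.03),
                       bcr_capture = 0.9,
                       kappa_fraction_normal = 0.6,
                       seed = 1L) {
  mixture <- mixture[.sim_types]
  assert_that(!anyNA(mixture) && all(mixture >= 0 & mixture <= 1),
              "mixture must give a proportion in [0,1] for every cell type")
  assert_that(abs(sum(mixture) - 1) <= 1e-9, "mixture must sum to 1")
  assert_that(ccnd1_fold >= 1, "ccnd1_fold must be >= 1")
  assert_that(all(qc_noise >= 0) && sum(qc_noise) < 1,
              "qc_noise fractions must be non-negative and sum to < 1")

  n_clones <- length(clone_parent)
  if (is.null(clone_ccf)) {
    clone_ccf <- rbind(c(1.00, 1.00, 1.00),
                       c(0.70, 0.25, 0.10),
                       c(0.40, 0.15, 0.05),
                       c(0.20, 0.60, 0.85))[, seq_len(n_samples), drop = FALSE]
    if (n_samples > 3)
      clone_ccf <- cbind(clone_ccf,
                         matrix(clone_ccf[, 3], n_clones, n_samples - 3))
  }
  assert_that(nrow(clone_ccf) == n_clones,
              "clone_ccf must have one row per clone")
  assert_that(all(clone_ccf >= 0 & clone_ccf <= 1), "CCFs must lie in [0,1]")
  # Sum rule: parent CCF >= sum of children CCFs in every sample.
  for (k in seq_len(n_clones)) {
    ch <- which(!is.na(clone_parent) & clone_parent == k)
    if (length(ch))
      assert_that(all(clone_ccf[k, ] + 1e-9 >=
                        colSums(clone_ccf[ch, , drop = FALSE])),
                  "clone_ccf violates the tree sum rule")
  }

  if (is.null(clonotypes)) {
    clonotypes <- list(
      list(id = "CT1", heavy_v = "IGHV4-34", heavy_j = "IGHJ6",
           heavy_cdr3 = "CARDRSTYAFDYW",
           light_v = "IGKV3-20", light_j = "IGKJ1",
           light_cdr3 = "CQQYGSSPWTF",
           shm = 0L, light_chain = "kappa"),
      list(id = "CT2", heavy_v = "IGHV4-34", heavy_j = "IGHJ4",
           heavy_cdr3 = "CARGGDYYGMDVW",
           light_v = "IGKV1-39", light_j = "IGKJ2",
           light_cdr3 = "CQQSYSTPYTF",
           shm = 2L, light_chain = "kappa"))
  }
  for (ct in clonotypes) {
    assert_that(ct$shm <= nchar(SYNTHETIC_GERMLINE_IGHV),
                "clonotype SHM count exceeds germline IGHV length")
    assert_that(ct$light_chain %in% c("kappa", "lambda"),
                "light_chain must be 'kappa' or 'lambda'")
  }
  assert_that(max(clone_clonotype) <= length(clonotypes),
              "clone_clonotype refers to a missing clonotype")
  if (is.null(purity)) purity <- rep(0.7, n_samples)
  assert_that(all(purity > 0 & purity <= 1), "purity must lie in (0,1]")
  assert_that(depth > 0, "depth must be positive")

  genes <- .make_gene_table(n_genes, seed)
  if (is.null(cnv_segments)) {
    cnv_segments <- .default_cnv_segments(genes, n_clones)
  }
  for (seg in cnv_segments) {
    assert_that(max(seg$genes) <= n_genes,
                "n_genes smaller than a CNV segment span")
    assert_that(seg$ratio > 0, "CNV copy ratio must be positive")
  }

  cfg <- list(n_samples = n_samples, n_cells = n_cells, n_genes = n_genes,
              mixture = mixture, dispersion = dispersion,
              ccnd1_fold = ccnd1_fold, sig_fold = sig_fold,
              program_fold = program_fold,
              clone_parent = clone_parent, clone_ccf = clone_ccf,
              clone_clonotype = clone_clonotype, clonotypes = clonotypes,
              cnv_segments = cnv_segments, purity = purity, depth = depth,
              n_variants_per_clone = n_variants_per_clone,
              caller_names = caller_names,
              caller_sensitivity = caller_sensitivity,
              caller_fp_rate = caller_fp_rate,
              n_panel = n_panel, n_artifacts = n_artifacts,
              n_weak_artifacts = n_weak_artifacts,
              qc_noise = qc_noise, bcr_capture = bcr_capture,
              kappa_fraction_normal = kappa_fraction_normal,
              seed = as.integer(seed),
              genes = genes,
              sample_ids = sprintf("S%02d", seq_len(n_samples)))
  class(cfg) <- "sim_config"
  cfg
}

# Gene annotation with deterministic placement of canonical marker symbols,
# immunoglobulin constant genes, CCND1, known lymphoma genes, and
# mitochondrial/ribosomal pseudo-gene groups. gdi and fpkm are drawn from
# the config seed.
.make_gene_table <- function(n_genes, seed) {
  n_mt <- 10L
  n_auto <- n_genes - n_mt
  assert_that(n_auto >= 300, "n_genes too small for the gene template")
  sizes <- floor(.chrom_weights / sum(.chrom_weights) * n_auto)
  sizes[1] <- sizes[1] + (n_auto - sum(sizes))
  chrom <- rep(paste0("chr", 1:22), sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  symbol <- sprintf("GENE%05d", seq_len(n_auto))
  place <- function(sym, chr, ordinal) {
    idx <- which(chrom == chr)[ordinal]
    symbol[idx] <<- sym
    idx
  }
  specials <- list(
    c("CD19", "chr16", 5), c("MS4A1", "chr11", 5), c("CD79A", "chr19", 5),
    c("CD3D", "chr11", 8), c("CD3E", "chr11", 10), c("CD3G", "chr11", 12),
    c("CD4", "chr12", 5), c("CD8A", "chr2", 5),
    c("XCL2", "chr1", 5), c("NKG7", "chr19", 8), c("GNLY", "chr2", 8),
    c("CD68", "chr17", 5), c("CD33", "chr19", 11), c("CST3", "chr20", 5),
    c("HBQ1", "chr16", 8), c("HBM", "chr16", 10), c("GYPA", "chr4", 5),
    c("CCND1", "chr11", 15), c("CD70", "chr19", 14), c("CD27", "chr12", 8),
    c("IGKC", "chr2", 12),
    c("IGLC1", "chr22", 3), c("IGLC2", "chr22", 4), c("IGLC3", "chr22", 5),
    c("IGLC5", "chr22", 6), c("IGLC6", "chr22", 7), c("IGLC7", "chr22", 8),
    c("IGHM", "chr14", 60),
    c("ATM", "chr11", 60), c("TP53", "chr17", 8), c("NOTCH1", "chr9", 8),
    c("CDKN2A", "chr9", 12), c("KMT2D", "chr12", 12), c("UBR5", "chr8", 8),
    c("MEF2B", "chr19", 20), c("SMARCA4", "chr19", 24),
    c("S1PR1", "chr1", 12), c("BIRC3", "chr11", 64), c("NOTCH2", "chr1", 16))
  for (s in specials) place(s[1], s[2], as.integer(s[3]))
  # ribosomal pseudo-genes scattered over the autosomes
  ribo_syms <- c(sprintf("RPL%d", 1:12), sprintf("RPS%d", 1:8))
  ribo_chr <- rep(paste0("chr", c(3, 5, 6, 7, 8, 10, 12, 13, 14, 15)), 2)
  for (i in seq_along(ribo_syms)) place(ribo_syms[i], ribo_chr[i], 30 + i %% 3)
  genes <- data.frame(
    symbol = c(symbol, sprintf("MT-G%d", seq_len(n_mt))),
    chrom = c(chrom, rep("chrM", n_mt)),
    start = c(within, seq_len(n_mt)) * 10000L + 1L,
    stringsAsFactors = FALSE)
  with_seed(derive_seed(seed, 0L), {
    genes$gdi <- round(rlnorm(n_genes, log(300), 1.0), 1)
    genes$fpkm <- round(rlnorm(n_genes, log(8), 1.2), 3)
  })
  genes
}

.default_cnv_segments <- function(genes, n_clones) {
  chr1 <- which(genes$chrom == "chr1")
  chr19 <- which(genes$chrom == "chr19")
  gain <- chr1[40:min(159, length(chr1))]
  loss <- chr19[20:min(119, length(chr19))]
  list(list(chrom = "chr1", genes = gain, ratio = 2.0,
            clones = seq_len(n_clones)),
       list(chrom = "chr19", genes = loss, ratio = 0.5,
            clones = seq_len(n_clones)))
}

# Baseline per-gene NB means plus signature/program gene sets, all drawn
# from the config seed (stream 0).
.expression_design <- function(config) {
  g <- config$genes
  n <- config$n_genes
  with_seed(derive_seed(config$seed, 10L), {
    base <- rlnorm(n, meanlog = log(1.2), sdlog = 1.0)
    base[startsWith(g$symbol, "MT-")] <- 20
    base[startsWith(g$symbol, "RPL") | startsWith(g$symbol, "RPS")] <- 25
    markers <- list(
      B = c("CD19", "MS4A1", "CD79A"),
      T = c("CD3D", "CD3E", "CD3G", "CD4", "CD8A"),
      NK = c("XCL2", "NKG7", "GNLY"),
      myeloid = c("CD68", "CD33", "CST3"))
    special <- c(unlist(markers), "CCND1", "CD70", "CD27", "HBQ1", "HBM",
                 "GYPA", "IGKC", paste0("IGLC", c(1:3, 5:7)), "IGHM")
    base[g$symbol %in% special] <- 0.05
    base[g$symbol == "IGHM"] <- 0.05
    # candidate generic genes for signatures/programs: mid-expression,
    # outside planted CNV segments and away from special symbols
    seg_idx <- unlist(lapply(config$cnv_segments, `[[`, "genes"))
    cand <- which(startsWith(g$symbol, "GENE") & base > 0.3 & base < 3 &
                    !(seq_len(n) %in% seg_idx))
    cand <- sample(cand)
    take <- function(k) {
      out <- cand[seq_len(k)]
      cand <<- cand[-seq_len(k)]
      out
    }
    sig <- list(B = c(which(g$symbol %in% markers$B), take(47)),
                T = c(which(g$symbol %in% markers$T), take(45)),
                NK = c(which(g$symbol %in% markers$NK), take(47)),
                myeloid = c(which(g$symbol %in% markers$myeloid), take(47)))
    # nonmalignant B cells carry their own naive/memory-like feature set,
    # mirroring how normal B subclusters separate from tumor cells
    normalB_extra <- take(30)
    programs <- list(P1 = take(40), P2 = take(40), P3 = take(40))
    list(base = base, markers = markers, sig = sig, programs = programs,
         normalB_extra = normalB_extra)
  })
}

# Deterministic per-cell identity assignment shared by the expression and
# BCR generators (stream 1): cell type, clone, clonotype, light chain,
# active program, QC class and library-size factor.
.assign_cells <- function(config) {
  n_clones <- nrow(config$clone_ccf)
  # exclusive clone fractions within the malignant compartment per sample
  excl <- config$clone_ccf
  for (k in seq_len(n_clones)) {
    ch <- which(!is.na(config$clone_parent) & config$clone_parent == k)
    if (length(ch))
      excl[k, ] <- excl[k, ] - colSums(config$clone_ccf[ch, , drop = FALSE])
  }
  excl <- pmax(excl, 0)
  with_seed(derive_seed(config$seed, 1L), {
    out <- lapply(seq_len(config$n_samples), function(s) {
      n <- config$n_cells
      type <- sample(.sim_types, n, replace = TRUE, prob = config$mixture)
      clone <- rep(NA_integer_, n)
      mal <- which(type == "malignantB")
      clone[mal] <- sample(seq_len(n_clones), length(mal), replace = TRUE,
                           prob = excl[, s] / sum(excl[, s]))
      clonotype <- rep(NA_integer_, n)
      clonotype[mal] <- config$clone_clonotype[clone[mal]]
      light <- rep(NA_character_, n)
      light[mal] <- vapply(config$clonotypes[clonotype[mal]],
                           `[[`, "", "light_chain")
      nb <- which(type == "normalB")
      light[nb] <- ifelse(runif(length(nb)) < config$kappa_fraction_normal,
                          "kappa", "lambda")
      program <- rep(NA_integer_, n)
      program[mal] <- sample(1:3, length(mal), replace = TRUE,
                             prob = c(0.4, 0.35, 0.25))
      qc <- sample(c("ok", "low_gene", "high_mito", "doublet"), n,
                   replace = TRUE,
                   prob = c(1 - sum(config$qc_noise), config$qc_noise))
      # doublets are a T cell plus a B cell: only meaningful for B-typed
      # draws, so restrict the doublet class to B cells
      qc[qc == "doublet" & !(type %in% c("malignantB", "normalB"))] <- "ok"
      lib <- rlnorm(n, 0, 0.25)
      data.frame(sample = config$sample_ids[s],
                 barcode = sprintf("%s-C%04d", config$sample_ids[s],
                                   seq_len(n)),
                 true_type = type, true_clone = clone,
                 true_clonotype = clonotype, light_chain = light,
                 true_program = program, qc_class = qc,
                 lib_factor = lib, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Expected NB mean vector for one cell identity.
.cell_mu <- function(config, design, type, clone, program, light) {
  g <- config$genes
  mu <- design$base
  sig_of <- c(malignantB = "B", normalB = "B", T = "T", NK = "NK",
              myeloid = "myeloid")
  mu[design$sig[[sig_of[[type]]]]] <- mu[design$sig[[sig_of[[type]]]]] *
    config$sig_fold
  mu[g$symbol %in% design$markers[[sig_of[[type]]]]] <- 2 * config$sig_fold
  if (type == "T") mu[g$symbol == "CD27"] <- 3
  if (type %in% c("malignantB", "normalB")) {
    mu[g$symbol == "CCND1"] <- 2
    mu[g$symbol == "IGHM"] <- 10
    if (type == "normalB")
      mu[design$normalB_extra] <- mu[design$normalB_extra] * 6
    if (identical(light, "kappa")) {
      mu[g$symbol == "IGKC"] <- 20
    } else {
      mu[g$symbol == "IGLC2"] <- 20
    }
  }
  if (type == "malignantB") {
    mu[g$symbol == "CCND1"] <- 2 * config$ccnd1_fold
    mu[g$symbol == "CD70"] <- 1.5
    for (seg in config$cnv_segments) {
      if (!is.na(clone) && clone %in% seg$clones)
        mu[seg$genes] <- mu[seg$genes] * seg$ratio
    }
    if (!is.na(program))
      mu[design$programs[[program]]] <-
        mu[design$programs[[program]]] * config$program_fold
  }
  mu
}

#' Generate the synthetic expression layer
#'
#' Draws negative-binomial counts for every cell of every sample according
#' to the planted design: cell-type signatures, CCND1 overexpression and
#' light-chain restriction in B cells, multiplicative copy-number segments
#' and expression programs in malignant cells, and planted QC-failing cells
#' (low-complexity cells, high-mitochondrial cells, and T+B doublets formed
#' by summing two independent draws).
#'
#' @param config a [sim_config()].
#' @return a list with `matrix` (a [cell_matrix()] whose `cell_meta`
#'   carries the per-cell ground truth) and `truth` (gene-level ground
#'   truth: signature, program and CNV-segment gene sets).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- .expression_design(config)
  cells <- .assign_cells(config)
  n <- nrow(cells)
  g <- config$genes
  mito <- startsWith(g$symbol, "MT-")
  with_seed(derive_seed(config$seed, 2L), {
    counts <- matrix(0, n, config$n_genes)
    for (i in seq_len(n)) {
      ci <- cells[i, ]
      mu <- .cell_mu(config, design, ci$true_type, ci$true_clone,
                     ci$true_program, ci$light_chain)
      if (ci$qc_class == "low_gene") mu <- mu * 0.02
      if (ci$qc_class == "high_mito") mu[mito] <- mu[mito] * 20
      x <- rnbinom(config$n_genes, mu = mu * ci$lib_factor,
                   size = config$dispersion)
      if (ci$qc_class == "doublet") {
        mu2 <- .cell_mu(config, design, "T", NA, NA, NA)
        x <- x + rnbinom(config$n_genes, mu = mu2 * ci$lib_factor,
                         size = config$dispersion)
      }
      counts[i, ] <- x
    }
  })
  cm <- cell_matrix(Matrix::Matrix(counts, sparse = TRUE),
                    cell_meta = cells, gene_meta = g)
  truth <- list(signatures = design$sig, programs = design$programs,
                markers = design$markers,
                cnv_segments = config$cnv_segments)
  list(matrix = cm, truth = truth)
}

# Apply `k` deterministic substitutions to a nucleotide sequence.
.mutate_seq <- function(seq, k, seed) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  with_seed(seed, {
    pos <- sample(length(chars), k)
    for (p in pos) {
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
    }
  })
  paste(chars, collapse = "")
}

# Distinct clonotype CDR3s for the polyclonal background, by construction.
.background_cdr3 <- function(i) {
  aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "C")
  digits <- integer(4)
  x <- i
  for (d in 4:1) {
    digits[d] <- x %% 20L
    x <- x %/% 20L
  }
  paste0("CAR", paste(aa[digits + 1L], collapse = ""), "FDYW")
}

#' Generate the synthetic single-cell BCR layer
#'
#' Emits an AIRR-style rearrangement table (one row per chain) for the same
#' cells as [generate_expression()]: malignant cells carry their clonotype's
#' paired heavy/light chains with the planted number of somatic
#' hypermutations against the stored germline IGHV; normal B cells carry
#' pairwise-distinct polyclonal clonotypes. A fraction `bcr_capture` of B
#' cells is covered.
#'
#' @param config a [sim_config()].
#' @return a list with `rearrangements` (data.frame with columns `cell_id`,
#'   `sample`, `locus`, `v_call`, `j_call`, `cdr3_aa`, `sequence`,
#'   `productive`, `complete_vdj`, `high_confidence`) and `truth` (per-cell
#'   clonotype assignment).
#' @export
generate_bcr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- .assign_cells(config)
  bc <- cells[cells$true_type %in% c("malignantB", "normalB") &
                cells$qc_class != "low_gene", ]
  germ <- SYNTHETIC_GERMLINE_IGHV
  ct_seq <- lapply(seq_along(config$clonotypes), function(j) {
    .mutate_seq(germ, config$clonotypes[[j]]$shm,
                derive_seed(config$seed, 100L + j))
  })
  with_seed(derive_seed(config$seed, 3L), {
    captured <- bc[runif(nrow(bc)) < config$bcr_capture, ]
    rows <- vector("list", nrow(captured))
    for (i in seq_len(nrow(captured))) {
      ci <- captured[i, ]
      if (!is.na(ci$true_clonotype)) {
        ct <- config$clonotypes[[ci$true_clonotype]]
        heavy <- data.frame(locus = "IGH", v_call = ct$heavy_v,
                            j_call = ct$heavy_j, cdr3_aa = ct$heavy_cdr3,
                            sequence = ct_seq[[ci$true_clonotype]])
        light <- data.frame(
          locus = if (ct$light_chain == "kappa") "IGK" else "IGL",
          v_call = ct$light_v, j_call = ct$light_j,
          cdr3_aa = ct$light_cdr3, sequence = "")
      } else {
        vh <- sample(c("IGHV1-2", "IGHV3-23", "IGHV3-7", "IGHV1-69"), 1)
        heavy <- data.frame(locus = "IGH", v_call = vh,
                            j_call = sample(paste0("IGHJ", 1:6), 1),
                            cdr3_aa = .background_cdr3(i),
                            sequence = .mutate_seq(
                              germ, sample(3:15, 1),
                              derive_seed(config$seed, 2000L + i)))
        kap <- identical(ci$light_chain, "kappa")
        light <- data.frame(locus = if (kap) "IGK" else "IGL",
                            v_call = if (kap) "IGKV1-5" else "IGLV3-19",
                            j_call = if (kap) "IGKJ4" else "IGLJ3",
                            cdr3_aa = paste0("CQQ",
                                             .background_cdr3(i)),
                            sequence = "")
      }
      pair <- rbind(heavy, light)
      pair$cell_id <- ci$barcode
      pair$sample <- ci$sample
      # a small fraction of contigs fail the quality flags
      pair$productive <- runif(2) > 0.01
      pair$complete_vdj <- runif(2) > 0.01
      pair$high_confidence <- runif(2) > 0.01
      rows[[i]] <- pair
    }
  })
  rearr <- do.call(rbind, rows)
  rearr <- rearr[, c("cell_id", "sample", "locus", "v_call", "j_call",
                     "cdr3_aa", "sequence", "productive", "complete_vdj",
                     "high_confidence")]
  rownames(rearr) <- NULL
  truth <- captured[, c("barcode", "sample", "true_type", "true_clone",
                        "true_clonotype", "light_chain")]
  rownames(truth) <- NULL
  list(rearrangements = rearr, truth = truth,
       germline_ighv = germ)
}

#' Generate synthetic multi-caller somatic variant tables
#'
#' Plants `n_variants_per_clone` somatic variants per clone. A variant's
#' allele fraction in each sample is drawn as
#' `Binomial(depth, purity * CCF * m / (purity * CN + (1 - purity) * 2)) /
#' depth` with multiplicity `m = 1` and local copy number `CN = 2`
#' (variants are placed outside the planted CNV segments). Each caller
#' reports a present variant with its configured sensitivity and adds
#' caller-private false positives at its configured per-base rate.
#' Systematic artifacts are planted into more than 30% of the germline
#' panel samples (and reported by every caller); weak artifacts touch fewer
#' than 30% of the panel and survive the panel filter.
#'
#' @param config a [sim_config()].
#' @return a list with `caller_tables` (one data.frame per caller:
#'   `patient`, `sample`, `chrom`, `pos`, `ref`, `alt`, `caller`, `vaf`,
#'   `depth`, `alt_count`), `panel` (germline panel VAF table), `pileup`
#'   (per-variant per-sample high-quality depth/alt counts for the rescue
#'   step), `wgs_segments` (bulk CNV segments implied by the planted
#'   expression segments), and `truth` (variant-level ground truth with
#'   clone assignment and per-sample CCF).
#' @export
generate_variant_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(config$clone_ccf) >= 1, "empty clone tree")
  g <- config$genes
  n_clones <- nrow(config$clone_ccf)
  driver_pool <- list(`1` = c("MEF2B"), `2` = c("NOTCH1", "S1PR1"),
                      `3` = c("SMARCA4", "UBR5"), `4` = c("CDKN2A"))
  seg_idx <- unlist(lapply(config$cnv_segments, `[[`, "genes"))
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(config$seed, 4L), {
    # eligible host genes: expressed, not damage-prone, outside planted
    # segments, not immunoglobulin
    ig <- startsWith(g$symbol, "IGK") | startsWith(g$symbol, "IGL") |
      startsWith(g$symbol, "IGH")
    ok <- which(g$fpkm >= 0.5 & g$gdi <= 2000 & !ig & g$chrom != "chrM" &
                  !(seq_len(config$n_genes) %in% seg_idx))
    truth <- NULL
    for (k in seq_len(n_clones)) {
      drv <- driver_pool[[as.character(k)]] %||% character()
      drv <- drv[drv %in% g$symbol[g$fpkm >= 0.5]]
      n_generic <- max(0L, config$n_variants_per_clone - length(drv))
      host <- c(match(drv, g$symbol), sample(ok, n_generic))
      ok <- setdiff(ok, host)
      truth <- rbind(truth, data.frame(
        gene = g$symbol[host], chrom = g$chrom[host],
        pos = g$start[host] + sample(1:5000, length(host)),
        ref = sample(bases, length(host), replace = TRUE),
        clone = k, stringsAsFactors = FALSE))
    }
    truth$alt <- vapply(truth$ref,
                        function(r) sample(setdiff(bases, r), 1), "")
    truth$key <- with(truth, paste(chrom, pos, ref, alt, sep = ":"))
    for (s in seq_len(config$n_samples))
      truth[[paste0("ccf_", config$sample_ids[s])]] <-
        config$clone_ccf[truth$clone, s]

    # per-sample binomial draws (these are also the pileup statistics)
    pileup <- NULL
    caller_rows <- stats::setNames(
      vector("list", length(config$caller_names)), config$caller_names)
    for (s in seq_len(config$n_samples)) {
      sid <- config$sample_ids[s]
      pur <- config$purity[s]
      ccf <- config$clone_ccf[truth$clone, s]
      p <- pur * ccf * 1 / (pur * 2 + (1 - pur) * 2)
      dp <- pmax(1L, rpois(nrow(truth), config$depth))
      alt_n <- rbinom(nrow(truth), dp, p)
      vaf <- alt_n / dp
      pileup <- rbind(pileup, data.frame(
        key = truth$key, sample = sid, depth = dp, alt_count = alt_n,
        stringsAsFactors = FALSE))
      present <- alt_n > 0
      for (j in seq_along(config$caller_names)) {
        det <- present & runif(nrow(truth)) < config$caller_sensitivity[j]
        if (any(det)) {
          caller_rows[[j]] <- rbind(caller_rows[[j]], data.frame(
            patient = "P1", sample = sid,
            chrom = truth$chrom[det], pos = truth$pos[det],
            ref = truth$ref[det], alt = truth$alt[det],
            caller = config$caller_names[j],
            vaf = vaf[det], depth = dp[det], alt_count = alt_n[det],
            stringsAsFactors = FALSE))
        }
      }
    }

    # systematic and weak panel artifacts, seen by every caller
    n_art <- config$n_artifacts + config$n_weak_artifacts
    if (n_art == 0) {
      art <- data.frame(gene = character(), chrom = character(),
                        pos = integer(), ref = character(),
                        alt = character(), key = character(),
                        n_panel_hit = integer(), stringsAsFactors = FALSE)
      panel <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          panel_sample = character(), vaf = numeric(),
                          depth = integer(), stringsAsFactors = FALSE)
    } else {
    art <- data.frame(
      gene = NA_character_,
      chrom = sample(paste0("chr", 1:22), n_art, replace = TRUE),
      pos = sample(1e6, n_art),
      ref = sample(bases, n_art, replace = TRUE), stringsAsFactors = FALSE)
    art$alt <- vapply(art$ref, function(r) sample(setdiff(bases, r), 1), "")
    art$key <- with(art, paste(chrom, pos, ref, alt, sep = ":"))
    art$n_panel_hit <- c(rep(4L, config$n_artifacts),
                         rep(2L, config$n_weak_artifacts))
    panel <- NULL
    for (i in seq_len(n_art)) {
      hit <- sample(config$n_panel, art$n_panel_hit[i])
      panel <- rbind(panel, data.frame(
        chrom = art$chrom[i], pos = art$pos[i], ref = art$ref[i],
        alt = art$alt[i], panel_sample = sprintf("G%02d", hit),
        vaf = round(runif(length(hit), 0.3, 0.6), 3),
        depth = pmax(1L, rpois(length(hit), config$depth)),
        stringsAsFactors = FALSE))
      for (s in config$sample_ids) {
        dp <- max(1L, rpois(1, config$depth))
        altn <- rbinom(1, dp, 0.4)
        for (j in seq_along(config$caller_names)) {
          caller_rows[[j]] <- rbind(caller_rows[[j]], data.frame(
            patient = "P1", sample = s, chrom = art$chrom[i],
            pos = art$pos[i], ref = art$ref[i], alt = art$alt[i],
            caller = config$caller_names[j], vaf = altn / dp, depth = dp,
            alt_count = altn, stringsAsFactors = FALSE))
        }
      }
    }
    }

    # caller-private false positives over the simulated genome
    genome_len <- sum(tapply(g$start, g$chrom, max)) + 1e5
    for (j in seq_along(config$caller_names)) {
      for (s in config$sample_ids) {
        n_fp <- rpois(1, config$caller_fp_rate[j] * genome_len)
        if (n_fp == 0) next
        fp_chrom <- sample(paste0("chr", 1:22), n_fp, replace = TRUE)
        fp_ref <- sample(bases, n_fp, replace = TRUE)
        caller_rows[[j]] <- rbind(caller_rows[[j]], data.frame(
          patient = "P1", sample = s, chrom = fp_chrom,
          pos = sample(2e6, n_fp),
          ref = fp_ref,
          alt = vapply(fp_ref, function(r) sample(setdiff(bases, r), 1), ""),
          caller = config$caller_names[j],
          vaf = round(runif(n_fp, 0.03, 0.15), 3),
          depth = pmax(1L, rpois(n_fp, config$depth)),
          alt_count = 1L, stringsAsFactors = FALSE))
      }
    }
  })

  # bulk WGS segments implied by the planted expression segments
  wgs <- do.call(rbind, lapply(config$cnv_segments, function(seg) {
    data.frame(chrom = seg$chrom,
               start = min(g$start[seg$genes]),
               end = max(g$start[seg$genes]) + 9999L,
               copy_number = 2 * seg$ratio, stringsAsFactors = FALSE)
  }))

  list(caller_tables = caller_rows, panel = panel, pileup = pileup,
       wgs_segments = wgs,
       truth = list(variants = truth, artifacts = art))
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper running [generate_expression()], [generate_bcr()]
#' and [generate_variant_tables()] on one configuration. Each layer draws
#' from its own seed stream derived from `config$seed`, so the layers are
#' individually reproducible and mutually consistent (the expression and
#' BCR layers share one cell-identity assignment).
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, all layers are written as
#'   plain-text files (Matrix Market triplets per sample, AIRR TSV,
#'   per-caller variant TSVs, panel and gene-annotation TSVs, truth JSON).
#' @return list with `expression`, `bcr`, `variants`, `config`.
#' @export
generate_cohort <- function(config, outdir = NULL) {
  expr <- generate_expression(config)
  bcr <- generate_bcr(config)
  var <- generate_variant_tables(config)
  out <- list(expression = expr, bcr = bcr, variants = var, config = config)
  if (!is.null(outdir)) write_cohort(out, outdir)
  out
}

#' Write a generated cohort to plain-text files
#'
#' @param cohort result of [generate_cohort()].
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cm <- cohort$expression$matrix
  for (s in unique(cm$cell_meta$sample)) {
    write_10x(subset_cells(cm, cm$cell_meta$sample == s),
              file.path(outdir, s))
  }
  write.table(cohort$bcr$rearrangements,
              file.path(outdir, "rearrangements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (cal in names(cohort$variants$caller_tables)) {
    write.table(cohort$variants$caller_tables[[cal]],
                file.path(outdir, paste0("calls_", cal, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(cohort$variants$panel, file.path(outdir, "germline_panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$config$genes, file.path(outdir, "gene_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$variants$wgs_segments,
              file.path(outdir, "wgs_segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(cells = cohort$expression$matrix$cell_meta,
                variants = cohort$variants$truth$variants)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(outdir)
}

#' Simulate a matrix with planted expression programs
#'
#' Small-scale generator for validating consensus NMF model selection:
#' every cell is assigned one of `k` programs; each program multiplies its
#' own block of `genes_per_program` genes by `fold` on top of a shared
#' negative-binomial baseline.
#'
#' @param n_cells,n_genes matrix size.
#' @param k number of planted programs.
#' @param genes_per_program genes per program block.
#' @param fold multiplicative program effect.
#' @param dispersion NB size parameter.
#' @param seed integer seed.
#' @return list with `counts` (cells x genes), `program` (per-cell truth),
#'   `program_genes` (list of gene-index blocks).
#' @export
simulate_programs <- function(n_cells = 240, n_genes = 300, k = 3,
                              genes_per_program = 40, fold = 6,
                              dispersion = 2, seed = 1L) {
  assert_that(k * genes_per_program <= n_genes,
              "program blocks exceed n_genes")
  with_seed(seed, {
    base <- rlnorm(n_genes, log(1), 0.6)
    prog <- sample(rep(seq_len(k), length.out = n_cells))
    blocks <- split(seq_len(k * genes_per_program),
                    rep(seq_len(k), each = genes_per_program))
    counts <- matrix(0, n_cells, n_genes)
    for (i in seq_len(n_cells)) {
      mu <- base
      mu[blocks[[prog[i]]]] <- mu[blocks[[prog[i]]]] * fold
      counts[i, ] <- rnbinom(n_genes, mu = mu, size = dispersion)
    }
  })
  rownames(counts) <- sprintf("cell%04d", seq_len(n_cells))
  colnames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  list(counts = counts, program = prog, program_genes = blocks)
}

#' Simulate a homogeneous negative-binomial count matrix
#'
#' A null-model generator used for type-I error and permutation-test
#' calibration: every cell is drawn from the same per-gene NB baseline.
#'
#' @param n_cells,n_genes matrix size.
#' @param dispersion NB size parameter.
#' @param seed integer seed.
#' @return a cells x genes integer matrix.
#' @export
simulate_homogeneous <- function(n_cells, n_genes, dispersion = 2,
                                 seed = 1L) {
  with_seed(seed, {
    base <- rlnorm(n_genes, log(1), 0.8)
    counts <- matrix(rnbinom(n_cells * n_genes,
                             mu = rep(base, each = n_cells),
                             size = dispersion),
                     n_cells, n_genes)
  })
  rownames(counts) <- sprintf("cell%04d", seq_len(n_cells))
  colnames(counts) <- sprintf("gene%04d", seq_len(n_genes))
  counts
}
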