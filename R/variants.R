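# Somatic-variant consensus over multiple callers and the ordered filter
# cascade: germline-panel filter, paired-sample rescue, gene-level GDI and
# expression filters, recurrence annotation, and WGS CNV segment
# classification.

.variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt,
                                   sep = ":")

# A consensus set carries its variants plus an ordered, replayable filter
# trail: one entry per applied stage recording the keys it kept.
.new_consensus <- function(variants, trail = NULL) {
  structure(list(variants = variants, trail = trail %||% list()),
            class = "consensus_set")
}

.log_stage <- function(set, stage, kept_keys) {
  set$trail <- c(set$trail, setNames(list(kept_keys), stage))
  set
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> %d variant(s); filter trail: %s\n",
              nrow(x$variants),
              paste(names(x$trail), collapse = " -> ")))
  invisible(x)
}

#' Replay a recorded filter trail
#'
#' Re-applies the ordered kept-key sets of a filter trail to the original
#' consensus variants, reproducing the cascade output exactly.
#'
#' @param set a `consensus_set` with a recorded trail.
#' @return the variants data.frame after replaying every stage.
#' @export
replay_trail <- function(set) {
  v <- set$variants0 %||% set$variants
  for (kept in set$trail) v <- v[v$key %in% kept, , drop = FALSE]
  v
}

#' Consensus calls across variant callers
#'
#' Variants are keyed by (chrom, pos, ref, alt) per sample and retained
#' when called by at least `min_callers` callers (default 2). SNVs and
#' indels are handled identically. Duplicate keys within one caller table
#' are deduplicated with a warning.
#'
#' @param caller_tables list of per-caller data.frames with columns
#'   `sample`, `chrom`, `pos`, `ref`, `alt`, `caller`, `vaf`, `depth`
#'   (and optionally `patient`, `alt_count`).
#' @param min_callers consensus threshold (default 2).
#' @return a `consensus_set`; `variants` has one row per (sample, key)
#'   with `callers` (comma-joined), `n_callers`, and the median `vaf` /
#'   `depth` across supporting callers.
#' @export
consensus_calls <- function(caller_tables, min_callers = 2) {
  assert_that(length(caller_tables) >= min_callers,
              "need at least `min_callers` caller tables")
  tabs <- lapply(caller_tables, function(t) {
    if (is.null(t) || nrow(t) == 0) return(NULL)
    t$key <- .variant_key(t)
    dup <- duplicated(t[, c("sample", "key")])
    if (any(dup)) {
      warning("duplicate keys in a caller table deduplicated")
      t <- t[!dup, , drop = FALSE]
    }
    t
  })
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  if (length(tabs) == 0) {
    v <- data.frame(patient = character(), sample = character(),
                    chrom = character(), pos = integer(),
                    ref = character(), alt = character(),
                    key = character(), callers = character(),
                    n_callers = integer(), vaf = numeric(),
                    depth = numeric(), stringsAsFactors = FALSE)
    out <- .new_consensus(v)
    out$variants0 <- v
    return(.log_stage(out, "consensus", character()))
  }
  all <- do.call(rbind, c(tabs, make.row.names = FALSE))
  sk <- paste(all$sample, all$key)
  agg <- lapply(split(all, sk), function(d) {
    data.frame(patient = d$patient[1] %||% NA_character_,
               sample = d$sample[1], chrom = d$chrom[1], pos = d$pos[1],
               ref = d$ref[1], alt = d$alt[1], key = d$key[1],
               callers = paste(sort(d$caller), collapse = ","),
               n_callers = nrow(d),
               vaf = median(d$vaf), depth = median(d$depth),
               stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, c(agg, make.row.names = FALSE))
  v <- v[v$n_callers >= min_callers, , drop = FALSE]
  v <- v[order(v$sample, v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  out <- .new_consensus(v)
  out$variants0 <- v
  .log_stage(out, "consensus", unique(v$key))
}

#' Germline-panel filter
#'
#' Drops variants present (positive VAF on high-quality reads) in at least
#' `ceiling(0.3 * N)` of the `N` germline panel samples (the default
#' resolves the 3-of-10 rule: with a 10-sample panel a variant seen in 3
#' or more panel samples is dropped). `strict = TRUE` instead requires
#' strictly more than 30% of the panel. Positions absent from the panel
#' table are treated as absent. An empty panel leaves the set unchanged
#' with a warning.
#'
#' @param set a `consensus_set`.
#' @param panel data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `panel_sample`, `vaf`.
#' @param n_panel total number of panel samples (defaults to the number
#'   of distinct `panel_sample` values).
#' @param strict use the strictly-greater-than-30% rule.
#' @return the filtered `consensus_set`.
#' @export
germline_panel_filter <- function(set, panel, n_panel = NULL,
                                  strict = FALSE) {
  stopifnot(inherits(set, "consensus_set"))
  if (is.null(panel) || nrow(panel) == 0) {
    warning("empty germline panel; set unchanged")
    return(.log_stage(set, "germline_panel", unique(set$variants$key)))
  }
  if (is.null(n_panel)) n_panel <- length(unique(panel$panel_sample))
  assert_that(n_panel >= 2, "panel needs at least 2 germline samples")
  panel$key <- .variant_key(panel)
  hits <- tapply(panel$vaf > 0, panel$key, sum)
  cutoff <- if (strict) floor(0.3 * n_panel) + 1L else ceiling(0.3 * n_panel)
  n_hit <- hits[set$variants$key]
  n_hit[is.na(n_hit)] <- 0
  keep <- n_hit < cutoff
  set$variants <- set$variants[keep, , drop = FALSE]
  .log_stage(set, "germline_panel", unique(set$variants$key))
}

#' Rescue and adjudicate timepoint-specific variants in a sample pair
#'
#' For a variant found in only one sample of a primary/relapse pair, the
#' partner sample's pileup decides its status: alt reads in the partner
#' re-label it `shared` (rescuing a call the pipeline missed, typically
#' due to low VAF); with zero alt reads the timepoint-specific status is
#' confirmed only when partner coverage exceeds `min_reads` total
#' high-quality reads (default 2), otherwise the variant is
#' `unassessable`. Missing pileup rows are unassessable, never dropped.
#' No variant is added or removed, only annotated.
#'
#' @param set a `consensus_set` covering the two samples.
#' @param pileup data.frame with `key` (or chrom/pos/ref/alt), `sample`,
#'   `depth`, `alt_count` of high-quality reads.
#' @param sample_pair character vector of the two sample ids
#'   (primary, relapse).
#' @param min_reads coverage rule: partner total reads must be strictly
#'   greater than this (default 2).
#' @return the `consensus_set` with a `pair_status` column
#'   (`shared` / `primary_specific` / `relapse_specific` /
#'   `unassessable`).
#' @export
rescue_paired <- function(set, pileup, sample_pair, min_reads = 2) {
  stopifnot(inherits(set, "consensus_set"))
  assert_that(length(sample_pair) == 2, "sample_pair must name 2 samples")
  if (is.null(pileup$key)) pileup$key <- .variant_key(pileup)
  v <- set$variants
  v$pair_status <- NA_character_
  in_pair <- v$sample %in% sample_pair
  for (i in which(in_pair)) {
    own <- v$sample[i]
    partner <- setdiff(sample_pair, own)
    called_in_partner <- any(v$key == v$key[i] & v$sample == partner)
    if (called_in_partner) {
      v$pair_status[i] <- "shared"
      next
    }
    pu <- pileup[pileup$key == v$key[i] & pileup$sample == partner, ,
                 drop = FALSE]
    if (nrow(pu) == 0) {
      v$pair_status[i] <- "unassessable"
    } else if (sum(pu$alt_count) > 0) {
      v$pair_status[i] <- "shared"
    } else if (sum(pu$depth) > min_reads) {
      v$pair_status[i] <- if (own == sample_pair[1]) "primary_specific"
                          else "relapse_specific"
    } else {
      v$pair_status[i] <- "unassessable"
    }
  }
  set$variants <- v
  .log_stage(set, paste0("rescue_paired:", paste(sample_pair,
                                                 collapse = "-")),
             unique(v$key))
}

#' Gene-level damage-index and expression filters
#'
#' Drops variants in genes with a gene damage index above `max_gdi`
#' (default 2000) unless the gene is `ATM` (a well-established tumor
#' suppressor kept despite its high background damage score), and
#' variants in genes with mean bulk FPKM strictly below `min_fpkm`
#' (default 0.5). Variants in genes missing from the annotation are kept
#' and flagged `unannotated`.
#'
#' @param set a `consensus_set` whose variants carry a `gene` column, or
#'   one that can be annotated via `gene_annotation` positions.
#' @param gene_annotation data.frame with `gene` (or `symbol`), `chrom`,
#'   `start`, `gdi`, `fpkm`.
#' @param max_gdi,min_fpkm thresholds (2000; 0.5).
#' @param gdi_exempt genes exempt from the GDI rule (default "ATM").
#' @return the filtered `consensus_set` (adds `gene`, `gdi`, `fpkm`,
#'   `unannotated` columns).
#' @export
gene_level_filters <- function(set, gene_annotation, max_gdi = 2000,
                               min_fpkm = 0.5, gdi_exempt = "ATM") {
  stopifnot(inherits(set, "consensus_set"))
  ga <- gene_annotation
  if (is.null(ga$gene)) ga$gene <- ga$symbol
  v <- set$variants
  if (is.null(v$gene)) {
    # annotate by position: a variant belongs to the nearest gene start
    # at or before it on the same chromosome, within 10 kb
    v$gene <- NA_character_
    for (i in seq_len(nrow(v))) {
      cand <- ga[ga$chrom == v$chrom[i] & ga$start <= v$pos[i] &
                   v$pos[i] < ga$start + 10000, , drop = FALSE]
      if (nrow(cand)) v$gene[i] <- cand$gene[which.max(cand$start)]
    }
  }
  idx <- match(v$gene, ga$gene)
  v$gdi <- ga$gdi[idx]
  v$fpkm <- ga$fpkm[idx]
  v$unannotated <- is.na(idx) | is.na(v$gene)
  drop_gdi <- !v$unannotated & v$gdi > max_gdi & !(v$gene %in% gdi_exempt)
  drop_fpkm <- !v$unannotated & v$fpkm < min_fpkm
  v <- v[!(drop_gdi | drop_fpkm), , drop = FALSE]
  set$variants <- v
  set <- .log_stage(set, "gdi_filter",
                    unique(v$key))
  .log_stage(set, "fpkm_filter", unique(v$key))
}

#' Recurrence-based reportable-gene annotation
#'
#' A gene is reportable when nonsilently mutated in at least two patients,
#' or in at least one patient while present on a curated list of
#' previously reported lymphoma genes.
#'
#' @param patient_gene_sets named list (per patient) of character vectors
#'   of nonsilently mutated genes.
#' @param known_genes curated gene list (may be empty: then only the
#'   two-patient rule applies).
#' @return data.frame with `gene`, `n_patients`, `known`, `reportable`.
#' @export
recurrence_annotation <- function(patient_gene_sets,
                                  known_genes = character()) {
  genes <- sort(unique(unlist(patient_gene_sets)))
  n_pat <- vapply(genes, function(g)
    sum(vapply(patient_gene_sets, function(s) g %in% s, TRUE)), 0L)
  known <- genes %in% known_genes
  data.frame(gene = genes, n_patients = n_pat, known = known,
             reportable = n_pat >= 2 | (n_pat >= 1 & known),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify bulk CNV segments and drop immunoglobulin loci
#'
#' Segments with copy number at or above `amp_cn` (default 2.3) are
#' amplified, at or below `del_cn` (default 1.7) deleted, otherwise
#' neutral. Segments overlapping any supplied immunoglobulin interval are
#' removed.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive), `copy_number`.
#' @param ig_loci optional data.frame of immunoglobulin intervals
#'   (`chrom`, `start`, `end`, 1-based inclusive).
#' @param amp_cn,del_cn thresholds (2.3 and 1.7, both inclusive).
#' @return the segment data.frame with a `class` column, immunoglobulin
#'   overlaps removed.
#' @export
classify_cnv_segments <- function(segments, ig_loci = NULL,
                                  amp_cn = 2.3, del_cn = 1.7) {
  assert_that(all(segments$copy_number >= 0),
              "copy numbers must be non-negative")
  assert_that(all(segments$end >= segments$start),
              "inverted segment interval")
  seg <- segments
  seg$class <- ifelse(seg$copy_number >= amp_cn, "amplified",
                      ifelse(seg$copy_number <= del_cn, "deleted",
                             "neutral"))
  if (!is.null(ig_loci) && nrow(ig_loci) > 0) {
    assert_that(all(ig_loci$end >= ig_loci$start),
                "inverted immunoglobulin interval")
    drop <- vapply(seq_len(nrow(seg)), function(i) {
      any(ig_loci$chrom == seg$chrom[i] &
            ig_loci$start <= seg$end[i] & ig_loci$end >= seg$start[i])
    }, TRUE)
    seg <- seg[!drop, , drop = FALSE]
  }
  rownames(seg) <- NULL
  seg
}

#' Convert BED intervals (0-based half-open) to 1-based inclusive
#'
#' @param bed data.frame with `chrom`, `start`, `end` in BED convention.
#' @return same data.frame with 1-based inclusive coordinates.
#' @export
bed_to_1based <- function(bed) {
  bed$start <- bed$start + 1L
  bed
}
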