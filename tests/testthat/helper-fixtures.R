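# Shared fixtures, generated in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small but complete cohort used across module tests.
tiny_config <- function(seed = 3) {
  sim_config(n_samples = 2, n_cells = 600, n_genes = 1200, seed = seed)
}

tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(tiny_config()))
}

tiny_malignant <- function() {
  memo("tiny_malignant", {
    co <- tiny_cohort()
    identify_malignant(co$expression$matrix, co$bcr$rearrangements,
                       seed = 5)
  })
}

# A hand-built count matrix with fully controlled QC properties:
# `detect` gives the number of detected genes per cell (count 1 each);
# filler cells expressing every gene keep all genes above the
# detected-in->=3-cells floor.
qc_matrix_fixture <- function(detect, n_genes = 600, n_filler = 3,
                              mito_counts = NULL, ribo_counts = 60) {
  n <- length(detect)
  syms <- c(sprintf("G%03d", seq_len(n_genes - 15)),
            sprintf("MT-G%d", 1:5), sprintf("RPL%d", 1:10))
  counts <- matrix(0, n + n_filler, n_genes)
  for (i in seq_len(n)) counts[i, seq_len(detect[i])] <- 1
  # every cell needs ribosomal content to pass the >=5% rule
  ribo_cols <- which(startsWith(syms, "RPL"))
  counts[seq_len(n), ribo_cols] <- ribo_counts
  if (!is.null(mito_counts)) {
    mito_cols <- which(startsWith(syms, "MT-"))
    for (i in seq_len(n)) counts[i, mito_cols] <- mito_counts[i]
  }
  counts[n + seq_len(n_filler), ] <- 2
  counts[n + seq_len(n_filler), ribo_cols] <- ribo_counts
  cell_matrix(counts,
              cell_meta = data.frame(
                sample = "s1",
                barcode = sprintf("c%02d", seq_len(n + n_filler))),
              gene_meta = data.frame(symbol = syms, chrom = "chr1",
                                     start = seq_len(n_genes) * 1000))
}

# Independent brute-force oracle: all rooted labeled trees on k nodes with
# a fixed root, via Prufer sequences, filtered by a direct statement of
# the sum rule.
oracle_trees <- function(ccf, epsilon, root) {
  k <- nrow(ccf)
  prufer_to_edges <- function(seq) {
    degree <- rep(1L, k)
    for (v in seq) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, 0, 2)
    for (v in seq) {
      leaf <- min(which(degree == 1L))
      edges <- rbind(edges, c(leaf, v))
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    rbind(edges, last)
  }
  root_at <- function(edges) {
    adj <- lapply(seq_len(k), function(v)
      c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
    parent <- integer(k)
    queue <- root; seen <- logical(k); seen[root] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!seen[u]) {
        seen[u] <- TRUE; parent[u] <- v; queue <- c(queue, u)
      }
    }
    parent
  }
  valid <- function(parent) {
    tol <- 1e-9
    for (v in seq_len(k)) {
      ch <- which(parent == v)
      if (length(ch) &&
          any(ccf[v, ] + epsilon + tol < colSums(ccf[ch, , drop = FALSE])))
        return(FALSE)
      if (parent[v] != 0L &&
          any(ccf[v, ] > ccf[parent[v], ] + epsilon + tol))
        return(FALSE)
    }
    TRUE
  }
  if (k == 2) {
    parent <- integer(2); parent[setdiff(1:2, root)] <- root
    return(if (valid(parent)) list(parent) else list())
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  out <- list()
  for (r in seq_len(nrow(seqs))) {
    parent <- root_at(prufer_to_edges(seqs[r, ]))
    if (valid(parent)) out[[length(out) + 1]] <- parent
  }
  out
}

tree_key <- function(parent) paste(parent, collapse = "-")
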