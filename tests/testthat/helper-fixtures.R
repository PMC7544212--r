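library(data.table)

# ---- random tag generator for dedup tests -------------------------------

random_tags <- function(n, seed, n_pos = 5L, umi_pool = 12L, umi_len = 8L,
                        n_samples = 1L) {
  set.seed(seed)
  pool <- replicate(umi_pool, paste(sample(c("A", "C", "G", "T"), umi_len,
                                           replace = TRUE), collapse = ""))
  data.table(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tss_pos = sample(seq(100L, 100L + n_pos), n, replace = TRUE),
    pas_pos = sample(c(900L, 901L, 950L), n, replace = TRUE),
    umi = sample(pool, n, replace = TRUE),
    sample_id = sample(sprintf("s%d", seq_len(n_samples)), n, replace = TRUE)
  )
}

# ---- independent O(n^2) connected-components dedup oracle ---------------
# Collapses identical molecules to counts, builds the full pairwise linkage
# graph (|dTSS| <= tss_shift, equal PAS bucket, UMI Hamming <= umi_mismatch,
# directional count rule) and takes igraph connected components.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_dedup <- function(tags, umi_mismatch = 1L, tss_shift = 1L,
                         method = "directional") {
  dt <- as.data.table(tags)[, .(count = .N),
                            by = .(sample_id, chrom, strand, tss_pos, pas_pos, umi)]
  n <- nrow(dt)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (dt$sample_id[i] != dt$sample_id[j]) next
      if (dt$chrom[i] != dt$chrom[j] || dt$strand[i] != dt$strand[j]) next
      if (dt$pas_pos[i] != dt$pas_pos[j]) next
      if (abs(dt$tss_pos[i] - dt$tss_pos[j]) > tss_shift) next
      if (oracle_hamming(dt$umi[i], dt$umi[j]) > umi_mismatch) next
      if (method == "directional") {
        hi <- max(dt$count[i], dt$count[j]); lo <- min(dt$count[i], dt$count[j])
        if (hi < 2L * lo - 1L) next
      }
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  dt[, comp := comp]
  out <- dt[, {
    o <- order(-count, tss_pos, umi)[1L]
    .(chrom = chrom[o], strand = strand[o], tss_pos = tss_pos[o],
      pas_pos = pas_pos[o], umi = umi[o], sample_id = sample_id[o],
      count = sum(count))
  }, by = comp][, comp := NULL]
  setorder(out, sample_id, chrom, strand, tss_pos, pas_pos, umi)
  out[]
}

# ---- tiny genome builder ------------------------------------------------
# Build a DNAStringSet from explicit sequences.

tiny_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# A minimal TIF table row for overlap/classification tests.
make_tif <- function(tif_id, chrom, strand, span_start, span_end,
                     tss_pos = NULL, pas_pos = NULL, width = 3L) {
  if (is.null(tss_pos)) tss_pos <- if (strand == "+") span_start else span_end - 1L
  if (is.null(pas_pos)) pas_pos <- if (strand == "+") span_end - 1L else span_start
  data.table(tif_id = tif_id, chrom = chrom, strand = strand,
             tss_id = paste0(tif_id, "_T"), pas_id = paste0(tif_id, "_P"),
             span_start = as.integer(span_start), span_end = as.integer(span_end),
             tss_start = as.integer(tss_pos), tss_end = as.integer(tss_pos + width),
             tss_pos = as.integer(tss_pos),
             pas_start = as.integer(pas_pos), pas_end = as.integer(pas_pos + width),
             pas_pos = as.integer(pas_pos), total_support = 10L)
}
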