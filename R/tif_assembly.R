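# Link TSS and PAS consensus clusters through supporting deduplicated read
# pairs into TIF calls and quantify them per sample.

#' Filter pairs on molecule span
#'
#' The molecule span is the inclusive base distance `|pas - tss| + 1`.
#' Pairs with extremely short (< `min_span`, default 300 bp) or extremely
#' long (> `max_span`, default 2 Mb) spans are dropped.
#'
#' @param tags Deduplicated tags with `tss_pos, pas_pos`.
#' @param min_span,max_span Inclusive span bounds (bp).
#' @return Logical vector, `TRUE` = keep.
#' @export
span_filter <- function(tags, min_span = 300L, max_span = 2e6) {
  d <- abs(tags$pas_pos - tags$tss_pos) + 1L
  d >= min_span & d <= max_span
}

# Assign positions to non-overlapping sorted intervals of one chrom/strand.
.assign_interval <- function(pos, starts, ends, ids) {
  if (length(starts) == 0L) return(rep(NA_character_, length(pos)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; ids <- ids[o]
  idx <- findInterval(pos, starts)
  hit <- idx >= 1L & pos < ends[pmax(idx, 1L)]
  out <- rep(NA_character_, length(pos))
  out[hit] <- ids[idx[hit]]
  out
}

#' Link read pairs to TSS/PAS consensus clusters
#'
#' A pair supports the combination `(tss_id, pas_id)` when its TSS position
#' lies inside that TSS consensus interval and its PAS position inside that
#' PAS interval, on the same chromosome and strand. Pairs matching no
#' cluster on either end are counted as unassigned.
#'
#' @param tags Deduplicated, priming- and span-filtered tags.
#' @param tss_clusters,pas_clusters Consensus cluster tables
#'   (`id, chrom, strand, start, end`).
#' @return List with `support` (data.table `tss_id, pas_id, sample_id, n`),
#'   `assigned` (tags plus `tss_id, pas_id`) and `n_unassigned`.
#' @export
link_pairs <- function(tags, tss_clusters, pas_clusters) {
  dt <- as.data.table(tags)
  tssc <- as.data.table(tss_clusters)
  pasc <- as.data.table(pas_clusters)
  dt[, tss_id := NA_character_]
  dt[, pas_id := NA_character_]
  for (g in split(seq_len(nrow(dt)), list(dt$chrom, dt$strand), drop = TRUE)) {
    ch <- dt$chrom[g[1L]]; st <- dt$strand[g[1L]]
    tc <- tssc[chrom == ch & strand == st]
    pc <- pasc[chrom == ch & strand == st]
    set(dt, g, "tss_id", .assign_interval(dt$tss_pos[g], tc$start, tc$end, tc$id))
    set(dt, g, "pas_id", .assign_interval(dt$pas_pos[g], pc$start, pc$end, pc$id))
  }
  assigned <- dt[!is.na(tss_id) & !is.na(pas_id)]
  support <- assigned[, .(n = .N), by = .(tss_id, pas_id, sample_id)]
  list(support = support, assigned = assigned,
       n_unassigned = nrow(dt) - nrow(assigned))
}

#' Call TIFs from cluster-linkage support
#'
#' A `(TSS cluster, PAS cluster)` combination becomes a transcript isoform
#' boundary (TIF) call when its summed support across all samples reaches
#' `min_support` (default 4 deduplicated read pairs). The per-sample
#' supporting pair counts form the expression matrix.
#'
#' @param support Support table from [link_pairs()].
#' @param tss_clusters,pas_clusters Consensus cluster tables (with
#'   `dominant_pos`).
#' @param min_support Minimum summed support across samples.
#' @param samples Sample ids for the matrix columns (default: those seen).
#' @return List with `tifs` (data.table `tif_id, chrom, strand, tss_id,
#'   pas_id, span_start, span_end, tss_start, tss_end, tss_pos, pas_start,
#'   pas_end, pas_pos, total_support`; ids deterministic by `(chrom,
#'   span_start, span_end)`) and `counts` (integer matrix TIF x sample).
#' @export
call_tifs <- function(support, tss_clusters, pas_clusters, min_support = 4L,
                      samples = NULL) {
  sup <- as.data.table(support)
  if (is.null(samples)) samples <- sort(unique(sup$sample_id))
  tot <- sup[, .(total_support = sum(n)), by = .(tss_id, pas_id)]
  called <- tot[total_support >= min_support]
  tssc <- as.data.table(tss_clusters)[, .(tss_id = id, chrom, strand,
                                          tss_start = start, tss_end = end,
                                          tss_pos = dominant_pos)]
  pasc <- as.data.table(pas_clusters)[, .(pas_id = id,
                                          pas_start = start, pas_end = end,
                                          pas_pos = dominant_pos)]
  tifs <- tssc[called, on = "tss_id"]
  tifs <- pasc[tifs, on = "pas_id"]
  tifs[, span_start := pmin(tss_start, pas_start)]
  tifs[, span_end := pmax(tss_end, pas_end)]
  setorder(tifs, chrom, span_start, span_end, strand)
  tifs[, tif_id := .make_ids("TIF", .N)]
  setcolorder(tifs, c("tif_id", "chrom", "strand", "tss_id", "pas_id",
                      "span_start", "span_end", "tss_start", "tss_end", "tss_pos",
                      "pas_start", "pas_end", "pas_pos", "total_support"))
  counts <- matrix(0L, nrow = nrow(tifs), ncol = length(samples),
                   dimnames = list(tifs$tif_id, samples))
  if (nrow(tifs)) {
    long <- sup[tifs[, .(tif_id, tss_id, pas_id)], on = c("tss_id", "pas_id"),
                nomatch = NULL]
    for (r in seq_len(nrow(long))) {
      counts[long$tif_id[r], long$sample_id[r]] <-
        counts[long$tif_id[r], long$sample_id[r]] + long$n[r]
    }
  }
  list(tifs = tifs[], counts = counts)
}
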