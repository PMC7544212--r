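# Pairwise genomic overlap between TIFs, tandem-arrangement typology, the
# 2-kb tandem PAS statistic, and read-through (transcriptional fusion)
# detection.

#' Classify the overlap pattern of a TIF pair
#'
#' Both overlap fractions above 0.9 -> `high_overlap` (alternative isoforms
#' of one locus); exactly one above 0.9 -> `truncated` (a long isoform and
#' its truncated form); both below 0.2 with a positive overlap ->
#' `low_tandem` (tandem transcription units); no overlap -> `disjoint`;
#' anything else -> `other`.
#'
#' @param frac_a,frac_b Overlap width divided by each TIF's span length.
#' @param overlap_width Overlap width in bp (0 when disjoint).
#' @param high,low Fraction cutoffs (strict comparisons).
#' @return Character vector of patterns.
#' @export
classify_pattern <- function(frac_a, frac_b, overlap_width,
                             high = 0.9, low = 0.2) {
  fifelse(overlap_width == 0, "disjoint",
          fifelse(frac_a > high & frac_b > high, "high_overlap",
                  fifelse(xor(frac_a > high, frac_b > high), "truncated",
                          fifelse(frac_a < low & frac_b < low, "low_tandem",
                                  "other"))))
}

#' Pairwise genomic overlap between same-strand TIFs
#'
#' For each ordered same-strand TIF pair whose strand-aware TSS-to-TSS
#' distance is at most `max_tss_window` (10 kb), reports the overlap width
#' (or the gap when disjoint), the overlap fraction of each TIF, and the
#' overlap pattern. TIF `a` is the upstream member (strand-aware TSS; ties
#' broken by span start). The `signed_overlap` column is positive for
#' overlap width and `-gap` when disjoint.
#'
#' @param tifs TIF table from [call_tifs()].
#' @param max_tss_window Maximum TSS-to-TSS distance (bp).
#' @return data.table of `OverlapRecord`s: `tif_a, tif_b, chrom, strand,
#'   overlap_width, gap, frac_a, frac_b, tss_tss_distance, signed_overlap,
#'   upstream_pas, downstream_tss, pattern`.
#' @export
pairwise_overlap <- function(tifs, max_tss_window = 10000L) {
  tf <- as.data.table(tifs)
  empty <- data.table(tif_a = character(), tif_b = character(),
                      chrom = character(), strand = character(),
                      overlap_width = integer(), gap = integer(),
                      frac_a = numeric(), frac_b = numeric(),
                      tss_tss_distance = integer(), signed_overlap = integer(),
                      upstream_pas = integer(), downstream_tss = integer(),
                      pattern = character())
  if (nrow(tf) < 2L) return(empty)
  recs <- list()
  for (g in split(tf, by = c("chrom", "strand"), sorted = TRUE)) {
    m <- nrow(g)
    if (m < 2L) next
    # order by strand-aware TSS so pair (i, j>i) has i upstream
    sgn <- if (g$strand[1L] == "+") 1L else -1L
    o <- order(sgn * g$tss_pos, g$span_start)
    g <- g[o]
    idx <- which(upper.tri(matrix(0L, m, m)), arr.ind = TRUE)
    i <- idx[, 1L]; j <- idx[, 2L]
    d_tss <- abs(g$tss_pos[j] - g$tss_pos[i])
    keep <- d_tss <= max_tss_window
    if (!any(keep)) next
    i <- i[keep]; j <- j[keep]; d_tss <- d_tss[keep]
    ov <- pmax(0L, pmin(g$span_end[i], g$span_end[j]) -
                 pmax(g$span_start[i], g$span_start[j]))
    gp <- pmax(0L, pmax(g$span_start[i], g$span_start[j]) -
                 pmin(g$span_end[i], g$span_end[j]))
    la <- g$span_end[i] - g$span_start[i]
    lb <- g$span_end[j] - g$span_start[j]
    recs[[length(recs) + 1L]] <- data.table(
      tif_a = g$tif_id[i], tif_b = g$tif_id[j],
      chrom = g$chrom[1L], strand = g$strand[1L],
      overlap_width = ov, gap = gp,
      frac_a = ov / la, frac_b = ov / lb,
      tss_tss_distance = d_tss,
      signed_overlap = fifelse(ov > 0L, ov, -gp),
      upstream_pas = g$pas_pos[i], downstream_tss = g$tss_pos[j])
  }
  if (length(recs) == 0L) return(empty)
  out <- rbindlist(recs)
  out[, pattern := classify_pattern(frac_a, frac_b, overlap_width)]
  out[]
}

#' Tandem PAS statistic: upstream poly(A) sites early in the downstream unit
#'
#' Among overlapping TIF pairs, the fraction whose upstream TIF's PAS lies
#' within `window` (2 kb) downstream of the downstream TIF's TSS -- the
#' signature that upstream transcription terminates within the first 2 kb
#' of the downstream transcription unit.
#'
#' @param records Overlap records from [pairwise_overlap()].
#' @param window Distance window (bp).
#' @return List with `fraction` (`NA` when no overlapping pairs), `n_pairs`
#'   and `flags` (records subset with a logical `within_window` column).
#' @export
tandem_pas_statistic <- function(records, window = 2000L) {
  dt <- as.data.table(records)
  ov <- dt[overlap_width > 0L]
  if (nrow(ov) == 0L) {
    return(list(fraction = NA_real_, n_pairs = 0L, flags = ov))
  }
  delta <- fifelse(ov$strand == "+",
                   ov$upstream_pas - ov$downstream_tss,
                   ov$downstream_tss - ov$upstream_pas)
  ov[, within_window := delta >= 0L & delta <= window]
  list(fraction = mean(ov$within_window), n_pairs = nrow(ov), flags = ov[])
}

#' Detect read-through TIFs bridging neighbouring genes
#'
#' A TIF is a read-through (potential transcriptional gene fusion) when its
#' TSS lies within (or within `tol` of) one gene's span and its PAS within
#' (or within `tol` of) a distinct same-strand gene downstream of the
#' first. Genes overlapping another same-strand gene are excluded from
#' candidacy (ambiguous assignment), and by default no third same-strand
#' gene may lie wholly between the TIF's TSS and PAS with both its
#' boundaries outside the two partners (`allow_skipped_genes` relaxes
#' this, for fusions stepping over an intervening annotated unit).
#'
#' @param tifs TIF table.
#' @param genes Gene models from [read_annotation()].
#' @param tol Boundary tolerance (bp).
#' @param allow_skipped_genes Permit intervening same-strand genes between
#'   the two partners.
#' @return data.table of `ReadThroughCall`s: `tif_id, upstream_gene,
#'   downstream_gene, tss_location, pas_location` (`inside` or `near`).
#' @export
detect_read_through <- function(tifs, genes, tol = 200L,
                                allow_skipped_genes = FALSE) {
  tf <- as.data.table(tifs)
  gn <- as.data.table(genes)
  empty <- data.table(tif_id = character(), upstream_gene = character(),
                      downstream_gene = character(), tss_location = character(),
                      pas_location = character())
  if (nrow(tf) == 0L || nrow(gn) < 2L) return(empty)
  # exclude genes overlapping another same-strand gene
  gn[, excluded := FALSE]
  for (r in seq_len(nrow(gn))) {
    gn[r, excluded := gn[chrom == gn$chrom[r] & strand == gn$strand[r] &
                           gene_id != gn$gene_id[r] &
                           start < gn$end[r] & end > gn$start[r], .N] > 0L]
  }
  cand_genes <- gn[excluded == FALSE]
  calls <- list()
  locate <- function(pos, g) {
    if (pos >= g$start && pos < g$end) "inside"
    else if (pos >= g$start - tol && pos < g$end + tol) "near"
    else NA_character_
  }
  nearest_gene <- function(ch, st, pos) {
    cc <- cand_genes[chrom == ch & strand == st]
    if (nrow(cc) == 0L) return(NULL)
    dist <- pmax(0L, pmax(cc$start - pos, pos - (cc$end - 1L)))
    cc2 <- cc[dist <= tol]
    if (nrow(cc2) == 0L) return(NULL)
    cc2[order(dist[dist <= tol], start)][1L]
  }
  for (r in seq_len(nrow(tf))) {
    ga <- nearest_gene(tf$chrom[r], tf$strand[r], tf$tss_pos[r])
    gb <- nearest_gene(tf$chrom[r], tf$strand[r], tf$pas_pos[r])
    if (is.null(ga) || is.null(gb) || ga$gene_id == gb$gene_id) next
    # B must be strand-aware downstream of A
    down_ok <- if (tf$strand[r] == "+") gb$start >= ga$end else gb$end <= ga$start
    if (!down_ok) next
    if (!allow_skipped_genes) {
      lo <- min(tf$tss_pos[r], tf$pas_pos[r])
      hi <- max(tf$tss_pos[r], tf$pas_pos[r])
      skipped <- gn[chrom == tf$chrom[r] & strand == tf$strand[r] &
                      !gene_id %in% c(ga$gene_id, gb$gene_id) &
                      start > lo & end <= hi + 1L, .N]
      if (skipped > 0L) next
    }
    calls[[length(calls) + 1L]] <- data.table(
      tif_id = tf$tif_id[r],
      upstream_gene = ga$gene_id, downstream_gene = gb$gene_id,
      tss_location = locate(tf$tss_pos[r], ga),
      pas_location = locate(tf$pas_pos[r], gb))
  }
  if (length(calls) == 0L) return(empty)
  rbindlist(calls)
}
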