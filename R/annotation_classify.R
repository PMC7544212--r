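# Assign TIFs to annotated transcripts/genes, classify them into five
# categories, and define unannotated transcribed regions.

#' Assign TIFs to overlapping annotated transcripts
#'
#' Candidate transcripts are those whose span overlaps the TIF span on the
#' same strand. `d1` is the distance between the TIF's TSS-side boundary
#' and the transcript's 5' end, `d2` between the PAS-side boundary and the
#' 3' end (strand-aware). The TIF is assigned to the candidate minimizing
#' `d1 + d2` (ties: smaller `d1`, then lexicographically smallest
#' transcript id), and inherits that transcript's gene. TIFs with no
#' same-strand overlap stay unassigned.
#'
#' @param tifs TIF table from [call_tifs()].
#' @param transcripts Transcript models from [read_annotation()].
#' @param mode Boundary used for distances: `"dominant"` (cluster dominant
#'   position, the best single-nucleotide estimate) or `"edge"` (nearest
#'   cluster edge to the transcript end).
#' @return data.table `tif_id, transcript_id, gene_id, d1, d2` (`NA` ids
#'   and distances when unassigned).
#' @export
assign_tifs <- function(tifs, transcripts, mode = c("dominant", "edge")) {
  mode <- match.arg(mode)
  tf <- as.data.table(tifs)
  tx <- as.data.table(transcripts)
  out <- data.table(tif_id = tf$tif_id, transcript_id = NA_character_,
                    gene_id = NA_character_, d1 = NA_real_, d2 = NA_real_)
  if (nrow(tf) == 0L || nrow(tx) == 0L) return(out)
  tf_gr <- GenomicRanges::GRanges(tf$chrom, .to_iranges(tf$span_start, tf$span_end),
                                  strand = tf$strand)
  tx_gr <- GenomicRanges::GRanges(tx$chrom, .to_iranges(tx$start, tx$end),
                                  strand = tx$strand)
  hits <- GenomicRanges::findOverlaps(tf_gr, tx_gr)  # strand-aware by default
  if (length(hits) == 0L) return(out)
  cand <- data.table(ti = S4Vectors::queryHits(hits), xi = S4Vectors::subjectHits(hits))
  cand[, tx5 := .five_prime(tx$start[xi], tx$end[xi], tx$strand[xi])]
  cand[, tx3 := .three_prime(tx$start[xi], tx$end[xi], tx$strand[xi])]
  if (mode == "dominant") {
    cand[, d1 := abs(tf$tss_pos[ti] - tx5)]
    cand[, d2 := abs(tf$pas_pos[ti] - tx3)]
  } else {
    near <- function(lo, hi, target) pmin(abs(lo - target), abs(hi - 1L - target))
    cand[, d1 := near(tf$tss_start[ti], tf$tss_end[ti], tx5)]
    cand[, d2 := near(tf$pas_start[ti], tf$pas_end[ti], tx3)]
  }
  cand[, dsum := d1 + d2]
  cand[, transcript_id := tx$transcript_id[xi]]
  cand[, gene_id := tx$gene_id[xi]]
  best <- cand[order(dsum, d1, transcript_id), .SD[1L], by = ti]
  out[best$ti, `:=`(transcript_id = best$transcript_id, gene_id = best$gene_id,
                    d1 = best$d1, d2 = best$d2)]
  out
}

#' Classify assigned TIFs into five categories
#'
#' Unassigned TIFs are `intergenic`. Otherwise, with tolerance `tol`
#' (default 200 bp, inclusive): both distances within tolerance ->
#' `annotated`; only the TSS distance beyond -> `new_tss`; only the PAS
#' distance beyond -> `new_pas`; both beyond -> `new_boundaries`.
#'
#' @param assignments Output of [assign_tifs()].
#' @param tol Distance tolerance (bp, inclusive).
#' @return `assignments` with an added `category` factor column.
#' @export
classify_tifs <- function(assignments, tol = 200L) {
  dt <- as.data.table(assignments)
  lv <- c("annotated", "new_tss", "new_pas", "new_boundaries", "intergenic")
  dt[, category := fifelse(
    is.na(transcript_id), "intergenic",
    fifelse(d1 <= tol & d2 <= tol, "annotated",
            fifelse(d1 > tol & d2 <= tol, "new_tss",
                    fifelse(d1 <= tol & d2 > tol, "new_pas", "new_boundaries"))))]
  dt[, category := factor(category, levels = lv)]
  dt[]
}

#' Define unannotated transcribed regions from intergenic TIFs
#'
#' Intergenic TIFs on one chromosome/strand are merged transitively when
#' their spans overlap; each merged region is one unannotated gene. Regions
#' touching an annotated gene on the same strand should not exist when
#' classification was correct; any found are dropped with a warning.
#'
#' @param tifs TIF table.
#' @param assignments Classified assignments ([classify_tifs()]).
#' @param genes Gene models from [read_annotation()].
#' @return data.table `id, chrom, strand, start, end, n_tifs, tif_ids`
#'   (comma-separated member TIF ids).
#' @export
define_unannotated_genes <- function(tifs, assignments, genes) {
  tf <- as.data.table(tifs)
  asg <- as.data.table(assignments)
  inter <- tf[tif_id %in% asg[category == "intergenic", tif_id]]
  empty <- data.table(id = character(), chrom = character(), strand = character(),
                      start = integer(), end = integer(), n_tifs = integer(),
                      tif_ids = character())
  if (nrow(inter) == 0L) return(empty)
  pieces <- lapply(split(inter, by = c("chrom", "strand"), sorted = TRUE), function(g) {
    ir <- .to_iranges(g$span_start, g$span_end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)  # merge only true overlaps
    within <- IRanges::findOverlaps(ir, red, type = "within")
    g[, region := S4Vectors::subjectHits(within)[order(S4Vectors::queryHits(within))]]
    bounds <- .from_iranges(red)
    g[, .(chrom = chrom[1L], strand = strand[1L],
          start = bounds$start[region[1L]], end = bounds$end[region[1L]],
          n_tifs = .N, tif_ids = paste(sort(tif_id), collapse = ",")),
      by = region][, region := NULL]
  })
  reg <- rbindlist(pieces)
  gn <- as.data.table(genes)
  if (nrow(gn)) {
    bad <- logical(nrow(reg))
    for (r in seq_len(nrow(reg))) {
      bad[r] <- gn[chrom == reg$chrom[r] & strand == reg$strand[r] &
                     start < reg$end[r] & end > reg$start[r], .N] > 0L
    }
    if (any(bad)) {
      warning(sum(bad), " unannotated region(s) overlap annotated genes; dropped ",
              "(indicates misclassified TIFs)")
      reg <- reg[!bad]
    }
  }
  if (nrow(reg) == 0L) return(empty)
  setorder(reg, chrom, start, strand)
  reg[, id := .make_ids("UG", .N)]
  setcolorder(reg, c("id", "chrom", "strand", "start", "end", "n_tifs", "tif_ids"))
  reg[]
}
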