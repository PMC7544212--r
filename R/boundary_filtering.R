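# Internal-priming artifact filter for PAS tags, and the hexamer-motif QC
# that justifies its threshold.

#' Genomic context around putative poly(A) sites
#'
#' For each PAS tag, extracts the 10 genomic bases immediately downstream of
#' the PAS base on the transcript strand (the PAS base itself is the last
#' transcribed nucleotide and is excluded) and the 15-30 nt upstream window,
#' both reverse-complemented for minus-strand tags and truncated at
#' chromosome ends. `a_count` is the number of `A`s in the downstream
#' window; `N` bases never count.
#'
#' @param tags data.table with `chrom, strand, pas_pos`.
#' @param genome `DNAStringSet` from [read_genome()].
#' @param downstream_len Downstream window length (nt).
#' @return Input columns plus `downstream10`, `upstream_window` (15-30 nt
#'   upstream, 5'->3' on the transcript strand) and `a_count`.
#' @export
pas_context <- function(tags, genome, downstream_len = 10L) {
  dt <- as.data.table(tags)
  .assert(all(dt$chrom %in% names(genome)),
          "unknown chromosome(s): %s",
          paste(unique(setdiff(dt$chrom, names(genome))), collapse = ","))
  lens <- setNames(Biostrings::width(genome), names(genome))
  .assert(all(dt$pas_pos >= 0L & dt$pas_pos < lens[dt$chrom]),
          "PAS position outside chromosome")
  down <- character(nrow(dt))
  up <- character(nrow(dt))
  for (i in seq_len(nrow(dt))) {
    p <- dt$pas_pos[i]; ch <- dt$chrom[i]
    if (dt$strand[i] == "+") {
      down[i] <- genome_seq(genome, ch, p + 1L, p + 1L + downstream_len, truncate = TRUE)
      up[i] <- genome_seq(genome, ch, p - 30L, p - 14L, truncate = TRUE)
    } else {
      down[i] <- .revcomp(genome_seq(genome, ch, p - downstream_len, p, truncate = TRUE))
      up[i] <- .revcomp(genome_seq(genome, ch, p + 15L, p + 31L, truncate = TRUE))
    }
  }
  dt[, downstream10 := down]
  dt[, upstream_window := up]
  dt[, a_count := vapply(strsplit(down, "", fixed = TRUE),
                         function(x) sum(x == "A"), integer(1))]
  dt[]
}

#' Flag internal-priming artifacts
#'
#' A 3'-end tag whose downstream 10 nt contain at least `threshold` adenines
#' is an internal-priming case (oligo-dT annealed to a genomic A-rich tract
#' rather than the poly(A) tail) and is excluded from all downstream
#' clustering.
#'
#' @param ctx Output of [pas_context()] (or any table with `a_count`).
#' @param threshold Minimum downstream A count to flag; must lie in 0..10.
#' @return Logical vector, `TRUE` = flagged as internal priming.
#' @export
flag_internal_priming <- function(ctx, threshold = 7L) {
  .assert(threshold >= 0 && threshold <= 10, "threshold must be in [0,10]")
  ctx$a_count >= threshold
}

#' Poly(A)-hexamer QC around kept and flagged PAS tags
#'
#' Diagnostic (never filters): for each partition of PAS tags (kept vs
#' flagged) and each upstream offset 1..`max_offset`, the fraction of tags
#' whose hexamer starting at that offset matches `AATAAA` or `ATTAAA`
#' (`A[AT]TAAA`). The offset of a hexamer is the upstream distance of its
#' 5'-most base, counted from the base immediately 5' of the PAS base
#' (distance 1). The summary is the fraction of tags with at least one
#' match at offsets 15-30, where poly(A)-associated hexamers concentrate at
#' genuine cleavage sites.
#'
#' @param tags data.table with `chrom, strand, pas_pos` and logical column
#'   `flagged` (from [flag_internal_priming()]).
#' @param genome `DNAStringSet`.
#' @param max_offset Largest upstream offset scanned.
#' @param summary_range Offset range (inclusive) for the summary fraction.
#' @return List with `table` (data.table `partition, offset, fraction`) and
#'   `summary` (named numeric: fraction of tags with a 15-30 nt match, per
#'   partition; `NA` for empty partitions).
#' @export
hexamer_qc <- function(tags, genome, max_offset = 40L, summary_range = c(15L, 30L)) {
  dt <- as.data.table(tags)
  .assert("flagged" %in% names(dt), "tags need a 'flagged' column")
  motifs <- c("AATAAA", "ATTAAA")
  parts <- list(kept = dt[flagged == FALSE], flagged = dt[flagged == TRUE])
  tab <- list()
  summ <- c(kept = NA_real_, flagged = NA_real_)
  for (pname in names(parts)) {
    p <- parts[[pname]]
    if (nrow(p) == 0L) next
    # upstream sequence 5'->3' on the transcript strand, long enough for a
    # hexamer starting max_offset upstream
    need <- max_offset + 5L
    seqs <- character(nrow(p))
    for (i in seq_len(nrow(p))) {
      pos <- p$pas_pos[i]; ch <- p$chrom[i]
      if (p$strand[i] == "+") {
        seqs[i] <- genome_seq(genome, ch, pos - need, pos, truncate = TRUE)
      } else {
        seqs[i] <- .revcomp(genome_seq(genome, ch, pos + 1L, pos + 1L + need,
                                       truncate = TRUE))
      }
    }
    # in seqs, the last character is upstream distance 1
    wid <- nchar(seqs)
    hit <- matrix(FALSE, nrow(p), max_offset)
    for (o in seq_len(max_offset)) {
      # hexamer 5' base at distance o spans distances o..o-5; representable
      # only when the full hexamer lies upstream of the PAS (o >= 6)
      if (o < 6L) next
      s <- wid - o + 1L
      hex <- substr(seqs, s, s + 5L)
      hit[, o] <- nchar(hex) == 6L & hex %in% motifs
    }
    tab[[pname]] <- data.table(partition = pname, offset = seq_len(max_offset),
                               fraction = colMeans(hit))
    in_range <- seq(summary_range[1], summary_range[2])
    summ[pname] <- mean(rowSums(hit[, in_range, drop = FALSE]) > 0L)
  }
  list(table = rbindlist(tab), summary = summ)
}

#' Apply the internal-priming filter to deduplicated tags
#'
#' Convenience wrapper: computes [pas_context()] for the distinct PAS
#' positions in `tags`, flags artifacts at `threshold`, and splits the tags.
#'
#' @param tags Deduplicated tags (`chrom, strand, tss_pos, pas_pos, ...`).
#' @param genome `DNAStringSet`.
#' @param threshold Passed to [flag_internal_priming()].
#' @return List with `kept`, `flagged` (tag subsets) and `context` (distinct
#'   PAS contexts with their flags).
#' @export
filter_internal_priming <- function(tags, genome, threshold = 7L) {
  dt <- as.data.table(tags)
  ctx <- pas_context(unique(dt[, .(chrom, strand, pas_pos)]), genome)
  ctx[, flagged := flag_internal_priming(ctx, threshold)]
  merged <- ctx[, .(chrom, strand, pas_pos, flagged)][dt, on = c("chrom", "strand", "pas_pos")]
  list(kept = merged[flagged == FALSE][, flagged := NULL][],
       flagged = merged[flagged == TRUE][, flagged := NULL][],
       context = ctx)
}
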