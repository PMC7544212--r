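# Raw aligned molecule records -> deduplicated single-nucleotide boundary
# pairs; library chimera-rate estimation from sample barcodes.

#' Extract single-nucleotide boundary pairs from raw molecule records
#'
#' The TSS is the first transcribed base (5' mate's outermost base) and the
#' PAS the last (3' mate's outermost base): on the plus strand
#' `tss = mate5_start`, `pas = mate3_end - 1`; on the minus strand
#' `tss = mate5_end - 1`, `pas = mate3_start`. Records whose mates map to
#' different chromosomes or strands, whose 5'/3' sample barcodes disagree
#' (detectable intermolecular circularization chimeras), or whose boundary
#' orientation contradicts the strand (PAS 5' of the TSS), are rejected
#' with a reason.
#'
#' @param records Raw molecule records from [read_paired_tags()] /
#'   [read_paired_bam()].
#' @return List with `tags` (data.table `chrom, strand, tss_pos, pas_pos,
#'   umi, sample_id`) and `rejected` (input rows plus `reason` in
#'   `cross_chromosome`, `discordant_strand`, `cross_barcode`,
#'   `inverted_orientation`).
#' @export
extract_boundary_pairs <- function(records) {
  dt <- as.data.table(records)
  if (!"chrom3" %in% names(dt)) dt[, chrom3 := chrom]
  if (!"strand3" %in% names(dt)) dt[, strand3 := strand]
  if (!"sample3" %in% names(dt)) dt[, sample3 := sample_id]
  dt[, reason := NA_character_]
  dt[, tss_pos := fifelse(strand == "+", mate5_start, mate5_end - 1L)]
  dt[, pas_pos := fifelse(strand == "+", mate3_end - 1L, mate3_start)]
  dt[chrom != chrom3, reason := "cross_chromosome"]
  dt[is.na(reason) & strand != strand3, reason := "discordant_strand"]
  dt[is.na(reason) & sample_id != sample3, reason := "cross_barcode"]
  dt[is.na(reason) &
       ((strand == "+" & pas_pos < tss_pos) | (strand == "-" & pas_pos > tss_pos)),
     reason := "inverted_orientation"]
  keep_cols <- c("chrom", "strand", "tss_pos", "pas_pos", "umi", "sample_id")
  list(tags = dt[is.na(reason), keep_cols, with = FALSE],
       rejected = dt[!is.na(reason)])
}

# Edge predicate of the duplicate-linkage graph for one candidate pair.
.dedup_edge <- function(dtss, dpas, hdist, ca, cb,
                        tss_shift, pas_shift, umi_mismatch, method) {
  ok <- dtss <= tss_shift & dpas <= pas_shift & hdist <= umi_mismatch
  if (method == "directional") {
    hi <- pmax(ca, cb); lo <- pmin(ca, cb)
    ok <- ok & (hi >= 2L * lo - 1L)
  }
  ok
}

#' Remove PCR duplicates by UMI clustering
#'
#' Tags are linkable when their TSS positions differ by at most `tss_shift`
#' (default 1 bp), their PAS positions by at most `pas_shift` (default 0:
#' exact), and their UMIs by at most `umi_mismatch` substitutions; with the
#' default `"directional"` method an edge between UMIs additionally requires
#' the higher count to be at least `2 x lower - 1` (directional adjacency,
#' as in UMI-tools network dedup). Connected components of this graph
#' collapse to one tag each: the representative is the highest-count member
#' (ties: smaller TSS coordinate, then lexicographically smallest UMI) and
#' the output `count` is the number of input molecules collapsed.
#'
#' Deduplication is performed independently per sample.
#'
#' @param tags data.table `chrom, strand, tss_pos, pas_pos, umi, sample_id`
#'   (optionally `count`, default 1 per row). UMIs must share one length.
#' @param umi_mismatch Maximum UMI Hamming distance for linkage.
#' @param tss_shift Maximum TSS coordinate shift for linkage (bp).
#' @param pas_shift Maximum PAS coordinate shift for linkage (bp).
#' @param method `"directional"` (count-gated edges) or `"cluster"`
#'   (plain single linkage).
#' @return data.table of deduplicated tags `chrom, strand, tss_pos, pas_pos,
#'   umi, sample_id, count`, ordered by `(sample_id, chrom, strand, tss_pos,
#'   pas_pos, umi)`. `sum(count)` equals the number of input molecules.
#' @export
dedup_umis <- function(tags, umi_mismatch = 1L, tss_shift = 1L, pas_shift = 0L,
                       method = c("directional", "cluster")) {
  method <- match.arg(method)
  dt <- as.data.table(tags)
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), strand = character(),
                      tss_pos = integer(), pas_pos = integer(),
                      umi = character(), sample_id = character(), count = integer()))
  }
  .assert(length(unique(nchar(dt$umi))) == 1L, "mixed UMI lengths")
  if (!"count" %in% names(dt)) dt[, count := 1L]
  if (!"sample_id" %in% names(dt)) dt[, sample_id := "sample"]
  # collapse identical molecules first; component counts follow these sums
  dt <- dt[, .(count = sum(count)),
           by = .(sample_id, chrom, strand, tss_pos, pas_pos, umi)]
  # candidate groups: tags can only link within the same sample/chrom/strand
  # and within pas_shift of each other, so bucket by exact PAS when
  # pas_shift = 0 (the default) to keep pairwise work local
  if (pas_shift == 0L) {
    dt[, grp := .GRP, by = .(sample_id, chrom, strand, pas_pos)]
  } else {
    dt[, grp := .GRP, by = .(sample_id, chrom, strand)]
  }
  out <- dt[, .dedup_group(.SD, umi_mismatch, tss_shift, pas_shift, method),
            by = grp]
  out[, grp := NULL]
  setorder(out, sample_id, chrom, strand, tss_pos, pas_pos, umi)
  out[]
}

# Deduplicate one candidate group (same sample/chrom/strand, PAS bucket).
.dedup_group <- function(g, umi_mismatch, tss_shift, pas_shift, method) {
  m <- nrow(g)
  if (m == 1L) {
    return(g[, .(chrom, strand, tss_pos, pas_pos, umi, sample_id, count)])
  }
  idx <- which(upper.tri(matrix(0L, m, m)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  ok <- .dedup_edge(abs(g$tss_pos[i] - g$tss_pos[j]),
                    abs(g$pas_pos[i] - g$pas_pos[j]),
                    .hamming(g$umi[i], g$umi[j]),
                    g$count[i], g$count[j],
                    tss_shift, pas_shift, umi_mismatch, method)
  comp <- .components(m, i[ok], j[ok])
  g2 <- copy(g)[, comp := comp]
  g2[, {
    o <- order(-count, tss_pos, umi)[1L]
    .(chrom = chrom[o], strand = strand[o], tss_pos = tss_pos[o],
      pas_pos = pas_pos[o], umi = umi[o], sample_id = sample_id[o],
      count = sum(count))
  }, by = comp][, comp := NULL][]
}

#' Estimate the intermolecular circularization (chimera) rate
#'
#' Chimeras join the 5' end of one cDNA to the 3' end of another during
#' circularization. With early sample pooling, a chimera between molecules
#' of different samples carries mismatched 5'/3' barcodes and is directly
#' observable. Under equal-mass pooling of `k` samples a chimera is
#' cross-sample with probability `(k-1)/k`, so the corrected rate is
#' `observed x k/(k-1)`, capped at 1.
#'
#' @param pairs data.table with columns `sample_id` (5'-side barcode) and
#'   `sample3` (3'-side barcode).
#' @param k Number of pooled samples; default the number of distinct
#'   barcodes seen. Must be at least 2.
#' @return List of class `chimera_estimate`: `n_pairs_total`,
#'   `n_cross_barcode`, `k_samples`, `observed_fraction`, `corrected_rate`.
#' @export
estimate_chimera_rate <- function(pairs, k = NULL) {
  dt <- as.data.table(pairs)
  .assert(all(c("sample_id", "sample3") %in% names(dt)),
          "pairs need sample_id and sample3 columns")
  if (is.null(k)) k <- length(unique(c(dt$sample_id, dt$sample3)))
  .assert(k >= 2, "chimera estimation needs k >= 2 pooled samples (got %d)", k)
  n_total <- nrow(dt)
  n_cross <- sum(dt$sample_id != dt$sample3)
  obs <- if (n_total > 0L) n_cross / n_total else 0
  structure(list(n_pairs_total = n_total, n_cross_barcode = n_cross,
                 k_samples = as.integer(k), observed_fraction = obs,
                 corrected_rate = min(1, obs * k / (k - 1))),
            class = "chimera_estimate")
}

#' @export
print.chimera_estimate <- function(x, ...) {
  cat(sprintf("chimera estimate: %d/%d cross-barcode pairs (k=%d)\n",
              x$n_cross_barcode, x$n_pairs_total, x$k_samples))
  cat(sprintf("  observed fraction %.4g, corrected rate %.4g\n",
              x$observed_fraction, x$corrected_rate))
  invisible(x)
}

#' Estimate the PCR duplicate rate from deduplication totals
#'
#' Under a model where each molecule gains one extra PCR copy with
#' probability `p`, the duplicate rate is estimated as
#' `(input rows - unique molecules) / unique molecules`.
#'
#' @param n_input Number of input molecule rows before deduplication.
#' @param n_unique Number of unique molecules after deduplication.
#' @return Estimated duplicate rate.
#' @export
estimate_duplicate_rate <- function(n_input, n_unique) {
  .assert(n_unique > 0, "no unique molecules")
  (n_input - n_unique) / n_unique
}
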