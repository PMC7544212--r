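# End-to-end orchestration: dedup -> span filter -> priming filter ->
# clustering -> TIF calling -> annotation -> overlap/read-through, with a
# resolved-config echo and a machine-readable summary.

#' Pipeline run configuration
#'
#' All stage thresholds with their standard defaults: 1 bp UMI mismatch and
#' 1 bp TSS shift for deduplication (exact PAS), internal-priming flag at
#' 7 or more downstream As, 10 bp clustering and consensus windows,
#' power-law normalization to `T * x^-alpha_ref` with `alpha_ref` 1.25 and
#' `T` 1e6 fitted over counts 10..1000, low-coverage exclusion when
#' normalized counts fall below 1 in more than one sample, singleton
#' clusters kept above 1 normalized count, 300 bp to 2 Mb molecule span,
#' at least 4 supporting read pairs per TIF, 200 bp annotation tolerance,
#' 10 kb pairwise-overlap window and 2 kb tandem PAS window.
#'
#' @param ... Named overrides of any default.
#' @return List of class `tif_run_config`.
#' @export
tif_run_config <- function(...) {
  cfg <- list(
    umi_mismatch = 1L, tss_shift = 1L, pas_shift = 0L,
    dedup_method = "directional",
    priming_max_a = 7L,
    cluster_window = 10L, alpha_ref = 1.25, T = 1e6, fit_range = c(10, 1000),
    max_low_samples = 1L, min_singleton_norm = 1,
    min_support = 4L, min_span = 300L, max_span = 2e6,
    annot_tol = 200L, boundary_mode = "dominant",
    overlap_window = 10000L, pas_window = 2000L, readthrough_tol = 200L,
    workers = 1L)
  over <- list(...)
  .assert(all(names(over) %in% names(cfg)),
          "unknown config field(s): %s",
          paste(setdiff(names(over), names(cfg)), collapse = ","))
  cfg[names(over)] <- over
  structure(cfg, class = "tif_run_config")
}

# Split chromosome names into `workers` deterministic chunks.
.chrom_chunks <- function(chroms, workers) {
  chroms <- sort(unique(chroms))
  workers <- max(1L, min(workers, length(chroms)))
  split(chroms, rep(seq_len(workers), length.out = length(chroms)))
}

#' Run the full TIF-calling pipeline
#'
#' Executes deduplication, molecule-span filtering, internal-priming
#' filtering, boundary clustering, TIF linking/calling and (when an
#' annotation is supplied) classification, unannotated-region definition,
#' overlap typology and read-through detection. Per-chromosome work is
#' independent; `config$workers` partitions chromosomes into chunks whose
#' results are recombined by deterministic sort, so outputs are identical
#' for any worker count.
#'
#' @param records Raw molecule records ([read_paired_tags()] /
#'   [simulate_library()]`$records`).
#' @param genome `DNAStringSet` reference (required for the priming filter).
#' @param annotation Optional list with `transcripts` and `genes`
#'   ([read_annotation()]).
#' @param config A [tif_run_config()].
#' @param out_dir Optional output directory; when given, writes cluster and
#'   TIF BED files, the counts matrix, the classified assignments, the
#'   resolved config (YAML) and a JSON summary.
#' @return List of class `tif_run` with elements `tags` (deduplicated),
#'   `flagged`, `tss`, `pas` (clustering results), `tifs`, `counts`,
#'   `assignments`, `unannotated_genes`, `overlaps`, `tandem_pas`,
#'   `read_through`, `chimera`, `summary` and `config`.
#' @export
run_tif_pipeline <- function(records, genome, annotation = NULL,
                             config = tif_run_config(), out_dir = NULL) {
  .assert(inherits(config, "tif_run_config"), "config must come from tif_run_config()")
  records <- as.data.table(records)
  extracted <- extract_boundary_pairs(records)
  n_input <- nrow(records)

  chunks <- .chrom_chunks(unique(extracted$tags$chrom), config$workers)
  dedup_parts <- lapply(chunks, function(ch) {
    dedup_umis(extracted$tags[chrom %in% ch],
               umi_mismatch = config$umi_mismatch, tss_shift = config$tss_shift,
               pas_shift = config$pas_shift, method = config$dedup_method)
  })
  tags <- rbindlist(dedup_parts)
  setorder(tags, sample_id, chrom, strand, tss_pos, pas_pos, umi)
  n_dedup <- nrow(tags)

  spanned <- tags[span_filter(tags, config$min_span, config$max_span)]
  n_span <- nrow(spanned)

  .assert(!is.null(genome), "a reference genome is required for the priming filter")
  primed <- filter_internal_priming(spanned, genome, config$priming_max_a)
  kept <- primed$kept
  n_primed <- nrow(primed$flagged)

  tss <- cluster_boundaries(kept, kind = "TSS", window = config$cluster_window,
                            alpha_ref = config$alpha_ref, T = config$T,
                            fit_range = config$fit_range,
                            max_low_samples = config$max_low_samples,
                            min_singleton_norm = config$min_singleton_norm,
                            chunks = chunks)
  pas <- cluster_boundaries(kept, kind = "PAS", window = config$cluster_window,
                            alpha_ref = config$alpha_ref, T = config$T,
                            fit_range = config$fit_range,
                            max_low_samples = config$max_low_samples,
                            min_singleton_norm = config$min_singleton_norm,
                            chunks = chunks)

  linked <- link_pairs(kept, tss$clusters, pas$clusters)
  samples <- sort(unique(extracted$tags$sample_id))
  called <- call_tifs(linked$support, tss$clusters, pas$clusters,
                      min_support = config$min_support, samples = samples)

  assignments <- NULL; unann <- NULL; rt <- NULL
  if (!is.null(annotation)) {
    assignments <- classify_tifs(
      assign_tifs(called$tifs, annotation$transcripts, mode = config$boundary_mode),
      tol = config$annot_tol)
    unann <- define_unannotated_genes(called$tifs, assignments, annotation$genes)
    rt <- detect_read_through(called$tifs, annotation$genes,
                              tol = config$readthrough_tol)
  }
  overlaps <- pairwise_overlap(called$tifs, max_tss_window = config$overlap_window)
  tandem <- tandem_pas_statistic(overlaps, window = config$pas_window)

  chimera <- NULL
  if ("sample3" %in% names(records) && length(samples) >= 2L) {
    chimera <- estimate_chimera_rate(records[, .(sample_id, sample3)],
                                     k = length(samples))
  }

  summary <- list(
    n_input_pairs = n_input,
    n_rejected = nrow(extracted$rejected),
    rejected_reasons = as.list(table(extracted$rejected$reason)),
    n_deduplicated = n_dedup,
    duplicate_rate = estimate_duplicate_rate(n_input - nrow(extracted$rejected), n_dedup),
    n_span_kept = n_span,
    n_priming_flagged = n_primed,
    n_priming_kept = nrow(kept),
    n_tss_clusters = nrow(tss$clusters),
    n_pas_clusters = nrow(pas$clusters),
    n_linked = nrow(linked$assigned),
    n_unassigned = linked$n_unassigned,
    n_tifs = nrow(called$tifs),
    category_tally = if (!is.null(assignments)) as.list(table(assignments$category)) else NULL,
    n_unannotated_genes = if (!is.null(unann)) nrow(unann) else NULL,
    n_read_through = if (!is.null(rt)) nrow(rt) else NULL,
    tandem_pas_fraction = tandem$fraction,
    chimera_corrected_rate = if (!is.null(chimera)) chimera$corrected_rate else NULL)

  run <- structure(list(tags = tags, flagged = primed$flagged,
                        priming_context = primed$context,
                        tss = tss, pas = pas, linked = linked,
                        tifs = called$tifs, counts = called$counts,
                        assignments = assignments, unannotated_genes = unann,
                        overlaps = overlaps, tandem_pas = tandem,
                        read_through = rt, chimera = chimera,
                        summary = summary, config = config),
                   class = "tif_run")
  if (!is.null(out_dir)) write_tif_run(run, out_dir)
  run
}

#' Write pipeline outputs to a directory
#'
#' Emits `tss_clusters.bed` / `pas_clusters.bed` (BED6), `tifs.bed`
#' (BED12), `tif_counts.tsv`, `assignments.tsv`, `unannotated_genes.bed`,
#' `read_through.tsv`, `overlaps.tsv`, the resolved `config.yaml` and
#' `summary.json`. Reruns with identical inputs produce byte-identical
#' files.
#'
#' @param run A `tif_run`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_tif_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  tssc <- copy(run$tss$clusters)[, norm := norm_sum]
  pasc <- copy(run$pas$clusters)[, norm := norm_sum]
  write_bed(tssc, pth("tss_clusters.bed"))
  write_bed(pasc, pth("pas_clusters.bed"))
  write_bed(run$tifs, pth("tifs.bed"))
  write_counts_matrix(run$counts, pth("tif_counts.tsv"))
  if (!is.null(run$assignments)) fwrite(run$assignments, pth("assignments.tsv"), sep = "\t")
  if (!is.null(run$unannotated_genes) && nrow(run$unannotated_genes)) {
    ug <- copy(run$unannotated_genes)
    write_bed(ug[, .(chrom, start, end, id, strand)], pth("unannotated_genes.bed"))
  }
  if (!is.null(run$read_through)) fwrite(run$read_through, pth("read_through.tsv"), sep = "\t")
  fwrite(run$overlaps, pth("overlaps.tsv"), sep = "\t")
  yaml::write_yaml(unclass(run$config), pth("config.yaml"))
  jsonlite::write_json(run$summary, pth("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.tif_run <- function(x, ...) {
  s <- x$summary
  cat("TIF pipeline run\n")
  cat(sprintf("  input pairs      %d (rejected %d)\n", s$n_input_pairs, s$n_rejected))
  cat(sprintf("  deduplicated     %d (duplicate rate %.3f)\n",
              s$n_deduplicated, s$duplicate_rate))
  cat(sprintf("  span-kept        %d; priming-flagged %d\n",
              s$n_span_kept, s$n_priming_flagged))
  cat(sprintf("  clusters         %d TSS / %d PAS\n", s$n_tss_clusters, s$n_pas_clusters))
  cat(sprintf("  TIFs             %d\n", s$n_tifs))
  if (!is.null(s$category_tally)) {
    cat("  categories       ",
        paste(names(s$category_tally), unlist(s$category_tally),
              sep = "=", collapse = " "), "\n")
  }
  if (!is.null(s$n_read_through)) {
    cat(sprintf("  read-through     %d\n", s$n_read_through))
  }
  invisible(x)
}
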