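# Ground-truth simulator: genomes with planted poly(A) hexamers and A-rich
# internal-priming tracts, annotations, isoform truth sets and multi-sample
# paired-tag libraries with PCR duplicates, boundary jitter, priming
# artifacts and inter-sample circularization chimeras.

#' Simulation configuration
#'
#' The defaults describe the reference study conditions used throughout the
#' test suite: 20 transcription units over two chromosomes, 4 pooled
#' samples, mean depth 50 molecules per unit abundance weight and sample,
#' 1 bp boundary jitter, 30% PCR duplication, 5% internal priming and 2%
#' chimera formation, with 8-mer UMIs and power-law (discrete Pareto,
#' exponent 1.25, truncated at 100) isoform abundances.
#'
#' `units` controls the layout: counts of isolated single-isoform genes,
#' two-isoform genes, genes whose expressed isoform has a novel TSS / PAS /
#' both (the annotation keeps the reference boundaries), unannotated
#' intergenic units, tandem-overlap gene pairs (upstream PAS inside the
#' first 2 kb of the downstream unit, low overlap fraction) and
#' read-through gene pairs (two genes plus a fusion isoform spanning both).
#'
#' @param seed Mandatory integer seed; the generator is fully deterministic
#'   given the seed.
#' @param units Named integer vector of layout counts (see above).
#' @param n_samples Number of pooled samples.
#' @param depth Expected molecules per sample for an isoform of abundance
#'   weight 1.
#' @param jitter_sd Boundary jitter standard deviation (bp; rounded normal,
#'   0 = exact boundaries).
#' @param pcr_dup_rate Probability a molecule emits one extra PCR copy.
#' @param priming_rate Probability a molecule's PAS is replaced by its
#'   unit's internal-priming artifact site.
#' @param chimera_rate Probability a molecule's 3' side is swapped with a
#'   uniformly drawn other molecule (circularization chimera).
#' @param alpha Pareto exponent of the isoform abundance law.
#' @param abundance_cap Truncation of the abundance law (dynamic range).
#' @param umi_length UMI length (nt).
#' @param read_length Mate length used to synthesize mate intervals (bp).
#' @param chrom_length Length of each simulated chromosome (bp).
#' @param slot_size Genomic slot reserved per transcription unit (bp).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       units = c(isolated = 7L, multi = 2L, new_tss = 2L,
                                 new_pas = 2L, new_boundaries = 1L,
                                 intergenic = 2L, tandem = 1L, readthrough = 1L),
                       n_samples = 4L, depth = 50, jitter_sd = 1,
                       pcr_dup_rate = 0.3, priming_rate = 0.05,
                       chimera_rate = 0.02, alpha = 1.25, abundance_cap = 100,
                       umi_length = 8L, read_length = 75L,
                       chrom_length = 300000L, slot_size = 25000L) {
  .assert(!missing(seed) && is.numeric(seed), "seed is mandatory")
  rates <- c(pcr_dup_rate, priming_rate, chimera_rate)
  .assert(all(rates >= 0 & rates <= 1), "rates must lie in [0,1]")
  .assert(jitter_sd >= 0, "jitter_sd must be >= 0")
  def <- eval(formals(sim_config)$units)
  u <- def
  u[names(units)] <- units
  structure(list(seed = as.integer(seed), units = u, n_samples = n_samples,
                 depth = depth, jitter_sd = jitter_sd,
                 pcr_dup_rate = pcr_dup_rate, priming_rate = priming_rate,
                 chimera_rate = chimera_rate, alpha = alpha,
                 abundance_cap = abundance_cap, umi_length = umi_length,
                 read_length = read_length, chrom_length = chrom_length,
                 slot_size = slot_size),
            class = "sim_config")
}

# Discrete Pareto(alpha, xmin = 1): P(X >= x) = x^-alpha, truncated at cap.
.rpareto_discrete <- function(n, alpha, cap = Inf) {
  x <- floor(runif(n)^(-1 / alpha))
  pmin(x, cap)
}

# Write `seq` along the transcript strand starting at genomic position
# `pos` and extending downstream (3') of the transcript. For "+" that is
# genome[pos .. pos+len), forward; for "-" it is genome[pos-len+1 .. pos]
# holding the reverse complement.
.plant <- function(chars, pos, seqstr, strand) {
  s <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  if (strand == "+") {
    chars[(pos + 1L):(pos + length(s))] <- s
  } else {
    comp <- chartr("ACGTN", "TGCAN", rev(s))
    chars[(pos - length(s) + 2L):(pos + 1L)] <- comp
  }
  chars
}

# Build the deterministic unit layout for a config. Returns the truth
# isoform table (boundaries, class labels, artifact sites) without
# abundances.
.build_layout <- function(config) {
  u <- config$units
  slot <- config$slot_size
  n_units <- sum(u)
  n_chroms <- max(1L, ceiling(n_units * slot / (config$chrom_length - slot)))
  chroms <- sprintf("chrS%d", seq_len(n_chroms))
  slots_per_chrom <- (config$chrom_length - 5000L) %/% slot
  .assert(slots_per_chrom >= 1L,
          "layout does not fit the configured chromosome length")
  iso <- list()
  unit_types <- rep(names(u), u)
  add <- function(...) iso[[length(iso) + 1L]] <<- data.table(...)
  slot_i <- 0L
  for (k in seq_along(unit_types)) {
    type <- unit_types[k]
    chrom <- chroms[(slot_i %/% slots_per_chrom) + 1L]
    base <- 5000L + (slot_i %% slots_per_chrom) * slot
    slot_i <- slot_i + 1L
    strand <- if (k %% 2L == 1L) "+" else "-"
    gid <- sprintf("G%03d", k)
    # spans on the genomic axis; tss/pas are strand-aware boundary bases
    mk <- function(s, e, suffix, class_label, annotated, ann_s = s, ann_e = e) {
      tss <- if (strand == "+") s else e - 1L
      pas <- if (strand == "+") e - 1L else s
      add(isoform_id = paste0(gid, "_", suffix), gene_id = gid,
          transcript_id = if (annotated) paste0("T", gid, "_", suffix) else NA_character_,
          chrom = chrom, strand = strand, tss = tss, pas = pas,
          start = s, end = e, class_label = class_label, annotated = annotated,
          ann_start = ann_s, ann_end = ann_e, unit = type)
    }
    if (type == "isolated") {
      mk(base, base + 3000L, "01", "annotated", TRUE)
    } else if (type == "multi") {
      mk(base, base + 5000L, "01", "annotated", TRUE)
      mk(base + 800L, base + 4200L, "02", "annotated", TRUE)
    } else if (type == "new_tss") {
      # annotation keeps the reference span; the expressed isoform starts
      # 600 bp inside it (novel TSS, same PAS)
      s <- base; e <- base + 4000L
      if (strand == "+") mk(s + 600L, e, "01", "new_tss", FALSE)
      else mk(s, e - 600L, "01", "new_tss", FALSE)
      add(isoform_id = paste0(gid, "_ref"), gene_id = gid,
          transcript_id = paste0("T", gid, "_ref"), chrom = chrom,
          strand = strand, tss = NA_integer_, pas = NA_integer_,
          start = s, end = e, class_label = "reference", annotated = TRUE,
          ann_start = s, ann_end = e, unit = type)
    } else if (type == "new_pas") {
      s <- base; e <- base + 4000L
      if (strand == "+") mk(s, e - 600L, "01", "new_pas", FALSE)
      else mk(s + 600L, e, "01", "new_pas", FALSE)
      add(isoform_id = paste0(gid, "_ref"), gene_id = gid,
          transcript_id = paste0("T", gid, "_ref"), chrom = chrom,
          strand = strand, tss = NA_integer_, pas = NA_integer_,
          start = s, end = e, class_label = "reference", annotated = TRUE,
          ann_start = s, ann_end = e, unit = type)
    } else if (type == "new_boundaries") {
      s <- base; e <- base + 4000L
      mk(s + 600L, e - 600L, "01", "new_boundaries", FALSE)
      add(isoform_id = paste0(gid, "_ref"), gene_id = gid,
          transcript_id = paste0("T", gid, "_ref"), chrom = chrom,
          strand = strand, tss = NA_integer_, pas = NA_integer_,
          start = s, end = e, class_label = "reference", annotated = TRUE,
          ann_start = s, ann_end = e, unit = type)
    } else if (type == "intergenic") {
      mk(base, base + 2000L, "01", "intergenic", FALSE)
    } else if (type == "tandem") {
      # upstream unit U ends 1 kb into downstream unit D; low overlap both
      if (strand == "+") {
        u_s <- base; u_e <- base + 6000L              # U: 6 kb
        d_s <- u_e - 1000L; d_e <- d_s + 12000L       # D: 12 kb, overlap 1 kb
      } else {
        d_e <- base + 12000L; d_s <- base
        u_s <- d_e - 1000L; u_e <- u_s + 6000L
      }
      gidu <- paste0(gid, "U"); gidd <- paste0(gid, "D")
      tssu <- if (strand == "+") u_s else u_e - 1L
      pasu <- if (strand == "+") u_e - 1L else u_s
      add(isoform_id = paste0(gidu, "_01"), gene_id = gidu,
          transcript_id = paste0("T", gidu, "_01"), chrom = chrom,
          strand = strand, tss = tssu, pas = pasu, start = u_s, end = u_e,
          class_label = "annotated", annotated = TRUE,
          ann_start = u_s, ann_end = u_e, unit = type)
      tssd <- if (strand == "+") d_s else d_e - 1L
      pasd <- if (strand == "+") d_e - 1L else d_s
      add(isoform_id = paste0(gidd, "_01"), gene_id = gidd,
          transcript_id = paste0("T", gidd, "_01"), chrom = chrom,
          strand = strand, tss = tssd, pas = pasd, start = d_s, end = d_e,
          class_label = "annotated", annotated = TRUE,
          ann_start = d_s, ann_end = d_e, unit = type)
    } else if (type == "readthrough") {
      # genes A and B, 2 kb apart, plus a fusion isoform spanning both
      if (strand == "+") {
        a_s <- base; a_e <- base + 3000L
        b_s <- a_e + 2000L; b_e <- b_s + 4000L
      } else {
        b_s <- base; b_e <- base + 4000L
        a_s <- b_e + 2000L; a_e <- a_s + 3000L
      }
      gida <- paste0(gid, "A"); gidb <- paste0(gid, "B")
      for (spec in list(list(gida, a_s, a_e), list(gidb, b_s, b_e))) {
        gi <- spec[[1]]; s <- spec[[2]]; e <- spec[[3]]
        tss <- if (strand == "+") s else e - 1L
        pas <- if (strand == "+") e - 1L else s
        add(isoform_id = paste0(gi, "_01"), gene_id = gi,
            transcript_id = paste0("T", gi, "_01"), chrom = chrom,
            strand = strand, tss = tss, pas = pas, start = s, end = e,
            class_label = "annotated", annotated = TRUE,
            ann_start = s, ann_end = e, unit = type)
      }
      # fusion: TSS of A, PAS of B; classified new_tss relative to B
      fs <- min(a_s, b_s); fe <- max(a_e, b_e)
      tss <- if (strand == "+") a_s else a_e - 1L
      pas <- if (strand == "+") b_e - 1L else b_s
      add(isoform_id = paste0(gid, "_RT"), gene_id = gidb,
          transcript_id = NA_character_, chrom = chrom, strand = strand,
          tss = tss, pas = pas, start = fs, end = fe,
          class_label = "new_tss", annotated = FALSE,
          ann_start = fs, ann_end = fe, unit = "readthrough_fusion")
    }
  }
  layout <- rbindlist(iso)
  .assert(all(layout$end + 100L <= config$chrom_length),
          "layout does not fit the configured chromosome length")
  layout[, n_chroms_used := n_chroms]
  layout
}

#' Generate a synthetic reference genome, annotation and truth skeleton
#'
#' Builds a random genome in which every expressed isoform's PAS has a
#' guaranteed A-free downstream 10 nt window and a planted `A[AT]TAAA`
#' hexamer 18-27 nt upstream (so 15-30 nt after up to 3 bp of jitter),
#' and every transcription unit carries one internal-priming artifact site
#' inside its body: a 26-base A-tract spanning 8 bases upstream to 17 bases
#' downstream of the artifact PAS, so jittered artifact positions still
#' show at least 7 downstream As. The annotated subset of isoforms is
#' written to the truth's transcript table (others stay unannotated to
#' exercise classification). Byte-identical output for identical seeds.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_reference`: `genome` (`DNAStringSet`),
#'   `transcripts` (annotated transcript models, 0-based half-open),
#'   `truth` (isoform table with `isoform_id, gene_id, transcript_id,
#'   chrom, strand, tss, pas, class_label, annotated, unit, artifact_pos,
#'   abundance`), `artifacts` (artifact site table) and `config`.
#' @export
generate_reference <- function(config) {
  .assert(inherits(config, "sim_config"), "config must come from sim_config()")
  set.seed(config$seed)
  layout <- .build_layout(config)
  n_chroms <- layout$n_chroms_used[1L]
  layout[, n_chroms_used := NULL]
  chroms <- sprintf("chrS%d", seq_len(n_chroms))
  genome_chars <- lapply(chroms, function(ch) {
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE)
  })
  names(genome_chars) <- chroms

  expressed <- layout[class_label != "reference"]
  # plant PAS context for every expressed isoform
  for (r in seq_len(nrow(expressed))) {
    ch <- expressed$chrom[r]; st <- expressed$strand[r]; pas <- expressed$pas[r]
    # A-free downstream 10 nt (starting at the base after the PAS base)
    down <- paste(sample(c("C", "G", "T"), 14L, replace = TRUE), collapse = "")
    start_down <- if (st == "+") pas + 1L else pas - 1L
    genome_chars[[ch]] <- .plant(genome_chars[[ch]], start_down, down, st)
    # hexamer with 5' base 18-27 nt upstream of the PAS base
    off <- sample(18:27, 1L)
    hex <- sample(c("AATAAA", "ATTAAA"), 1L)
    # transcript-strand position of the hexamer start (5'-most base)
    hex_pos <- if (st == "+") pas - off else pas + off
    genome_chars[[ch]] <- .plant(genome_chars[[ch]], hex_pos, hex, st)
  }
  # artifact sites: one per expressed unit, ~60% into the isoform body
  arts <- expressed[!unit %in% "readthrough_fusion"]
  artifact <- arts[, {
    span <- abs(pas - tss) + 1L
    offset <- pmax(400L, as.integer(span * 0.6))
    apos <- as.integer(tss + fifelse(strand == "+", 1L, -1L) * offset)
    .(artifact_pos = apos)
  }, by = .(isoform_id, gene_id, chrom, strand, tss, pas)]
  for (r in seq_len(nrow(artifact))) {
    ch <- artifact$chrom[r]; st <- artifact$strand[r]; ap <- artifact$artifact_pos[r]
    # 26 As spanning 8 upstream .. 17 downstream of the artifact PAS base
    tract_start <- if (st == "+") ap - 8L else ap + 8L
    genome_chars[[ch]] <- .plant(genome_chars[[ch]], tract_start,
                                 strrep("A", 26L), st)
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms

  truth <- expressed[, .(isoform_id, gene_id, transcript_id, chrom, strand,
                         tss, pas, start, end, class_label, annotated, unit)]
  truth <- artifact[, .(isoform_id, artifact_pos)][truth, on = "isoform_id"]
  truth[, abundance := .rpareto_discrete(.N, config$alpha, config$abundance_cap)]
  transcripts <- layout[annotated == TRUE,
                        .(transcript_id, gene_id, chrom, strand,
                          start = ann_start, end = ann_end)]
  setorder(transcripts, chrom, start, transcript_id)
  structure(list(genome = genome, transcripts = transcripts, truth = truth,
                 artifacts = artifact, config = config),
            class = "sim_reference")
}

#' Write a simulated reference to disk (FASTA + GTF)
#'
#' @param ref A `sim_reference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  gtf <- file.path(dir, "ref.gtf")
  Biostrings::writeXStringSet(ref$genome, fa)
  write_gtf(ref$transcripts, gtf)
  invisible(c(fasta = fa, gtf = gtf))
}

#' Simulate a multi-sample paired-tag library
#'
#' Per sample, each isoform emits `Poisson(depth * weight)` molecules,
#' where `weight = abundance / mean(abundance)`. Boundaries get independent
#' rounded zero-mean Gaussian jitter; each molecule receives a uniform
#' random UMI; with probability `priming_rate` the molecule's PAS is
#' replaced by its unit's artifact site (plus the molecule's PAS jitter);
#' with probability `chimera_rate` the molecule's 3' side (chromosome,
#' strand, PAS, barcode) is replaced by that of a uniformly drawn other
#' molecule; with probability `pcr_dup_rate` the final molecule emits one
#' extra identical copy. Fully deterministic given the config seed.
#'
#' @param ref A `sim_reference` from [generate_reference()].
#' @return List of class `sim_library`: `records` (raw molecule table in
#'   the paired-tag dialect plus truth labels `molecule_id, isoform_id,
#'   is_duplicate, dup_of, is_priming, is_chimera`), and `samples`.
#' @export
simulate_library <- function(ref) {
  config <- ref$config
  set.seed(config$seed + 1L)
  truth <- ref$truth
  samples <- sprintf("s%d", seq_len(config$n_samples))
  w <- truth$abundance / mean(truth$abundance)
  mols <- list()
  for (si in seq_along(samples)) {
    n_per_iso <- rpois(nrow(truth), config$depth * w)
    idx <- rep(seq_len(nrow(truth)), n_per_iso)
    if (length(idx) == 0L) next
    mols[[si]] <- data.table(isoform_id = truth$isoform_id[idx],
                             chrom = truth$chrom[idx], strand = truth$strand[idx],
                             tss = truth$tss[idx], pas = truth$pas[idx],
                             artifact_pos = truth$artifact_pos[idx],
                             sample_id = samples[si])
  }
  m <- rbindlist(mols)
  n <- nrow(m)
  .assert(n > 0L, "simulated library is empty; increase depth")
  m[, molecule_id := sprintf("M%07d", .I)]
  # boundary jitter, independent per end
  jit <- function(k) as.integer(round(rnorm(k, 0, config$jitter_sd)))
  if (config$jitter_sd > 0) {
    m[, tss := tss + jit(.N)]
    m[, pas := pas + jit(.N)]
  }
  # internal priming: PAS replaced by the unit's artifact site
  m[, is_priming := runif(.N) < config$priming_rate & !is.na(artifact_pos)]
  if (config$jitter_sd > 0) {
    m[is_priming == TRUE, pas := artifact_pos + jit(.N)]
  } else {
    m[is_priming == TRUE, pas := artifact_pos]
  }
  # UMIs
  m[, umi := do.call(paste0, as.data.table(matrix(
    sample(c("A", "C", "G", "T"), .N * config$umi_length, replace = TRUE),
    nrow = .N)))]
  # chimeras: 3' side replaced by a uniformly drawn other molecule's
  m[, `:=`(chrom3 = chrom, strand3 = strand, sample3 = sample_id)]
  m[, is_chimera := runif(.N) < config$chimera_rate]
  ci <- which(m$is_chimera)
  if (length(ci)) {
    partner <- sample(seq_len(n), length(ci), replace = TRUE)
    clash <- partner == ci
    while (any(clash)) {
      partner[clash] <- sample(seq_len(n), sum(clash), replace = TRUE)
      clash <- partner == ci
    }
    m[ci, `:=`(chrom3 = m$chrom[partner], strand3 = m$strand[partner],
               pas = m$pas[partner], sample3 = m$sample_id[partner])]
  }
  # clamp to chromosome bounds
  lens <- setNames(Biostrings::width(ref$genome), names(ref$genome))
  m[, tss := pmin(pmax(tss, 0L), lens[chrom] - 1L)]
  m[, pas := pmin(pmax(pas, 0L), lens[chrom3] - 1L)]
  # PCR duplicates: one extra identical copy with probability pcr_dup_rate
  m[, is_duplicate := FALSE]
  m[, dup_of := NA_character_]
  dup <- m[runif(.N) < config$pcr_dup_rate]
  if (nrow(dup)) {
    dup[, dup_of := molecule_id]
    dup[, molecule_id := paste0(molecule_id, "d")]
    dup[, is_duplicate := TRUE]
    m <- rbind(m, dup)
  }
  # mate intervals from boundary positions
  rl <- config$read_length
  m[, mate5_start := fifelse(strand == "+", tss, pmax(0L, tss - rl + 1L))]
  m[, mate5_end := fifelse(strand == "+", pmin(lens[chrom], tss + rl), tss + 1L)]
  m[, mate3_start := fifelse(strand3 == "+", pmax(0L, pas - rl + 1L), pas)]
  m[, mate3_end := fifelse(strand3 == "+", pas + 1L, pmin(lens[chrom3], pas + rl))]
  setorder(m, molecule_id)
  records <- m[, .(chrom, strand, mate5_start, mate5_end, mate3_start, mate3_end,
                   umi, sample_id, chrom3, strand3, sample3,
                   molecule_id, isoform_id, is_duplicate, dup_of,
                   is_priming, is_chimera)]
  structure(list(records = records, samples = samples, config = config),
            class = "sim_library")
}

#' Write a simulated library to disk
#'
#' `pairs.tsv` holds the paired-tag dialect columns; `truth.tsv` the full
#' per-molecule truth labels; `isoforms.tsv` the isoform truth set.
#'
#' @param lib A `sim_library`.
#' @param ref The matching `sim_reference`.
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_library <- function(lib, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- file.path(dir, "pairs.tsv")
  truth <- file.path(dir, "truth.tsv")
  isof <- file.path(dir, "isoforms.tsv")
  write_paired_tags(lib$records[, .(chrom, strand, mate5_start, mate5_end,
                                    mate3_start, mate3_end, umi, sample_id,
                                    chrom3, strand3, sample3)], pairs)
  fwrite(lib$records, truth, sep = "\t")
  fwrite(ref$truth, isof, sep = "\t")
  invisible(c(pairs = pairs, truth = truth, isoforms = isof))
}

#' Evaluate TIF recovery against simulated truth
#'
#' A call matches a truth isoform when the truth TSS lies inside the call's
#' TSS consensus interval and the truth PAS inside its PAS interval, on the
#' same chromosome and strand. Precision = matched calls / calls (absent
#' when there are no calls); recall = matched truths / truths. Boundary
#' errors are `dominant position - truth position` for matched boundaries.
#'
#' @param tifs TIF table from [call_tifs()].
#' @param truth Isoform truth table from [generate_reference()].
#' @return List: `precision`, `recall`, `n_calls`, `n_truth`,
#'   `matched_calls`, `matched_truths`, `tss_errors`, `pas_errors`,
#'   `matches` (call/truth id pairs).
#' @export
evaluate_recovery <- function(tifs, truth) {
  tf <- as.data.table(tifs)
  tr <- as.data.table(truth)
  n_calls <- nrow(tf); n_truth <- nrow(tr)
  matches <- list()
  for (r in seq_len(n_calls)) {
    hit <- tr[chrom == tf$chrom[r] & strand == tf$strand[r] &
                tss >= tf$tss_start[r] & tss < tf$tss_end[r] &
                pas >= tf$pas_start[r] & pas < tf$pas_end[r]]
    if (nrow(hit)) {
      matches[[length(matches) + 1L]] <- data.table(
        tif_id = tf$tif_id[r], isoform_id = hit$isoform_id,
        tss_error = tf$tss_pos[r] - hit$tss, pas_error = tf$pas_pos[r] - hit$pas)
    }
  }
  mt <- if (length(matches)) rbindlist(matches) else
    data.table(tif_id = character(), isoform_id = character(),
               tss_error = integer(), pas_error = integer())
  matched_calls <- uniqueN(mt$tif_id)
  matched_truths <- uniqueN(mt$isoform_id)
  list(precision = if (n_calls > 0L) matched_calls / n_calls else NA_real_,
       recall = if (n_truth > 0L) matched_truths / n_truth else NA_real_,
       n_calls = n_calls, n_truth = n_truth,
       matched_calls = matched_calls, matched_truths = matched_truths,
       tss_errors = mt$tss_error, pas_errors = mt$pas_error, matches = mt)
}
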