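# Readers/writers for on-disk formats and the in-memory genome/annotation
# model. All in-memory coordinates are 0-based half-open; GTF/GFF I/O
# converts at the boundary, BED is written natively 0-based.

#' Read a reference genome from FASTA
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique chromosome names
#'   (anything after the first whitespace in a FASTA header is dropped).
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  .assert(!anyDuplicated(names(genome)), "duplicated chromosome names in %s", path)
  .assert(all(Biostrings::width(genome) > 0L), "empty sequence in %s", path)
  genome
}

#' Extract genomic sequence, 0-based half-open
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval. Out-of-bounds lookups are an
#'   error; use `truncate = TRUE` to clip at chromosome ends instead.
#' @param truncate Clip the interval at chromosome bounds instead of erroring.
#' @return Character scalar (possibly shorter than requested when truncated).
#' @export
genome_seq <- function(genome, chrom, start, end, truncate = FALSE) {
  .assert(chrom %in% names(genome), "unknown chromosome '%s'", chrom)
  len <- length(genome[[chrom]])
  if (truncate) {
    start <- max(0L, start)
    end <- min(len, end)
    if (start >= end) return("")
  }
  .assert(start >= 0 && end <= len && start < end,
          "interval [%d,%d) out of bounds for %s (length %d)", start, end, chrom, len)
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Read transcript/gene models from GTF or GFF3
#'
#' Consumes `transcript` (and, when present, `gene`) records; exon structure
#' is ignored — this assay sees transcript boundaries only. 1-based inclusive
#' file coordinates are converted to 0-based half-open. Genes absent from the
#' file are synthesized as the union of their transcripts' spans.
#'
#' @param path GTF (Gencode dialect) or GFF3 file.
#' @return A list with `transcripts` and `genes` data.tables. Transcripts
#'   carry `transcript_id, gene_id, chrom, strand, start, end`, ordered by
#'   `(chrom, start, transcript_id)`; genes carry `gene_id, chrom, strand,
#'   start, end`.
#' @export
read_annotation <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("annotation parse error in ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  if (length(gr) == 0L) {
    warning("empty annotation file: ", path)
    empty_tx <- data.table(transcript_id = character(), gene_id = character(),
                           chrom = character(), strand = character(),
                           start = integer(), end = integer())
    empty_g <- data.table(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(), end = integer())
    return(list(transcripts = empty_tx, genes = empty_g))
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_tx <- type %in% c("transcript", "mRNA")
  .assert(any(is_tx), "no transcript records in %s", path)
  tx_gr <- gr[is_tx]
  tx_md <- S4Vectors::mcols(tx_gr)
  tid <- as.character(tx_md$transcript_id)
  gid <- as.character(tx_md$gene_id)
  .assert(!is.null(tid) && !anyNA(tid), "transcript without transcript_id in %s", path)
  if (length(gid) != length(tid) || anyNA(gid) || any(gid == "")) {
    bad <- if (length(gid) == length(tid)) tid[which(is.na(gid) | gid == "")[1]] else tid[1]
    stop("transcript '", bad, "' has no gene_id in ", path, call. = FALSE)
  }
  transcripts <- data.table(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomeInfoDb::seqnames(tx_gr)),
    strand = as.character(BiocGenerics::strand(tx_gr)),
    start = BiocGenerics::start(tx_gr) - 1L,  # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(tx_gr)
  )
  .assert(all(transcripts$strand %in% c("+", "-")),
          "transcript without strand in %s", path)
  .assert(all(transcripts$start < transcripts$end), "degenerate transcript span in %s", path)
  setorder(transcripts, chrom, start, transcript_id)

  genes <- transcripts[, .(chrom = chrom[1L], strand = strand[1L],
                           start = min(start), end = max(end)),
                       by = gene_id]
  # prefer explicit gene records when present (their span must cover members)
  if (any(type == "gene")) {
    g_gr <- gr[type == "gene"]
    g_md <- S4Vectors::mcols(g_gr)
    explicit <- data.table(
      gene_id = as.character(g_md$gene_id),
      chrom = as.character(GenomeInfoDb::seqnames(g_gr)),
      strand = as.character(BiocGenerics::strand(g_gr)),
      start = BiocGenerics::start(g_gr) - 1L,
      end = BiocGenerics::end(g_gr)
    )
    explicit <- explicit[gene_id %in% genes$gene_id]
    merged <- explicit[genes, on = "gene_id",
                       .(gene_id, chrom = i.chrom, strand = i.strand,
                         start = pmin(x.start, i.start, na.rm = TRUE),
                         end = pmax(x.end, i.end, na.rm = TRUE))]
    genes <- merged
  }
  setorder(genes, chrom, start, gene_id)
  list(transcripts = transcripts, genes = genes[, .(gene_id, chrom, strand, start, end)])
}

#' Write transcript models as Gencode-dialect GTF
#'
#' Emits one `gene` and one `transcript` line per record, converting the
#' internal 0-based half-open spans back to 1-based inclusive.
#'
#' @param transcripts data.table with `transcript_id, gene_id, chrom, strand,
#'   start, end` (0-based half-open).
#' @param path Output file.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path, source = "tifseqr") {
  tx <- as.data.table(transcripts)
  genes <- tx[, .(chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end)), by = gene_id]
  setorder(genes, chrom, start, gene_id)
  gl <- genes[, sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                        chrom, source, start + 1L, end, strand, gene_id)]
  setorder(tx, chrom, start, transcript_id)
  tl <- tx[, sprintf('%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
                     chrom, source, start + 1L, end, strand, gene_id, transcript_id)]
  writeLines(c(gl, tl), path)
  invisible(path)
}

#' Read raw paired boundary tags from TSV
#'
#' The paired-tag TSV dialect has a header and one molecule per row with
#' columns `chrom, strand, mate5_start, mate5_end, mate3_start, mate3_end,
#' umi, sample` (coordinates 0-based half-open). Three optional columns
#' `chrom3, strand3, sample3` describe the 3' mate when it differs from the
#' 5' side (chimeric or cross-chromosome molecules); when absent the mates
#' share chromosome, strand and sample. Cross-chromosome records are
#' retained here and flagged; they are rejected later by
#' [extract_boundary_pairs()].
#'
#' @param path TSV file.
#' @return data.table of raw molecule records with the columns above plus
#'   `cross_chromosome` (logical).
#' @export
read_paired_tags <- function(path) {
  need <- c("chrom", "strand", "mate5_start", "mate5_end",
            "mate3_start", "mate3_end", "umi", "sample")
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = "umi"))
  .assert(all(need %in% names(dt)),
          "paired-tag TSV %s missing columns: %s", path,
          paste(setdiff(need, names(dt)), collapse = ","))
  setnames(dt, "sample", "sample_id")
  if (!"chrom3" %in% names(dt)) dt[, chrom3 := chrom]
  if (!"strand3" %in% names(dt)) dt[, strand3 := strand]
  if (!"sample3" %in% names(dt)) dt[, sample3 := sample_id]
  dt[is.na(chrom3) | chrom3 == "", chrom3 := chrom]
  dt[is.na(strand3) | strand3 == "", strand3 := strand]
  dt[is.na(sample3) | sample3 == "", sample3 := sample_id]
  .assert(!anyNA(dt$umi) && all(nzchar(dt$umi)), "missing UMI in %s", path)
  ok_strand <- dt$strand %in% c("+", "-") & dt$strand3 %in% c("+", "-")
  if (!all(ok_strand)) {
    stop("unknown strand code '", dt$strand[!ok_strand][1], "' in ", path, call. = FALSE)
  }
  dt[, cross_chromosome := chrom != chrom3]
  dt[]
}

#' Write raw paired boundary tags as TSV
#'
#' Inverse of [read_paired_tags()]. The optional `chrom3/strand3/sample3`
#' columns are written only when any row needs them.
#'
#' @param records data.table of raw molecule records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paired_tags <- function(records, path) {
  dt <- as.data.table(records)
  if ("sample_id" %in% names(dt)) setnames(dt, "sample_id", "sample")
  cols <- c("chrom", "strand", "mate5_start", "mate5_end",
            "mate3_start", "mate3_end", "umi", "sample")
  extra <- character()
  if ("chrom3" %in% names(dt) && any(dt$chrom3 != dt$chrom)) extra <- c(extra, "chrom3")
  if ("strand3" %in% names(dt) && any(dt$strand3 != dt$strand)) extra <- c(extra, "strand3")
  if ("sample3" %in% names(dt) && any(dt$sample3 != dt$sample)) extra <- c(extra, "sample3")
  fwrite(dt[, c(cols, extra), with = FALSE], path, sep = "\t")
  invisible(path)
}

#' Read name-paired alignments (SAM/BAM) into raw molecule records
#'
#' Mate 1 is taken as the 5'-end read and mate 2 as the 3'-end read of each
#' molecule. The UMI comes from a tag (default `RX`) or, when absent, from
#' the read-name suffix after the last underscore (UMI-tools convention);
#' the sample label from the read group (`RG`) or the file name.
#'
#' @param path BAM file (SAM files are converted via [Rsamtools::asBam()]).
#' @param umi_tag Optional SAM tag holding the UMI.
#' @param sample Sample label override; default read group or basename.
#' @return data.table in the same shape as [read_paired_tags()] output.
#' @export
read_paired_bam <- function(path, umi_tag = "RX", sample = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  hasUnmappedMate = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "cigar"),
    tag = c(umi_tag, "RG"))
  res <- Rsamtools::scanBam(path, param = par)[[1]]
  n <- length(res$qname)
  .assert(n > 0L, "no paired alignments in %s", path)
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  dt <- data.table(
    qname = res$qname,
    first = bitwAnd(res$flag, 64L) > 0L,
    chrom = as.character(res$rname),
    strand = as.character(res$strand),
    start = res$pos - 1L,
    end = res$pos - 1L + width,
    umi = if (!is.null(res$tag[[umi_tag]])) as.character(res$tag[[umi_tag]]) else NA_character_,
    rg = if (!is.null(res$tag$RG)) as.character(res$tag$RG) else NA_character_
  )
  dt[is.na(umi), umi := sub("^.*_", "", qname)]
  .assert(all(nzchar(dt$umi)), "missing UMI (no %s tag, no name suffix) in %s", umi_tag, path)
  m5 <- dt[first == TRUE]
  m3 <- dt[first == FALSE]
  .assert(nrow(m5) > 0L && nrow(m3) > 0L, "no complete pairs in %s", path)
  setkey(m5, qname); setkey(m3, qname)
  pairs <- m5[m3, nomatch = NULL]
  if (is.null(sample)) {
    sample <- pairs$rg
    sample[is.na(sample)] <- tools::file_path_sans_ext(basename(path))
  }
  # the 3'-end read of a + strand molecule aligns to the - strand and vice
  # versa; the molecule strand is the 5' read's strand
  out <- data.table(
    chrom = pairs$chrom, strand = pairs$strand,
    mate5_start = pairs$start, mate5_end = pairs$end,
    mate3_start = pairs$i.start, mate3_end = pairs$i.end,
    umi = pairs$umi, sample_id = sample,
    chrom3 = pairs$i.chrom,
    strand3 = ifelse(pairs$i.strand == "+", "-", "+"),
    sample3 = sample
  )
  out[, cross_chromosome := chrom != chrom3]
  out[]
}

#' Write tags or clusters as BED6, or TIFs as BED12
#'
#' Clusters and single-position tags become BED6 lines (`score` = normalized
#' count x 10, rounded; name = record id). TIFs become BED12 lines whose two
#' blocks mark the TSS and PAS clusters. Output is sorted by
#' `(chrom, start, end)`.
#'
#' @param records data.table. For BED6: columns `chrom, start, end, id,
#'   strand` and optionally `norm` (normalized count). For BED12 (detected by
#'   presence of `tss_start`): TIF records from [call_tifs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if ("tss_start" %in% names(dt)) {
    setorder(dt, chrom, span_start, span_end)
    b1s <- pmin(dt$tss_start, dt$pas_start)
    b1e <- pmin(dt$tss_end, dt$pas_end)
    b2s <- pmax(dt$tss_start, dt$pas_start)
    b2e <- pmax(dt$tss_end, dt$pas_end)
    # clamp abutting/overlapping blocks so BED12 blocks stay disjoint
    b1e <- pmin(b1e, b2s)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0\t2\t%d,%d\t%d,%d",
                     dt$chrom, dt$span_start, dt$span_end, dt$tif_id,
                     pmin(1000L, as.integer(round(dt$total_support))),
                     dt$strand, dt$span_start, dt$span_end,
                     b1e - b1s, b2e - b2s,
                     b1s - dt$span_start, b2s - dt$span_start)
  } else {
    if (!"start" %in% names(dt) && "pos" %in% names(dt)) {
      dt[, `:=`(start = pos, end = pos + 1L)]
    }
    if (!"id" %in% names(dt)) dt[, id := .make_ids("REC", .N)]
    score <- if ("norm" %in% names(dt)) as.integer(round(dt$norm * 10)) else 0L
    dt[, score := score]
    setorder(dt, chrom, start, end)
    .assert(all(dt$start >= 0L & dt$start < dt$end), "invalid BED interval")
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                     dt$chrom, dt$start, dt$end, dt$id, dt$score, dt$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a TIF-by-sample counts matrix as TSV
#'
#' @param mat Numeric matrix, rows = TIF ids, columns = samples.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_matrix <- function(mat, path) {
  dt <- data.table(tif_id = rownames(mat))
  for (s in colnames(mat)) dt[[s]] <- mat[, s]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
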