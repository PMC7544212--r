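tx_row <- function(tid, gid, chrom, strand, start, end) {
  data.table::data.table(transcript_id = tid, gene_id = gid, chrom = chrom,
                         strand = strand, start = as.integer(start),
                         end = as.integer(end))
}

test_that("TIFs are assigned to the overlapping transcript minimizing d1+d2", {
  tx <- rbind(tx_row("t1", "g1", "c1", "+", 1000L, 5000L),
              tx_row("t2", "g1", "c1", "+", 1060L, 5030L),
              tx_row("t3", "g2", "c1", "-", 1000L, 5000L))
  # TIF identical to t1
  tif <- make_tif("TIF1", "c1", "+", 1000L, 5000L)
  a <- assign_tifs(tif, tx)
  expect_equal(a$transcript_id, "t1")
  expect_equal(a$gene_id, "g1")
  expect_equal(a$d1 + a$d2, 0)
  # TIF boundaries (1050, 5020): t1 sum = 50+21 = 71 > t2 sum = 10+9 = 19
  tif2 <- make_tif("TIF2", "c1", "+", 1050L, 5021L)
  a2 <- assign_tifs(tif2, tx)
  expect_equal(a2$transcript_id, "t2")
  expect_equal(a2$d1, 10)
  expect_equal(a2$d2, 9)
  # antisense overlap does not assign
  tif3 <- make_tif("TIF3", "c1", "-", 6000L, 7000L)
  expect_true(is.na(assign_tifs(tif3, tx)$transcript_id))
  # exhaustive-minimization oracle on random candidates
  set.seed(8)
  for (i in 1:10) {
    n <- 6L
    starts <- sample(500:1500, n)
    ends <- starts + sample(2000:4000, n)
    txr <- data.table::rbindlist(lapply(seq_len(n), function(k)
      tx_row(sprintf("tx%02d", k), "g", "c1", "+", starts[k], ends[k])))
    tifr <- make_tif("T", "c1", "+", 1200L, 4000L)
    got <- assign_tifs(tifr, txr)
    d1 <- abs(1200L - starts); d2 <- abs(3999L - (ends - 1L))
    ov <- starts < 4000L & ends > 1200L
    cand <- data.table::data.table(id = sprintf("tx%02d", seq_len(n)),
                                   d1 = d1, d2 = d2)[ov]
    best <- cand[order(d1 + d2, d1, id)][1]
    expect_equal(got$transcript_id, best$id)
    expect_equal(got$d1 + got$d2, best$d1 + best$d2)
  }
})

test_that("five-way classification uses the 200 bp tolerance inclusively", {
  mk <- function(d1, d2, tid = "t") data.table::data.table(
    tif_id = "x", transcript_id = tid, gene_id = "g", d1 = d1, d2 = d2)
  cls <- function(d1, d2) as.character(classify_tifs(mk(d1, d2))$category)
  expect_equal(cls(50, 100), "annotated")
  expect_equal(cls(200, 200), "annotated")   # inclusive boundary
  expect_equal(cls(201, 0), "new_tss")
  expect_equal(cls(0, 201), "new_pas")
  expect_equal(cls(500, 900), "new_boundaries")
  un <- data.table::data.table(tif_id = "x", transcript_id = NA_character_,
                               gene_id = NA_character_, d1 = NA_real_, d2 = NA_real_)
  expect_equal(as.character(classify_tifs(un)$category), "intergenic")
})

test_that("every TIF gets exactly one category and tallies sum to the total", {
  ref <- generate_reference(sim_config(seed = 17))
  lib <- simulate_library(ref)
  run <- run_tif_pipeline(lib$records, ref$genome,
                          annotation = list(transcripts = ref$transcripts,
                                            genes = read_annotation(
                                              write_gtf(ref$transcripts,
                                                        tempfile(fileext = ".gtf")))$genes))
  expect_false(anyNA(run$assignments$category))
  expect_equal(sum(table(run$assignments$category)), nrow(run$tifs))
})

test_that("designed boundary offsets classify on the confusion diagonal", {
  # simulate only class-bearing units; expected category = planted class
  cfg <- sim_config(seed = 23,
                    units = c(isolated = 4L, multi = 1L, new_tss = 2L,
                              new_pas = 2L, new_boundaries = 2L,
                              intergenic = 2L, tandem = 0L, readthrough = 0L))
  ref <- generate_reference(cfg)
  lib <- simulate_library(ref)
  ann <- read_annotation(write_gtf(ref$transcripts, tempfile(fileext = ".gtf")))
  run <- run_tif_pipeline(lib$records, ref$genome, annotation = ann)
  ev <- evaluate_recovery(run$tifs, ref$truth)
  joined <- merge(run$assignments[, .(tif_id, category)],
                  ev$matches[, .(tif_id, isoform_id)], by = "tif_id")
  joined <- merge(joined, ref$truth[, .(isoform_id, class_label)], by = "isoform_id")
  expect_equal(as.character(joined$category), joined$class_label)
})

test_that("overlapping intergenic TIFs merge into unannotated genes", {
  tifs <- rbind(make_tif("T1", "c1", "+", 1000L, 2000L),
                make_tif("T2", "c1", "+", 1500L, 2500L),
                make_tif("T3", "c1", "+", 9000L, 9500L))
  asg <- data.table::data.table(tif_id = c("T1", "T2", "T3"),
                                transcript_id = NA_character_,
                                gene_id = NA_character_, d1 = NA_real_, d2 = NA_real_)
  asg <- classify_tifs(asg)
  genes <- data.table::data.table(gene_id = "g", chrom = "c1", strand = "-",
                                  start = 1L, end = 10L)
  ug <- define_unannotated_genes(tifs, asg, genes)
  expect_equal(nrow(ug), 2L)
  expect_equal(ug$start, c(1000L, 9000L))
  expect_equal(ug$end, c(2500L, 9500L))
  expect_equal(ug$n_tifs, c(2L, 1L))
  expect_equal(ug$tif_ids[1], "T1,T2")
  # zero intergenic TIFs -> empty set
  asg2 <- data.table::copy(asg)[, `:=`(transcript_id = "t", gene_id = "g",
                                       d1 = 0, d2 = 0)]
  expect_equal(nrow(define_unannotated_genes(tifs, classify_tifs(asg2), genes)), 0L)
  # regions touching a same-strand annotated gene are dropped with a warning
  genes2 <- data.table::data.table(gene_id = "g", chrom = "c1", strand = "+",
                                   start = 1800L, end = 2100L)
  expect_warning(ug2 <- define_unannotated_genes(tifs, asg, genes2), "overlap")
  expect_equal(ug2$start, 9000L)
})
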