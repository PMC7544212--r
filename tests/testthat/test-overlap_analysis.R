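test_that("pairwise overlap arithmetic and upstream ordering are exact", {
  tifs <- rbind(make_tif("A", "c1", "+", 0L, 1000L),
                make_tif("B", "c1", "+", 500L, 2000L))
  rec <- pairwise_overlap(tifs)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$tif_a, "A")  # upstream by strand-aware TSS
  expect_equal(rec$overlap_width, 500L)
  expect_equal(rec$frac_a, 0.5)
  expect_equal(rec$frac_b, 1 / 3)
  expect_equal(rec$signed_overlap, 500L)
  # identical spans
  rec2 <- pairwise_overlap(rbind(make_tif("A", "c1", "+", 0L, 1000L),
                                 make_tif("B", "c1", "+", 0L, 1000L)))
  expect_equal(rec2$frac_a, 1)
  expect_equal(rec2$frac_b, 1)
  # disjoint: overlap 0, gap 200, signed overlap -200
  rec3 <- pairwise_overlap(rbind(make_tif("A", "c1", "+", 0L, 100L),
                                 make_tif("B", "c1", "+", 300L, 400L)))
  expect_equal(rec3$overlap_width, 0L)
  expect_equal(rec3$gap, 200L)
  expect_equal(rec3$signed_overlap, -200L)
  expect_equal(rec3$pattern, "disjoint")
  # pairs starting farther than 10 kb apart are not reported
  far <- pairwise_overlap(rbind(make_tif("A", "c1", "+", 0L, 1000L),
                                make_tif("B", "c1", "+", 20000L, 21000L)))
  expect_equal(nrow(far), 0L)
  # minus strand: upstream = larger TSS coordinate
  minus <- pairwise_overlap(rbind(make_tif("A", "c1", "-", 1000L, 3000L),
                                  make_tif("B", "c1", "-", 0L, 1500L)))
  expect_equal(minus$tif_a, "A")
})

test_that("overlap patterns follow the 90%/20% rule table and partition", {
  expect_equal(classify_pattern(0.95, 0.97, 100L), "high_overlap")
  expect_equal(classify_pattern(0.95, 0.30, 100L), "truncated")
  expect_equal(classify_pattern(0.30, 0.95, 100L), "truncated")
  expect_equal(classify_pattern(0.10, 0.15, 100L), "low_tandem")
  expect_equal(classify_pattern(0.5, 0.5, 100L), "other")
  expect_equal(classify_pattern(0, 0, 0L), "disjoint")
  # symmetric for the symmetric classes
  set.seed(31)
  fa <- runif(50); fb <- runif(50)
  p1 <- classify_pattern(fa, fb, rep(1L, 50))
  p2 <- classify_pattern(fb, fa, rep(1L, 50))
  sym <- p1 %in% c("high_overlap", "low_tandem", "other")
  expect_equal(p1[sym], p2[sym])
  # every record gets exactly one pattern
  expect_false(anyNA(p1))
})

test_that("designed overlap fractions classify exactly as designed", {
  # construct spans realizing fractions {0.95/0.97, 0.95/0.30, 0.10/0.15}
  tifs <- rbind(
    make_tif("H1", "c1", "+", 0L, 10000L),      # len 10000
    make_tif("H2", "c1", "+", 300L, 10090L),    # overlap 9700: 0.97/~0.99
    make_tif("T1", "c1", "+", 20000L, 30000L),  # len 10000
    make_tif("T2", "c1", "+", 26500L, 30000L))  # overlap 3500 -> 0.35/1.0
  rec <- pairwise_overlap(tifs)
  expect_equal(rec[tif_a == "H1" & tif_b == "H2", pattern], "high_overlap")
  expect_equal(rec[tif_a == "T1" & tif_b == "T2", pattern], "truncated")
  low <- rbind(make_tif("L1", "c1", "+", 0L, 2000L),
               make_tif("L2", "c1", "+", 1800L, 3133L))
  # overlap 200 -> frac 0.10 and 0.15
  rec2 <- pairwise_overlap(low)
  expect_equal(rec2$frac_a, 0.1)
  expect_equal(round(rec2$frac_b, 3), 0.15)
  expect_equal(rec2$pattern, "low_tandem")
})

test_that("tandem PAS statistic counts upstream PASs within 2 kb of downstream TSS", {
  mk_pair <- function(id1, id2, up_pas_offset) {
    # downstream TIF starts at 10000; upstream PAS = 10000 + offset
    rbind(make_tif(id1, "c1", "+", 4000L, 10000L + up_pas_offset + 1L),
          make_tif(id2, "c1", "+", 10000L, 18000L))
  }
  rec_in <- pairwise_overlap(mk_pair("U", "D", 1500L))
  st_in <- tandem_pas_statistic(rec_in)
  expect_equal(st_in$fraction, 1)
  rec_out <- pairwise_overlap(mk_pair("U", "D", 2500L))
  st_out <- tandem_pas_statistic(rec_out)
  expect_equal(st_out$fraction, 0)
  # no overlapping pairs -> fraction reported absent
  st_none <- tandem_pas_statistic(pairwise_overlap(
    rbind(make_tif("A", "c1", "+", 0L, 1000L),
          make_tif("B", "c1", "+", 5000L, 6000L))))
  expect_true(is.na(st_none$fraction))
  expect_equal(st_none$n_pairs, 0L)
})

test_that("read-through calls need TSS in one gene and PAS in a distinct downstream gene", {
  genes <- data.table::data.table(
    gene_id = c("A", "B", "C"), chrom = "c1", strand = "+",
    start = c(1000L, 6000L, 20000L), end = c(4000L, 10000L, 24000L))
  # TIF from inside A to inside B -> called
  rt <- detect_read_through(make_tif("F1", "c1", "+", 2000L, 8000L), genes)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$upstream_gene, "A")
  expect_equal(rt$downstream_gene, "B")
  expect_equal(rt$tss_location, "inside")
  # TIF entirely inside one gene -> not called
  expect_equal(nrow(detect_read_through(make_tif("F2", "c1", "+", 1500L, 3500L),
                                        genes)), 0L)
  # intergenic TSS (beyond tol of any gene) -> not called
  expect_equal(nrow(detect_read_through(make_tif("F3", "c1", "+", 4500L, 8000L),
                                        genes)), 0L)
  # within-tolerance TSS (150 bp upstream of A) -> called, location "near"
  rt2 <- detect_read_through(make_tif("F4", "c1", "+", 850L, 8000L), genes)
  expect_equal(rt2$tss_location, "near")
  # a wholly skipped third gene blocks the call unless allowed
  genes2 <- rbind(genes,
                  data.table::data.table(gene_id = "M", chrom = "c1",
                                         strand = "+", start = 4400L, end = 5600L))
  tif_skip <- make_tif("F5", "c1", "+", 2000L, 8000L)
  expect_equal(nrow(detect_read_through(tif_skip, genes2)), 0L)
  rt3 <- detect_read_through(tif_skip, genes2, allow_skipped_genes = TRUE)
  expect_equal(nrow(rt3), 1L)
  # genes overlapping each other are excluded from candidacy
  genes3 <- data.table::data.table(
    gene_id = c("A", "B"), chrom = "c1", strand = "+",
    start = c(1000L, 3500L), end = c(4000L, 9000L))
  expect_equal(nrow(detect_read_through(make_tif("F6", "c1", "+", 2000L, 8000L),
                                        genes3)), 0L)
})

test_that("simulated fusion layouts are recovered with no false calls", {
  ref <- generate_reference(sim_config(seed = 29))
  lib <- simulate_library(ref)
  ann <- read_annotation(write_gtf(ref$transcripts, tempfile(fileext = ".gtf")))
  run <- run_tif_pipeline(lib$records, ref$genome, annotation = ann)
  ev <- evaluate_recovery(run$tifs, ref$truth)
  truth_rt <- ref$truth[unit == "readthrough_fusion", isoform_id]
  called_rt <- run$read_through$tif_id
  matched_rt <- ev$matches[isoform_id %in% truth_rt, unique(tif_id)]
  expect_setequal(called_rt, matched_rt)   # precision & recall 1
  # a layout without fusions yields no calls
  cfg0 <- sim_config(seed = 29, units = c(isolated = 4L, multi = 1L,
                                          new_tss = 1L, new_pas = 1L,
                                          new_boundaries = 1L, intergenic = 1L,
                                          tandem = 1L, readthrough = 0L))
  ref0 <- generate_reference(cfg0)
  lib0 <- simulate_library(ref0)
  ann0 <- read_annotation(write_gtf(ref0$transcripts, tempfile(fileext = ".gtf")))
  run0 <- run_tif_pipeline(lib0$records, ref0$genome, annotation = ann0)
  expect_equal(nrow(run0$read_through), 0L)
})
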