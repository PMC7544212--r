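test_that("reverse cumulative counts positions with at least x tags", {
  rc <- reverse_cumulative(c(1, 1, 2, 5))
  expect_equal(rc$x, c(1, 2, 5))
  expect_equal(rc$R, c(4, 2, 1))
  expect_true(all(diff(rc$R) <= 0))
  rc2 <- reverse_cumulative(rep(3, 7))
  expect_equal(rc2, data.table::data.table(x = 3, R = 7))
  expect_equal(reverse_cumulative(1)$R, 1)
  expect_error(reverse_cumulative(numeric(0)), "empty")
})

test_that("power-law fit recovers an exact synthetic line", {
  x <- 10:1000
  rc <- data.table::data.table(x = x, R = 1e6 * x^-1.25)
  fit <- fit_power_law(rc, fit_range = c(10, 1000))
  expect_equal(fit$b, -1.25, tolerance = 1e-9)
  expect_equal(fit$a, 6, tolerance = 1e-9)
  expect_equal(fit$alpha_hat, 1.25, tolerance = 1e-9)
  # flat distribution (single distinct count) is degenerate
  expect_error(fit_power_law(reverse_cumulative(rep(5, 100))), "fit_range")
})

test_that("normalization maps counts onto the reference line", {
  # hand-evaluated: a=6, b=-1, alpha_ref=2, T=1e6, x=100 -> x' = 10
  fit <- structure(list(a = 6, b = -1, alpha_hat = 1,
                        fit_range = c(10, 1000), n_points = 100),
                   class = "powerlaw_fit")
  expect_equal(normalize_counts(100, fit, alpha_ref = 2, T = 1e6), 10,
               tolerance = 1e-12)
  # identity when the data already lie on the reference line
  fit_id <- structure(list(a = 6, b = -1.25), class = "powerlaw_fit")
  x <- c(1, 3, 10, 400)
  expect_equal(normalize_counts(x, fit_id, alpha_ref = 1.25, T = 1e6), x,
               tolerance = 1e-12)
  # monotone increasing on random fits
  set.seed(2)
  for (i in 1:20) {
    f <- structure(list(a = runif(1, 2, 8), b = -runif(1, 0.5, 2)),
                   class = "powerlaw_fit")
    xs <- sort(10^runif(10, 0, 4))
    expect_true(all(diff(normalize_counts(xs, f, runif(1, 0.5, 2), 10^runif(1, 4, 7))) > 0))
  }
  expect_error(normalize_counts(0, fit), "positive")
})

test_that("Pareto-distributed counts recover their exponent and renormalize", {
  set.seed(314)
  alpha <- 1.25
  counts <- floor(runif(1e5)^(-1 / alpha))  # discrete Pareto: P(X>=x) = x^-alpha
  rc <- reverse_cumulative(counts)
  fit <- fit_power_law(rc, c(10, 1000))
  expect_equal(fit$alpha_hat, alpha, tolerance = 0.05)
  # after normalization with the data's own fit, the reverse-cumulative
  # slope over the fit range equals -alpha_ref
  alpha_ref <- 1.25
  norm <- normalize_counts(counts, fit, alpha_ref = alpha_ref, T = 1e6)
  fit2 <- fit_power_law(reverse_cumulative(norm), c(10, 1000))
  expect_equal(fit2$b, -alpha_ref, tolerance = 0.05)
})

test_that("low-coverage filter drops positions below 1 in more than one sample", {
  mk <- function(vals) {
    data.table::data.table(chrom = "c", strand = "+", pos = 1L,
                           sample_id = sprintf("s%d", seq_along(vals)),
                           norm = vals, raw = 1L)
  }
  expect_equal(nrow(filter_low_coverage(mk(c(0.5, 0.8, 2, 3)))), 0L)  # two low
  expect_equal(nrow(filter_low_coverage(mk(c(0.4, 1.2, 2, 5)))), 4L)  # one low
  expect_equal(nrow(filter_low_coverage(mk(c(1, 1.2, 2, 5)))), 4L)
  # a position absent from a sample counts as 0 there
  two <- data.table::data.table(chrom = "c", strand = "+", pos = 1L,
                                sample_id = c("s1", "s2"), norm = c(5, 5), raw = 1L)
  expect_equal(nrow(filter_low_coverage(two, samples = c("s1", "s2", "s3", "s4"))), 0L)
})

test_that("tag clustering chains within 10 bp and applies the singleton rule", {
  mk <- function(pos, norm = 2) data.table::data.table(pos = pos, raw = 1L, norm = norm)
  cl <- cluster_tags(mk(c(100L, 105L, 114L)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 115L)
  # 10 bp apart merges; 11 splits
  expect_equal(nrow(cluster_tags(mk(c(100L, 110L)))), 1L)
  expect_equal(nrow(cluster_tags(mk(c(100L, 111L)))), 2L)
  # singleton kept only above 1 normalized count
  expect_equal(nrow(cluster_tags(mk(500L, norm = 0.8))), 0L)
  expect_equal(nrow(cluster_tags(mk(500L, norm = 1.2))), 1L)
  expect_equal(nrow(cluster_tags(mk(500L, norm = 1.0))), 0L)  # strict
  # dominant position = max normalized count, tie -> smaller coordinate
  d <- cluster_tags(data.table::data.table(pos = c(10L, 12L, 14L), raw = 1L,
                                           norm = c(3, 5, 5)))
  expect_equal(d$dominant_pos, 12L)
})

test_that("clustering equals a brute-force chaining oracle on random input", {
  set.seed(99)
  for (rep in 1:10) {
    pos <- sort(sample(1:500, 60))
    dt <- data.table::data.table(pos = pos, raw = 1L, norm = 2)
    got <- cluster_tags(dt)
    # oracle: explicit pairwise chaining via connected components
    adj <- abs(outer(pos, pos, "-")) <= 10
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(adj))$membership
    want <- data.table::data.table(pos = pos, comp = comp)[
      , .(start = min(pos), end = max(pos) + 1L), by = comp][, comp := NULL]
    expect_equal(got[, .(start, end)], want)
  }
})

test_that("consensus merges per-sample clusters within 10 bp, not beyond", {
  mk <- function(sample, start, end) {
    data.table::data.table(sample_id = sample, chrom = "c", strand = "+",
                           start = start, end = end, raw_sum = 5, norm_sum = 5,
                           dominant_pos = start)
  }
  cons <- build_consensus(rbind(mk("s1", 100L, 110L), mk("s2", 105L, 118L)))
  expect_equal(nrow(cons$clusters), 1L)
  expect_equal(cons$clusters$start, 100L)
  expect_equal(cons$clusters$end, 118L)
  # gap 11 -> two consensus clusters (gap = next.start - prev.end)
  cons2 <- build_consensus(rbind(mk("s1", 100L, 110L), mk("s2", 121L, 130L)))
  expect_equal(nrow(cons2$clusters), 2L)
  # gap 10 merges
  cons3 <- build_consensus(rbind(mk("s1", 100L, 110L), mk("s2", 120L, 130L)))
  expect_equal(nrow(cons3$clusters), 1L)
  # one sample -> its clusters verbatim
  cons4 <- build_consensus(rbind(mk("s1", 100L, 110L), mk("s1", 200L, 230L)))
  expect_equal(cons4$clusters[, .(start, end)],
               data.table::data.table(start = c(100L, 200L), end = c(110L, 230L)))
  # per-sample aggregation survives
  expect_equal(sort(cons$per_sample$sample_id), c("s1", "s2"))
  # consensus intervals of one kind/strand are separated by > 10 bp
  set.seed(4)
  many <- data.table::rbindlist(lapply(1:40, function(i) {
    s <- sample(1:2000, 1)
    mk(sample(c("s1", "s2"), 1), s, s + sample(1:15, 1))
  }))
  cc <- build_consensus(many)$clusters
  data.table::setorder(cc, start)
  if (nrow(cc) > 1L) expect_true(all(cc$start[-1] - cc$end[-nrow(cc)] > 10L))
})

test_that("cluster_boundaries partitions kept positions into clusters once", {
  ref <- generate_reference(sim_config(seed = 21))
  lib <- simulate_library(ref)
  tags <- dedup_umis(extract_boundary_pairs(lib$records)$tags)
  res <- suppressWarnings(cluster_boundaries(tags, kind = "TSS"))
  # every kept position lies in exactly one consensus cluster
  kept <- filter_low_coverage(res$pos_norm)
  for (r in seq_len(min(nrow(kept), 200L))) {
    hits <- res$clusters[chrom == kept$chrom[r] & strand == kept$strand[r] &
                           start <= kept$pos[r] & end > kept$pos[r]]
    expect_lte(nrow(hits), 1L)
  }
  # chunked processing yields identical output
  res2 <- suppressWarnings(
    cluster_boundaries(tags, kind = "TSS",
                       chunks = list("chrS1", "chrS2")))
  expect_equal(res2$clusters, res$clusters)
  expect_equal(res2$per_sample, res$per_sample)
})
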