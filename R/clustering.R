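# Power-law normalization of boundary-tag counts and spatial clustering of
# tags into per-sample and cross-sample consensus TSS/PAS clusters.

#' Reverse-cumulative distribution of tag counts
#'
#' For each distinct count value `x`, the number of positions whose count is
#' at least `x`. `R` is non-increasing and `R(min value) = n` positions.
#'
#' @param counts Positive numeric vector of per-position tag counts (counts
#'   are integers before normalization, positive reals after).
#' @return data.table with columns `x` (ascending distinct values) and `R`.
#' @export
reverse_cumulative <- function(counts) {
  .assert(length(counts) > 0L, "empty count vector")
  .assert(all(counts > 0), "counts must be positive")
  x <- sort(unique(counts))
  n <- length(counts)
  # number of counts < x, via findInterval on the sorted vector
  below <- findInterval(x, sort(counts), left.open = TRUE)
  data.table(x = x, R = n - below)
}

#' Fit a power law to a reverse-cumulative distribution
#'
#' Least squares of `log10 R(x)` on `log10 x` restricted to `fit_range`.
#' The fitted line `log10 R = a + b log10 x` describes a power law with
#' exponent `alpha_hat = -b`. By default the regression is
#' inverse-variance weighted with weights proportional to `R(x)`: the
#' sampling variance of `log R(x)` scales as `1/R(x)`, so unweighted
#' least squares lets the sparse, noisy tail (large `x`, `R` of order 10)
#' dominate and roughly doubles the spread of the recovered exponent.
#' `weighting = "none"` gives the plain unweighted fit.
#'
#' @param revcum data.table from [reverse_cumulative()] (columns `x`, `R`).
#' @param fit_range Numeric length-2, inclusive count range used for the
#'   fit; at least 3 distinct `x` values must fall inside it.
#' @param weighting `"R"` (inverse-variance, default) or `"none"`.
#' @return Object of class `powerlaw_fit`: `a` (intercept), `b` (slope),
#'   `alpha_hat = -b`, `fit_range`, `n_points`.
#' @export
fit_power_law <- function(revcum, fit_range = c(10, 1000),
                          weighting = c("R", "none")) {
  weighting <- match.arg(weighting)
  dt <- as.data.table(revcum)
  sel <- dt[x >= fit_range[1] & x <= fit_range[2] & R > 0]
  if (length(unique(sel$x)) < 3L) {
    stop("fewer than 3 distinct count values in fit_range [",
         fit_range[1], ",", fit_range[2],
         "]; widen fit_range", call. = FALSE)
  }
  w <- if (weighting == "R") sel$R else rep(1, nrow(sel))
  fit <- lm(log10(R) ~ log10(x), data = sel, weights = w)
  b <- unname(coef(fit)[2])
  a <- unname(coef(fit)[1])
  if (!is.finite(b) || b >= 0) {
    warning("power-law fit has non-negative slope (", signif(b, 3),
            "); counts do not follow a decreasing power law")
  }
  structure(list(a = a, b = b, alpha_hat = -b,
                 fit_range = fit_range, n_points = nrow(sel)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: log10 R = %.4g %+.4g log10 x (alpha_hat %.4g, %d points in [%g,%g])\n",
              x$a, x$b, x$alpha_hat, x$n_points, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Normalize raw tag counts onto a reference power law
#'
#' The reference distribution is `R_ref(x') = T * x'^-alpha_ref`, i.e.
#' `log10 R_ref(x') = log10 T - alpha_ref * log10 x'`. A raw count `x` maps
#' to the normalized count `x'` whose reference reverse-cumulative equals
#' the fitted reverse-cumulative of `x`:
#' `x' = 10^((a + b log10 x - log10 T) / (-alpha_ref))`.
#' The mapping is monotone increasing in `x`, and is the identity when the
#' data already lie on the reference line.
#'
#' @param x Positive raw counts.
#' @param fit `powerlaw_fit` for the sample's own count distribution.
#' @param alpha_ref Reference exponent (> 0).
#' @param T Reference total (number of positions with normalized count >= 1
#'   on the reference line).
#' @return Normalized counts (positive reals, not re-rounded).
#' @export
normalize_counts <- function(x, fit, alpha_ref = 1.25, T = 1e6) {
  .assert(all(x > 0), "raw counts must be positive")
  .assert(alpha_ref > 0 && T > 0, "alpha_ref and T must be positive")
  10^((fit$a + fit$b * log10(x) - log10(T)) / (-alpha_ref))
}

#' Exclude low-coverage positions across samples
#'
#' A position is excluded when its normalized count falls below 1 in more
#' than `max_low_samples` samples (default: more than one). Positions absent
#' from a sample count as 0 there.
#'
#' @param pos_norm data.table `chrom, strand, pos, sample_id, norm`.
#' @param samples Character vector of all sample ids (defaults to those
#'   present; pass explicitly when a sample might have no tags at all).
#' @param max_low_samples Maximum tolerated number of samples below 1.
#' @return `pos_norm` restricted to kept positions (all samples' rows).
#' @export
filter_low_coverage <- function(pos_norm, samples = NULL, max_low_samples = 1L) {
  dt <- as.data.table(pos_norm)
  if (nrow(dt) == 0L) return(dt)
  if (is.null(samples)) samples <- unique(dt$sample_id)
  k <- length(samples)
  agg <- dt[, .(n_high = sum(norm >= 1)), by = .(chrom, strand, pos)]
  agg[, n_low := k - n_high]
  keep_pos <- agg[n_low <= max_low_samples, .(chrom, strand, pos)]
  dt[keep_pos, on = c("chrom", "strand", "pos")]
}

#' Cluster boundary positions within a distance window
#'
#' Single-linkage chaining over sorted positions of one sample, chromosome,
#' strand and kind: consecutive positions join one cluster when their
#' distance is at most `window` (10 bp). Clusters containing a single
#' position are kept only when that position's normalized count is above 1.
#'
#' @param positions data.table `pos, raw, norm` for one
#'   sample/chromosome/strand/kind (any order; sorted internally).
#' @param window Maximum merge distance (bp).
#' @param min_singleton_norm Strict lower bound for keeping single-position
#'   clusters.
#' @return data.table `start, end` (half-open, spanning member positions),
#'   `dominant_pos` (position of maximal normalized count, ties to the
#'   smaller coordinate), `n_pos`, `raw_sum`, `norm_sum`.
#' @export
cluster_tags <- function(positions, window = 10L, min_singleton_norm = 1) {
  dt <- as.data.table(positions)
  if (nrow(dt) == 0L) {
    return(data.table(start = integer(), end = integer(), dominant_pos = integer(),
                      n_pos = integer(), raw_sum = numeric(), norm_sum = numeric()))
  }
  setorder(dt, pos)
  dt[, cluster_id := cumsum(c(TRUE, diff(pos) > window))]
  cl <- dt[, {
    o <- order(-norm, pos)[1L]
    .(start = min(pos), end = max(pos) + 1L, dominant_pos = pos[o],
      n_pos = .N, raw_sum = sum(raw), norm_sum = sum(norm))
  }, by = cluster_id][, cluster_id := NULL]
  cl[n_pos > 1L | norm_sum > min_singleton_norm]
}

#' Merge per-sample clusters into cross-sample consensus clusters
#'
#' Clusters of one kind and strand from all samples are merged transitively
#' when their intervals overlap or lie within `window` (10 bp) of each
#' other (gap defined as `next.start - prev.end`). The consensus interval is
#' the union span; per-sample raw/normalized counts are aggregated; the
#' consensus dominant position is the member position with the highest
#' total normalized count. Resulting intervals of one kind/strand are
#' pairwise separated by more than `window`.
#'
#' @param sample_clusters data.table of per-sample clusters with columns
#'   `sample_id, chrom, strand, start, end, raw_sum, norm_sum, dominant_pos`.
#' @param pos_norm Optional position-level table (`chrom, strand, pos,
#'   sample_id, raw, norm`) used to locate consensus dominant positions;
#'   when `NULL` the dominant position of the highest-norm member cluster
#'   is used.
#' @param window Maximum merge gap (bp).
#' @param id_prefix Prefix for deterministic consensus ids (assigned by
#'   `(chrom, start)` order).
#' @return List with `clusters` (data.table `id, chrom, strand, start, end,
#'   dominant_pos, n_samples, raw_sum, norm_sum`), `membership` (mapping
#'   member cluster rows to consensus ids) and `per_sample` (long table of
#'   per-sample aggregated raw/norm counts per consensus cluster).
#' @export
build_consensus <- function(sample_clusters, pos_norm = NULL, window = 10L,
                            id_prefix = "C") {
  sc <- as.data.table(sample_clusters)
  if (nrow(sc) == 0L) {
    cl <- data.table(id = character(), chrom = character(), strand = character(),
                     start = integer(), end = integer(), dominant_pos = integer(),
                     n_samples = integer(), raw_sum = numeric(), norm_sum = numeric())
    return(list(clusters = cl,
                membership = data.table(),
                per_sample = data.table(id = character(), sample_id = character(),
                                        raw_sum = numeric(), norm_sum = numeric())))
  }
  sc <- copy(sc)[, member_id := .I]
  pieces <- lapply(split(sc, by = c("chrom", "strand"), sorted = TRUE), function(g) {
    ir <- .to_iranges(g$start, g$end)
    red <- IRanges::reduce(ir, min.gapwidth = window + 1L)
    # reduce() guarantees each member interval lies inside exactly one
    # consensus interval; containment hits are unambiguous
    within <- IRanges::findOverlaps(ir, red, type = "within")
    g[, consensus_grp := S4Vectors::subjectHits(within)[order(S4Vectors::queryHits(within))]]
    bounds <- .from_iranges(red)
    g[, `:=`(c_start = bounds$start[consensus_grp], c_end = bounds$end[consensus_grp])]
    g
  })
  sc2 <- rbindlist(pieces)
  agg <- sc2[, .(chrom = chrom[1L], strand = strand[1L],
                 start = c_start[1L], end = c_end[1L],
                 n_samples = uniqueN(sample_id),
                 raw_sum = sum(raw_sum), norm_sum = sum(norm_sum),
                 dominant_pos = dominant_pos[order(-norm_sum)][1L]),
             by = .(chrom_key = chrom, strand_key = strand, consensus_grp)]
  agg[, c("chrom_key", "strand_key", "consensus_grp") := NULL]
  setorder(agg, chrom, start, strand)
  agg[, id := .make_ids(id_prefix, .N)]
  if (!is.null(pos_norm)) {
    pn <- as.data.table(pos_norm)[, .(norm = sum(norm)), by = .(chrom, strand, pos)]
    for (r in seq_len(nrow(agg))) {
      cand <- pn[chrom == agg$chrom[r] & strand == agg$strand[r] &
                   pos >= agg$start[r] & pos < agg$end[r]]
      if (nrow(cand)) {
        setorder(cand, -norm, pos)
        agg[r, dominant_pos := cand$pos[1L]]
      }
    }
  }
  # membership + per-sample aggregation
  mem <- sc2[, .(member_id, sample_id, chrom, strand, start, end, raw_sum, norm_sum)]
  key <- sc2[, .(member_id, chrom, strand, c_start)]
  lookup <- agg[, .(id, chrom, strand, start)]
  mem2 <- lookup[key, on = c("chrom", "strand", start = "c_start")]
  mem[, id := mem2$id[match(member_id, mem2$member_id)]]
  per_sample <- mem[, .(raw_sum = sum(raw_sum), norm_sum = sum(norm_sum)),
                    by = .(id, sample_id)]
  setcolorder(agg, c("id", "chrom", "strand", "start", "end", "dominant_pos",
                     "n_samples", "raw_sum", "norm_sum"))
  list(clusters = agg[], membership = mem[], per_sample = per_sample[])
}

#' Normalize, filter and cluster one boundary kind across samples
#'
#' Pipeline wrapper: per-position counts per sample, per-sample power-law
#' fit and normalization, cross-sample low-coverage filtering, per-sample
#' 10-bp clustering with the singleton rule, and cross-sample consensus
#' building.
#'
#' If fewer than 3 distinct count values fall inside `fit_range` for a
#' sample (a shallow library), the fit range is widened to `[1, max]` with a
#' warning; if the distribution is still degenerate, that sample's counts
#' pass through unnormalized.
#'
#' @param tags Deduplicated, filtered tags (`chrom, strand, tss_pos,
#'   pas_pos, sample_id`); each row is one unique molecule.
#' @param kind `"TSS"` (cluster `tss_pos`) or `"PAS"` (cluster `pas_pos`).
#' @param window Clustering/consensus window (bp).
#' @param alpha_ref,T,fit_range Power-law normalization parameters.
#' @param max_low_samples Low-coverage filter tolerance.
#' @param min_singleton_norm Singleton-cluster rule bound.
#' @param chunks Optional list of chromosome-name vectors; the spatial
#'   clustering and consensus steps run independently per chunk and results
#'   are recombined by deterministic sort, so the output is identical for
#'   any partition (the normalization fit is always genome-wide).
#' @return List with `clusters` (consensus clusters, deterministic ids by
#'   `(chrom, start)`), `per_sample` (per-sample aggregated counts per
#'   consensus cluster), `sample_clusters`, `pos_norm` (per-position
#'   normalized counts) and `fits` (per-sample `powerlaw_fit` or `NULL`).
#' @export
cluster_boundaries <- function(tags, kind = c("TSS", "PAS"), window = 10L,
                               alpha_ref = 1.25, T = 1e6, fit_range = c(10, 1000),
                               max_low_samples = 1L, min_singleton_norm = 1,
                               chunks = NULL) {
  kind <- match.arg(kind)
  dt <- as.data.table(tags)
  dt[, pos := if (kind == "TSS") tss_pos else pas_pos]
  counts <- dt[, .(raw = .N), by = .(sample_id, chrom, strand, pos)]
  samples <- sort(unique(counts$sample_id))
  fits <- setNames(vector("list", length(samples)), samples)
  norm_list <- list()
  for (s in samples) {
    cs <- counts[sample_id == s]
    fit <- tryCatch(fit_power_law(reverse_cumulative(cs$raw), fit_range),
                    error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch({
        warning("sample ", s, " (", kind, "): fewer than 3 distinct counts in fit_range; ",
                "widening to [1, max]", call. = FALSE)
        fit_power_law(reverse_cumulative(cs$raw), c(1, max(cs$raw)))
      }, error = function(e) NULL)
    }
    fits[[s]] <- fit
    cs[, norm := if (is.null(fit)) as.numeric(raw) else normalize_counts(raw, fit, alpha_ref, T)]
    norm_list[[s]] <- cs
  }
  pos_norm <- rbindlist(norm_list)
  kept <- filter_low_coverage(pos_norm, samples = samples,
                              max_low_samples = max_low_samples)
  if (is.null(chunks)) chunks <- list(sort(unique(dt$chrom)))
  parts <- lapply(chunks, function(ch) {
    sub <- kept[chrom %in% ch]
    if (nrow(sub) == 0L) return(NULL)
    sample_clusters <- sub[, cluster_tags(.SD[, .(pos, raw, norm)],
                                          window, min_singleton_norm),
                           by = .(sample_id, chrom, strand)]
    cons <- build_consensus(sample_clusters, pos_norm = sub, window = window,
                            id_prefix = paste0(kind, "_"))
    list(sample_clusters = sample_clusters, cons = cons)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    empty <- build_consensus(data.table())
    return(list(clusters = empty$clusters, per_sample = empty$per_sample,
                sample_clusters = data.table(), pos_norm = pos_norm, fits = fits))
  }
  sample_clusters <- rbindlist(lapply(parts, `[[`, "sample_clusters"))
  setorder(sample_clusters, chrom, start, strand, sample_id)
  # chunk-local ids -> global deterministic ids by (chrom, start)
  clusters <- rbindlist(lapply(seq_along(parts), function(i) {
    copy(parts[[i]]$cons$clusters)[, chunk := i]
  }))
  per_sample <- rbindlist(lapply(seq_along(parts), function(i) {
    copy(parts[[i]]$cons$per_sample)[, chunk := i]
  }))
  setorder(clusters, chrom, start, strand)
  map <- clusters[, .(chunk, old = id)][, new := .make_ids(paste0(kind, "_"), .N)]
  clusters[, id := map$new]
  clusters[, chunk := NULL]
  per_sample <- map[per_sample, on = c("chunk", old = "id")]
  per_sample <- per_sample[, .(id = new, sample_id, raw_sum, norm_sum)]
  setorder(per_sample, id, sample_id)
  list(clusters = clusters[], per_sample = per_sample[],
       sample_clusters = sample_clusters, pos_norm = pos_norm, fits = fits)
}
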