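# Shared internal helpers. All genomic coordinates inside the package are
# 0-based half-open; conversion to/from 1-based inclusive happens only at
# file-format boundaries (GTF, IRanges).

#' @keywords internal
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# 0-based half-open [start, end) -> IRanges (1-based closed)
.to_iranges <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

# IRanges -> 0-based half-open start/end columns
.from_iranges <- function(ir) {
  list(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Reverse-complement a DNA string (ACGTN)
#' @keywords internal
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Vectorised Hamming distance between equal-length strings.
.hamming <- function(a, b) {
  .assert(all(nchar(a) == nchar(b)), "Hamming distance needs equal lengths")
  m1 <- matrix(unlist(strsplit(a, "", fixed = TRUE)), nrow = length(a), byrow = TRUE)
  m2 <- matrix(unlist(strsplit(b, "", fixed = TRUE)), nrow = length(b), byrow = TRUE)
  rowSums(m1 != m2)
}

# Connected components from an edge list (i, j) over n nodes
# (union-find with path halving).
.components <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(ei)) {
    for (k in seq_along(ei)) {
      a <- find(ei[k]); b <- find(ej[k])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Strand-aware 5' end of a 0-based half-open span.
.five_prime <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}
.three_prime <- function(start, end, strand) {
  ifelse(strand == "+", end - 1L, start)
}

# Deterministic zero-padded ids.
.make_ids <- function(prefix, n) sprintf("%s%06d", prefix, seq_len(n))
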