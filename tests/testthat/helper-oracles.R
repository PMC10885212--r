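# Independent oracles used to cross-check the implementation.

# Plain dynamic-programming Levenshtein distance (independent of adist).
lev_dp <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1L, length(b) + 1L)
  d[, 1] <- 0:length(a)
  d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[length(a) + 1L, length(b) + 1L]
}

# Brute-force greedy-by-abundance clustering of barcode counts:
# all pairwise DP distances, then scan in descending abundance
# (lexicographic ties); each surviving barcode absorbs every
# not-yet-absorbed rarer barcode within distance < dmax.
greedy_cluster_oracle <- function(barcodes, counts, dmax = 2L) {
  ord <- order(-counts, barcodes)
  barcodes <- barcodes[ord]
  counts <- counts[ord]
  n <- length(barcodes)
  dist <- outer(seq_len(n), seq_len(n),
                Vectorize(function(i, j) lev_dp(barcodes[i], barcodes[j])))
  absorbed <- logical(n)
  for (i in seq_len(n)) {
    if (absorbed[i]) next
    for (j in seq_len(n)) {
      if (j > i && !absorbed[j] && dist[i, j] < dmax) {
        counts[i] <- counts[i] + counts[j]
        absorbed[j] <- TRUE
      }
    }
  }
  out <- data.frame(barcode = barcodes[!absorbed],
                    barcode_count = counts[!absorbed],
                    stringsAsFactors = FALSE)
  out[order(-out$barcode_count, out$barcode), , drop = FALSE]
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
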