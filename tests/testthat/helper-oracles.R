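# Independent brute-force oracles used by both the per-module tests and the
# acceptance suite.  These deliberately avoid the package's vectorized
# counting / dynamic-programming code paths.

oracle_ngram_counts <- function(sequence, n, alphabet) {
  enc <- encode_sequence(sequence, alphabet)
  counts <- table(factor(
    vapply(seq_len(nchar(enc) - n + 1),
           function(i) substr(enc, i, i + n - 1), character(1)),
    levels = scheme_attributes(scheme_spec("npeptide", alphabet = alphabet,
                                           n = n))))
  as.vector(counts)
}

oracle_gapped_counts <- function(sequence, g) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  attrs <- scheme_attributes(scheme_spec("gapped_dipeptide", g = g))
  counts <- setNames(integer(length(attrs)), attrs)
  for (i in seq_len(L)) {
    j <- i + g + 1
    if (j <= L) {
      nm <- paste0(chars[i], strrep("x", g), chars[j])
      counts[nm] <- counts[nm] + 1L
    }
  }
  unname(counts)
}

oracle_window_counts <- function(sequence, l) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  h <- (l - 1) / 2
  attrs <- scheme_attributes(scheme_spec("window", l = l))
  counts <- setNames(integer(length(attrs)), attrs)
  for (p in seq_len(L)) {
    for (q in seq_len(L)) {
      if (q != p && abs(q - p) <= h) {
        nm <- paste0(chars[p], ":", chars[q])
        counts[nm] <- counts[nm] + 1L
      }
    }
  }
  unname(counts)
}

# exhaustive recursion over all global alignments; a length-L gap run is
# scored -(open + L * ext)
brute_global_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca); lb <- length(cb)
  helper <- function(i, j, last) {
    if (i > la && j > lb) return(0)
    best <- -Inf
    if (i <= la && j <= lb) {
      best <- max(best, mat[ca[i], cb[j]] + helper(i + 1, j + 1, "M"))
    }
    if (i <= la) {
      best <- max(best, -(ext + if (last != "A") open else 0) +
                    helper(i + 1, j, "A"))
    }
    if (j <= lb) {
      best <- max(best, -(ext + if (last != "B") open else 0) +
                    helper(i, j + 1, "B"))
    }
    best
  }
  helper(1, 1, "none")
}
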