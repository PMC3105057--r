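#' Define a coding scheme
#'
#' A coding scheme turns a protein sequence into a named, normalized
#' frequency vector.  Four kinds are supported:
#' \describe{
#'   \item{npeptide}{composition of contiguous n-grams of the (possibly
#'     reduced-alphabet-encoded) sequence; n = 1 is the plain amino-acid
#'     composition `C`.}
#'   \item{partitioned}{the sequence is split into `k` contiguous
#'     near-equal segments (remainder residues go to the leading segments)
#'     and the n-peptide composition is computed per segment; attributes
#'     are namespaced by segment (`X_k` schemes).}
#'   \item{gapped_dipeptide}{frequency of ordered residue pairs `a (x)_g b`
#'     with exactly `g` intervening residues of any type (`D_g` schemes;
#'     always over the original alphabet).}
#'   \item{window}{for every residue type `c`, the amino-acid composition
#'     of the neighbors pooled from length-`l` windows centered on each
#'     occurrence of `c` (`W_l` schemes; original alphabet).}
#' }
#'
#' @param kind One of `"npeptide"`, `"partitioned"`, `"gapped_dipeptide"`,
#'   `"window"`.
#' @param alphabet Name of a built-in reduced alphabet (npeptide /
#'   partitioned kinds).
#' @param n n-peptide order (npeptide / partitioned).
#' @param k Number of segments (partitioned).
#' @param g Number of intervening residues (gapped_dipeptide).
#' @param l Odd window length >= 3 (window).
#' @param include_center Should window pooling include the center residue
#'   itself?  Default `FALSE` (the window describes the center's neighbors).
#' @param window_ends `"truncate"` (default) clips windows at the sequence
#'   ends; `"skip"` ignores center occurrences whose window does not fit.
#' @param label Optional display label; autogenerated otherwise.
#' @return A `scheme_spec` object.
#' @examples
#' scheme_spec("gapped_dipeptide", g = 0)          # dipeptide composition D_0
#' scheme_spec("partitioned", alphabet = "H", n = 3, k = 5)
#' @export
scheme_spec <- function(kind = c("npeptide", "partitioned",
                                 "gapped_dipeptide", "window"),
                        alphabet = "A", n = 1L, k = 1L, g = 0L, l = 7L,
                        include_center = FALSE,
                        window_ends = c("truncate", "skip"),
                        label = NULL) {
  kind <- match.arg(kind)
  window_ends <- match.arg(window_ends)
  n <- as.integer(n); k <- as.integer(k); g <- as.integer(g); l <- as.integer(l)
  stopifnot(n >= 1L, k >= 1L, g >= 0L)
  if (kind == "window" && (l < 3L || l %% 2L == 0L)) {
    stop("window length l must be odd and >= 3")
  }
  if (kind %in% c("gapped_dipeptide", "window")) alphabet <- "A"
  if (is.null(label)) {
    label <- switch(kind,
      npeptide = if (alphabet == "A" && n == 1L) "C"
                 else sprintf("%s%d", alphabet, n),
      partitioned = if (alphabet == "A" && n == 1L) sprintf("X%d", k)
                    else sprintf("%s%dX%d", alphabet, n, k),
      gapped_dipeptide = sprintf("D%d", g),
      window = sprintf("W%d", l))
  }
  structure(list(kind = kind, alphabet = alphabet, n = n, k = k, g = g,
                 l = l, include_center = include_center,
                 window_ends = window_ends, label = label),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("coding scheme %s (%s, alphabet %s, %d attributes)\n",
              x$label, x$kind, x$alphabet, length(scheme_attributes(x))))
  invisible(x)
}

all_words <- function(symbols, n) {
  words <- symbols
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      words <- as.vector(t(outer(words, symbols, paste0)))
    }
  }
  words
}

#' Canonical attribute names of a scheme
#'
#' The attribute order is fixed (lexicographic in the alphabet's declared
#' symbol order, segment-major for partitioned schemes, center-major for
#' window schemes) so feature masks are portable across runs.
#'
#' @param spec A `scheme_spec`.
#' @param alphabets Alphabet registry (defaults to [builtin_alphabets()]).
#' @return Character vector of attribute names.
#' @export
scheme_attributes <- function(spec, alphabets = builtin_alphabets()) {
  stopifnot(inherits(spec, "scheme_spec"))
  switch(spec$kind,
    npeptide = all_words(alphabets[[spec$alphabet]]$symbols, spec$n),
    partitioned = {
      words <- all_words(alphabets[[spec$alphabet]]$symbols, spec$n)
      as.vector(t(outer(sprintf("s%d", seq_len(spec$k)), words,
                        function(s, w) paste0(s, ":", w))))
    },
    gapped_dipeptide = {
      gap <- strrep("x", spec$g)
      as.vector(t(outer(AMINO_ACIDS, AMINO_ACIDS,
                        function(a, b) paste0(a, gap, b))))
    },
    window = as.vector(t(outer(AMINO_ACIDS, AMINO_ACIDS,
                               function(c, x) paste0(c, ":", x)))))
}

#' Minimum sequence length a scheme can encode
#'
#' @inheritParams scheme_attributes
#' @return Integer minimum length.
#' @export
scheme_min_length <- function(spec) {
  switch(spec$kind,
    npeptide = spec$n,
    partitioned = spec$k * spec$n,
    gapped_dipeptide = spec$g + 2L,
    window = 1L)
}

# segment start indices (1-based) and lengths for a partitioned scheme:
# lengths differ by <= 1, remainder residues go to the leading segments
segment_bounds <- function(L, k) {
  base <- L %/% k
  lens <- base + as.integer(seq_len(k) <= L %% k)
  starts <- cumsum(c(1L, lens[-k]))
  list(starts = starts, lengths = lens)
}

degenerate_input_error <- function(spec, L) {
  stop(structure(class = c("afp_degenerate_input", "error", "condition"),
                 list(message = sprintf(
                        "sequence of length %d too short for scheme %s (needs >= %d)",
                        L, spec$label, scheme_min_length(spec)),
                      call = sys.call(-1))))
}

count_ngrams <- function(encoded_chars, n, words) {
  L <- length(encoded_chars)
  grams <- if (n == 1L) encoded_chars else {
    vapply(seq_len(L - n + 1L),
           function(i) paste(encoded_chars[i:(i + n - 1L)], collapse = ""),
           character(1))
  }
  tabulate(factor(grams, levels = words), nbins = length(words))
}

# raw occurrence counts and per-attribute-block denominators for any scheme;
# feature vectors are counts / denominator, so the two stay consistent with
# match_attribute_positions by construction
feature_counts <- function(sequence, spec, alphabets = builtin_alphabets()) {
  L <- nchar(sequence)
  if (L < scheme_min_length(spec)) degenerate_input_error(spec, L)
  attrs <- scheme_attributes(spec, alphabets)
  switch(spec$kind,
    npeptide = {
      enc <- strsplit(encode_sequence(sequence, alphabets[[spec$alphabet]]),
                      "")[[1]]
      counts <- count_ngrams(enc, spec$n, attrs)
      list(attrs = attrs, counts = counts,
           denom = rep(L - spec$n + 1L, length(attrs)))
    },
    partitioned = {
      enc <- strsplit(encode_sequence(sequence, alphabets[[spec$alphabet]]),
                      "")[[1]]
      words <- all_words(alphabets[[spec$alphabet]]$symbols, spec$n)
      sb <- segment_bounds(L, spec$k)
      counts <- integer(0); denom <- integer(0)
      for (s in seq_len(spec$k)) {
        seg <- enc[sb$starts[s]:(sb$starts[s] + sb$lengths[s] - 1L)]
        counts <- c(counts, count_ngrams(seg, spec$n, words))
        denom <- c(denom, rep(sb$lengths[s] - spec$n + 1L, length(words)))
      }
      list(attrs = attrs, counts = counts, denom = denom)
    },
    gapped_dipeptide = {
      chars <- strsplit(sequence, "")[[1]]
      span <- spec$g + 1L
      i <- seq_len(L - span)
      pairs <- paste0(chars[i], strrep("x", spec$g), chars[i + span])
      counts <- tabulate(factor(pairs, levels = attrs), nbins = length(attrs))
      list(attrs = attrs, counts = counts,
           denom = rep(L - span, length(attrs)))
    },
    window = {
      chars <- strsplit(sequence, "")[[1]]
      h <- (spec$l - 1L) %/% 2L
      counts <- integer(length(attrs)); denom <- integer(length(attrs))
      names(counts) <- attrs
      for (cen in AMINO_ACIDS) {
        occ <- which(chars == cen)
        if (spec$window_ends == "skip") {
          occ <- occ[occ > h & occ <= L - h]
        }
        pool <- character(0)
        for (p in occ) {
          idx <- max(1L, p - h):min(L, p + h)
          if (!spec$include_center) idx <- setdiff(idx, p)
          pool <- c(pool, chars[idx])
        }
        block <- paste0(cen, ":", AMINO_ACIDS)
        if (length(pool)) {
          counts[block] <- tabulate(factor(pool, levels = AMINO_ACIDS),
                                    nbins = 20L)
          denom[match(block, attrs)] <- length(pool)
        }
      }
      list(attrs = attrs, counts = unname(counts), denom = denom)
    })
}

#' Compute the feature vector of a sequence under a scheme
#'
#' Each attribute's value is its occurrence count divided by the number of
#' occurrence opportunities in its normalization block, so every block
#' (whole sequence for n-peptide and gapped schemes, each segment for
#' partitioned schemes, each present center type for window schemes) sums
#' to 1.  Attribute blocks with no opportunities (e.g. absent window
#' centers) are all-zero.
#'
#' @param sequence Canonical protein sequence.
#' @param spec A `scheme_spec`.
#' @param alphabets Alphabet registry.
#' @return Named numeric vector over the scheme's full attribute space.
#' @examples
#' v <- feature_vector("NTALT", scheme_spec("gapped_dipeptide", g = 0))
#' v[["LT"]]  # 0.25
#' @export
feature_vector <- function(sequence, spec, alphabets = builtin_alphabets()) {
  fc <- feature_counts(sequence, spec, alphabets)
  vals <- ifelse(fc$denom > 0, fc$counts / fc$denom, 0)
  stats::setNames(vals, fc$attrs)
}

#' n-peptide composition
#'
#' Convenience wrappers around [feature_vector()] for each scheme kind.
#'
#' @param sequence Canonical protein sequence.
#' @param n n-peptide order.
#' @param alphabet Built-in alphabet name.
#' @return Named numeric feature vector.
#' @export
npeptide_composition <- function(sequence, n = 1L, alphabet = "A") {
  feature_vector(sequence, scheme_spec("npeptide", alphabet = alphabet, n = n))
}

#' @rdname npeptide_composition
#' @param k Number of contiguous segments.
#' @export
partitioned_composition <- function(sequence, k, n = 1L, alphabet = "A") {
  feature_vector(sequence,
                 scheme_spec("partitioned", alphabet = alphabet, n = n, k = k))
}

#' @rdname npeptide_composition
#' @param g Number of intervening residues between the dipeptide anchors.
#' @export
gapped_dipeptide_composition <- function(sequence, g = 0L) {
  feature_vector(sequence, scheme_spec("gapped_dipeptide", g = g))
}

#' @rdname npeptide_composition
#' @param l Odd window length.
#' @export
window_composition <- function(sequence, l = 7L) {
  feature_vector(sequence, scheme_spec("window", l = l))
}

#' Build the feature matrix of a dataset under one scheme
#'
#' @param dataset data.frame with `id` and `sequence` columns (or a named
#'   character vector of sequences).
#' @param spec A `scheme_spec`.
#' @param alphabets Alphabet registry.
#' @return Numeric matrix, rows named by record id in record order, columns
#'   the scheme's canonical attributes.  Sequences shorter than the
#'   scheme's minimum length are excluded with a warning; their ids are
#'   kept in `attr(, "excluded")`.
#' @export
build_scheme_matrix <- function(dataset, spec,
                                alphabets = builtin_alphabets()) {
  if (is.character(dataset)) {
    dataset <- data.frame(id = names(dataset), sequence = unname(dataset),
                          stringsAsFactors = FALSE)
  }
  attrs <- scheme_attributes(spec, alphabets)
  ok <- nchar(dataset$sequence) >= scheme_min_length(spec)
  if (!all(ok)) {
    warning(sum(!ok), " sequence(s) shorter than scheme ", spec$label,
            " minimum length excluded: ",
            paste(dataset$id[!ok], collapse = ", "))
  }
  kept <- dataset[ok, , drop = FALSE]
  m <- matrix(0, nrow = nrow(kept), ncol = length(attrs),
              dimnames = list(kept$id, attrs))
  for (i in seq_len(nrow(kept))) {
    m[i, ] <- feature_vector(kept$sequence[i], spec, alphabets)
  }
  attr(m, "excluded") <- dataset$id[!ok]
  m
}

#' Locate the residue positions matching an attribute
#'
#' Reports every occurrence of a scheme attribute in a sequence together
#' with the exact residue indices constituting it: the `n` residues of an
#' n-peptide occurrence, the two anchor residues of a gapped dipeptide
#' (intervening residues are not part of the footprint), and the
#' center/neighbor residue pair for window attributes.
#'
#' @param sequence Canonical protein sequence.
#' @param spec A `scheme_spec`.
#' @param attribute One of the scheme's attribute names.
#' @param alphabets Alphabet registry.
#' @return List of integer vectors of 0-based residue indices, one per
#'   occurrence, in order of occurrence.
#' @examples
#' match_attribute_positions("NTALT", scheme_spec("gapped_dipeptide", g = 0), "LT")
#' # list(c(3L, 4L))
#' @export
match_attribute_positions <- function(sequence, spec, attribute,
                                      alphabets = builtin_alphabets()) {
  attrs <- scheme_attributes(spec, alphabets)
  if (!attribute %in% attrs) {
    stop("unknown attribute '", attribute, "' for scheme ", spec$label)
  }
  L <- nchar(sequence)
  if (L < scheme_min_length(spec)) degenerate_input_error(spec, L)
  switch(spec$kind,
    npeptide = {
      enc <- strsplit(encode_sequence(sequence, alphabets[[spec$alphabet]]),
                      "")[[1]]
      word <- strsplit(attribute, "")[[1]]
      n <- spec$n
      hits <- Filter(function(i) all(enc[i:(i + n - 1L)] == word),
                     seq_len(L - n + 1L))
      lapply(hits, function(i) (i:(i + n - 1L)) - 1L)
    },
    partitioned = {
      parts <- strsplit(attribute, ":", fixed = TRUE)[[1]]
      s <- as.integer(sub("^s", "", parts[1]))
      word <- strsplit(parts[2], "")[[1]]
      n <- spec$n
      enc <- strsplit(encode_sequence(sequence, alphabets[[spec$alphabet]]),
                      "")[[1]]
      sb <- segment_bounds(L, spec$k)
      s0 <- sb$starts[s]
      seg <- enc[s0:(s0 + sb$lengths[s] - 1L)]
      hits <- Filter(function(i) all(seg[i:(i + n - 1L)] == word),
                     seq_len(sb$lengths[s] - n + 1L))
      lapply(hits, function(i) (s0 - 1L) + (i:(i + n - 1L)) - 1L)
    },
    gapped_dipeptide = {
      chars <- strsplit(sequence, "")[[1]]
      a <- substr(attribute, 1L, 1L)
      b <- substr(attribute, nchar(attribute), nchar(attribute))
      span <- spec$g + 1L
      hits <- which(chars[seq_len(L - span)] == a &
                    chars[seq_len(L - span) + span] == b)
      lapply(hits, function(i) c(i - 1L, i + span - 1L))
    },
    window = {
      chars <- strsplit(sequence, "")[[1]]
      parts <- strsplit(attribute, ":", fixed = TRUE)[[1]]
      cen <- parts[1]; x <- parts[2]
      h <- (spec$l - 1L) %/% 2L
      occ <- which(chars == cen)
      if (spec$window_ends == "skip") occ <- occ[occ > h & occ <= L - h]
      out <- list()
      for (p in occ) {
        idx <- max(1L, p - h):min(L, p + h)
        if (!spec$include_center) idx <- setdiff(idx, p)
        for (q in idx[chars[idx] == x]) {
          out[[length(out) + 1L]] <- c(p - 1L, q - 1L)
        }
      }
      out
    })
}

#' The default 13-scheme jury set
#'
#' The default ensemble couples the global amino-acid composition `C`, the
#' partitioned compositions `X_5`, `X_6`, `X_7`, the g-gap dipeptide
#' compositions `D_0`, `D_1`, `D_3`, `D_6`, the reduced-alphabet
#' partitioned compositions `H_3X_5`, `P_3X_5`, `S_2X_5`, and the window
#' compositions `W_7`, `W_11`.
#'
#' @return Named list of 13 `scheme_spec` objects.
#' @export
default_scheme_set <- function() {
  specs <- list(
    C = scheme_spec("npeptide", alphabet = "A", n = 1),
    X5 = scheme_spec("partitioned", n = 1, k = 5),
    X6 = scheme_spec("partitioned", n = 1, k = 6),
    X7 = scheme_spec("partitioned", n = 1, k = 7),
    D0 = scheme_spec("gapped_dipeptide", g = 0),
    D1 = scheme_spec("gapped_dipeptide", g = 1),
    D3 = scheme_spec("gapped_dipeptide", g = 3),
    D6 = scheme_spec("gapped_dipeptide", g = 6),
    H3X5 = scheme_spec("partitioned", alphabet = "H", n = 3, k = 5),
    P3X5 = scheme_spec("partitioned", alphabet = "P", n = 3, k = 5),
    S2X5 = scheme_spec("partitioned", alphabet = "S", n = 2, k = 5),
    W7 = scheme_spec("window", l = 7),
    W11 = scheme_spec("window", l = 11))
  specs
}
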