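#' Specify a motif to plant in synthetic positives
#'
#' Patterns are attribute-style: literal residues with lowercase `x`
#' wildcard positions, so `"LT"` is a contiguous dipeptide and `"TxxT"`
#' a gapped pair with two intervening residues of any type (which stay
#' background-sampled).  Such residue repeats — alanine-rich helices,
#' TXT/TCT spacings — are the sequence regularities that distinguish real
#' ice-binding proteins.
#'
#' @param pattern Pattern string over uppercase residues and `x`.
#' @param rate Expected plantings per 100 residues; 0 disables the motif
#'   (positives then carry no signal).
#' @param jitter Standard deviation (residues) of the positional noise
#'   around the regular planting grid.
#' @return A `motif_spec`.
#' @export
motif_spec <- function(pattern, rate = 6, jitter = 2) {
  stopifnot(nzchar(pattern), rate >= 0, jitter >= 0)
  chars <- strsplit(pattern, "")[[1]]
  if (!all(chars %in% c(AMINO_ACIDS, "x"))) {
    stop("pattern may contain only canonical residues and the wildcard 'x'")
  }
  structure(list(pattern = pattern, rate = rate, jitter = jitter,
                 span = length(chars),
                 literal = which(chars != "x"),
                 residues = chars[chars != "x"]),
            class = "motif_spec")
}

#' Specify a synthetic planted-motif benchmark
#'
#' Positives are background sequences with motifs planted on a jittered
#' regular grid (non-overlapping by construction); negatives are pure
#' background.  Background residue frequencies default to uniform 1/20,
#' which makes planted-signal analysis exact.
#'
#' @param n_pos,n_neg Numbers of positive / negative sequences.
#' @param length_range Sequence lengths are uniform integers in this range.
#' @param motifs List of [motif_spec()]s; the default plants the `LT`
#'   dipeptide and the `T(x)2T` gapped pair.
#' @param background Named residue probability vector (default uniform).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `benchmark_spec`.
#' @export
benchmark_spec <- function(n_pos = 200L, n_neg = 200L,
                           length_range = c(60L, 120L),
                           motifs = list(motif_spec("LT"),
                                         motif_spec("TxxT")),
                           background = NULL, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1] >= 2L, length_range[1] <= length_range[2])
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  }
  stopifnot(setequal(names(background), AMINO_ACIDS),
            abs(sum(background) - 1) < 1e-8)
  spans <- vapply(motifs, `[[`, numeric(1), "span")
  if (any(spans > length_range[1])) {
    stop("motif longer than the minimum sequence length")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range), motifs = motifs,
                 background = background[AMINO_ACIDS],
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

plant_motifs <- function(chars, motifs, occupied) {
  truth <- list()
  L <- length(chars)
  for (m in motifs) {
    if (m$rate <= 0) next
    spacing <- max(m$span, round(100 / m$rate))
    anchors <- seq(1L, L - m$span + 1L, by = spacing)
    for (a in anchors) {
      s <- a + as.integer(round(stats::rnorm(1, 0, m$jitter)))
      s <- min(max(s, 1L), L - m$span + 1L)
      span_idx <- s:(s + m$span - 1L)
      if (any(occupied[span_idx])) next
      chars[s + m$literal - 1L] <- m$residues
      occupied[span_idx] <- TRUE
      truth[[length(truth) + 1L]] <- data.frame(
        start = s - 1L, end = s + m$span - 1L, motif = m$pattern,
        stringsAsFactors = FALSE)
    }
  }
  list(chars = chars, occupied = occupied,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Generate a labeled planted-motif benchmark
#'
#' @param spec A [benchmark_spec()].
#' @return List with `records` (data.frame id, description, sequence,
#'   label) and `truth` (data.frame id, start, end, motif; 0-based
#'   half-open coordinates of every planted occurrence).
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, {
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   spec$n_pos + spec$n_neg, replace = TRUE)
    ids <- c(sprintf("pos%03d", seq_len(spec$n_pos)),
             sprintf("neg%03d", seq_len(spec$n_neg)))
    labels <- rep(c("AFP", "NONAFP"), c(spec$n_pos, spec$n_neg))
    seqs <- character(length(ids))
    truth <- list()
    for (i in seq_along(ids)) {
      chars <- sample(AMINO_ACIDS, lens[i], replace = TRUE,
                      prob = spec$background)
      if (labels[i] == "AFP") {
        res <- plant_motifs(chars, spec$motifs, logical(lens[i]))
        chars <- res$chars
        if (!is.null(res$truth)) {
          res$truth$id <- ids[i]
          truth[[length(truth) + 1L]] <- res$truth
        }
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    truth <- if (length(truth)) {
      do.call(rbind, truth)[, c("id", "start", "end", "motif")]
    } else {
      data.frame(id = character(0), start = integer(0), end = integer(0),
                 motif = character(0), stringsAsFactors = FALSE)
    }
    list(records = data.frame(id = ids, description = "synthetic",
                              sequence = seqs, label = labels,
                              stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Write a benchmark to disk
#'
#' Emits FASTA, a 2-column label TSV and a BED-like ground-truth TSV
#' (id, start, end, motif; 0-based half-open).
#'
#' @param benchmark Output of [generate_benchmark()].
#' @param dir Output directory (created if needed).
#' @param stem File name stem (default `"benchmark"`).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_benchmark <- function(benchmark, dir, stem = "benchmark") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(stem, ".fasta"))
  labels <- file.path(dir, paste0(stem, ".labels.tsv"))
  truth <- file.path(dir, paste0(stem, ".truth.tsv"))
  write_fasta(benchmark$records, fasta)
  utils::write.table(benchmark$records[, c("id", "label")], labels,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(benchmark$truth, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, labels = labels, truth = truth))
}

#' In-package worked-example fixtures
#'
#' Fixture `ntalt`: the peptide `NTALT` with the selected-attribute set
#' `{LT (contiguous dipeptide), T(x)2T (2-gap pair)}` and its expected
#' per-residue vote vector `(0, 1, 0, 1, 2)` — the L and the first T sit
#' in one selected occurrence each, and the final T anchors both the LT
#' and the T(x)2T occurrence.
#'
#' Fixture `msi_fragment`: the residues 9–18 (`QLIPINTALT`) of the eelpout
#' type III AFP (PDB 1msi) with the published per-residue vote totals;
#' the totals come from an unpublished selected-attribute set, so they are
#' illustrative documentation, not a recomputable target.
#'
#' @return Named list of fixtures.
#' @export
worked_example_fixtures <- function() {
  list(
    ntalt = list(
      sequence = "NTALT",
      selected = list(
        list(spec = scheme_spec("gapped_dipeptide", g = 0),
             attribute = "LT"),
        list(spec = scheme_spec("gapped_dipeptide", g = 2),
             attribute = "TxxT")),
      expected_votes = c(N = 0L, T = 1L, A = 0L, L = 1L, T = 2L)),
    msi_fragment = list(
      pdb = "1msi",
      sequence = "QLIPINTALT",
      positions = 9:18,
      votes = c(Q = 3L, L = 3L, I = 0L, P = 1L, I = 2L, N = 4L,
                T = 8L, A = 5L, L = 3L, T = 4L)))
}
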