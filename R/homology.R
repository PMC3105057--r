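#' Global alignment parameters
#'
#' @param matrix Substitution matrix name (a matrix bundled with
#'   Biostrings, default `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative affine gap penalties: a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param si_denominator `"alignment"` (default) divides identities by the
#'   full alignment length including gap columns; `"shorter"` divides by
#'   the shorter sequence's length.
#' @return An `alignment_params` object.
#' @export
alignment_params <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 1,
                             si_denominator = c("alignment", "shorter")) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 si_denominator = match.arg(si_denominator)),
            class = "alignment_params")
}

substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Optimal global pairwise alignment with sequence identity
#'
#' Needleman–Wunsch-style global alignment with affine gap penalties
#' (computed via Biostrings).  Sequence identity (SI) is
#' `100 * identities / alignment length` where the alignment length
#' counts gap columns (switchable to the shorter-sequence denominator).
#'
#' @param a,b Non-empty protein sequences.
#' @param params An [alignment_params()].
#' @return List with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `identities`, `length` (alignment columns) and `si` (percentage).
#' @examples
#' global_align("NTALT", "NTALT")$si  # 100
#' @export
global_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  idents <- sum(ca == cb & ca != "-")
  len <- length(ca)
  denom <- if (params$si_denominator == "alignment") len
           else min(nchar(a), nchar(b))
  list(aligned_a = pa, aligned_b = pb, score = Biostrings::score(aln),
       identities = idents, length = len, si = 100 * idents / denom)
}

#' Best-hit sequence identity of a query against a library
#'
#' Aligns the query with every library sequence and keeps the single
#' best-scoring hit by maximal SI; ties break deterministically to the
#' first sequence in library order.
#'
#' @param query Query sequence (single string).
#' @param library Named character vector of library sequences.
#' @param params An [alignment_params()].
#' @param exclude_self Drop library entries identical in id to `query_id`.
#' @param query_id Id of the query (for reporting and self-exclusion).
#' @return data.frame row (`query`, `target`, `si`).
#' @export
best_hit_si <- function(query, library, params = alignment_params(),
                        exclude_self = FALSE, query_id = "query") {
  if (exclude_self) library <- library[names(library) != query_id]
  if (length(library) == 0L) stop("library is empty")
  if (is.null(names(library))) {
    names(library) <- sprintf("lib%d", seq_along(library))
  }
  sis <- vapply(library, function(s) global_align(query, s, params)$si,
                numeric(1))
  best <- which.max(sis)  # first maximum = first in library order
  data.frame(query = query_id, target = names(library)[best],
             si = unname(sis[best]), stringsAsFactors = FALSE)
}

#' Identification rate binned by best-hit sequence identity
#'
#' @param si_records data.frame with columns `query` and `si` (e.g. rows
#'   from [best_hit_si()]).
#' @param verdicts Named logical vector (`TRUE` = identified), keyed by
#'   query id; must cover exactly the queries in `si_records`.
#' @param bin_edges Increasing numeric vector of SI bin edges covering
#'   \[0, 100\]; bins are left-closed, the last bin closed on both sides.
#' @return data.frame (bin, lower, upper, n, identified, rate); empty bins
#'   have `n = 0` and `rate = NA`.
#' @export
si_binned_accuracy <- function(si_records, verdicts,
                               bin_edges = seq(0, 100, by = 20)) {
  if (!setequal(si_records$query, names(verdicts))) {
    stop("si_records and verdicts must be keyed by the same query ids")
  }
  v <- verdicts[si_records$query]
  idx <- findInterval(si_records$si, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin = sprintf("[%g,%g%s", bin_edges[-length(bin_edges)],
                                  bin_edges[-1],
                                  c(rep(")", nb - 1L), "]")),
                    lower = bin_edges[-length(bin_edges)],
                    upper = bin_edges[-1],
                    n = tabulate(idx, nbins = nb),
                    identified = vapply(seq_len(nb),
                                        function(b) sum(v[idx == b]),
                                        integer(1)))
  out$rate <- ifelse(out$n > 0, 100 * out$identified / out$n, NA_real_)
  out
}
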