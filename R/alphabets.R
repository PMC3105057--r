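AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

EXPECTED_GROUP_COUNTS <- c(A = 20L, H = 3L, V = 3L, Z = 3L, P = 3L,
                           F = 4L, S = 7L, E = 8L)

#' Construct a reduced amino-acid alphabet
#'
#' A reduced alphabet partitions the 20 canonical residues into ordered,
#' disjoint groups; each group has a symbol and every residue maps to the
#' symbol of its group.
#'
#' @param name Alphabet name (a single string).
#' @param groups Named list: group symbol -> character vector of member
#'   residues.  Groups must be disjoint and jointly cover all 20 residues.
#' @return An object of class `reduced_alphabet` with fields `name`,
#'   `groups`, `symbols` (ordered group symbols) and `symbol_of` (named
#'   character vector residue -> symbol).
#' @export
reduced_alphabet <- function(name, groups) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("alphabet '", name, "': groups are not disjoint")
  }
  if (!setequal(members, AMINO_ACIDS)) {
    missing <- setdiff(AMINO_ACIDS, members)
    extra <- setdiff(members, AMINO_ACIDS)
    stop("alphabet '", name, "' does not partition the 20 canonical residues",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = "")),
         if (length(extra)) paste0("; non-canonical: ", paste(extra, collapse = "")))
  }
  symbol_of <- character(0)
  for (sym in names(groups)) {
    symbol_of[groups[[sym]]] <- sym
  }
  symbol_of <- symbol_of[AMINO_ACIDS]
  structure(list(name = name, groups = groups, symbols = names(groups),
                 symbol_of = symbol_of),
            class = "reduced_alphabet")
}

#' @export
print.reduced_alphabet <- function(x, ...) {
  cat(sprintf("reduced alphabet '%s' (%d groups)\n", x$name, length(x$groups)))
  for (sym in names(x$groups)) {
    cat(sprintf("  %s: %s\n", sym, paste(x$groups[[sym]], collapse = "")))
  }
  invisible(x)
}

parse_alphabet_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("alphabet", "symbol", "residues")
  if (!all(need %in% names(tab))) {
    stop("alphabet table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (nm in unique(tab$alphabet)) {
    rows <- tab[tab$alphabet == nm, , drop = FALSE]
    groups <- lapply(rows$residues, function(r) strsplit(r, "")[[1]])
    names(groups) <- rows$symbol
    out[[nm]] <- reduced_alphabet(nm, groups)
  }
  out
}

.alphabet_cache <- new.env(parent = emptyenv())

#' Built-in reduced amino-acid alphabets
#'
#' Returns the registry of the eight coding alphabets: `A` (identity, 20
#' groups), the three-class physicochemical descriptors `H` (hydrophobicity:
#' polar RKEDQN / neutral GASTPHY / hydrophobic CLVIMFW), `V` (normalized
#' van der Waals volume), `Z` (polarizability), `P` (polarity), and the
#' coarser partitions `F` (4 groups), `S` (7) and `E` (8).  Group tables are
#' loaded from the bundled TSV; `F`/`S`/`E` memberships are documented
#' approximations and any alphabet may be replaced through `overrides`.
#'
#' @param overrides Optional path to a TSV (columns alphabet, symbol,
#'   residues) whose alphabets replace the built-in ones of the same name,
#'   or a list of `reduced_alphabet` objects.
#' @return Named list of `reduced_alphabet` objects.
#' @examples
#' length(builtin_alphabets()[["H"]]$groups)  # 3
#' @export
builtin_alphabets <- function(overrides = NULL) {
  if (is.null(.alphabet_cache$builtin)) {
    path <- system.file("extdata", "alphabet_groups.tsv", package = "afpvote",
                        mustWork = TRUE)
    reg <- parse_alphabet_table(path)
    counts <- vapply(reg, function(a) length(a$groups), integer(1))
    stopifnot(identical(counts[names(EXPECTED_GROUP_COUNTS)],
                        EXPECTED_GROUP_COUNTS))
    .alphabet_cache$builtin <- reg
  }
  reg <- .alphabet_cache$builtin
  if (!is.null(overrides)) {
    extra <- if (is.character(overrides)) parse_alphabet_table(overrides)
             else overrides
    stopifnot(all(vapply(extra, inherits, logical(1), "reduced_alphabet")))
    for (nm in names(extra)) reg[[nm]] <- extra[[nm]]
  }
  reg
}

#' Encode a sequence in a reduced alphabet
#'
#' Replaces each residue by the symbol of its group; length preserving and
#' position-wise independent.
#'
#' @param sequence Canonical amino-acid sequence (single string).
#' @param alphabet A `reduced_alphabet` or the name of a built-in one.
#' @return The encoded string over the alphabet's group symbols.
#' @examples
#' encode_sequence("NTALT", "H")  # "12232"
#' @export
encode_sequence <- function(sequence, alphabet) {
  if (is.character(alphabet)) {
    alphabet <- builtin_alphabets()[[alphabet]]
  }
  stopifnot(inherits(alphabet, "reduced_alphabet"))
  chars <- strsplit(sequence, "")[[1]]
  syms <- alphabet$symbol_of[chars]
  if (anyNA(syms)) {
    bad <- unique(chars[is.na(syms)])
    stop("residue(s) not in alphabet '", alphabet$name, "': ",
         paste(bad, collapse = ", "))
  }
  paste(syms, collapse = "")
}
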