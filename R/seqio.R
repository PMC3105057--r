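#' Read protein sequences from a FASTA file
#'
#' A deliberately strict reader: it reports malformed input (sequence data
#' before the first header, empty headers, records with no residues) with
#' the offending line number, which generic readers silently tolerate.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `description`, `sequence`
#'   (uppercased), one row per record in file order.  Zero rows for an
#'   empty file.  Duplicate ids are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  chunks <- NULL; header_line <- 0L
  flush <- function() {
    if (is.null(chunks)) return(invisible())
    s <- paste(chunks, collapse = "")
    if (!nzchar(s)) {
      stop("FASTA parse error at line ", header_line,
           ": record '", ids[length(ids)], "' has an empty sequence")
    }
    seqs[length(seqs) + 1L] <<- toupper(s)
    chunks <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- sub("\r$", "", lines[[i]])
    if (startsWith(line, ">")) {
      flush()
      header <- sub("^>\\s*", "", line)
      if (!nzchar(header)) {
        stop("FASTA parse error at line ", i, ": empty header")
      }
      id <- sub("\\s.*$", "", header)
      desc <- sub("^\\S+\\s*", "", header)
      ids[length(ids) + 1L] <- id
      descs[length(descs) + 1L] <- desc
      chunks <- character(0)
      header_line <- i
    } else if (nzchar(trimws(line))) {
      if (length(ids) == 0L) {
        stop("FASTA parse error at line ", i,
             ": sequence data before first '>' header")
      }
      chunks <- c(chunks, gsub("\\s", "", line))
    }
  }
  flush()
  if (length(ids) && anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(id = ids, description = descs, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write records to a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if ("description" %in% names(records)) records$description[i] else ""
    header <- if (nzchar(desc)) paste0(">", records$id[i], " ", desc)
              else paste0(">", records$id[i])
    writeLines(header, con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Canonicalize a raw protein sequence
#'
#' Resolves nonstandard residue codes and gap characters so that downstream
#' composition features see only the 20 canonical residues.
#'
#' Policies: `"strict"` errors on any of B/J/O/U/X/Z, gaps (`-`, `.`, `*`)
#' or other non-canonical characters, listing the offending positions;
#' `"drop"` removes them; `"map_to_most_frequent"` maps each ambiguity code
#' to the most frequent residue it stands for (B->N, Z->Q, U->C) and drops
#' what cannot be mapped (X, J, O, gaps).
#'
#' @param sequence Raw sequence string (case-insensitive).
#' @param policy One of `"drop"`, `"strict"`, `"map_to_most_frequent"`.
#' @return Canonical uppercase sequence.
#' @examples
#' canonicalize("ACXDE", "drop")               # "ACDE"
#' canonicalize("ABZ", "map_to_most_frequent") # "ANQ"
#' @export
canonicalize <- function(sequence,
                         policy = c("drop", "strict", "map_to_most_frequent")) {
  policy <- match.arg(policy)
  chars <- strsplit(toupper(sequence), "")[[1]]
  canon <- chars %in% AMINO_ACIDS
  if (policy == "strict") {
    if (!all(canon)) {
      stop("non-canonical residue(s) under strict policy: ",
           paste(sprintf("%s@%d", chars[!canon], which(!canon)),
                 collapse = ", "))
    }
    return(paste(chars, collapse = ""))
  }
  if (policy == "map_to_most_frequent") {
    map <- c(B = "N", Z = "Q", U = "C")
    mappable <- chars %in% names(map)
    chars[mappable] <- map[chars[mappable]]
    canon <- chars %in% AMINO_ACIDS
  }
  paste(chars[canon], collapse = "")
}

#' Read a label (and optional subset) table
#'
#' @param path TSV with 2 or 3 columns: id, label (`AFP`/`NONAFP`), and
#'   optionally the positive-subset index used for fold assignment.
#' @return data.frame with columns `id`, `label` and, when present,
#'   `subset` (integer, NA for negatives).
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label table needs at least 2 columns (id, label)")
  out <- data.frame(id = tab[[1]], label = toupper(tab[[2]]),
                    stringsAsFactors = FALSE)
  if (!all(out$label %in% c("AFP", "NONAFP"))) {
    stop("labels must be 'AFP' or 'NONAFP'")
  }
  if (ncol(tab) >= 3L) {
    out$subset <- suppressWarnings(as.integer(tab[[3]]))
  }
  out
}

#' Attach labels to sequence records
#'
#' @param records data.frame from [read_fasta()].
#' @param labels data.frame from [read_labels()] (or with the same columns).
#' @return The records with `label` (and `subset` if provided) joined by id;
#'   every record must be labeled.
#' @export
label_dataset <- function(records, labels) {
  if (anyDuplicated(records$id)) stop("duplicate record ids")
  idx <- match(records$id, labels$id)
  if (anyNA(idx)) {
    stop("unlabeled record(s): ",
         paste(records$id[is.na(idx)], collapse = ", "))
  }
  records$label <- labels$label[idx]
  if ("subset" %in% names(labels)) records$subset <- labels$subset[idx]
  records
}

#' Assign cross-validation folds
#'
#' Positives (AFPs) are placed in the fold given by their declared subset
#' index — subsets group sequences by homology so that no fold is tested on
#' sequences homologous to its training set.  Negatives are shuffled with
#' the given seed (Fisher–Yates via `sample`) and dealt round-robin across
#' the folds, so negative fold sizes differ by at most one.
#'
#' @param dataset Labeled records data.frame (columns `id`, `label`).
#' @param positive_subsets Named integer vector id -> subset in
#'   `1..n_folds`, covering every AFP record (defaults to the dataset's
#'   `subset` column).
#' @param n_folds Number of folds (default 7).
#' @param seed Integer seed for the negative shuffle.
#' @return The dataset with an integer `fold` column.
#' @export
assign_folds <- function(dataset, positive_subsets = NULL, n_folds = 7L,
                         seed = 1L) {
  stopifnot(all(c("id", "label") %in% names(dataset)))
  if (is.null(positive_subsets)) {
    if (!"subset" %in% names(dataset)) {
      stop("positive_subsets not given and dataset has no 'subset' column")
    }
    pos <- dataset$label == "AFP"
    positive_subsets <- stats::setNames(dataset$subset[pos], dataset$id[pos])
  }
  pos_ids <- dataset$id[dataset$label == "AFP"]
  missing <- setdiff(pos_ids, names(positive_subsets))
  if (length(missing)) {
    stop("positive record(s) missing from positive_subsets: ",
         paste(missing, collapse = ", "))
  }
  subs <- positive_subsets[pos_ids]
  if (anyNA(subs) || any(subs < 1L | subs > n_folds)) {
    stop("positive subsets must lie in 1..", n_folds)
  }
  fold <- integer(nrow(dataset))
  names(fold) <- dataset$id
  fold[pos_ids] <- as.integer(subs)
  neg_ids <- dataset$id[dataset$label == "NONAFP"]
  if (length(neg_ids)) {
    shuffled <- with_seed(seed, sample(neg_ids))
    fold[shuffled] <- rep_len(seq_len(n_folds), length(shuffled))
  }
  if (!all(seq_len(n_folds) %in% fold)) {
    warning("some folds are empty")
  }
  dataset$fold <- unname(fold[dataset$id])
  dataset
}

#' Write a fold map as TSV
#'
#' @param dataset Output of [assign_folds()].
#' @param path Output path.
#' @export
write_folds <- function(dataset, path) {
  stopifnot("fold" %in% names(dataset))
  utils::write.table(dataset[, c("id", "fold")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library randomness never leaks into user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
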