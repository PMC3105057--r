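#' Reference PDB ice-binding protein subsets
#'
#' The bundled table of the 44 structure-verified AFP identifiers grouped
#' into 7 homology subsets (subset sizes 1, 33, 1, 3, 3, 1, 2): insect
#' AFPs (subsets 1, 6), type III fish AFPs (2), the beta-helical insect
#' AFPs (3, 5), type I fish AFPs (4) and type II fish AFPs (7).  Used as
#' the declared `positive_subsets` input of [assign_folds()] when working
#' with the real data, and for dataset bookkeeping tests.
#'
#' @return data.frame with columns `id`, `label` (`"AFP"`), `subset`.
#' @export
afp_reference_subsets <- function() {
  path <- system.file("extdata", "afp_subsets.tsv", package = "afpvote",
                      mustWork = TRUE)
  read_labels(path)
}

#' Reference organism distribution of the independent AFP cohort
#'
#' The bundled per-organism sequence counts of the curated UniProtKB
#' antifreeze-protein evaluation cohort (369 sequences across algae,
#' bacteria, fish, insects and plants).
#'
#' @return data.frame with columns `organism`, `n`.
#' @export
afp_organism_counts <- function() {
  path <- system.file("extdata", "afp_organism_counts.tsv",
                      package = "afpvote", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
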