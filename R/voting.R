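#' Assemble a jury of scheme classifiers
#'
#' @param members Named list of `scheme_classifier` objects (each must
#'   carry its `scheme_spec`); the default jury is the 13 schemes of
#'   [default_scheme_set()].
#' @param sequence_vote_threshold Positive verdicts needed for a
#'   sequence-level AFP call; default is the majority
#'   `ceiling(n_members / 2)` (7 of 13).
#' @return A `jury_config`.
#' @export
jury_config <- function(members, sequence_vote_threshold = NULL) {
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "scheme_classifier")),
            all(vapply(members, function(m) !is.null(m$scheme), logical(1))))
  if (is.null(sequence_vote_threshold)) {
    sequence_vote_threshold <- ceiling(length(members) / 2)
  }
  stopifnot(sequence_vote_threshold >= 1L,
            sequence_vote_threshold <= length(members))
  if (is.null(names(members))) {
    names(members) <- vapply(members, function(m) m$scheme$label, character(1))
  }
  structure(list(members = members,
                 sequence_vote_threshold = as.integer(sequence_vote_threshold)),
            class = "jury_config")
}

#' @export
print.jury_config <- function(x, ...) {
  cat(sprintf("jury of %d scheme classifiers (threshold %d): %s\n",
              length(x$members), x$sequence_vote_threshold,
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Sequence-level AFP call by jury vote
#'
#' Each member classifier votes on the sequence's feature vector under its
#' own scheme.  Members whose scheme cannot encode the sequence (too
#' short) abstain; the majority threshold is then rescaled proportionally
#' to the number of non-abstaining members.
#'
#' @param sequence Canonical protein sequence.
#' @param jury A `jury_config`.
#' @param alphabets Alphabet registry.
#' @return List with `verdict` (`"AFP"`/`"NONAFP"`), `positive_votes`,
#'   `threshold` (the effective, possibly rescaled threshold),
#'   `abstentions`, and `verdicts` (per-member data.frame for audit).
#' @export
classify_sequence <- function(sequence, jury,
                              alphabets = builtin_alphabets()) {
  stopifnot(inherits(jury, "jury_config"))
  rows <- lapply(names(jury$members), function(nm) {
    member <- jury$members[[nm]]
    if (nchar(sequence) < scheme_min_length(member$scheme)) {
      return(data.frame(member = nm, verdict = NA_character_,
                        score = NA_real_, abstained = TRUE,
                        stringsAsFactors = FALSE))
    }
    fv <- feature_vector(sequence, member$scheme, alphabets)
    pred <- predict(member, fv)
    data.frame(member = nm, verdict = pred$label, score = pred$score,
               abstained = FALSE, stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  active <- sum(!verdicts$abstained)
  if (active == 0L) {
    stop("undecidable: every jury member abstained on this sequence")
  }
  threshold <- max(1L, ceiling(jury$sequence_vote_threshold *
                                 active / length(jury$members)))
  positive <- sum(verdicts$verdict == "AFP", na.rm = TRUE)
  list(verdict = if (positive >= threshold) "AFP" else "NONAFP",
       positive_votes = positive, threshold = threshold,
       abstentions = length(jury$members) - active, verdicts = verdicts)
}

#' Batch sequence classification
#'
#' @param records data.frame with `id` and `sequence` columns.
#' @inheritParams classify_sequence
#' @return data.frame (id, verdict, positive_votes, abstentions).
#' @export
classify_batch <- function(records, jury, alphabets = builtin_alphabets()) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    res <- classify_sequence(records$sequence[i], jury, alphabets)
    data.frame(id = records$id[i], verdict = res$verdict,
               positive_votes = res$positive_votes,
               abstentions = res$abstentions, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a vote-only jury from explicit attribute selections
#'
#' Constructs jury members that carry a scheme and a selected-attribute
#' mask but no fitted model — enough for [residue_votes()], which only
#' needs to know which attributes were selected.  Useful for worked
#' examples and for re-scoring residues under a published attribute set.
#' Such members cannot vote in [classify_sequence()].
#'
#' @param selections List of `list(spec = <scheme_spec>, attribute =
#'   <character vector>)` entries.
#' @param ... Passed to [jury_config()].
#' @return A `jury_config`.
#' @examples
#' fx <- worked_example_fixtures()$ntalt
#' jury <- attribute_jury(fx$selected)
#' residue_votes(fx$sequence, jury)$votes  # 0 1 0 1 2
#' @export
attribute_jury <- function(selections, ...) {
  members <- lapply(selections, function(sel) {
    attrs <- scheme_attributes(sel$spec)
    mask <- attrs %in% sel$attribute
    if (!all(sel$attribute %in% attrs)) {
      stop("attribute(s) not in scheme ", sel$spec$label, ": ",
           paste(setdiff(sel$attribute, attrs), collapse = ", "))
    }
    structure(list(scheme = sel$spec, mask = mask, config = NULL,
                   model = NULL, attributes = attrs,
                   cv_scores = data.frame(C = numeric(0),
                                          gamma = numeric(0),
                                          mcc = numeric(0))),
              class = "scheme_classifier")
  })
  names(members) <- vapply(selections,
                           function(sel) sel$spec$label, character(1))
  jury_config(members, ...)
}

#' Residue-level vote accumulation
#'
#' For every jury member, every selected (unmasked) attribute of its
#' scheme, and every occurrence of that attribute in the sequence, each
#' residue in the occurrence footprint gains one vote.  Votes accumulate
#' across schemes and across overlapping occurrences; residues with many
#' votes are candidate ice-binding positions.
#'
#' @inheritParams classify_sequence
#' @param id Sequence identifier carried into the profile.
#' @return A `vote_profile`: list with `id`, `sequence`, `votes`
#'   (integer per residue) and `tiers` (filled by [tier_residues()]).
#' @export
residue_votes <- function(sequence, jury, alphabets = builtin_alphabets(),
                          id = "query") {
  stopifnot(inherits(jury, "jury_config"))
  votes <- integer(nchar(sequence))
  for (member in jury$members) {
    spec <- member$scheme
    if (nchar(sequence) < scheme_min_length(spec)) next
    fc <- feature_counts(sequence, spec, alphabets)
    present <- fc$attrs[fc$counts > 0L]
    for (attribute in intersect(selected_attributes(member), present)) {
      for (occ in match_attribute_positions(sequence, spec, attribute,
                                            alphabets)) {
        votes[occ + 1L] <- votes[occ + 1L] + 1L
      }
    }
  }
  structure(list(id = id, sequence = sequence, votes = votes,
                 tiers = NULL),
            class = "vote_profile")
}

#' Assign display tiers to residue votes
#'
#' Residues with at least 6 votes are tier `"red"` (strong ice-binding
#' candidates), 4–5 votes `"yellow"`, and at most 3 votes `"gray"`.  The
#' conventional color legend leaves counts of exactly 3 and 6 unassigned;
#' this implementation fixes the boundaries at red >= 6 and gray <= 3
#' (see the methods vignette).
#'
#' @param profile A `vote_profile` from [residue_votes()].
#' @return The profile with its `tiers` field populated.
#' @export
tier_residues <- function(profile) {
  stopifnot(inherits(profile, "vote_profile"))
  v <- profile$votes
  profile$tiers <- ifelse(v >= 6L, "red", ifelse(v >= 4L, "yellow", "gray"))
  profile
}

#' @export
print.vote_profile <- function(x, ...) {
  cat(sprintf("vote profile for '%s' (%d residues, %d total votes)\n",
              x$id, nchar(x$sequence), sum(x$votes)))
  cat(" ", x$sequence, "\n ", paste(ifelse(x$votes > 9, "+",
                                           x$votes), collapse = ""), "\n")
  invisible(x)
}

#' Write a vote profile as per-residue TSV
#'
#' Columns: position (1-based), residue, votes, tier.
#'
#' @param profile A `vote_profile` (tiers are computed if absent).
#' @param path Output path.
#' @export
write_vote_profile <- function(profile, path) {
  if (is.null(profile$tiers)) profile <- tier_residues(profile)
  tab <- data.frame(position = seq_len(nchar(profile$sequence)),
                    residue = strsplit(profile$sequence, "")[[1]],
                    votes = profile$votes, tier = profile$tiers,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Train a full jury from a labeled dataset
#'
#' Pipeline glue: builds the per-scheme feature matrices, optionally runs
#' genetic-algorithm attribute selection per scheme, grid-searches each
#' scheme classifier, and assembles the jury.  Sequences too short for a
#' scheme are excluded from that member's training (they will also lead
#' to abstention at prediction time).
#'
#' @param dataset Labeled records data.frame (`id`, `sequence`, `label`).
#' @param schemes Named list of `scheme_spec`s (default the 13-scheme set).
#' @param grid Hyperparameter grid for [grid_search_train()].
#' @param ga A [ga_config()] to run attribute selection per scheme, or
#'   `NULL` for all-ones masks.
#' @param internal_folds Internal CV folds for the grid search.
#' @param seed Base seed; per-scheme seeds are derived from it.
#' @param alphabets Alphabet registry.
#' @param verbose Print per-scheme progress to stderr.
#' @return A `jury_config` whose members carry their scheme, mask and
#'   fitted model.
#' @export
train_jury <- function(dataset, schemes = default_scheme_set(),
                       grid = default_grid(), ga = NULL,
                       internal_folds = 5L, seed = 1L,
                       alphabets = builtin_alphabets(), verbose = FALSE) {
  members <- list()
  for (i in seq_along(schemes)) {
    nm <- names(schemes)[i]
    spec <- schemes[[i]]
    m <- build_scheme_matrix(dataset, spec, alphabets)
    labels <- dataset$label[match(rownames(m), dataset$id)]
    mask <- NULL
    ga_history <- NULL
    if (!is.null(ga)) {
      ga_i <- ga
      ga_i$seed <- as.integer((ga$seed + i * 1009L) %% .Machine$integer.max)
      res <- run_ga(m, labels, config = ga_i)
      mask <- res$best$mask
      ga_history <- res$history
      if (verbose) {
        message(sprintf("scheme %s: GA kept %d/%d attributes (MCC %.3f)",
                        nm, sum(mask), length(mask), res$best$mcc))
      }
    }
    members[[nm]] <- grid_search_train(
      m, labels, internal_folds = internal_folds, grid = grid,
      seed = as.integer((seed + i) %% .Machine$integer.max),
      scheme = spec, mask = mask)
    members[[nm]]$ga_history <- ga_history
    if (verbose) {
      message(sprintf("scheme %s: trained (C=%g gamma=%g)", nm,
                      members[[nm]]$config$C, members[[nm]]$config$gamma))
    }
  }
  jury_config(members)
}
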