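#' Genetic-algorithm configuration
#'
#' @param population_size Individuals per generation (>= 2, default 50).
#' @param generations Number of generations (default 100).
#' @param crossover_rate Probability a child pair is produced by uniform
#'   crossover rather than cloning (default 0.8).
#' @param mutation_rate Per-bit flip probability; `NULL` (default) resolves
#'   to `1 / n_attributes`.
#' @param elitism_count Top individuals copied unchanged into the next
#'   generation (>= 1, default 2).
#' @param tournament_size Tournament selection size (default 3).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 50L, generations = 100L,
                      crossover_rate = 0.8, mutation_rate = NULL,
                      elitism_count = 2L, tournament_size = 3L, seed = 1L) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            is.null(mutation_rate) ||
              (mutation_rate >= 0 && mutation_rate <= 1),
            elitism_count >= 1L, elitism_count < population_size,
            tournament_size >= 1L)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "ga_config")
}

mask_key <- function(mask) {
  pad <- (8L - length(mask) %% 8L) %% 8L
  paste(as.character(packBits(c(mask, rep(FALSE, pad)), "raw")),
        collapse = "")
}

# fitness ordering: higher MCC, then fewer false positives, then fewer
# selected attributes; returns TRUE if a is strictly better than b
fitness_better <- function(a, b) {
  if (a$mcc != b$mcc) return(a$mcc > b$mcc)
  if (a$fp != b$fp) return(a$fp < b$fp)
  a$n_selected < b$n_selected
}

#' Fitness of a feature mask
#'
#' The fitness of a mask is the internal cross-validated MCC of a
#' classifier trained on the masked matrix; false-positive count and the
#' number of selected attributes are carried along as tie-breakers (the
#' selection goal is as few false positives, with as few attributes, as
#' possible).
#'
#' @param mask Logical vector over the matrix columns, at least one bit
#'   set.
#' @param matrix Feature matrix (records x attributes).
#' @param labels `"AFP"`/`"NONAFP"` (or +1/-1) per row.
#' @param internal_folds Cross-validation folds (default 3).
#' @param grid List of `classifier_config`s; each is evaluated and the best
#'   internal result kept (a single-config grid skips that inner search).
#' @param seed Seed for the internal fold assignment (or a precomputed
#'   integer fold vector, which genetic-algorithm runs pass so every mask
#'   is scored on identical folds).
#' @return A `fitness_record`: list with `mask`, `mcc`, `tp`, `fp`,
#'   `n_selected`.
#' @export
evaluate_fitness <- function(mask, matrix, labels, internal_folds = 3L,
                             grid = list(classifier_config(8, 2)),
                             seed = 1L) {
  if (!any(mask)) stop("empty feature mask")
  y <- labels_to_y(labels)
  fold <- if (length(seed) == nrow(matrix)) seed
          else stratified_folds(y, internal_folds, seed)
  Xm <- matrix[, mask, drop = FALSE]
  best <- NULL
  for (cfg in grid) {
    cc <- cv_counts(Xm, y, fold, cfg)
    rec <- list(mask = mask, mcc = mcc(cc), tp = cc$tp, fp = cc$fp,
                n_selected = sum(mask))
    if (is.null(best) || fitness_better(rec, best)) best <- rec
  }
  structure(best, class = "fitness_record")
}

tournament_pick <- function(fitness, k) {
  contenders <- sample.int(length(fitness), k, replace = TRUE)
  best <- contenders[1]
  for (t in contenders[-1]) {
    if (fitness_better(fitness[[t]], fitness[[best]])) best <- t
  }
  best
}

#' Genetic-algorithm feature-attribute selection
#'
#' Evolves binary feature masks over one scheme's attributes, maximizing
#' internal cross-validated MCC (ties: fewer false positives, then fewer
#' attributes).  Generation 0 is random masks at 50% density plus the
#' injected all-ones mask, so the final mask can never score below
#' no-selection on the internal criterion; elitism makes the best-ever
#' fitness monotone non-decreasing.
#'
#' @param matrix Feature matrix (records x attributes).
#' @param labels `"AFP"`/`"NONAFP"` (or +1/-1) per row.
#' @param config A [ga_config()].
#' @param grid Classifier configuration(s) used in fitness evaluation;
#'   `NULL` (default) pre-selects a single configuration by grid search
#'   over [coarse_grid()] on the all-ones mask and uses it throughout.
#' @param internal_folds Folds for fitness cross-validation (default 3).
#' @return List with `best` (the best-ever `fitness_record`), `history`
#'   (data.frame: generation, best_mcc, best_fp, best_n_selected) and
#'   `grid` (the configuration(s) actually used).
#' @export
run_ga <- function(matrix, labels, config = ga_config(), grid = NULL,
                   internal_folds = 3L) {
  y <- labels_to_y(labels)
  if (length(unique(y)) < 2L) stop("degenerate labels: one class only")
  p <- ncol(matrix)
  mut <- if (is.null(config$mutation_rate)) 1 / p else config$mutation_rate
  fold <- stratified_folds(y, internal_folds, config$seed)
  if (is.null(grid)) {
    all_ones <- rep(TRUE, p)
    pre <- lapply(coarse_grid(), function(cfg) {
      list(cfg = cfg, fit = evaluate_fitness(all_ones, matrix, labels,
                                             grid = list(cfg), seed = fold))
    })
    best_i <- 1L
    for (i in seq_along(pre)[-1]) {
      if (fitness_better(pre[[i]]$fit, pre[[best_i]]$fit)) best_i <- i
    }
    grid <- list(pre[[best_i]]$cfg)
  }
  cache <- new.env(parent = emptyenv())
  score <- function(mask) {
    key <- mask_key(mask)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rec <- evaluate_fitness(mask, matrix, labels, grid = grid, seed = fold)
    cache[[key]] <- rec
    rec
  }
  with_seed(config$seed, {
    pop <- replicate(config$population_size,
                     stats::runif(p) < 0.5, simplify = FALSE)
    pop[[1]] <- rep(TRUE, p)
    pop <- lapply(pop, function(m) if (any(m)) m else {
      m[sample.int(p, 1)] <- TRUE; m
    })
    best_ever <- NULL
    history <- vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      fitness <- lapply(pop, score)
      ord <- order(vapply(fitness, `[[`, numeric(1), "mcc"),
                   -vapply(fitness, `[[`, numeric(1), "fp"),
                   -vapply(fitness, `[[`, numeric(1), "n_selected"),
                   decreasing = TRUE)
      gen_best <- fitness[[ord[1]]]
      if (is.null(best_ever) || fitness_better(gen_best, best_ever)) {
        best_ever <- gen_best
      }
      history[[gen]] <- data.frame(generation = gen,
                                   best_mcc = best_ever$mcc,
                                   best_fp = best_ever$fp,
                                   best_n_selected = best_ever$n_selected)
      if (gen == config$generations) break
      nextgen <- pop[ord[seq_len(config$elitism_count)]]
      while (length(nextgen) < config$population_size) {
        p1 <- pop[[tournament_pick(fitness, config$tournament_size)]]
        p2 <- pop[[tournament_pick(fitness, config$tournament_size)]]
        if (stats::runif(1) < config$crossover_rate) {
          take1 <- stats::runif(p) < 0.5
          child1 <- ifelse(take1, p1, p2)
          child2 <- ifelse(take1, p2, p1)
        } else {
          child1 <- p1
          child2 <- p2
        }
        for (child in list(child1, child2)) {
          flips <- stats::runif(p) < mut
          child <- xor(child, flips)
          if (!any(child)) child[sample.int(p, 1)] <- TRUE
          if (length(nextgen) < config$population_size) {
            nextgen[[length(nextgen) + 1L]] <- child
          }
        }
      }
      pop <- nextgen
    }
    list(best = best_ever, history = do.call(rbind, history), grid = grid)
  })
}

#' Write a genetic-algorithm history table
#'
#' @param history The `history` component of a [run_ga()] result.
#' @param path Output TSV path.
#' @export
write_ga_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
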