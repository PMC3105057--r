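#' Classifier hyperparameter configuration
#'
#' @param C Penalty parameter of the soft-margin objective (> 0).
#' @param gamma Radial-basis-kernel width parameter (> 0).
#' @param class_weight_positive Multiplier on `C` for positive (AFP)
#'   examples; `NA` (default) resolves at training time to
#'   `n_negative / n_positive`, which counteracts the extreme class
#'   imbalance of AFP benchmarks.
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(C, gamma, class_weight_positive = NA_real_) {
  stopifnot(C > 0, gamma > 0,
            is.na(class_weight_positive) || class_weight_positive > 0)
  structure(list(C = C, gamma = gamma,
                 class_weight_positive = class_weight_positive),
            class = "classifier_config")
}

#' Default hyperparameter grid
#'
#' The conventional exponential grid for radial-basis-kernel classifiers:
#' `C = 2^{-5}, 2^{-3}, ..., 2^{15}` and `gamma = 2^{-15}, 2^{-13}, ...,
#' 2^{3}`.
#'
#' @param C_exponents,gamma_exponents Base-2 exponents to cross.
#' @return List of `classifier_config` objects, ordered by increasing C
#'   then gamma (the tie-break order of [grid_search_train()]).
#' @export
default_grid <- function(C_exponents = seq(-5, 15, by = 2),
                         gamma_exponents = seq(-15, 3, by = 2)) {
  grid <- list()
  for (ce in sort(C_exponents)) {
    for (ge in sort(gamma_exponents)) {
      grid[[length(grid) + 1L]] <- classifier_config(2^ce, 2^ge)
    }
  }
  grid
}

#' A coarse grid for inner loops
#'
#' Sixteen-point subgrid used where the full grid would be wasteful, e.g.
#' inside genetic-algorithm fitness evaluation.
#'
#' @return List of `classifier_config` objects.
#' @export
coarse_grid <- function() {
  default_grid(C_exponents = c(-1, 3, 7, 11),
               gamma_exponents = c(-7, -3, 1, 5))
}

labels_to_y <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(-1, 1)))
    return(as.numeric(labels))
  }
  stopifnot(all(labels %in% c("AFP", "NONAFP")))
  ifelse(labels == "AFP", 1, -1)
}

resolve_weight <- function(config, y) {
  w <- config$class_weight_positive
  if (is.na(w)) w <- sum(y < 0) / sum(y > 0)
  max(w, .Machine$double.eps)
}

# stratified fold assignment, deterministic in `seed`
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

svm_fit <- function(X, y, config) {
  wpos <- resolve_weight(config, y)
  fit <- .svm_train_cpp(X, y, config$C, config$gamma, wpos)
  sv_rows <- X[fit$sv_index + 1L, , drop = FALSE]
  list(SV = sv_rows, coef = as.numeric(fit$alpha) * as.numeric(fit$sv_y),
       rho = fit$rho, gamma = config$gamma, config = config)
}

svm_score <- function(model, X) {
  if (nrow(model$SV) == 0L) {
    return(rep(-model$rho, nrow(X)))
  }
  as.numeric(.svm_decision_cpp(model$SV, model$coef, model$rho,
                               model$gamma, X))
}

# cross-validated confusion counts for one config on (a masked view of) X
cv_counts <- function(X, y, fold, config) {
  wpos <- resolve_weight(config, y)
  cc <- .svm_cv_counts_cpp(X, y, as.integer(fold), config$C, config$gamma,
                           wpos)
  confusion_counts(cc[1], cc[2], cc[3], cc[4])
}

# cheap content fingerprint (no digest dependency): md5 of the serialized
# object via a temporary file
fingerprint_of <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f, version = 2)
  unname(tools::md5sum(f))
}

#' Train one scheme classifier with hyperparameter grid search
#'
#' Selects the `classifier_config` maximizing internal cross-validated MCC
#' (ties broken toward smaller C, then smaller gamma), then refits on all
#' rows.
#'
#' @param matrix Numeric feature matrix (records x attributes), e.g. from
#'   [build_scheme_matrix()].
#' @param labels Character vector over `{"AFP", "NONAFP"}` (or +1/-1),
#'   aligned with the matrix rows.
#' @param internal_folds Folds for the internal cross-validation
#'   (default 5).
#' @param grid List of `classifier_config` candidates.
#' @param seed Seed for the internal fold assignment.
#' @param scheme Optional `scheme_spec` the matrix came from; stored for
#'   prediction from raw sequences.
#' @param mask Optional logical feature mask over the matrix columns
#'   (default all ones); training and prediction use only unmasked
#'   attributes.
#' @return A `scheme_classifier` with fields `scheme`, `mask`, `config`,
#'   `model`, `cv_scores` (per-config internal MCC) and
#'   `training_fingerprint`.
#' @export
grid_search_train <- function(matrix, labels, internal_folds = 5L,
                              grid = default_grid(), seed = 1L,
                              scheme = NULL, mask = NULL) {
  y <- labels_to_y(labels)
  if (length(unique(y)) < 2L) {
    stop("training requires both classes to be present")
  }
  stopifnot(nrow(matrix) >= internal_folds, length(grid) >= 1L)
  if (is.null(mask)) mask <- rep(TRUE, ncol(matrix))
  stopifnot(length(mask) == ncol(matrix), any(mask))
  Xm <- matrix[, mask, drop = FALSE]
  fold <- stratified_folds(y, internal_folds, seed)
  scores <- vapply(grid, function(cfg) mcc(cv_counts(Xm, y, fold, cfg)),
                   numeric(1))
  # max MCC; grid is ordered by (C, gamma) so which.max realizes the
  # smaller-C-then-smaller-gamma tie-break when candidates are ordered
  ord <- order(-scores,
               vapply(grid, `[[`, numeric(1), "C"),
               vapply(grid, `[[`, numeric(1), "gamma"))
  best <- grid[[ord[1]]]
  model <- svm_fit(Xm, y, best)
  obj <- structure(list(scheme = scheme, mask = mask, config = best,
                        model = model,
                        attributes = colnames(matrix),
                        cv_scores = data.frame(
                          C = vapply(grid, `[[`, numeric(1), "C"),
                          gamma = vapply(grid, `[[`, numeric(1), "gamma"),
                          mcc = scores),
                        internal_folds = internal_folds, seed = seed),
                   class = "scheme_classifier")
  obj$training_fingerprint <- fingerprint_of(
    list(dim(matrix), colnames(matrix), sum(matrix), y, best, mask, seed))
  obj
}

#' @export
print.scheme_classifier <- function(x, ...) {
  cat(sprintf(
    "scheme classifier%s: %d/%d attributes, C=%g gamma=%g, internal MCC=%.3f\n",
    if (!is.null(x$scheme)) paste0(" [", x$scheme$label, "]") else "",
    sum(x$mask), length(x$mask), x$config$C, x$config$gamma,
    max(x$cv_scores$mcc)))
  invisible(x)
}

#' Predict AFP/non-AFP for feature vectors
#'
#' @param object A `scheme_classifier`.
#' @param newdata Numeric matrix over the classifier's full attribute
#'   space (rows = records), or a single named feature vector.
#' @param ... Unused.
#' @return data.frame with columns `label` (`"AFP"` iff score > 0) and
#'   `score` (signed decision value).
#' @export
predict.scheme_classifier <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  if (ncol(newdata) != length(object$mask)) {
    stop("dimensionality mismatch: classifier expects ",
         length(object$mask), " attributes, got ", ncol(newdata))
  }
  scores <- svm_score(object$model, newdata[, object$mask, drop = FALSE])
  data.frame(label = ifelse(scores > 0, "AFP", "NONAFP"), score = scores,
             stringsAsFactors = FALSE)
}

#' Attributes selected by a classifier's mask
#'
#' @param classifier A `scheme_classifier`.
#' @return Character vector of unmasked attribute names.
#' @export
selected_attributes <- function(classifier) {
  classifier$attributes[classifier$mask]
}
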