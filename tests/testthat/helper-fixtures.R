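# Shared fixtures, built in code and memoized so expensive objects are
# constructed at most once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# two well-separated Gaussian clusters; linearly separable
toy_separable <- function(n_per_class = 20, seed = 42) {
  afpvote:::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per_class, 0, 0.5), n_per_class),
               matrix(rnorm(2 * n_per_class, 3, 0.5), n_per_class))
    colnames(X) <- c("f1", "f2")
    list(X = X, labels = rep(c("NONAFP", "AFP"), each = n_per_class))
  })
}

# a small planted-motif benchmark shared across GA / pipeline tests
small_benchmark <- function() {
  fixture("small_benchmark", function() {
    generate_benchmark(benchmark_spec(n_pos = 60, n_neg = 60,
                                      length_range = c(50, 80), seed = 101))
  })
}

# jury member that always votes the same way: an empty support-vector set
# leaves the decision function at the constant -rho
constant_member <- function(spec, verdict = c("AFP", "NONAFP")) {
  verdict <- match.arg(verdict)
  attrs <- scheme_attributes(spec)
  structure(list(
    scheme = spec, mask = rep(TRUE, length(attrs)),
    config = classifier_config(1, 1),
    model = list(SV = matrix(numeric(0), 0, length(attrs)),
                 coef = numeric(0),
                 rho = if (verdict == "AFP") -1 else 1,
                 gamma = 1),
    attributes = attrs,
    cv_scores = data.frame(C = 1, gamma = 1, mcc = NA_real_)),
    class = "scheme_classifier")
}

constant_jury <- function(verdicts, threshold = NULL) {
  specs <- lapply(seq_along(verdicts), function(i) {
    scheme_spec("gapped_dipeptide", g = 0, label = sprintf("m%02d", i))
  })
  members <- Map(constant_member, specs, verdicts)
  names(members) <- vapply(specs, `[[`, character(1), "label")
  jury_config(members, sequence_vote_threshold = threshold)
}

random_protein <- function(L) {
  paste(sample(afpvote:::AMINO_ACIDS, L, replace = TRUE), collapse = "")
}
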