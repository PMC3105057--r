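test_that("worked composition examples are exact", {
  v <- npeptide_composition("AAAG", 1)
  expect_equal(unname(v[c("A", "G")]), c(0.75, 0.25))
  expect_equal(sum(v), 1)

  d <- npeptide_composition("NTALT", 2)
  expect_equal(unname(d[c("NT", "TA", "AL", "LT")]), rep(0.25, 4))
  expect_equal(sum(d), 1)

  p <- partitioned_composition("AAAAGG", k = 2)
  expect_equal(unname(p[["s1:A"]]), 1.0)
  expect_equal(unname(p[["s2:A"]]), 1 / 3)
  expect_equal(unname(p[["s2:G"]]), 2 / 3)
  expect_equal(sum(p), 2)  # one unit per segment

  g0 <- gapped_dipeptide_composition("NTALT", 0)
  expect_equal(unname(g0[["LT"]]), 0.25)
  g2 <- gapped_dipeptide_composition("NTALT", 2)
  expect_equal(unname(g2[["TxxT"]]), 0.5)

  w <- window_composition("AAA", l = 3)
  expect_equal(unname(w[["A:A"]]), 1.0)
  expect_equal(sum(w), 1)
  # no lysine -> all (K, .) attributes zero
  expect_true(all(w[startsWith(names(w), "K:")] == 0))
})

test_that("g = 0 gapped composition equals the n = 2 n-peptide composition", {
  set.seed(31)
  for (rep in 1:5) {
    s <- random_protein(sample(5:25, 1))
    expect_equal(unname(gapped_dipeptide_composition(s, 0)),
                 unname(npeptide_composition(s, 2)))
  }
  # and k = 1 partitioned reduces to plain n-peptide
  s <- random_protein(18)
  expect_equal(unname(partitioned_composition(s, k = 1, n = 2)),
               unname(npeptide_composition(s, 2)))
})

test_that("attribute counts match brute-force enumeration (oracle)", {
  set.seed(33)
  for (rep in 1:12) {
    s <- random_protein(sample(8:30, 1))
    L <- nchar(s)
    for (n in 1:2) {
      for (alpha in c("A", "H", "S")) {
        spec <- scheme_spec("npeptide", alphabet = alpha, n = n)
        fc <- afpvote:::feature_counts(s, spec)
        expect_equal(fc$counts, oracle_ngram_counts(s, n, alpha))
        expect_equal(unname(feature_vector(s, spec)),
                     oracle_ngram_counts(s, n, alpha) / (L - n + 1))
      }
    }
    for (g in c(0, 2, 5)) {
      spec <- scheme_spec("gapped_dipeptide", g = g)
      expect_equal(afpvote:::feature_counts(s, spec)$counts,
                   oracle_gapped_counts(s, g))
    }
    for (l in c(3, 7)) {
      spec <- scheme_spec("window", l = l)
      expect_equal(afpvote:::feature_counts(s, spec)$counts,
                   oracle_window_counts(s, l))
    }
  }
})

test_that("normalization: every composition block sums to one", {
  set.seed(37)
  for (rep in 1:8) {
    s <- random_protein(sample(15:40, 1))
    expect_equal(sum(npeptide_composition(s, 2)), 1, tolerance = 1e-12)
    expect_equal(sum(gapped_dipeptide_composition(s, 3)), 1,
                 tolerance = 1e-12)
    p <- partitioned_composition(s, k = 3)
    for (seg in 1:3) {
      expect_equal(sum(p[startsWith(names(p), paste0("s", seg, ":"))]), 1,
                   tolerance = 1e-12)
    }
    w <- window_composition(s, l = 7)
    present <- unique(strsplit(s, "")[[1]])
    for (cen in afpvote:::AMINO_ACIDS) {
      block <- sum(w[startsWith(names(w), paste0(cen, ":"))])
      expect_equal(block, as.numeric(cen %in% present), tolerance = 1e-12)
    }
  }
})

test_that("too-short sequences raise degenerate-input errors", {
  expect_error(npeptide_composition("AC", 3), class = "afp_degenerate_input")
  expect_error(partitioned_composition("ACDE", k = 5),
               class = "afp_degenerate_input")
  expect_error(gapped_dipeptide_composition("ACD", g = 2),
               class = "afp_degenerate_input")
  expect_error(scheme_spec("window", l = 4), "odd")
})

test_that("match_attribute_positions reports exact footprints", {
  d0 <- scheme_spec("gapped_dipeptide", g = 0)
  expect_equal(match_attribute_positions("NTALT", d0, "LT"),
               list(c(3L, 4L)))
  d2 <- scheme_spec("gapped_dipeptide", g = 2)
  expect_equal(match_attribute_positions("NTALT", d2, "TxxT"),
               list(c(1L, 4L)))
  np2 <- scheme_spec("npeptide", n = 2)
  expect_equal(match_attribute_positions("AAAA", np2, "AA"),
               list(c(0L, 1L), c(1L, 2L), c(2L, 3L)))
  # partitioned footprints are offset into the owning segment
  px <- scheme_spec("partitioned", n = 1, k = 2)
  expect_equal(match_attribute_positions("AAAAGG", px, "s2:G"),
               list(4L, 5L))
  expect_error(match_attribute_positions("NTALT", d0, "not-an-attr"),
               "unknown attribute")
})

test_that("shift consistency: a disjoint prefix shifts anchors exactly", {
  s <- "NTALT"
  d2 <- scheme_spec("gapped_dipeptide", g = 2)
  for (shift in c(1, 4)) {
    shifted <- paste0(strrep("W", shift), s)
    expect_equal(match_attribute_positions(shifted, d2, "TxxT"),
                 lapply(match_attribute_positions(s, d2, "TxxT"),
                        function(x) x + shift))
  }
})

test_that("occurrences / denominators reproduce feature values exactly", {
  set.seed(41)
  specs <- list(scheme_spec("npeptide", n = 2),
                scheme_spec("npeptide", alphabet = "H", n = 3),
                scheme_spec("gapped_dipeptide", g = 1),
                scheme_spec("partitioned", n = 1, k = 3),
                scheme_spec("window", l = 5))
  for (rep in 1:4) {
    s <- random_protein(sample(12:25, 1))
    for (spec in specs) {
      fc <- afpvote:::feature_counts(s, spec)
      vals <- feature_vector(s, spec)
      nonzero <- which(fc$counts > 0)
      for (a in sample(nonzero, min(5, length(nonzero)))) {
        occ <- match_attribute_positions(s, spec, fc$attrs[a])
        expect_equal(length(occ), fc$counts[a])
        expect_equal(unname(vals[a]), length(occ) / fc$denom[a])
      }
    }
  }
})

test_that("build_scheme_matrix is deterministic and keeps zero columns", {
  d <- data.frame(id = c("a", "b", "c"),
                  sequence = c("NTALTNTALT", "NTALTNTALT", "AC"),
                  stringsAsFactors = FALSE)
  spec <- scheme_spec("gapped_dipeptide", g = 1)
  expect_warning(m <- build_scheme_matrix(d, spec), "excluded")
  expect_equal(rownames(m), c("a", "b"))
  expect_equal(attr(m, "excluded"), "c")
  expect_equal(m["a", ], m["b", ])
  expect_equal(ncol(m), 400L)          # unobserved attributes retained
  expect_true(any(colSums(m) == 0))
})

test_that("the default scheme set instantiates with known dimensions", {
  specs <- default_scheme_set()
  expect_equal(names(specs),
               c("C", "X5", "X6", "X7", "D0", "D1", "D3", "D6",
                 "H3X5", "P3X5", "S2X5", "W7", "W11"))
  dims <- vapply(specs, function(sp) length(scheme_attributes(sp)),
                 integer(1))
  expect_equal(unname(dims),
               c(20L, 100L, 120L, 140L, 400L, 400L, 400L, 400L,
                 135L, 135L, 245L, 400L, 400L))
})
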