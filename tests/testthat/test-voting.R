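test_that("sequence-level jury calls respect the majority threshold", {
  seq13 <- "NTALTNTALT"
  all_afp <- constant_jury(rep("AFP", 13))
  expect_equal(classify_sequence(seq13, all_afp)$verdict, "AFP")
  # 6 of 13 positive with threshold 7 -> NONAFP (boundary)
  six <- constant_jury(rep(c("AFP", "NONAFP"), c(6, 7)))
  expect_equal(six$sequence_vote_threshold, 7L)
  res <- classify_sequence(seq13, six)
  expect_equal(res$verdict, "NONAFP")
  expect_equal(res$positive_votes, 6L)
  seven <- constant_jury(rep(c("AFP", "NONAFP"), c(7, 6)))
  expect_equal(classify_sequence(seq13, seven)$verdict, "AFP")
})

test_that("verdicts are invariant under jury member reordering", {
  seq13 <- "NTALTNTALT"
  verdicts <- rep(c("AFP", "NONAFP"), c(5, 8))
  jury <- constant_jury(verdicts)
  afpvote:::with_seed(5, {
    shuffled <- jury
    perm <- sample(length(jury$members))
    shuffled$members <- jury$members[perm]
  })
  a <- classify_sequence(seq13, jury)
  b <- classify_sequence(seq13, shuffled)
  expect_equal(a$verdict, b$verdict)
  expect_equal(a$positive_votes, b$positive_votes)
})

test_that("threshold 1 is OR and threshold m is AND", {
  seq13 <- "NTALTNTALT"
  one_afp <- rep(c("AFP", "NONAFP"), c(1, 4))
  expect_equal(classify_sequence(
    seq13, constant_jury(one_afp, threshold = 1))$verdict, "AFP")
  expect_equal(classify_sequence(
    seq13, constant_jury(one_afp, threshold = 5))$verdict, "NONAFP")
  all_afp <- rep("AFP", 5)
  expect_equal(classify_sequence(
    seq13, constant_jury(all_afp, threshold = 5))$verdict, "AFP")
})

test_that("abstention rescales the threshold; full abstention errors", {
  # jury of a short-capable and a long-only member
  m_short <- constant_member(scheme_spec("gapped_dipeptide", g = 0,
                                         label = "short"), "AFP")
  m_long <- constant_member(scheme_spec("gapped_dipeptide", g = 30,
                                        label = "long"), "NONAFP")
  jury <- jury_config(list(short = m_short, long = m_long),
                      sequence_vote_threshold = 2)
  res <- classify_sequence("NTALT", jury)   # long member must abstain
  expect_equal(res$abstentions, 1L)
  expect_equal(res$threshold, 1L)           # ceil(2 * 1/2)
  expect_equal(res$verdict, "AFP")
  jury_long <- jury_config(list(long = m_long))
  expect_error(classify_sequence("NTALT", jury_long), "abstain")
})

test_that("the NTALT worked example votes exactly as published", {
  fx <- worked_example_fixtures()$ntalt
  jury <- attribute_jury(fx$selected)
  prof <- residue_votes(fx$sequence, jury)
  expect_equal(prof$votes, unname(fx$expected_votes))
  expect_equal(prof$votes, c(0L, 1L, 0L, 1L, 2L))
})

test_that("votes are additive and conserve total footprint size", {
  fx <- worked_example_fixtures()$ntalt
  jury <- attribute_jury(fx$selected)
  # duplicating a member doubles its contribution
  dup <- attribute_jury(c(fx$selected, fx$selected[1]))
  single <- residue_votes(fx$sequence, attribute_jury(fx$selected[1]))
  both <- residue_votes(fx$sequence, jury)
  dup_prof <- residue_votes(fx$sequence, dup)
  expect_equal(dup_prof$votes, both$votes + single$votes)
  # conservation: total votes = sum of occurrence footprint sizes
  total <- 0L
  for (member in jury$members) {
    for (a in selected_attributes(member)) {
      occ <- match_attribute_positions(fx$sequence, member$scheme, a)
      total <- total + sum(lengths(occ))
    }
  }
  expect_equal(sum(both$votes), total)
})

test_that("no matching attribute yields an all-zero profile", {
  jury <- attribute_jury(list(list(
    spec = scheme_spec("gapped_dipeptide", g = 0), attribute = "WW")))
  expect_equal(residue_votes("NTALT", jury)$votes, rep(0L, 5))
})

test_that("reversal equivariance holds for symmetric dipeptide selections", {
  # select both orientations so the attribute set is reversal-symmetric
  jury <- attribute_jury(list(list(
    spec = scheme_spec("gapped_dipeptide", g = 0),
    attribute = c("LT", "TL"))))
  s <- "NTALTTLN"
  fwd <- residue_votes(s, jury)$votes
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  bwd <- residue_votes(rev_s, jury)$votes
  expect_equal(bwd, rev(fwd))
})

test_that("tier boundaries follow the red >= 6 / yellow 4-5 / gray <= 3 rule", {
  prof <- structure(list(id = "x", sequence = "AAAAAAAAA",
                         votes = c(0L, 3L, 4L, 5L, 6L, 8L, 2L, 7L, 1L),
                         tiers = NULL), class = "vote_profile")
  tiers <- tier_residues(prof)$tiers
  expect_equal(tiers, c("gray", "gray", "yellow", "yellow", "red", "red",
                        "gray", "red", "gray"))
})

test_that("vote profiles export as per-residue TSV", {
  fx <- worked_example_fixtures()$ntalt
  prof <- residue_votes(fx$sequence, attribute_jury(fx$selected))
  f <- withr::local_tempfile()
  write_vote_profile(prof, f)
  tab <- read.delim(f)
  expect_equal(tab$position, 1:5)
  expect_equal(tab$residue, c("N", "T", "A", "L", "T"))
  expect_equal(tab$votes, c(0L, 1L, 0L, 1L, 2L))
  expect_equal(tab$tier, rep("gray", 5))
})

test_that("the documented eelpout fragment fixture is internally consistent", {
  fx <- worked_example_fixtures()$msi_fragment
  expect_equal(nchar(fx$sequence), 10L)
  expect_equal(fx$positions, 9:18)
  expect_equal(names(fx$votes), strsplit(fx$sequence, "")[[1]])
  # T15 (8 votes) is the strongest candidate, a red-tier key residue
  expect_equal(unname(fx$votes[fx$positions == 15]), 8L)
  prof <- structure(list(id = "1msi", sequence = fx$sequence,
                         votes = unname(fx$votes), tiers = NULL),
                    class = "vote_profile")
  expect_equal(tier_residues(prof)$tiers[fx$positions == 15], "red")
  expect_equal(tier_residues(prof)$tiers[fx$positions == 16], "yellow")
})
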