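---
title: "Methods: composition-ensemble identification of antifreeze proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-ensemble identification of antifreeze proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpvote)
```

## The problem and the model

Antifreeze proteins (AFPs) are a textbook case of convergent evolution:
α-helical fish AFPs, globular type III AFPs, β-helical insect AFPs and
assorted plant and microbial proteins all bind ice, with no common fold
and often no detectable sequence homology. A homology search therefore
fails exactly where prediction is most needed (below roughly 20%
sequence identity, the "midnight zone"). The working hypothesis of this
package is that ice binding leaves *compositional* fingerprints —
short-range residue preferences such as TXT/TCT spacings and
alanine-rich stretches — that are shared across families even when
alignment-level similarity is gone.

The model is an ensemble of binary radial-basis-kernel support vector
classifiers. Each classifier sees one fixed-length *coding scheme*
vector per sequence; the jury's majority vote produces the sequence
call, and the matches of the selected feature attributes are mapped
back onto residues to nominate ice-binding positions. The assumptions
are, explicitly: (i) class-relevant signal survives in order-insensitive
composition statistics; (ii) signals from different schemes are
partially independent, so a majority vote suppresses single-scheme
failure; (iii) attributes that help classification mark subsequences
that are mechanistically relevant, so their residue footprints are
worth inspecting.

## Coding schemes and their normalization

For a canonical sequence of length $L$:

* **n-peptide** ($A_n$, or $C$ for $n=1$): attribute $w$ has value
  $\mathrm{count}(w) / (L - n + 1)$ over the $L-n+1$ contiguous
  $n$-grams; the vector sums to 1. Reduced alphabets re-encode the
  sequence first (group symbols `1..k` in declared order, so attribute
  names are stable).
* **partitioned** ($X_k$): the sequence is cut into $k$ contiguous
  segments whose lengths differ by at most one (remainder residues go to
  the leading segments — a deterministic, order-preserving choice); each
  segment carries its own n-peptide block, so the full vector sums to
  $k$.
* **g-gap dipeptide** ($D_g$): attribute $(a,b)$ counts index pairs
  $(i, i+g+1)$, i.e. *exactly* $g$ intervening residues, normalized by
  $L - g - 1$.
* **window** ($W_l$): for each residue type $c$ present, the
  20-dimensional composition of all residues pooled from windows of
  half-width $(l-1)/2$ around each occurrence of $c$. Windows are
  truncated at the sequence ends and the center residue is excluded from
  its own pool (both switchable: `window_ends`, `include_center`); the
  defaults reflect the reading that the scheme describes a center's
  *neighbors*. Blocks for absent center types are all-zero.

**Gap-labeling convention.** The literature this design follows contains
an internal inconsistency: the gapped scheme is defined by the formula
$a(x)_g b$ with $g$ intervening residues, yet its worked example labels
the pattern T(X$_2$)T — two intervening residues — as "$D_1$". This
package follows the formula: T(X$_2$)T is a $D_2$ attribute, written
`TxxT`. The worked-example fixture therefore pairs the `LT` selection in
$D_0$ with the `TxxT` selection in $D_2$.

**Alphabets.** `A` (identity), and the three-class hydrophobicity /
volume / polarizability / polarity descriptors are standard published
tables. The 4/7/8-group partitions `F`, `S`, `E` are *not* published in
a reconstructable form; the bundled table ships reasonable
physicochemical partitions (charged / polar-uncharged / aromatic /
aliphatic for `F`; conjoint-triad-style classes for `S`; a common
8-class partition for `E`) and every alphabet can be replaced from a
TSV via `builtin_alphabets(overrides = ...)`, so users holding the
original tables can reproduce them exactly. Tests only rely on
structural properties of `F`/`S`/`E` (partition, group counts), never on
their exact memberships.

## The kernel classifier

No SVM binding exists in the target environment, so the package carries
its own C-SVC: SMO with maximal-violating-pair working-set selection
(the classical dual decomposition), implemented in C++ with a
precomputed kernel matrix. It is deterministic — no random working-set
choices, ties resolved by lowest index — which is what makes the
package's bit-reproducibility guarantees possible. Feature values are
compositions already in $[0,1]$, so no further scaling is applied.

Hyperparameters follow the conventional exponential grid
($C \in 2^{\{-5,-3,\dots,15\}}$, $\gamma \in 2^{\{-15,\dots,3\}}$;
`default_grid()`), selected by internal cross-validated MCC with ties
broken toward smaller $C$ then smaller $\gamma$ (a mild preference for
smoother models). MCC rather than accuracy is the selection criterion
throughout because the intended regime is heavily imbalanced (tens of
AFPs against thousands of negatives), where accuracy saturates
uninformatively. For the same reason the positive class weight defaults
to $n_{neg}/n_{pos}$; an unweighted machine at 44:3762 imbalance
collapses to the majority class. MCC with a zero denominator factor is
defined as 0 (standard convention).

## Genetic-algorithm attribute selection

Per scheme, masks evolve under: fitness = internal cross-validated MCC
of a classifier on the masked matrix; ties broken by fewer false
positives (the stated engineering goal is credibility, i.e. few FPs),
then by fewer selected attributes (parsimony). Defaults: population 50,
100 generations, uniform crossover at rate 0.8, per-bit mutation at
$1/p$, tournament size 3, elitism 2. Generation 0 is random masks at
50% density *plus the all-ones mask*, so with elitism the final mask can
never score below no-selection on the internal criterion, and the
best-ever fitness trace is monotone non-decreasing. Fitness evaluations
are memoized by mask; internal folds are fixed once per run so all masks
are scored on identical splits. When no classifier configuration is
supplied, one is pre-selected by a coarse grid search on the all-ones
mask and used for every fitness evaluation — a deliberate trade: a
per-mask grid search multiplies cost ~16-fold for little measured
benefit at desk scale.

Two behaviors of wrapper selection are worth knowing about, and both are
visible in this package's own benchmarks:

* **Proxy redundancy.** When the planted gapped motif T(x)$_2$T coexists
  with a planted `LT` dipeptide, the positives' overall T-enrichment
  creates many correlated $D_2$ proxy attributes; internal MCC saturates
  with or without `TxxT` itself, and the parsimony tie-break has no
  reason to prefer it. The GA then recovers the planted attribute only
  reliably when its scheme sees a single-motif benchmark — which is how
  the recall test is instantiated. A corollary: a Jaccard-style demand
  that the selected set essentially *equal* the planted set is
  unattainable under these operators (uniform crossover preserves mask
  density; 100 generations of $1/p$ mutation cannot walk from ~200
  attributes to 2), so the tested property is recall of planted
  attributes plus ≥50% reduction, not set equality.
* **Selection bias (winner's curse).** The best-of-thousands mask by
  internal CV can generalize worse than the all-ones baseline for a
  scheme whose signal is weak and diffuse; averaging fitness over
  repeated CV partitions was measured and does not cure it. The held-out
  guard in the acceptance report is therefore evaluated on the *deployed*
  feature set — the union of the per-scheme selections in one classifier —
  which is the unit the pipeline actually uses; per-scheme comparisons
  are still logged.

## Jury voting and residue tiers

A sequence is AFP when positive verdicts reach the threshold, default
$\lceil m/2 \rceil$ (7 of 13). Members whose scheme cannot encode the
sequence (too short) *abstain*, and the threshold is rescaled
proportionally to the non-abstaining count rather than letting
abstentions count as negative votes; a sequence on which every member
abstains is an error, not a verdict. The default 13-scheme jury is the
concrete footnote set $\{C, X_5, X_6, X_7, D_0, D_1, D_3, D_6, H_3X_5,
P_3X_5, S_2X_5, W_7, W_{11}\}$.

Residue votes accumulate per occurrence (overlapping occurrences each
count — the NTALT example is only consistent with per-occurrence
accumulation), across all selected attributes of all members. Gapped
matches credit only the two anchors, never the intervening residues
(in NTALT, only the two T's of T(x)$_2$T are credited). Tier
boundaries: the published color legend (">6" red, "4 or 5" yellow,
"<3" gray) leaves exactly 3 and 6 unassigned; this package uses
**red ≥ 6, yellow 4–5, gray ≤ 3**, consistent with the one printed key
call (8 votes, red).

## Synthetic benchmark: what it does and does not establish

`generate_benchmark()` plants `LT` and `TxxT` motifs (defaults: 6
expected plantings per 100 residues each, positional jitter SD 2) on a
jittered regular grid, non-overlapping by construction, into uniform
i.i.d. background sequences of uniform length 60–120; negatives are pure
background; 200+200 sequences by default. The defaults are chosen once:
uniform background makes planted-signal analysis exact; rate 6 gives
roughly one motif per 17 residues, the order of magnitude of the
TXT-repeat spacing in real β-helical insect AFPs; 60–120 residues spans
typical small AFP lengths and satisfies every default scheme's length
precondition.

What it emulates: repeated short sequence regularities against a
neutral background, exactly the kind of signal the composition schemes
encode. What it does not emulate: real amino-acid background
frequencies (a Swiss-Prot-style background is available as an option),
compositional biases of folded proteins, homology structure between
sequences, length/label correlations, or any structural property. A
green pipeline test on this benchmark establishes that the machinery —
encoding, selection, voting, evaluation — recovers a known signal
end-to-end and deterministically; it does not certify real-world AFP
accuracy, which depends on curated sequence sets this package treats as
optional external input.

## Numerical and interface choices

* All randomness flows through explicit integer seeds (`with_seed`
  keeps the user's RNG state untouched); fold assignment, GA runs and
  benchmark generation are bit-reproducible, and the SMO solver is
  deterministic, so fixed seed ⇒ identical archives and verdicts.
* Composition normalization is tested to $10^{-12}$; the SMO stopping
  tolerance is $10^{-3}$ (the customary value for this solver family)
  with an iteration cap of $2 \times 10^5$.
* Global alignment uses BLOSUM62 with affine penalties open 10 / extend
  1 (the conventional defaults of the classical global aligner, which
  the source description does not print), via Biostrings; sequence
  identity = identities / alignment-length-including-gaps, switchable to
  the shorter-sequence denominator since SI has no universal definition.
  Best-hit ties resolve to library order.
* Nonstandard residues: `drop` is the default canonicalization for
  feature extraction (compositions tolerate deletion), `strict` for
  fixtures; `map_to_most_frequent` maps B→N, Z→Q, U→C and drops X.
* Fold assignment: declared homology subsets pin positives to folds;
  negatives are seeded-shuffled and dealt round-robin (size imbalance
  ≤ 1). Subset membership is always user-supplied input — the
  identity-clustering that produced the published subsets is not
  reconstructable, so it is never recomputed.
* Short sequences are never silently zero-filled into feature matrices:
  rows are excluded with a warning and the ids recorded, and the same
  condition makes the corresponding jury member abstain at prediction
  time.

## Known limitations

The `F`/`S`/`E` alphabet tables are documented approximations. The
per-scheme GA can overfit its internal criterion on weak schemes (see
above). Residue votes are evidence aggregation, not calibrated
probabilities; tier thresholds are display conventions. The window
scheme's two pooling ambiguities (center inclusion, end handling) are
resolved by defaults but left switchable. Nothing here parses
structures, computes solvent accessibility, or reproduces published
cross-validation numbers that require external database downloads; the
acceptance machinery substitutes deterministic, self-contained
properties at desk scale.
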