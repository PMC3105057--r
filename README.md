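# afpvote

Identification of antifreeze proteins (AFPs) and their candidate
ice-binding residues from primary sequence alone.

AFPs let cold-adapted fish, insects, plants and microbes survive below
0 °C by docking onto nascent ice crystals and arresting their growth.
They are hard to recognize computationally: the known families are
evolutionarily divergent, share neither fold nor obvious sequence motifs,
and most candidate sequences have no solved structure, so
structure-based ice-binding-surface detectors cannot be applied.
`afpvote` is for computational biologists screening genomes, proteomes or
metagenomes of cold-adapted organisms, and for protein scientists who
want residue-level hypotheses about where an ice-binding surface lies
before any structure exists.

## Method

The classifier is an ensemble ("jury") of radial-basis-kernel support
vector classifiers, one per *coding scheme*. A coding scheme maps a
sequence to a normalized composition vector:

- **n-peptide composition** `A_n` / `C`: frequencies of length-*n*
  contiguous subwords; with reduced physicochemical alphabets
  (hydrophobicity `H`, van der Waals volume `V`, polarizability `Z`,
  polarity `P`, and 4/7/8-group partitions `F`/`S`/`E`) the subwords are
  read over group symbols.
- **partitioned composition** `X_k`: the composition computed separately
  on *k* contiguous, near-equal segments and concatenated.
- **g-gap dipeptide composition** `D_g`: frequencies of ordered residue
  pairs `a (x)_g b` with exactly *g* intervening residues of any type.
- **window composition** `W_l`: for each residue type, the composition of
  the neighbors pooled from length-*l* windows centered on its
  occurrences.

The default jury is the 13-scheme set
`{C, X5, X6, X7, D0, D1, D3, D6, H3X5, P3X5, S2X5, W7, W11}`.

Per scheme, a **genetic algorithm** evolves a binary mask over the
scheme's feature attributes, maximizing internal cross-validated Matthews
correlation coefficient (ties: fewer false positives, then fewer
attributes), which typically discards well over half of the attributes.
A sequence is called AFP when at least a majority (7 of 13 by default) of
scheme classifiers vote AFP. Evaluation uses per-class accuracy
`Q_i = 100 c_i / n_i`, overall accuracy, precision and

```
MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

**Residue voting.** Every occurrence of a GA-selected attribute in a
query sequence gives one vote to each residue in its footprint (both
anchors of a gapped dipeptide, all *n* residues of an n-peptide, the
center/neighbor pair of a window attribute). Accumulated votes rank
residues as ice-binding candidates: ≥ 6 votes "red", 4–5 "yellow",
≤ 3 "gray".

The package also ships global-alignment sequence-identity (SI) tools
(best-hit SI against a library, SI-binned identification rates) for
interpreting predictions on divergent sequences, and a synthetic
planted-motif benchmark generator (`LT` and `T(x)2T` repeats, echoing the
TXT/alanine-rich repeats of real AFPs) so the whole pipeline is testable
offline.

## Worked example

```r
library(afpvote)

## 1. a labeled planted-motif benchmark (ice-binding-like repeats)
bench <- generate_benchmark(benchmark_spec(n_pos = 60, n_neg = 60,
                                           length_range = c(50, 90),
                                           seed = 7))
train <- bench$records[c(1:40, 61:100), ]   # 40 + 40 training sequences
test  <- bench$records[c(41:60, 101:120), ] # 20 + 20 held out

## 2. train a small jury with GA attribute selection per scheme
schemes <- default_scheme_set()[c("C", "D0", "D1", "W7")]
jury <- train_jury(train, schemes = schemes, grid = coarse_grid(),
                   ga = ga_config(population_size = 24, generations = 20,
                                  seed = 1),
                   internal_folds = 3, seed = 1)
print(jury)
#> jury of 4 scheme classifiers (threshold 2): C, D0, D1, W7

## 3. sequence-level verdicts on the held-out set
verdicts <- classify_batch(test, jury)
print(evaluation_report(tally_confusion(test$label, verdicts$verdict)))
#>                 metric value
#> 1     AFP accuracy (%)  95.0
#> 2    AFP precision (%)  95.0
#> 3 Overall accuracy (%)  95.0
#> 4                  MCC   0.9
#> 5                   TP  19.0
#> 6                   TN  19.0
#> 7                   FP   1.0
#> 8                   FN   1.0

## 4. residue-level votes: the NTALT worked example
fx <- worked_example_fixtures()$ntalt
prof <- residue_votes(fx$sequence, attribute_jury(fx$selected))
print(tier_residues(prof))
#> vote profile for 'query' (5 residues, 4 total votes)
#>   NTALT
#>   01012
```

Reading the output: of the 40 held-out sequences, 19 of 20 true AFPs and
19 of 20 backgrounds are called correctly (MCC 0.90). In the `NTALT`
peptide, with the dipeptide `LT` selected in the contiguous scheme and
the 2-gap pair `T(x)2T` selected in the gapped scheme, the `L` and the
first `T` each collect one vote and the final `T` — an anchor of both
selected attributes — collects two, exactly the vote bookkeeping used for
flagging ice-binding candidates.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "afpvote", package = "afpvote"))')
Rscript $CLI simulate --n-pos 60 --n-neg 60 --seed 7 --out bench/
Rscript $CLI train    --fasta bench/benchmark.fasta \
                      --labels bench/benchmark.labels.tsv \
                      --schemes C,D0,D1,W7 --fast-grid --seed 1 \
                      --out jury.rds
Rscript $CLI predict  --fasta bench/benchmark.fasta --archive jury.rds \
                      --out verdicts.tsv
Rscript $CLI votes    --fasta bench/benchmark.fasta --archive jury.rds \
                      --out votes.tsv
Rscript $CLI evaluate --verdicts verdicts.tsv \
                      --labels bench/benchmark.labels.tsv
```

The jury archive is an RDS file `{format, version, package_version, seed,
jury, fingerprint}`; `predict`/`votes` refuse archives whose fingerprint
or package version do not match. All outputs start with a `#` header
recording version, seed and configuration fingerprint.

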