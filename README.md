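# nsalign

Non-sequential pairwise protein structure alignment in R: global
optimization by conformational space annealing (CSA) and fast local
refinement by a best-first greedy move list, under four alignment scoring
functions (DALI, SP, SO with a logistic surrogate, TM-score).

Structurally similar proteins do not always share segment order:
circularly permuted domains, swapped segments, and occasionally segments
matched in opposite chain direction are invisible to sequential aligners,
which require aligned pairs (i, j), (k, l) with i < k to satisfy j < l.
`nsalign` represents an alignment as an arbitrary one-to-one set of
Cα index pairs and optimizes a scoring function over that space, under
two constraints with direct biological motivation: a **minimum alignment
block size** (a block is a maximal run of pairs consecutive in both
chains; short blocks make fragmented, hard-to-interpret alignments — the
default minimum is 4) and a **reverse-alignment permission** (whether
blocks matching one chain N→C against the other C→N are allowed).

The package is aimed at structural bioinformaticians who need
high-quality non-sequential alignments of specific pairs (not database
scans), want to compare what different scoring functions consider
"optimal", or need to clean up an external tool's alignment under block
constraints.

## The optimizers

* **`refine_alignment()`** — local search. All score-improving moves
  (single-pair additions/deletions that respect the block constraints,
  whole-block deletions, and minimum-size block seeds) are held in a
  list with their score deltas; the best move is re-evaluated against
  the current alignment, accepted only if it still improves, and the
  list is repaired around the touched residues. A full superposition
  refit backs every candidate delta for the superposition-based scores.
  Deterministic, typically sub-second to seconds.
* **`csa_search()`** — global search. A bank of locally refined,
  mutually diverse alignments is evolved by crossover (block transplants
  between members) and perturbation (block deletion / shift / truncation
  / relocation), with every trial refined and inserted under a shrinking
  diversity cutoff D_cut that plays the role of temperature. The best
  bank score never decreases, and runs are bit-reproducible given a
  seed.

Scores: DALI's distance-matrix elastic score (d0 = 20 Å, both published
envelope variants, no superposition — hence its mirror-image blindness,
which the package surfaces via a `mirror_rmsd` diagnostic in every
summary); SP (d0 = 4 Å, α = 0.3, core/neighbour normalization);
SO, the fraction of aligned pairs within 3.5 Å (optimized through its
logistic surrogate SO_L, k = 10 Å⁻¹, and re-evaluated exactly for
reporting); TM-score (d0 = 1.24·(L_N − 15)^⅓ − 1.8 Å, normalized by
either chain or their average).

## Worked example

Align a 60-residue chain against a noisy circularly permuted copy of
itself (halves swapped, 0.5 Å coordinate noise) — ground truth known by
construction:

```r
library(nsalign)

chain_a <- make_synthetic_chain("walk", 60, seed = 42)
pp <- make_permuted_pair(chain_a,
                         data.frame(start = c(31, 1), end = c(60, 30),
                                    reverse = FALSE),
                         noise_sigma = 0.5, seed = 43)
chain_b <- pp$chain

bank <- csa_search(chain_a, chain_b, score_spec("TM"),
                   constraints(min_block_size = 4, allow_reverse = TRUE),
                   csa_config(bank_size = 10, n_collect = 60, rng_seed = 1))
best <- bank_best(bank)
print(bank)
#> <csa_bank> 10 members, best score 0.908045, D_cut 0.485, 60 trials generated
summarize_alignment(best$alignment, chain_a, chain_b)
#> <alignment_summary> n = 60, rmsd = 0.854 A (mirror 6.262 A)
#>   blocks: 30+30 (0 reverse)
#>   scores: DALI=578.3, SP=0.8623, SO=1, SO_L=1, TM=0.908
precision_recall(best$alignment, pp$truth)
#> precision    recall
#>         1         1
```

The search recovers the permutation exactly: all 60 residues aligned in
two forward blocks of 30 (the swapped halves), 0.85 Å RMSD (the injected
noise), TM-score 0.91, and perfect precision/recall against the
generator's ground truth. `mirror_rmsd` (6.3 Å) far above `rmsd` confirms
the solution is not a mirror-image artifact.

A command-line interface wraps the same functionality
(`inst/exec/nsalign`, subcommands `align`, `refine`, `score`, `eval`,
`synth`); every randomized subcommand takes `--seed` and echoes its full
configuration into a JSON run summary.

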