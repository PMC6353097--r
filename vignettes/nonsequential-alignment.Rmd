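---
title: "Non-sequential structure alignment by annealing and greedy refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-sequential structure alignment by annealing and greedy refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsalign)
```

## The problem

Two protein structures can share local geometry even when the shared
segments appear in a different order along the two chains — circularly
permuted domains, swapped segments, and occasionally segments matched in
opposite chain direction.  Sequential aligners, which require aligned
residue pairs \((i, j)\) and \((k, l)\) with \(i < k\) to satisfy
\(j < l\), cannot express such correspondences.  `nsalign` treats a
pairwise alignment as an arbitrary one-to-one set of Cα index pairs and
searches for the set that maximizes a chosen scoring function, subject to
two structural constraints:

* **minimum block size** — an alignment block is a maximal run of pairs
  consecutive in both chains (forward blocks step \((i{+}1, j{+}1)\),
  reverse blocks \((i{+}1, j{-}1)\)); blocks shorter than the minimum are
  forbidden.  Small blocks produce fragmented alignments whose biological
  meaning is doubtful; a minimum of 4 (the package default) suppresses
  them.
* **reverse permission** — whether reverse blocks (of size ≥ 2) are
  allowed at all.  A single pair has no direction and never counts as
  reverse.

## Scoring functions

Four scores are implemented behind one interface (`score_spec()`,
`align_score()`).  For an alignment of \(n\) pairs between chains of
lengths \(L_A\), \(L_B\):

* **DALI** sums, over ordered pairs of aligned pairs, the elastic term
  \(\left(0.2 - \frac{|d^A_{ij} - d^B_{ij}|}{(d^A_{ij}+d^B_{ij})/2}\right) w_{ij}\)
  with 0.2 for the diagonal, where \(d^A\), \(d^B\) are intra-chain Cα
  distances and \(d_0 = 20\) Å scales the envelope \(w\).  Two envelope
  variants are provided: `"deviation"`,
  \(w = \exp(-|d^A - d^B|^2/d_0^2)\) (the default), and
  `"mean_distance"`, \(w = \exp(-\bar d^2/d_0^2)\), the form used in
  classic distance-matrix alignment.  Published descriptions of the
  elastic score differ on this point, so both are available and every
  report echoes the variant used.  DALI uses no superposition at all,
  which makes it invariant under mirror reflection of either chain —
  a genuine pathology that the package surfaces through an RMSD
  diagnostic rather than "fixing" (see below).
* **SP** superposes the aligned subsets (least-RMSD Kabsch fit), sums
  \(\frac{1}{1+(d/d_0)^2} - 0.2\) over pairs with deviation
  \(d < 2d_0\) (strict, as the definition is printed), with
  \(d_0 = 4\) Å, and normalizes by \(3L^{1-\alpha}\), \(\alpha = 0.3\).
  \(L\) counts the core pairs (\(d \le 2d_0\), non-strict) plus the
  average over the two chains of the number of non-core residues within
  \(3d_0\) of a core Cα, each chain measured in its own coordinates.
  The definition does not say which chain the neighbours are counted in;
  averaging the two per-chain counts is the symmetric, deterministic
  reading adopted here.
* **SO** is the fraction of aligned pairs with deviation \(\le 3.5\) Å,
  normalized by \(\min(L_A, L_B)\).  Its gradient is zero almost
  everywhere, so the optimizers use the logistic surrogate **SO_L**
  (steepness \(k = 10\,\text{Å}^{-1}\), midpoint at \(d_0\)) and final
  reports re-evaluate the original SO.
* **TM** superposes, sums \(\frac{1}{1+(d/d_{0,\mathrm{TM}})^2}\) with
  \(d_{0,\mathrm{TM}} = 1.24\sqrt[3]{L_N - 15} - 1.8\) Å, and normalizes
  by \(L_N\).  \(L_N\) is \(L_A\), \(L_B\), or both (the `"average"`
  mode, the default optimization objective, is the mean of the two
  normalized values, each with its own \(d_{0,\mathrm{TM}}\)).  The
  formula turns non-positive for \(L_N \lesssim 21\); the package clamps
  \(d_{0,\mathrm{TM}}\) below at 0.5 Å so short synthetic chains remain
  scoreable.

Superposition for SP/SO/SO_L/TM is always the least-RMSD proper rotation
over the currently aligned pairs (refit in full for every candidate move;
no incremental approximation), not a score-maximizing rotation search.
Reflections are excluded by the usual determinant sign correction, so a
chiral structure never "fits" its mirror image.  Degenerate subsets (one
or two points, collinear sets) get a deterministic optimal transform.

## The mirror diagnostic

Because DALI sees only internal distances, a DALI-optimal alignment can
superpose one chain onto the *mirror image* of the other; the aligned
RMSD is then large while the same alignment fits the mirrored partner
almost perfectly.  Every summary therefore reports both `rmsd` and
`mirror_rmsd` (the fit after reflecting chain B); `mirror_rmsd ≪ rmsd`
flags a mirror solution.  This is deliberately a diagnostic, not a
constraint: the invariance is a property of the score itself.

## Greedy refinement

`refine_alignment()` implements a best-first move-list search.  The move
set (`admissible_moves()`) contains single-pair additions and deletions
that keep every block at or above the minimum size, whole-block
deletions, and — when the minimum block size exceeds one — *block seeds*:
complete runs of exactly the minimum size at any placement over unaligned
residues, forward or (when permitted) reverse.  Without block seeds no
single-pair move can ever start a new block under a minimum-size
constraint, so the refiner could never grow new aligned regions; they are
ranked by score improvement like every other move.

The loop builds the list of all improving moves with their score deltas;
takes the best, re-evaluates its delta against the current alignment
(deltas go stale because every accepted move changes the superposition),
accepts it only if it still improves, removes list entries sharing a
residue with the accepted move, and re-enumerates improving moves among
those touching the accepted residues.  When the list empties, the
implementation rebuilds the full list and continues until a rebuild finds
no improving move — the touched-residue bookkeeping alone can leave a
distant move undiscovered, and the rebuild guarantees the result is a
genuine single-move local optimum (which the CSA bank relies on).
Improvements must exceed `1e-9` absolutely; refits oscillate at machine
precision below that.  Equal-delta ties break lexicographically
(delete_pair, add_pair, delete_block, add_block; then the indices), so
refinement is fully deterministic.

Inputs are first projected onto the constraint set
(`enforce_constraints()`): forbidden reverse blocks are removed — if
nothing survives, one pair per original block is kept at the block center
(C-terminal of the two central pairs for even sizes); undersized blocks
are removed — if nothing survives, the largest blocks are extended to the
minimum size, symmetrically around the block along its own orientation,
preferring the C-terminal side on odd remainders and skipping positions
that hit chain ends or one-to-one conflicts.  The projection is
idempotent and errors only when no nonempty satisfying alignment can be
produced (for example a single pair on length-1 chains).

## Conformational space annealing

`csa_search()` maintains a *bank* of locally refined, mutually diverse
alignments.  Diversity is measured by
\(1 - |a \cap b| / \max(|a|, |b|)\) on pair sets — any metric that is
zero exactly on identical pair sets and symmetric works for annealing
control; this normalized overlap is the simplest such choice.  The
cutoff \(D_\mathrm{cut}\) starts at half the average pairwise bank
distance and shrinks geometrically (ratio 0.97 per round, floor 0.05),
playing the role of temperature: early trials may replace only their
*nearest* bank member (keeping the bank spread out), late trials compete
directly with the worst member.

Seeding superposes fragment windows (length 6, shortened to half the
chain length for very short chains so several windows exist) of chain A
onto windows of chain B, forward and reverse, harvests all residue pairs
within \(2 d_{0,\mathrm{SO}}\) of each other greedily into one-to-one
alignments, projects them onto the constraint set, and keeps the most
mutually distant high-scoring candidates; those are then locally refined
to form the bank.  Scoring every harvested candidate is cheap, so the
expensive refinement is spent only on the selected bank — refining every
fragment candidate would dominate runtime without changing the bank
contract (members locally refined, diverse, high scoring).

Each round picks the least recently used members as seeds (deterministic
coverage of the bank) and generates trials per seed: an optional
crossover with a random other member (transplant a random nonempty subset
of the partner's blocks, delete conflicting pairs, project), followed by
a random perturbation depth of 1–3.  The elementary perturbations are:
delete a random block; rigidly shift a block by one position in either
index; truncate a block end; or relocate a block to a random
non-conflicting placement with random orientation.  Relocation and
composition are this package's choices: block placement is exactly the
degree of freedom a non-sequential alignment has, and with single
\(\pm 1\) shifts alone the annealing could not leave basins that differ
by a coordinated rearrangement of two or more blocks (observed directly
on tiny instances where exhaustive enumeration gives the true optimum).
Every trial is refined and inserted by the bank-update rule above; the
run stops after `n_collect` refined trials and returns the bank sorted by
score.

One RNG stream, seeded once from `rng_seed`, drives every stochastic
choice, so runs are bit-reproducible; the best bank score never
decreases; and every returned member satisfies the constraints and is a
fixed point of the refiner.

## Synthetic data

Because curated benchmark structures cannot be bundled, the package
generates its own test material.  `make_synthetic_chain()` builds ideal
α-helical traces (rise 1.5 Å, 100° turn, radius 2.3 Å — consecutive Cα
≈ 3.8 Å) and self-avoiding random walks (3.8 Å steps, non-bonded
separation ≥ 3.5 Å), deterministic given a seed.
`make_permuted_pair()` derives a second chain by concatenating chosen
segments in a new order, optionally reversed, with i.i.d. Gaussian
coordinate noise, and returns the exact ground-truth alignment — the
circular permutations, segment swaps and reversed segments the aligner
exists to recover.  What these fixtures do *not* emulate is real protein
geometry: secondary-structure packing, domain architecture, and the
partial, noisy similarity of true homologs.  Tests passing on them show
the optimizers and scores behave as specified, not that alignments of
real homologs will match curated references.

## Problem sizes used by the test suite

The suite verifies global optimality on one hundred 6-residue
random-walk pairs (the full constraint-satisfying alignment space of
such a pair — about \(10^4\) alignments — is enumerated exhaustively in
C++ as the oracle; the annealing uses a generous 1600-trial budget per
instance, since demonstrating convergence is the point of that test),
refinement properties on one hundred 12-residue starts, superposition
against a quaternion-grid brute-force minimizer on fifty 6-point sets,
and ground-truth recovery on noise-free 60–72-residue permuted and
reversed pairs with the default constraints (minimum block size 4,
reverse allowed).  `scripts/acceptance.R` re-runs the recovery,
refinement and mirror-diagnostic computations from scratch for an
arbitrary seed.

## Limitations

* A single rigid-body fit per alignment: no flexible or hinge
  superposition.
* Pairwise only; the global search costs minutes on ~100-residue pairs
  and is not meant for database scanning — refinement of an external
  alignment is the fast path.
* DALI scoring is quadratic in the match length per move evaluation,
  making it the slowest objective to refine.
* The annealing is stochastic: on adversarial landscapes (unrelated
  chains) small trial budgets can return near-optimal rather than
  optimal alignments; budget and seeds are explicit so such runs are
  reproducible and extendable.
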