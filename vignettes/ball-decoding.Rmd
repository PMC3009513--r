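---
title: "Robust HMM decoding with balls of labellings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust HMM decoding with balls of labellings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmball)
```

## The decoding problem

A labelled hidden Markov model assigns each state a feature label, so every
state path `x0, x1, ..., xn` for a sequence `y1, ..., yn` induces a
*labelling*: the per-position feature annotation that is usually the real
object of interest (for a membrane protein, which residues are cytoplasmic,
membrane-embedded, or extracellular). Classical decoders are ill-suited to
the question practitioners actually ask. Viterbi maximizes the probability
of one path, which can be vanishingly small and locally sloppy; posterior
decoding maximizes per-position correctness but can return annotations no
path supports. What one usually wants is an annotation whose *segment
boundaries* are approximately right.

`hmmball` decodes with that goal made explicit. For a distance `d` between
labellings and a radius `r`, the ball `B_d(λ, r)` is the set of labellings
within distance `r` of a centre `λ`, and the decoding target is the centre
maximizing `Pr[B_d(λ, r) | y]` — the probability that the true labelling is
within `r` of the prediction.

## Distances

Labellings are compared at emission positions `1..n` only; the silent start
state's label is a model artifact and takes no part in footprints, borders,
or any distance. (Throughout the package a labelling is therefore a plain
length-`n` character vector.)

* **Border shift**: two labellings with the same *footprint* (run-length
  compression) are compared by the maximum absolute displacement of
  corresponding borders; different footprints are at infinite distance.
* **Border shift sum**: the L1 counterpart — the summed displacement over
  all borders. The sum dominates the max, so at equal radius the sum-ball
  is nested inside the shift-ball; both facts are asserted in the tests.
* **Generalized Hamming**: a position-wise sum of penalties `H[a_i, b_i]`
  from a non-negative integer label-pair matrix; the 0/1 matrix gives plain
  Hamming distance.

## Ball probabilities by constrained forward passes

All ball probabilities are exact sums over member labellings, computed by
restricted or augmented forward passes rather than enumeration:

* a **labelling** pins the allowed state set per position;
* a **footprint** `f1..fk` is handled on a layered model with one group of
  states per footprint entry and transitions only within a group or to the
  next one, entered at group 1 and left from group `k`;
* a **border-shift ball** adds per-position windows: group `i` may occupy
  positions `b[i-1] - r` to `b[i] + r - 1` (clamped to `1..n`, with
  `b[0] = 1`, `b[k] = n + 1`). Because groups cannot be skipped, the window
  constraint is exactly equivalent to every border moving by at most `r`;
  `r = 0` reproduces the labelling probability and `r >= n` the footprint
  probability, identities the tests check at `1e-12` relative tolerance;
* a **shift-sum ball** carries an extra budget coordinate `0..r`; placing
  border `i` at position `p` costs `|p - b[i]|` and over-budget transitions
  are dropped;
* a **Hamming ball** runs on a product automaton of states `(state, d)`
  where entering a state labelled `z` at a position the centre labels `z'`
  costs `H[z', z]`.

Every pass uses per-column rescaling with accumulated log normalizers, the
standard defence against underflow that — unlike pure log-space dynamic
programming — keeps the inner loop as plain matrix-vector products, which
matters because ball probabilities are sums, not maxima. A constrained
event of probability zero simply yields 0 (`-Inf` on the log scale), never
an error.

All three ball algorithms, the labelling probability and the footprint
probability are validated against exhaustive path enumeration on a battery
of 50 seeded random models small enough to enumerate (`m <= 4`,
binary alphabet, `n <= 7`), at `1e-9` relative tolerance; the brute-force
reference lives in the package (`brute_ball_probability()` and friends) so
it can also be called from the command line for debugging.

## Local search over borders

Finding the best ball centre is intractable in general (it contains
maximum-probability labelling as the radius-0 case), so `local_search()`
does steepest-ascent over border positions: each iteration scores the ball
of every labelling that matches the current centre in all borders but one,
shifted one position left or right, and moves to the best strictly
improving neighbour.

Neighbour scoring is incremental. Shifting border `t` by one changes the
active windows only at positions `b[t] - r - 1 .. b[t] + r`, so the cached
forward columns are reused up to the edge of that range, `O(r)` columns are
recomputed, and the cached backward column closes the product. After an
accepted move the caches are rebuilt from scratch, which doubles as a
running cross-check of the incremental arithmetic; the test suite replays
every neighbour evaluation of every iteration against a from-scratch pass.

Numerical conventions, fixed for determinism:

* a move is skipped if it would empty a feature or push a border outside
  `[2, n]`, so the footprint is preserved by construction;
* ties go to the smallest border index, leftward before rightward;
* a move must improve the log ball probability by more than `1e-12`
  (relative on probabilities), so accepted probabilities strictly increase
  and termination is guaranteed; the default iteration cap is 80.

`decode_with_restarts()` wraps the search with multiple starting centres
drawn by forward-filtering backward-sampling from `Pr[x | y]` — sampled
footprints concentrate on high-probability structures, so a sample tends to
land inside or near the best ball — and returns the best result. Everything
is reproducible from one integer seed.

## Exact decoding for regular path balls

For balls of *state paths* (each state its own label) whose centres are
`(2r+1)`-regular — every maximal state run lasts at least `2r + 1`
positions — the optimal centre is computable exactly in `O(n m^2 r)` time
by dynamic programming (`regular_ball_dp()`). The table entry `F[j, s]` is
the best *weakly* regular ball up to position `j` ending in state `s`
(final run only `>= r + 1`, which still pins every member path to `s` at
`j`); it arises either by extending the final run or by placing a border at
`j - r`, in which case members may switch from the previous state `s'`
anywhere in a `2r + 1`-wide window whose summed probability is the window
quantity `Q(s, s', j)`. Combining a border with `F[j - 2r - 1, s']` makes
the completed `s'` run at least `2r + 1` long, so regularity is preserved
without tracking run lengths. Values at `j = n - r` are extended in-state
to position `n`, restoring strong regularity of the final run.

Two numerical/structural choices:

* `Q` windows are evaluated directly in log space (log-sum-exp over the
  `2r + 1` switch points). A sliding-window update reusing position `j - 1`
  would be asymptotically cheaper by a factor of `r` but requires
  subtracting probabilities, which is unstable in log space; at the problem
  sizes this package targets the direct evaluation is never the bottleneck.
* candidates are scanned in predecessor-state order with strict
  improvement, so ties break to the lowest state index and at `r = 0` the
  recursion, path and probability coincide bit-for-bit with Viterbi — an
  identity the tests assert, alongside agreement with exhaustive
  maximization over all regular paths at `r = 1`.

The reported probability is also recomputed independently as the
border-shift ball probability of the returned centre under identity labels
(`path_ball_probability()`), a self-consistency check run in the tests.

## The toy topology model and what it shows

`toy_topology_hmm()` emulates the structure of transmembrane-topology
HMMs: cytoplasmic (`i`) and non-cytoplasmic (`o`) loops alternate with
membrane (`M`) helices; helices last at least 15 positions (enforced by two
directed 15-state chains, one per crossing direction, so the loop sides
must alternate) with mean length 21 (a geometric tail on the final chain
state). Loops self-loop with mean run length 15. Emissions use a reduced
4-letter residue alphabet — hydrophobic, polar, positively charged, other —
with hydrophobic-rich helices and a positively-charged bias in cytoplasmic
loops, the signal that makes topology recoverable. Defaults are fixed once
in the generator; `simulate_dataset()` draws sequences and true labellings
from the generative process under a seed.

The end-to-end check simulates 100 sequences of length 80–160 (a
desk-scale stand-in for curated membrane-protein sets, whose proteins are
longer and more numerous) and compares multi-start ball decoding
(10 sampled starts, `r = 5`, chosen to target the τ = 5 measure) against
Viterbi under two measures: *overlap* (footprint correct and every
membrane segment overlapping its true counterpart by ≥ 5 positions) and
*τ = 5* (border shift distance to the truth at most 5, a much more
stringent demand). The suite asserts the directional result — ball
decoding's τ = 5 accuracy is at least Viterbi's — and
`scripts/acceptance.R` recomputes both accuracies from scratch.

What passing these tests does *not* show: the toy model has a handful of
states and a 4-letter alphabet, its emission contrasts are stronger than
real residue statistics, and there are no signal peptides, re-entrant
loops, or training artifacts. Results on it validate the algorithms, not
biological performance; on real models the relative advantage of ball
decoding will depend on how much probability mass sits near the true
labelling.

## Degenerate inputs and edge conventions

* Infeasible centres (a footprint label with no states, or no compatible
  path) give probability 0 from every ball routine, not an error.
* `regular_ball_dp()` requires `n >= 2r + 1`; shorter sequences admit no
  regular path and are rejected explicitly. A single-run (border-free)
  centre is always considered alongside bordered ones.
* Sampling from `Pr[x | y]` rejects sequences with `Pr[y] = 0` explicitly.
* Radii are non-negative integers; labellings must match their sequence in
  length, checked wherever files pair them.

## Problem sizes used in the checks

Enumeration-backed checks use 50 seeded models with `m <= 4`, binary
alphabet and `n <= 7` (at most `4^7` paths each); DP cross-checks use 20
models with `m <= 3`, `n <= 9`; sampling calibration uses 50,000 draws on a
two-state model; the end-to-end comparison uses 100 toy sequences. These
sizes make every reference computation exact or statistically
well-resolved while keeping the whole suite comfortably fast on one CPU.
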