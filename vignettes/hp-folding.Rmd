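---
title: "Lattice HP folding by local search: model, method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice HP folding by local search: model, method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`hpfold` predicts low-energy backbone conformations for a simplified
protein model.  A protein is a chain of monomers, each classed hydrophobic
(H) or polar (P); the chain is embedded in the face-centered cubic (FCC)
lattice as a *self-avoiding walk*: consecutive monomers occupy lattice
neighbours (the chain constraint) and no two monomers share a site (the
self-avoidance constraint).  FCC is the standard choice because each site
has twelve neighbours — the densest sphere packing — so the discretisation
artefacts that plague the simple cubic lattice (parity locking, unrealistic
bond angles) are much weaker.

The energy is the classic HP contact potential: every pair of
non-consecutive monomers that are both H and are lattice neighbours
contributes −1,

$$E(c) \;=\; \sum_{i+1<j} c_{ij}\, e_{ij}, \qquad
e_{ij} = \begin{cases} -1 & s_i = s_j = \mathrm{H} \\ 0 & \text{else,}\end{cases}$$

so minimising $E$ maximises the number of H–H contacts — the hydrophobic
core.  `hp_energy()` implements this; `optimal_saw_energy()` computes the
exact optimum for short chains by exhaustive symmetry-reduced enumeration
and serves as the test oracle.

## The search fitness

The search is not guided by $E$ directly (it is a coarse step function)
but by a smoother surrogate: the summed squared deviation of all
non-consecutive H–H pair distances from the contact distance,

$$f(c) \;=\; \sum_{\substack{i+1<j\\ s_i=s_j=\mathrm{H}}} \big(d(i,j) - 2\big)^2,$$

where $d(i,j)$ is the **squared** Euclidean distance between monomers $i$
and $j$.  On FCC every realisable pairwise squared distance is even and at
least 2, with $d = 2$ exactly at contact, so $f \ge 0$ and $f = 0$
characterises a perfectly packed core.  Energy still scores the result;
the fitness only steers (`hp_fitness()`, and the incremental
`delta_fitness()` used by the move generator).

One deliberate reading is buried here.  The source description of the
deviation term can be read literally as $dv = d^2 - 2$ with $d$ already
the squared distance; under that reading a contact pair contributes
$(2^2-2)^2 = 4$ and the packed core is **not** the zero of the function,
which contradicts the stated intent of minimising the summed H–H
distances.  We therefore adopt $dv = d - 2$ (zero at contact) as the
default and keep the literal variant behind `literal_fitness = TRUE` for
comparison.  A stray multiplicative factor in the printed formula (a
leading sequence-length symbol) is treated as typographic noise: constant
factors cannot change the argmin and no surrounding text motivates it.

## The search framework

`run_fold()` is a tabu-style stochastic local search over single-monomer
moves: monomer $i$ may relocate to any free site in contact with both its
chain neighbours (chain ends use their single neighbour; configurable
off).  Each iteration:

1. a monomer type is scheduled — `period_h` H-iterations then `period_p`
   P-iterations (defaults 9 and 1).  H moves are ranked by incremental
   fitness delta, best first; P moves cannot change the fitness, so one is
   drawn uniformly at random;
2. candidates are filtered through the *local-minima memory* (below);
   the first survivor is performed.  The moved monomer becomes tabu for a
   tenure drawn once per tabu epoch from $[4, n/4]$ (clamped to 4 for very
   short chains, where the printed interval degenerates);
3. if the conformation is a 1-move local minimum — its fitness strictly
   below that of every H move, tabu ignored, since local optimality is a
   property of the landscape rather than of the short-term memory — its
   canonical encoding is offered to the memory, which keeps it with
   probability `memory_rate` (default 0.05);
4. after `max_stable` (default 100) iterations without a fitness
   improvement, the tabu list is re-initialised and the search *retreats*
   (below).  An iteration whose candidate list empties — all moves tabu or
   all matched by the memory — immediately forces the stagnation branch.

Improvement is tracked against the best fitness seen since the last
retreat; a retreat naturally lands on a worse-fitness conformation and
must not be punished for it.  The best conformation overall is tracked by
HP energy throughout.

## Revisitation control: memory and canonical encodings

The memory stores a 5% sample of the local minima encountered, as packed
canonical encodings.  A candidate whose encoding lies within `proximity`
(default 3) Hamming **symbols** of a stored entry is discarded.  Symbol-
rather than bit-level distance is deliberate: the distance notion predates
the 4-bit packing, which is purely a storage device, and bit-level
counting would weight symbol substitutions unevenly (adjacent codes differ
in 1 bit, others in up to 4).

The encoding itself (`noniso_encode()`) is the package's canonical
conformation key.  Starting from the *absolute* encoding — the sequence of
basis-vector indices of consecutive displacements, already translation
invariant — each previously unseen direction is relabelled with the next
unused integer in one left-to-right pass.  Any lattice rotation or
reflection permutes the twelve absolute directions but cannot change
*which positions carry the first occurrences*, so all 48 point-group
images of a conformation collapse to one code sequence, in $O(n)$ time and
4 bits per symbol.  The tests sweep all 48 operations times random
translations over hundreds of random conformations to pin this down.

Two honest caveats, both consequences of the construction rather than
implementation choices:

* the map is **not injective**: distinct, non-isometric conformations can
  share a code (already `[0, 1]` covers both an orthogonal and a
  back-folded second step).  Equal codes therefore certify similarity, not
  isometry.  `canonical_coords()` decodes code $k$ to basis vector
  $v_{k+1}$, which yields a well-defined representative chain but not
  necessarily a self-avoiding one;
* at very short chain lengths the *realised* code space collapses (it is
  bounded by the number of first-occurrence patterns, not by $12^{n-1}$),
  which matters for the memory radius — see *Limitations*.

## Elite conformations: store and explore

A greedy single-candidate search generates many good moves per iteration
and explores exactly one.  The runner-up candidates — all moves whose
fitness delta equals the smallest delta strictly worse than the selected
move's, capped at `max_runner_up = 3` per iteration — are archived in a
bounded priority store (`elite_set()`, capacity 5000, worst evicted),
ordered by fitness with ties to the *more recent* iteration; each is
admitted only if it does not match the minima memory.  At stagnation the
search re-checks the best live element against the (possibly grown)
memory, popping matched ones, and retreats to the first survivor; a fixed
fraction `elite_release` (default 0.05, at least one element, including
the one returned) of the top of the store is released at the same time so
that consecutive stagnations do not retreat into the same neighbourhood.
If the store exhausts, the search falls back to restarting from the
best-so-far conformation, the base framework's behaviour.

Several knobs here are genuinely open in the source material and fixed as
package decisions: the runner-up definition and its cap, the release
fraction and the capacity bound, the tie-break direction (fresher
iteration preferred, as the fresher region is less explored), clearing —
rather than merely re-tenuring — the tabu list at stagnation, and the
best-so-far fallback.  Each is a parameter, so none is load-bearing for
the interfaces.

## Initialization and reproducibility

Initial conformations are grown as seeded random self-avoiding walks,
choosing uniformly among free neighbours with backtracking at dead ends;
on FCC dead ends are rare enough that growth practically always succeeds
on the first attempt.  Every stochastic ingredient (growth, P-move choice,
tabu tenure, storage sampling) draws from R's session RNG, so
`search_params(seed = ...)` makes a run bit-reproducible; the test suite
asserts identical traces for identical seeds.

## Synthetic fixtures and what a green test establishes

The published benchmarks (the R and f180 instances, and HP conversions of
several CASP targets) are external and not reprinted, so the package
generates synthetic stand-ins: `generate_fixture_sequence(n, h_fraction)`
draws i.i.d. positions with a given hydrophobic fraction (default 0.5,
typical of the benchmark literature, fixed up front).  Synthetic chains
reproduce the *scale* and composition of the benchmarks but not their
correlation structure — real sequences have clustered H-runs — so green
tests establish correctness of the machinery (energies, encodings,
invariants, optimum recovery on exhaustively enumerable instances), not
benchmark-level performance.  The relative-improvement report
(`relative_improvement()`) is validated against the published comparison
table, whose energies are inputs to the measure.

## Numerical and degenerate-input choices

* Coordinates are unbounded signed integers; nothing is ever clamped to a
  box.  Fitness values are exact in doubles far beyond any feasible chain
  length (the largest term is $O(n^4)$).
* Chains of length 1 and 2 and all-P chains are legal; the search simply
  has nothing to optimise and reports fitness 0.
* Exhaustive enumeration is capped (8 monomers reduced, 5 unreduced;
  optimum oracle at 9) — beyond that the walk counts explode and the
  enumerator is the wrong tool by design.
* Ties among equal-fitness moves resolve by generation order (monomer
  index, then basis order), keeping runs deterministic.

## Limitations

* Single-monomer moves are not ergodic on all of conformation space; the
  searched region depends on the initial walk.  The original method shares
  this property.
* The memory's proximity radius is calibrated for long chains
  (hundreds of encoding symbols).  On very short chains the encoding
  space collapses and a radius-3 ball around even one stored minimum can
  cover — and therefore permanently block — every encoding of an optimal
  conformation: with the memory active the length-8 oracle suite
  typically recovers 8–9 of 10 exact optima, while the identical search
  with `memory_rate = 0` recovers 10/10 in half the iteration budget (both
  measured by the test suite).  This is faithful behaviour of the
  published parameterisation outside its intended scale, not a property of
  the search core; for chains below a few dozen monomers either disable
  the memory or shrink `proximity`.
* The package implements the HP potential only; 20×20 contact-matrix
  models, pull-move neighbourhoods and large-neighbourhood search are out
  of scope.
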