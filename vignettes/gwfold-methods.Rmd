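---
title: "Folding on the FCC lattice with a group-weighted contact potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding on the FCC lattice with a group-weighted contact potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwfold)
```

## The model

gwfold performs ab initio folding simulation in a reduced protein model:
each residue occupies one point of the face-centred-cubic (FCC) lattice,
consecutive residues occupy FCC-adjacent points (the *chain constraint*),
and no two residues share a point (the *self-avoiding walk constraint*).
Two points are FCC-adjacent when each coordinate differs by at most one and
the L1 distance is exactly two; every point then has twelve neighbours,
reachable by the twelve integer basis vectors returned by
`fcc_basis_vectors()`. The FCC lattice is the standard choice for reduced
protein models because its 12-neighbour geometry approximates real backbone
packing much better than the cubic lattice.

A conformation is stored in *relative encoding*: a string of $n-1$ indices
into the basis-vector set, decoded by anchoring residue 1 at the origin and
adding one basis vector per step (`decode_conformation()`). The encoding
guarantees the chain constraint by construction; self-avoidance is an
explicit check (`validate_conformation()`). Because the encoding carries no
absolute frame, any move that displaces residue 1 re-anchors the decoded
coordinates at the origin; comparisons across moves should therefore be
made on direction strings or on internal distances, both frame-free.

Residues $a$ and $b$ form a *contact* when $|a-b|>1$ and their points are
FCC-adjacent. The energy of a conformation is the sum of a 20x20 pairwise
potential over all contacts. The search problem is to minimise this energy.

## Contact potentials

Three potentials are available, all as `contact_energy_matrix` objects:

* **BM scale** (`bm_matrix()`): a full 20x20 pairwise potential in which
  every unordered residue pair carries an empirically-shaped energy. The
  bundled table is a **synthetic stand-in**, not an empirical matrix: it is
  constructed deterministically from the Fauchere–Pliska side-chain
  hydrophobicity scale and formal residue charges,
  $$E_0(a,b) = -3.2\,H_aH_b - 0.6\,(H_a+H_b) + 0.6\,q_aq_b +
  0.4\,(1-g_a)(1-g_b) - 0.1,$$
  with $H$ the clamped normalized hydrophobicity, $g$ its full-range
  normalization and $q$ the formal charge, scaled so that the largest
  magnitude is exactly 3.477 and rounded to three decimals. This yields the
  qualitative features the search cares about — strongly attractive
  hydrophobic pairs (W–W the strongest), mildly repulsive like-charge
  pairs, weakly attractive salt bridges, a quasi-linear magnitude spectrum
  spanning all six grouping bands, and both signs present — but its
  individual entries are not measurements. A real empirical table in the
  same 20x20 tab-separated format drops in via `read_energy_matrix()`.
* **HP** (`hp_matrix()`): the hydrophobic–polar simplification, $-1$ for
  H–H contacts and $0$ otherwise. The default H set
  \{A, C, F, I, L, M, V, W, Y\} is the common Dill-style assignment; it is
  a parameter because no single classification is canonical.
* **GW** (`derive_gw_matrix()`): the group-weighted rescaling described
  next.

## The group-weighted derivation

A raw pairwise potential gives a search algorithm little help in
distinguishing one large-magnitude contact from an accumulation of small
ones, so searches guided by it stall in local minima; the HP potential has
the opposite problem — it is blind to everything except H–H. The GW
potential interpolates: sort the energy levels by magnitude $|E|$, cut them
into bands, and multiply every entry of band $m$ by
$$g_m = 1 + \frac{m(m+1)}{2},$$
giving multipliers 1, 2, 4, 7, 11, 16 for the default six bands. The
default band edges on $|E|\times 10^3$ are 0–100, 101–500, 501–1000,
1001–1500, 1501–2000, 2000–3477. Grouping acts on magnitudes, so both
attractive and repulsive entries are amplified: strong attractions are
favoured *and* strong repulsions inhibited. Within a band the scaling is a
common factor, so relative order inside a band is untouched, and because
$g_m$ increases with $m$ the scaling never inverts magnitude order across
bands. One band reproduces the input potential exactly; many bands make the
top multiplier so large that the search becomes greedy for a handful of
contact types — six bands is the calibrated compromise.

Two numerical conventions resolve ambiguities in the printed band table:
band edges are upper-inclusive (a magnitude of exactly 100 is band 0),
except that the two top bands share the printed edge 2000, and a value of
exactly 2000 goes to the *higher* band. `assign_group()` implements exactly
this rule and refuses magnitudes above the top edge, which is also why
`read_energy_matrix()` rejects tables whose magnitudes exceed the scheme
unless a matching custom scheme is supplied.

## The genetic algorithm

`run_search()` implements a generational search over a population of 50
encoded conformations (the calibrated default):

1. **Initialization** — random chain growth (`chain_growth_init()`): grow
   the walk one residue at a time, sampling uniformly among free
   directions; a dead end restarts the chain, and 1000 restarts abort with
   an error. Restarting rather than backtracking keeps the sampling simple
   and unbiased enough for seeding purposes.
2. **Operator selection** — one operator per generation, drawn from the
   non-uniform distribution pull 0.40, crossover 0.25, diagonal 0.20,
   rotation 0.15 (calibrated; uniform selection wastes generations on
   operators that stop contributing).
3. **Exhaustive application** — the chosen operator is applied to every
   individual in all possible ways and the best-fit candidate kept
   (`exhaustive_apply()`): crossover enumerates every cut point and both
   children against a uniformly drawn mate; pull enumerates every residue,
   both pull directions and every free target; diagonal every residue and
   every candidate target; rotation draws one re-sampled suffix per start
   position (enumerating all $12^{n-s}$ suffixes is intractable, so the
   operator stays stochastic with one draw per start, each retried up to 50
   times for validity). Ties break by enumeration order — residue index
   ascending, tail before head, basis-vector order — so results are
   reproducible under a fixed seed. With `exhaustive = FALSE` each
   individual instead receives one random application (the cheaper, noisier
   variant).
4. **Elitist selection** — a child replaces its parent only when strictly
   fitter; ties keep the parent (`elitist_replace()`).
5. **Stagnation recovery** — after more than `threshold` consecutive
   non-improving generations (length-keyed default, 50 down to 15 — see
   `default_threshold()`), every individual is shuffled by $k$ successive
   random feasible pull moves, with
   $k = \text{shuffle} \times \max(1, n/10)$. The shuffle parameter starts
   at 1 and increments whenever two consecutive recoveries bring no new
   global best, so later recoveries diversify harder. The pull move is the
   natural shuffling primitive because it makes small, always-valid,
   well-mixing perturbations. The non-improvement counter resets to zero
   after recovery (the simplest consistent reading of the stagnation
   protocol), and the incumbent best is archived outside the population, so
   recovery can never lose it.
6. **Termination** — any of a wall-clock budget, a generation budget, or an
   objective-evaluation budget. The evaluation budget is the recommended
   stop for reproducible experiments: the number of candidate conformations
   scored is hardware-independent, which is also why it is the package's
   comparison metric (`speedup()`).

Search guidance and reporting are decoupled: selection uses the configured
guidance matrix (GW by default), while the incumbent best is additionally
re-scored under the base BM-scale matrix, so runs with different guidance
are comparable on one scale. The objective-evaluation counter ticks once
per candidate scored under the guidance matrix — initial population,
every enumerated candidate, and post-recovery re-scores; the bookkeeping
re-score of the incumbent under the base matrix is not an objective
evaluation.

### Pull-move mechanics

Pull moves on the FCC lattice are under-specified in the square-lattice
literature, so the package fixes one scheme: the pulled residue moves to a
free point adjacent to its chain neighbour on the side *opposite* the
pulled end (for an end residue, adjacent to its own position), and each
residue toward the pulled end then steps into the position its predecessor
just vacated, stopping as soon as chain adjacency is restored. Every
dragged residue lands on a point that was part of the old chain, so
self-avoidance holds automatically; the only bond that needs checking is
the reconnection bond, and the implementation validates the whole chain
anyway. A target adjacent to both chain neighbours reduces to a
single-residue relocation. The move set is not proven complete or
reversible — a known open point for lattice move sets generally — which is
acceptable here because the genetic algorithm does not require detailed
balance.

## Metrics

* `drmsd()` — distance-matrix RMSD: the root mean squared difference of
  intra-structure pairwise distances over all $n(n-1)/2$ pairs. It needs no
  superposition and is invariant to rigid motion. Note the range
  difference: dRMSD sums over *all* pairs ($j \ge i+1$), while the contact
  energy sums only pairs with $j \ge i+2$. Lattice coordinates are compared
  to native angstrom coordinates as-is (an optional uniform scale factor
  exists but defaults to off), because the statistic is a shape comparison,
  not a superposition fit.
* `relative_improvement()` — $(E_t - E_r)/E_r \times 100$, the normalized
  energy improvement of a target over a reference.
* `speedup()` — ratio of average objective-evaluation counts.
* `trend_fit()` — ordinary least squares through the closed-form normal
  equations, used for energy-difference-versus-length trend lines.

## What the synthetic inputs do and do not emulate

Random chain growth plus the synthetic potential reproduce the *structure*
of the search problem: a rugged landscape over self-avoiding walks with a
heavy-tailed contact-energy spectrum. Passing tests therefore demonstrate
the correctness of the geometry, the operators, the bookkeeping and the
search machinery, and the internal consistency of the GW derivation. They
do not demonstrate biological accuracy: the synthetic entries are not
empirical contact energies, so absolute energies are not comparable to
published values, and the *advantage* of GW over raw BM guidance — which
rests on how uninformative the real empirical spectrum is — transfers only
partially. Under the synthetic potential, whose two-scale construction is
already well separated, GW-guided and BM-guided runs reach closely similar
energies at desk scale (the acceptance suite computes this comparison
directly). Likewise, the weak correlation between contact energy and
native-structure dRMSD is a property of reduced contact models in general
and is not resolved here.

## Problem sizes used by the test suite

The tests run the full machinery at sizes chosen to keep the whole suite
fast while still exercising every code path: oracle comparisons use 1000
random conformations of up to 30 residues (enumeration oracles up to 10),
the step-by-step search oracle uses a population of 3 on an 8-residue
chain, and the headline search comparison runs the 54-residue benchmark at
$2\times 10^6$ objective evaluations per run — the order of a full
benchmark run for that chain — for five seeds under each guidance.
Evaluation budgets rather than wall-clock budgets make these runs
hardware-independent and exactly reproducible.

## Known limitations

* The bundled potential is a labelled synthetic stand-in; conclusions that
  depend on the fine structure of a real empirical spectrum require loading
  one.
* Move-set completeness and reversibility are unproven; some conformations
  may be unreachable from a given start.
* Chain-growth restarting is not a uniform sampler over self-avoiding
  walks; it is mildly biased toward compact-feasible growth orders, which
  is irrelevant for seeding a search but matters for equilibrium
  statistics.
* The evaluation-budget stop checks at generation boundaries, so a run may
  overshoot the budget by up to one generation's worth of candidates.
* Energies are dimensionless (BM scale); no temperature, solvent or
  side-chain terms.
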