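---
title: "Multi-objective decoy sampling: model, operators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective decoy sampling: model, operators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(evodiverse)
```

## The problem

Template-free structure prediction must search an enormous, rugged
conformation space with an energy model that is only loosely correlated
with nativeness. Practical pipelines therefore do not look for a single
minimum: they generate large sets of low-energy candidate structures
(*decoys*) and hope the set is diverse enough to cover the basin that
contains the native fold. This package implements a memetic evolutionary
algorithm that makes that diversity an explicit objective of the search,
rather than a by-product of restarts: survival is decided by Pareto
non-domination over three energy components plus a crowding-distance
density estimate, so the population is pushed simultaneously toward low
energy and toward unoccupied regions of objective space.

## Conformation model

A chain of $l$ residues is represented by its backbone dihedrals
$(\phi_i, \psi_i, \omega_i)$, with each side chain reduced to a single
centroid pseudo-atom (CEN) — the classic coarse-grained representation of
fragment-assembly samplers. Cartesian coordinates of N, CA, C, O and CEN
are a pure function of the dihedrals: atoms are placed sequentially by
three-atom frame construction (NeRF) from a canonical origin frame, with
ideal trans-peptide bond lengths and angles
(`backbone_geometry()`). Because all comparisons the sampler makes are
internal, any self-consistent ideal geometry would do; the shipped
constants are standard textbook values. $\omega_i$ denotes the peptide
torsion *following* residue $i$, so $\phi_1$, $\psi_l$ and $\omega_l$ are
carried but geometrically inert, and the "extended chain" is defined as
all torsions at 180°.

Moves are molecular fragment replacements: a start position in
$[1, l-f+1]$ is drawn uniformly, and the $3f$ dihedrals of the window are
overwritten with a configuration drawn uniformly from a fragment library
($f = 9$ during initialization, $f = 3$ for variation and improvement).
Libraries are plain text; `make_synthetic_library()` builds them around a
known native by mixing near-native configurations (native torsions plus
Gaussian noise) with decoys drawn from the three canonical Ramachandran
basins — helix $(-57, -47)$, strand $(-120, 120)$ and left-handed
$(60, 45)$. Deviations of $\omega$ are clamped to $\pm 15°$ so peptide
bonds stay near-trans; cis-proline is not modeled.

## Energy model

The original sampler delegates scoring to a suite of staged knowledge-based
functions whose published descriptions state their *roles* but not their
formulas. The package ships minimal analogs with the same roles, in
arbitrary units (a.u.):

* **stage 0, steric only** — soft repulsion
  $\sum ((r_c - d)/r_c)^2$ over CA–CA and CEN–CEN pairs with sequence
  separation $\ge 2$ and $d < r_c = 4$ Å. Used with a Metropolis scaling
  of $\alpha = 0$ to randomize extended chains without self-collisions.
* **stage 1, adds hydrogen bonds** — a square well of depth $-1$ for every
  backbone O(i)⋯N(j) pair with $|i-j| \ge 3$ and distance in
  $[2.6, 3.4]$ Å, with no angular term. This lets secondary structure
  form; an ideal helix gains both its $i,i{+}3$ and $i,i{+}4$ contacts.
* **stage 3, adds compactness** — $w_{rg}\,\max(0, R_g - R_g^0(l))^2$ with
  $R_g^0(l) = 2.2\,l^{0.38}$ Å, the empirical radius-of-gyration scaling
  of globular proteins. This is the score the greedy improvement operator
  descends; the compactness term dominates its gradient for extended
  chains, mirroring the role of the stage that drives tertiary packing.

The three **optimization objectives** split the same total: short-range
hydrogen bonds ($|i-j| \le s_{cut} = 4$, the helical contacts), long-range
hydrogen bonds ($|i-j| > 4$, sheet and tertiary contacts), and everything
else (steric + compactness + a small torsion-preference penalty of 0.1 per
residue outside all three basins). Their sum is the total energy used by
the single-objective baseline selector.

Two numerical choices deserve notice. First, the steric weight is 10: the
hydrogen-bond well is unsaturated (every O⋯N pair in range counts), so a
soft steric term would let interpenetrating "blobs" harvest arbitrarily
many long-range bonds; with $w_{steric} = 10$ a half-radius clash costs
about 2.5 bond units and collision avoidance dominates at every stage,
which is that term's documented role. Second, although the compactness
*weight* (2) is smaller than the steric weight, its squared-Ångström term
is the largest single stage-3 contribution for any extended-ish chain
(≈ 64 a.u. for an extended 30-mer), which is what "upweighting
compaction" means here; the weights multiply terms of different units, so
comparing raw weights across terms is not meaningful.

Every call of any stage function counts as one energy evaluation; the
run's budget is expressed in these evaluations, and the counter can never
pass the budget.

## The evolutionary loop

* **Initialization** (`init_population()`): each of $N$ individuals starts
  extended and passes two Metropolis Monte Carlo stages of $f=9$ moves:
  stage 1 on the steric score with $\alpha = 0$ (5$l$ attempted moves;
  downhill and flat moves only), stage 2 on the stage-1 score with
  $\alpha = 2$, running until $l$ consecutive rejections.
* **Variation** (`variation()`): every parent yields exactly one offspring
  by a single unconditional $f=3$ replacement — no Metropolis filter, so
  at most nine dihedrals change.
* **Improvement** (`improvement()`): greedy $f=3$ local search on the
  stage-3 score; a move is kept only if it strictly lowers the score
  (a zero change counts as a failure), stopping after $k = l$ consecutive
  failures. This is where most of the budget is spent.
* **Selection**: over the combined $2N$ individuals only (no archive).
  The shipped selectors are `evo_diverse` (whole non-dominated fronts in
  order, the first non-fitting front filtered by descending crowding
  distance), and the published baselines `mea` (total-energy truncation),
  `mea_pr` (Pareto rank, then total) and `mea_prpc` (Pareto rank, Pareto
  count, total).

The Metropolis criterion accepts $\Delta E \le 0$ always and uphill moves
with probability $e^{-\Delta E / \alpha}$ ($\alpha = 0$: never). Accepting
flat moves at every $\alpha$ is deliberate: from an extended chain all
collision-free moves are flat under the steric-only score, so a strict
"must lower" rule would never randomize the chain at all. A consequence is
that a library consisting only of identity moves can never *fail* stage 2,
so the stage carries a 50$l$-attempt safety cap; with any real library the
$l$-consecutive-failure rule fires long before the cap (median stage-2
length is under 10$l$ attempts on the toy targets).

Crowding-distance ties are broken by input order, cumulative front sizes
landing exactly on $N$ skip the next front, and a degenerate objective
(max = min within a front) contributes nothing to interior members — all
choices made so runs are bit-reproducible under a fixed seed. The hot
loops (coordinate rebuild, scoring, the MMC and greedy searches) are
compiled, but draw their randomness from R's RNG, so `set.seed()` governs
the whole pipeline end to end.

## Metrics and the statistical protocol

Decoys are compared to a known native by CA lRMSD after optimal (Kabsch)
superposition, by TM-score with
$d_0 = \max(0.5,\ 1.24(L-15)^{1/3} - 1.8)$ Å, and by GDT_TS (mean maximal
coverage at 1, 2, 4, 8 Å). TM and GDT maximize over a deterministic seeded
superposition search (windows of length $L$, $L/2$, $L/4$, iterative
inclusion of residues within the distance scale). The search is a
heuristic, as in the reference implementations of both scores; the test
suite bounds it against an exhaustive all-window oracle on toy cases.

Head-to-head algorithm comparison builds a 2×2 win/loss table over paired
per-target values; a tie credits *both* sides, so columns can sum to more
than the target count — this is the convention that reproduces the
published win counts, where a tied target appears in both algorithms'
tallies. Superiority is then assessed by one-sided exact tests:

* **Fisher** — conditional, hypergeometric upper tail $P(X \ge a)$; the
  two-sided value uses the doubling convention $\min(1, 2p_1)$, which is
  the convention the published two-sided values follow exactly.
* **Barnard** — unconditional: rows are independent binomials and the
  p-value is $\max_\pi P(T \ge T_{obs})$ for the pooled-variance Wald
  statistic. Outcomes tied with $T_{obs}$ are included under a relative
  tolerance of $10^{-7}$ — a strict floating-point comparison silently
  drops exactly-tied outcome tables such as $(5,4)$ against an observed
  $(6,5)$ and noticeably understates the p-value. The nuisance
  maximization scans a $10^{-4}$ grid with local refinement, clamped to
  $[10^{-4}, 1-10^{-4}]$: for a null table like $[[5,5],[5,5]]$ the
  supremum over the open interval is 1, approached at the boundary, so
  the clamp is part of the test's definition. This variant reproduces all
  thirteen published Barnard values to their printed precision except
  that null table, where it gives 0.9990 against a printed 0.9991 — a
  fourth-decimal boundary-grid artifact.

## Synthetic data: what it does and does not emulate

`make_toy_native()` builds ideal-torsion natives (helix, β-hairpin, mixed
topology) of 12+ residues, and `default_suite()` fixes a four-target panel
(helix-20, helix-30, hairpin-24, mixed-40). Synthetic libraries default to
200 configurations per position — the size real fragment servers return —
with a near-native fraction of 0.3 and 10° torsion noise in the shipped
study conditions. These fixtures exercise every code path (I/O, moves,
scoring, selection, metrics, statistics) with no external data, and the
helix-30 recovery check shows the full pipeline can find sub-2 Å decoys
when the library contains the signal.

They do **not** emulate real prediction: sequences carry no structural
information (fragments come from the known native, not from sequence
profiles), the energy analogs share only the roles of the original staged
scores (values are not comparable to any published energies), and toy
targets are far shorter than real ones. Passing the toy checks therefore
validates the algorithmic machinery, not predictive accuracy on proteins.

## Problem sizes and defaults

The published study conditions are $N = 100$, a budget of $10^7$
evaluations and 5 runs per target. The package defaults to a desk-scale
budget of $10^5$ (a run on a 30-mer takes seconds) and the acceptance
checks use $N = 50$ with $2 \times 10^5$ evaluations and 5 seeded runs —
enough for the toy targets to saturate. The study-scale budget is one
config edit away (`run_config(budget = 1e7)`); nothing in the code depends
on the scale.

## Known limitations

* The hydrogen-bond well has no angular term and no donor/acceptor
  saturation; strong sterics keep this harmless at ordinary densities,
  but the long-range bond counts of tightly packed decoys are optimistic.
* $R_g^0(l)$ describes globular chains, so a long ideal helix (a rod) is
  penalized as "too extended" at stage 3; on the helix toys this makes
  the improvement operator bend what initialization built, and the best
  near-native decoys typically date from early generations.
* Metric superposition search is heuristic (bounded by the exhaustive
  oracle only on toy sizes); different-length chains are out of scope.
* Single chains, standard residues, trans peptides only.
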