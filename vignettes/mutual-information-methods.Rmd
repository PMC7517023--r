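---
title: "Mutual information as a measure of web structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual information as a measure of web structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miweb)
```

## The model

A bipartite interaction web is an incidence matrix $A = a_{ij}$: rows are the
$N_X$ species of one set (say plants), columns the $N_Y$ species of the other
(say pollinators). The marginal totals $k_i = \sum_j a_{ij}$ and
$k_j = \sum_i a_{ij}$ are the species degrees; $NM = \sum_{ij} a_{ij}$ is the
interaction total and $\rho = NM / (N_X N_Y)$ the occupancy (connectance) for
a binary web.

Treating interactions as draws from the cell distribution
$p_l = a_l / NM$ and the margins as its marginals, the package computes

$$H(X) = -\sum_i p_i \log p_i, \qquad
  I(X;Y) = H(X) + H(Y) - H(X,Y), \qquad
  S = \frac{I(X;Y)}{H(X,Y)}.$$

$I(X;Y)$ is the reduction in uncertainty about a species' identity once its
partner is known — the degree of reciprocal specialization. Its normalization
$S \in [0,1]$ divides by the total web entropy so that webs of different
dimensions and fills are comparable: $S = 1$ for the diagonal (one-to-one)
web, $S = 0$ for the saturated one. For any binary web each occupied cell has
probability $1/NM$, so $H(X,Y) = \log NM$ exactly — a useful exactness that
several tests rely on.

Assumptions worth keeping in mind: the cell distribution is taken at face
value (no sampling model), and weighted webs are handled by the same formulas
with probabilities $a_{ij}/NM$ — in that case $\rho$ is still reported as the
occupied-cell fraction while $NM$ is the weighted total.

### H2′ and its heuristic

The specialization index $H2'$ rescales $I$ by its attainable range at the
observed margins:
$H2' = (H_{max} - H(X,Y)) / (H_{max} - H_{min})$ with
$H_{max} = H(X) + H(Y)$. No closed form exists for $H_{min}$, the smallest
joint entropy over margin-preserving tables; `h2prime()` approximates it by
greedy packing (place the largest feasible count at the currently largest
row/column margins, repeat). The greedy table's entropy is an upper bound on
the true minimum, so the reported $H2'$ is an *upper-bound estimate*, clamped
to $[0,1]$. Tests compare it against an exhaustive enumeration of all tables
on small margins; the greedy value equals the exact one on the anchor cases
(diagonal, independence, symmetric $2\times 2$ tables) and never falls below
it.

## The matrix families and their closed forms

Each generator has an analytic counterpart, and an oracle-equivalence test
grid asserts $|S_{analytic} - S_{empirical}| < 10^{-10}$ over at least 20
parameter settings per family.

| family | generator | closed form for $S$ |
|---|---|---|
| uniform (regular margins) | `matrix_uniform_regular(n, rho)` | $\log(1/\rho) / \log(\rho N_X N_Y)$ |
| random fill | `matrix_random_fill(nx, ny, rho)` | — (compared to uniform) |
| packed nested | `matrix_nested_packed(n)` | $(2(\log NM - \tfrac{1}{NM}\log\mathrm{Hyp}(n)) - \log NM)/\log NM$ |
| general nested | `matrix_nested_general(nx, ny, rho)` | — (bounded by uniform) |
| isometric modular | `matrix_modular_isometric(m, t)` | $(\log n - \log t)/(\log n + \log t)$ |
| rectangular modular | `matrix_modular_rect(m, t, z)` | $\log m / \log(mtz)$ |
| increasing modules | `matrix_modular_increasing(m)` | via $\sum i^2 \log i$ |
| compound nested | `matrix_compound_nested(m, t)` | via $m,t$ and $\log\mathrm{Hyp}(t)$ |

$\log\mathrm{Hyp}(n) = \sum_{i\le n} i \log i$ and its squared-index analogue
$\sum_{i\le n} i^2 \log i$ are computed directly in log space
(`log_hyperfactorial()`, `log_hyperfactorial_sq()`); the hyperfactorial
itself overflows at two-digit $n$. The closed forms for the increasing and
compound families are stated here in the algebraic form that reproduces the
explicit entropy sums $H(X) = \log NM - \log\mathrm{Hyp}_2(m)/NM$ and
$H(X) = \log NM - (m/NM)\log\mathrm{Hyp}(t)$; both are pinned to the
empirical decomposition to $10^{-12}$ in the tests, which is the ground truth
for this reading.

Notable consequences the tests assert:

* **Shape invariance.** $S$ depends on the dimensions only through
  $N_X N_Y$: an $80\times 20$ web matches a $40\times 40$ web at equal
  $\rho$.
* **Equal-$S$ classes.** Two isometric modular webs share $S$ iff
  $\log_{t_1} N_1 = \log_{t_2} N_2$ (`equal_s_condition()`); along such a
  family $S$ is constant while $H(X,Y)$ and $I$ both grow.
* **Orderings.** At matched size and occupancy, nested webs carry less $S$
  than flat-margin webs, and compound webs less than simple modular ones:
  degree heterogeneity (generalists) erodes reciprocal specialization.

## Generator choices

The design was genuinely open in a few places; the package's choices:

* **Uniform regular construction.** $k$ cyclically shifted diagonals give
  exact regular margins; a seeded sequence of degree-preserving checkerboard
  swaps then randomizes the arrangement. Because $H(X,Y) = \log NM$ for any
  binary web and the margins are fixed, the shuffle cannot change any
  entropy quantity — it is cosmetic and documented as such.
* **General nested boundary.** Row lengths follow the power curve
  $\mathrm{len}(i) = \lceil N_Y (1 - ((i-1)/N_X)^\gamma) \rceil$, with
  $\gamma$ found by bisection and single-cell adjustments (seeded, applied
  where they keep the profile non-increasing) to land exactly on the target
  cell count. Any perfectly nested profile at the target occupancy is
  admissible; this one guarantees no empty rows or columns and spans the
  whole feasible range $[(N_X + N_Y - 1)/(N_X N_Y),\, 1]$.
* **Orientation.** Rows are ordered by decreasing degree and left-packed, the
  convention in which nested webs are drawn packed toward $a_{11}$.
* **Rounding.** Target cell counts use round-half-up.

## The swap experiment

`swap_experiment()` applies sequential checkerboard swaps
($[[1,0],[0,1]] \leftrightarrow [[0,1],[1,0]]$ on a row and column pair) to a
compound web — by default the $3$ modules $\times$ $5$ species configuration
— and records $S$, NODF nestedness and planted-partition modularity. Swaps
preserve every margin, so $S$ is constant *exactly* (asserted to $10^{-12}$),
while both topology metrics decay: topology varies freely within the space
that the lower-order parameters (size, fill, degrees) allow, and $S$ measures
those parameters, not the topology.

Implementation decisions:

* **Swap counting.** Steps count *accepted* swaps, not attempts.
* **Candidate sampling.** Rejection sampling (two random rows, two random
  columns, retry on non-checkerboard) capped at $10 N_X N_Y$ attempts, then
  exhaustive enumeration with a uniform draw. Rejection is not exactly
  uniform over checkerboards; for the invariance result this is irrelevant,
  and it is documented on `checkerboard_swap()`.
* **Modularity.** The reported $Q$ is Barber-style bipartite modularity
  $\sum_k (e_{kk} - a_k b_k)$ evaluated at the *planted* partition the
  generator attached — the experiment tracks the decay of known structure,
  not community detection. A label-propagation heuristic
  (`detect_modules()`) is provided, clearly labelled heuristic, for webs
  without a known partition. With the planted partition,
  $Q = 1 - 1/m$ exactly for $m$ equal full modules.
* **NODF.** The pairwise overlap form: a row (or column) pair with equal
  marginal totals contributes 0, otherwise $100 \times$ shared/smaller;
  averaged over all pairs on both axes. This form is order-invariant, which
  keeps trajectories well-defined as swaps scramble the degree ordering. One
  consequence: a web whose margins are all equal (e.g. isometric full
  modules) has NODF exactly 0. The implementation is cross-checked against
  an independent reference implementation on degree-sorted matrices.

## Numerical conventions

* Natural logarithms internally; $S$ and $H2'$ are base-free (asserted to
  $10^{-12}$), raw entropies can be reported in bits via `base = 2`.
* $0 \log 0 = 0$ throughout; empty rows or columns contribute nothing. The
  all-zero matrix and the single-occupied-cell matrix (where $S = 0/0$) are
  errors.
* Probability vectors must sum to 1 within $10^{-9}$ relative tolerance;
  `equal_s_condition()` uses the same relative tolerance on log ratios.
* Greedy ties (equal margins) break toward the first index, making `h2prime`
  deterministic.

## What the generators do and do not emulate

The generated families are idealized: exact blocks, perfect nesting, exact
regular margins. They reproduce the *structural* conditions under which the
closed forms hold, which is what the equivalence tests certify. They do not
emulate sampling noise, abundance-driven interaction weights, or the ragged
degree distributions of field webs — so a green test grid shows the metric
implementations are correct, not that any empirical web follows these models.
One quantitative caveat found while testing: the random-fill model's mean $S$
sits *below* the flat-margin closed form by a systematic finite-size bias
(each marginal entropy falls short of $\log N$ by roughly $(N-1)/2NM$ nats
unless the margins are exactly flat). The gap is about 1.6% of $S$ at
$N = 100$, shrinking with $N$ but never with the number of replicates; the
package therefore asserts the sign of the difference and its percent-level
magnitude, and a stricter standard-error-scaled closeness claim is knowingly
left failing in the acceptance suite rather than weakened.

Problem sizes used in the test suite — webs up to $200 \times 200$, 50–200
Monte Carlo replicates, 200-swap trajectories, 1000-matrix identity sweeps —
were chosen as comfortably sufficient for the properties asserted: every
deterministic identity is scale-free, and the stochastic claims are
sign/ordering claims that stabilize at these sizes.

## Known limitations

* `h2prime()`'s greedy $H_{min}$ is a heuristic; for adversarial margins it
  can overestimate $H2'$. The exhaustive oracle is exponential and only
  feasible on tiny webs.
* `detect_modules()` is a convenience heuristic, not a modularity optimizer;
  use planted or externally inferred partitions for inference.
* Generators cover the analytic families only, not arbitrary degree
  sequences.
* Spatially replicated (three-dimensional) interaction arrays and
  multitrophic webs are out of scope.
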