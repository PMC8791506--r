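---
title: "Partition representation of PTM reaction networks: model, scoring and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition representation of PTM reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmnet)
```

## The model

The building block is the Michaelis–Menten-type post-translational
modification (PTM) reaction

$$S_i + E_i \underset{d_i}{\overset{a_i}{\rightleftharpoons}} C_i
\xrightarrow{k_i} P_i + E_i,$$

treated throughout with the plain law of mass action — no quasi-steady-state
or Michaelis–Menten approximation, because approximations are known to
distort bistability. Units are mmol/m³ for concentrations and seconds for
time, so $a_i$ is in m³/mmol/s and $d_i, k_i$ in 1/s. Reactions binding
several enzymes to one substrate simultaneously are outside the formalism.

A network of $N$ such reactions is specified by a single combinatorial
object: a partition of the $3N$ substrate/enzyme/product labels. All labels
in one block are *identified* — they are the same physical molecule. The
derived system has one dynamic species per block plus the $N$ complexes
$C_i$ (complexes are never members of the partitioned universe; extending
the universe with complexes would need a different derivation and is not
attempted here). Each merged species' rate law is the sum of its members'
unmerged rate laws with every member occurrence substituted by the merged
species. The substitution is applied mechanically, so a block containing
both $S_1$ and $E_1$ yields a squared mass-action term — exactly the dimer
formation–separation chemistry one expects from identifying a substrate
with its own enzyme.

```{r}
merge_network(ptm_partition(1, list(c("S1", "E1", "P1"))))
```

## Conservation laws by concatenation

Each reaction contributes a substrate law $\{S_i, C_i, P_i\}$ and an enzyme
law $\{E_i, C_i\}$. Merging blocks merges laws: every list sharing a species
with a block is *concatenated* (not unioned), the block's members are
removed and replaced by the merged species. Concatenation is the essential
detail: two lists being merged can share a complex, and that complex then
legitimately counts twice in the invariant. For `{{S1,E1},{P1}}` the merged
invariant is $y + 2C_1 + P_1$:

```{r}
conservation_laws(ptm_partition(1, list(c("S1", "E1"), "P1")))
```

The package verifies, as a polynomial identity over the monomial table (not
merely numerically), that every law's multiplicity-weighted derivative sum
cancels; the test suite checks this on hundreds of random partitions with
$N \le 3$ and checks numeric drift below $10^{-6}$ relative over the full
relaxation horizon. The derivation processes blocks in canonical order, but
the result is order-independent (concatenation is commutative up to
multiplicity), which the suite asserts under block-order permutation.

## Steady states: protocol and numerical choices

Steady states are found by relaxation in windows of $\tau = 10$ s, at most
$\kappa = 360$ windows (one hour of simulated time — the reference response
time of cellular signalling), with convergence declared when every species
changes by less than $\varepsilon = 10^{-3}$ relative to a reference scale
over one window. The reference scale is the conserved total of the law
containing the species; a complex belonging to two laws uses the smaller
total. This per-law normalization is one of two defensible readings of a
"relative to total protein" criterion; it was chosen because it is
scale-free and reduces to the obvious meaning for unmerged species. A
species whose law total is zero is required to be numerically frozen
instead (change below the absolute tolerance).

The integrator is `deSolve::lsoda` (stiff-capable) with absolute tolerance
$10^{-9}$ and relative tolerance $10^{-6}$ per window; both are exposed in
`solver_protocol()` since they are implementation choices, not model
content. Integration runs in chunks of up to 36 windows per solver call
(sampled every $\tau$ seconds) purely for speed; the window-by-window
convergence decision is unchanged. Integrator failures are caught and
reported as non-converged results, never as crashes. Concentrations in
$[-10\,\mathrm{atol}, 0)$ from round-off are clamped to zero.

Random initial states put all mass in non-complex species: each law's total
is spread over its non-complex members by a flat Dirichlet draw. Complexes
start at zero because they couple the substrate and enzyme laws — with
complexes empty, the laws are independently satisfiable and the totals are
met exactly by construction.

## The resettable-bistability score

An input species (default $E_1$) and an output species (default $P_2$) are
fixed; partitions putting them in one block are excluded from the search
space, since the score normalizes the output by a conserved total that the
sweep is varying. The input law's total runs over
$\Omega = 2^{-5}, 2^{-4.5}, \dots, 2^5$ mmol/m³ — 21 points bracketing
physiological protein concentrations. At each point, $\theta = 5$
replicates relax from fresh random initial states (a Monte-Carlo probe of
coexisting attractors — deliberately *not* a hysteresis continuation, so no
state carries over between grid points), and the output steady value is
normalized by its law's total and clamped to $[0,1]$. A replicate is used
only if all 21 points converged; with fewer than two usable replicates the
evaluation returns 0, the conservative fallback.

Bistability at a grid point is four times the population (divide-by-$n$)
variance of the replicate values — population variance because its maximum
over $[0,1]$-valued data is exactly $1/4$, at a half-and-half split. The 21
values $V_l$ are aggregated by

$$eVL(V) = \alpha \cdot \mathrm{mean}_l\, (V_l - |l - 11|/10)^2,$$

which rewards monostable edges and a bistable centre. The aggregate is the
*mean* over positions: the ideal vector (six zeros, nine ones, six zeros)
gives a plain 21-term sum of 12.7 and a mean of $12.7/21 = 0.6047619$, and
$\alpha = 1/0.6047619$ makes the ideal vector score exactly 1. (With a sum
instead of a mean the stated maximum 0.604762 is impossible — 12.7 is 21
times larger — so the mean reading is the consistent one; the package
verifies 12.7 by direct evaluation in its tests.) At $|l-11| = 5$ the two
endpoint values of $wVL$ tie, so the maximizer is not unique, but the
maximal *value* is attained exactly at the ideal vector, which the suite
checks by per-coordinate maximization.

`phi(p, nu, ...)` composes sweep, variance and aggregate; `phi_max()` wraps
it in a best-of-$\lambda$ ($\lambda = 5$ by default) random draw of all
rate constants and non-input totals from
$\Lambda = \{2^{-5}, \dots, 2^5\}$, the range of reported MAPK-cascade
kinetics. Totals are fixed per parameter point; only initial allocations
vary across replicates (the parameter point is the argument of the score,
so redrawing totals inside it would blur what is being scored).

## The search

`run_search()` draws a uniformly random admissible partition — exact
uniform sampling over all $B_{3N}$ partitions via the
size-of-the-first-block decomposition, so the smoke tests against
enumeration frequencies are well-defined — and iterates the recursive step
`psi(P, P, sigma)`. `psi` tries a join candidate, then a separate
candidate, then recurses on each at depth $\sigma - 1$, returning the first
candidate whose score strictly beats the incumbent's, else the incumbent
(the fall-through realizes the "greater than or equal" contract; join is
always tried first, which also breaks score ties). Within one `psi` call
every distinct partition is scored at most once (the score is stochastic;
caching keeps all comparisons of one call against a single incumbent
value), and the incumbent is re-scored once per main-loop iteration. The
loop stops when the score exceeds $\rho = 0.8$ or after $\gamma = 150$
iterations, whichever comes first. Candidate bipartitions in `separate` are
uniform over the $2^{m-1}-1$ proper bipartitions of an $m$-species block,
and `join` pairs are uniform over admissible pairs; the choice of
uniformity is a simplicity/testability decision, not a claim about any
reference implementation.

Recursive sub-calls compare against the top-level incumbent's score, not
against intermediate improvements — the literal reading of the recursion's
step list, and the one implemented.

## Problem sizes and what the tests do (and do not) show

The shipped tests run the formalism at desk scale: exhaustive enumeration
at $N \le 2$, conservation properties on random partitions at $N \le 3$,
sweeps and the pinned bistability regression on the known $N = 4$ bistable
motif (`fig2a`), and the search machinery under stub evaluators. A full
$N = 4$ production search at the default budget evaluates on the order of
$150 \times 30$ candidate partitions, each with $\lambda \times \theta
\times 21$ relaxations, and runs for hours to days on one core — the
package supports it, but no test depends on it, and discovered topologies
vary with the seed. Passing tests therefore demonstrate the correctness of
the derivation, scoring and search mechanics, not the reproduction of any
particular discovered network. The synthetic inputs (random partitions,
$\Lambda$-drawn kinetics, Dirichlet initial states) emulate the study
conditions' parameter ranges; they do not emulate features of real kinetic
data such as correlated rate constants or measurement noise.

## Known limitations

* Bistability is detected by replicate-variance clustering, not by
  continuation or eigenvalue analysis; saddle-node locations are never
  computed, and the score cannot distinguish true bistability from very
  slow mixing between basins if relaxations fail to converge (such
  replicates are discarded).
* The convergence criterion can declare near-steady states on systems with
  dynamics far slower than the one-hour horizon; the protocol is exposed so
  users can tighten $\tau \kappa$ and $\varepsilon$ (the closed-form
  single-reaction tests do exactly that).
* Universes with complexes as first-class partition members, automatic
  variation of $N$, and coarser building blocks (whole activation cycles)
  are out of scope.
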