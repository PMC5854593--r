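---
title: "Methods: local-information control of directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local-information control of directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netctrl)
```

`netctrl` treats a directed network as the coupling matrix of a linear
time-invariant system `dx/dt = A x + B u` and answers two questions with only
local topological information: which nodes need independent external inputs
for structural controllability, and where extra inputs should go to make the
minimum-energy control cheap. This vignette documents the model, every
tunable parameter that matters, the numerical choices, and what the
synthetic-data experiments do and do not establish.

## Conventions

An edge `i -> j` with weight `w` is stored at `A[j, i]`: rows of `A` index
state equations, so row `j` collects the influences flowing into node `j`.
Node identifiers are opaque strings, mapped to dense indices only at the
matrix boundary. Duplicate edges collapse (matching is structural);
self-loops are allowed. Weights default to 1, are ignored by matching, and
are used by the energy module.

Two length conventions coexist deliberately. A control path's length `L_i`
counts **nodes** — the min-max allocator's worked example splits a 10-node
network into paths of 7 and 3 nodes. The circle experiments instead measure
the longest control path as the maximum number of **edges** between adjacent
control nodes around the circle. Each function documents which convention it
uses.

## Local-game matching

Nodes play synchronous rounds. In each round every node without a fixed
child sends one child request to the unmatched child neighbour with the
lowest u-input degree, and every node without a fixed parent sends one
parent request to the unmatched parent neighbour with the lowest u-output
degree; a node with a self-loop may request itself. The u-input (u-output)
degree of a node is its number of parent (child) neighbours that have not
yet fixed a child (parent) — targeting low-u-degree neighbours raises the
chance of mutual requests, because those neighbours receive fewer competing
requests. Only a mutual pair fixes a match; the matched parent then drops
its other outgoing links and the matched child its other incoming links.
Availability flags make the explicit link removal redundant for bookkeeping:
a removed link always has an endpoint that is no longer available in the
relevant role.

**Tie handling.** When several candidates share the minimum u-degree the
node waits with probability `omega` (default 0) or picks uniformly at
random. The waiting decision is taken per tie event, and u-degrees are
recomputed between rounds, consistent with simultaneous play; both choices
are design decisions, since the protocol description fixes neither. All
randomness flows from one seed, and node iteration order is sorted node
order, so a run is fully reproducible from `(network, omega, seed)`.

**Termination.** Rounds continue until no request can be sent, or until a
round fixes no match *and* involved no random tie-break — such a
configuration is a deterministic fixed point and would repeat forever. When
random tie-breaks keep the outcome open, the run stops after `stall_rounds`
(default 25) consecutive matchless rounds. On ER networks with
`N = 100..2000` the observed round count is 3–15, far below `N`, consistent
with the protocol's linear total work.

**What LM achieves and what it cannot.** At termination the matching is
*maximal* — no live edge remains between an available parent and an
available child (the test suite checks this indirectly through partition
validity, and it was verified directly during development). It is not
*maximum*: turning a maximal matching into a maximum one requires augmenting
paths, which need non-local information. The driver count `N_D^LM` therefore
always dominates the exact `N_D`, with mean driver counts close to the
optimum across mixed ER/BA ensembles (the acceptance suite bounds the ratio
of ensemble means by 1.15 over 100 graphs, `N` up to 500, mean degree 1–8).
The excess concentrates in dense graphs, where `N_D` is a handful of
forced in-degree-0 nodes while LM strands a few extra nodes with positive
in-degree. That is why the driver *out*-degree distributions of LM and MM
agree closely (total variation ~0.11 at `N = 1000`, mean degree 6, pooled
over 20 seeds) while the *in*-degree distributions differ visibly there —
a genuine limitation of purely local matching, not a numerical artefact:
it persists for every waiting probability tried and for an asynchronous
variant prototyped during development.

A non-empty network whose nodes all lie on circled control paths still needs
one external input to hook the circles onto, so `required_inputs()` returns
`max(#DCPs, 1)` for non-empty networks and 0 for the empty one.

## Exact maximum matching

`mm_exact()` is the global oracle: maximum bipartite matching (igraph's
exact matcher) on the out-copy/in-copy representation, `N_D = max(N -
|matching|, 1)`, drivers = unmatched in-copies. The test suite validates it
against an exhaustive recursive matcher on small random graphs. Driver sets
of a maximum matching are not unique; `mm_exact()` returns the single
realization the matcher produces, which is the appropriate baseline for the
random-allocation method.

## Min-max input allocation (MLCP)

Given path lengths `L_i` (nodes) and `m0` extra inputs, the allocator
minimizes `max_i L_i / (1 + n_i)` subject to `sum n_i = m0`, granting each
input greedily to the current arg-max ratio with ties toward the lowest
index. Greedy is optimal here by an exchange argument; rather than assuming
that, the test suite proves it empirically against exhaustive search over
all compositions on 200 random instances (up to 5 paths, `L_i <= 20`,
`m0 <= 6`). The longest resulting path is `max_i ceil(L_i / (1 + n_i))`, and
it is non-increasing in `m0`.

CCPs are merged onto DCPs before allocation: largest CCP first, each onto
the currently shortest effective path (ties toward the lowest index). The
balancing rule is a design choice — the source material defers the precise
assignment to supplementary detail — and any rule that keeps effective
lengths balanced serves the min-max objective. When only CCPs exist, a
virtual path seeded by the largest CCP hosts the mandatory single input.

On a path of `L` nodes carrying `k` inputs, input `j` (0-based) attaches at
node `floor(j L / k) + 1`: the head (driver) always gets the first input and
segments differ by at most one node. `build_B()` produces unit columns, so
`B'B = I` holds exactly and every node has a binary connection to at most
one input.

## Energy module

All matrix integrals use the Van Loan block-exponential identity: the upper
right block of `expm([[-A, Q], [0, A']] t_f)` yields
`int_0^tf exp(At) Q exp(A't) dt` after multiplication by `exp(A'tf)'`. The
test suite cross-checks it against fixed-order Gauss-Legendre quadrature to
1e-8 relative error on random stable systems up to `n = 8`.

The expected cost over random initial states with `E[x0 x0'] = Sigma0`
(identity by default — i.i.d. zero-mean unit-variance entries) is
`E(B) = tr(W_B^{-1} exp(A tf) Sigma0 exp(A' tf))`; a Monte-Carlo average of
realized costs over 10^4 sampled initial states agrees with the trace
formula within three standard errors in the tests.

**Gradient sign.** Direct matrix calculus gives
`dE/dB = -2 [int_0^tf exp(A't) W^{-1} C W^{-1} exp(At) dt] B` with
`C = exp(A tf) Sigma0 exp(A' tf)`. A published form of this gradient chains
an extra minus sign in a way that is internally inconsistent with the cost
it differentiates; `grad_cost()` therefore returns the derivative computed
from first principles, validated against central finite differences to 1e-4
relative error, and `opgm()` always steps in the direction that decreases
the cost.

**OPGM.** The update is the projected step
`Bhat = B - eta (I - BB') dE/dB` followed by the exact trace rescaling
`B <- sqrt(tr(Bhat'Bhat) / tr((Bhat'Bhat)^2)) Bhat`, which restores
`tr((B'B)^2) = tr(B'B)` identically (checked to 1e-10 per iterate). With
`M = N` and identity initialization the projector vanishes and the iterate
is a fixed point. Initialization is a seeded random matrix with
orthonormalized columns; the learning step `eta` must be small relative to
the gradient scale, which varies enormously with topology: on a 3-node stem
at `tf = 1` costs are O(10) and `eta = 1e-4` descends monotonically, while a
4-node circle with one input has cost O(10^6) and needs `eta = 1e-8`.
Divergence (cost increasing for `patience` consecutive iterates) stops the
run with a suggestion to shrink `eta`.

**Precision and the numerical controllability transition.** Everything runs
in double precision. The Gramian's smallest eigenvalue decays roughly like
`(tf^g / g!)^2` in the longest graph distance `g` from an input, so
long uncontrolled stretches make `W_B` numerically singular even when the
system is structurally controllable. The package flags this rather than
papering over it: `ctrl_gramian()` warns below a reciprocal condition number
of 1e-12, `expected_cost()` can return `Inf`/`NA` sentinels on solve
failure, and `cost_vs_longest_path()` reports `NA` for layouts whose Gramian
has `rcond < 1e-14`. Arbitrary-precision arithmetic would extend the
reachable regime (the original circle experiment at 100 nodes used 130
significant digits); within this package the circle experiments are sized at
20 nodes instead.

**Horizon choices.** `tf = 1` is the package default (no canonical value is
printed anywhere). For the circle experiment `cost_vs_longest_path()`
defaults to `tf = n/4`: with `n = 20` and segments up to 19 edges,
`tf = 5` keeps `(tf^g / g!)^2` above the double-precision floor for most
random layouts while preserving the strong growth of cost with the longest
segment (costs rank-correlate with the longest segment at Spearman rho
~0.99 across mixed layouts with 2–10 inputs). In the MLCP-versus-random
comparison the win-rate experiment runs at the stated sparse setting (ER,
`N = 100`, mean degree 2, `m0 = 10`, `tf = 1`, 50 seeds). The gap-shrink
comparison toward mean degree 6 uses `m0 = 30` at both densities: with only
`m0 = 10`, the ~12 total inputs on a dense 100-node ER network sit below the
numerical controllability transition and every cost overflows double
precision — the regime MLCP is explicitly meant to stay beyond.

## Synthetic generators

The generators emulate the validation topologies: directed ER with edge
probability `mu/(N-1)`; directed preferential attachment (each new node
sends `m` out-edges to targets drawn proportionally to in-degree + 1 — one
standard directed variant, chosen and fixed here with `m` exposed);
configuration models drawing in/out degree sequences i.i.d. from
Chi-squared (df 2), Weibull (shape 1.5) or Gamma (shape 2) laws rescaled to
mean `mu` (shape defaults are package choices; no canonical values exist),
rounded, balanced by random unit increments, and realized by random stub
pairing with duplicates collapsed. Realized mean degrees land within 10% of
`mu` at `N = 2000`. Stems, circles and dilations are built exactly;
`make_dilation()` is parameterized because the exact 5-node dilation used in
the published basin-of-attraction percentages is shown only graphically, so
those percentages are reproduced qualitatively (two basins) rather than
numerically.

What the generators do *not* emulate: degree correlations, community
structure, edge weights other than 1, and temporal change. Passing tests on
these ensembles therefore says nothing about, e.g., assortative regulatory
networks with heterogeneous interaction strengths; LM itself is purely
structural, so only the energy-stage conclusions depend on weights.

## Problem sizes

The test suite runs LM/MM comparisons on 100 graphs up to `N = 500`, the
driver-statistics pooling on 20 ER graphs at `N = 1000`, energy oracles up
to `n = 8`, circle experiments at `n = 20`, and the MLCP/RAM comparison on
ER at `N = 100` over 50 seeds — sizes chosen so the whole suite completes in
about two minutes while every qualitative regime (sparse/dense, path/circle,
below/above the controllability transition) is represented.
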