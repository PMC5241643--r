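---
title: "Multiscale linear optimization with dqqlp: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale linear optimization with dqqlp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dqqlp)
```

## The problem

Flux balance analysis (FBA) of a biochemical network with stoichiometric
matrix $S \in \mathbb{R}^{m \times n}$ is the linear optimization problem

$$\min_v \; c^\top v \quad \text{s.t.} \quad S v = b, \qquad l \le v \le u,$$

with $b = 0$ at steady state.  Integrated metabolism-and-expression (ME)
models couple metabolic fluxes (mmol/gDW/h scale) to macromolecular
synthesis fluxes (nmol/gDW/h scale and below) through coupling constraints
on flux ratios.  The resulting LPs are *multiscale*: matrix entries
routinely span 6-12 orders of magnitude and biochemically meaningful
solution values range from $10^{-10}$ to $10^{8}$.  A conventional
double-precision simplex solver on such data may return solutions whose
unscaled primal or dual infeasibilities are large, report false
infeasibility, or lose every significant digit of the objective.

`dqqlp` addresses this with one precision-generic revised primal simplex
engine instantiated in two arithmetics -- IEEE double (about 16 digits)
and `__float128` quadruple precision (about 34 digits) -- plus a
compensated double-quad ("qd") context of roughly 68 digits used for every
certification quantity, high-precision residual, and planted-solution
check.

## The three-step pipeline

`run_dqq()` executes:

* **Step D** — double precision, geometric-mean scaling, feasibility and
  optimality tolerances $\delta_1 = \delta_2 = 10^{-7}$, tight LU
  tolerances (1.9).  Cheap; does the bulk of the pivoting.
* **Step Q1** — quad precision, scaling on, $\delta = 10^{-15}$, LU
  tolerances 10.0, warm-started from D's final basis.  Statuses are
  carried over verbatim and the basic values are *recomputed* in quad from
  the refactorized basis rather than copied, so no double rounding is
  embedded in the quad iterate.
* **Step Q2** — quad precision, *no* scaling, $\delta = 10^{-15}$, LU
  tolerances 5.0, warm-started from Q1.  This is the insurance step: it
  guarantees the tolerances hold on the original, unscaled data, because
  unscaling an approximately feasible point can inflate its residuals
  (demonstrated in the test suite on iid ill-scaled data).

Every reported Pinf (largest violation of row activities beyond their
sense, and of bounds) and Dinf (largest reduced-cost sign violation given
each variable's basis status, slacks included) is recomputed in the qd
context on the original data, never taken from the solver's internal
scaled-space bookkeeping.  `certify()` renders the conventional log10
table cells, with an em-dash for an exact zero.

Step D runs under an iteration limit, by default $5(m+n)$: when double
arithmetic is failing, spending unbounded effort in D is wasted because Q1
recovers from any starting basis.  A step-D infeasibility claim is never
reported directly; it is re-verified by a quad phase-1 solve first.

## The simplex engine

The engine is a textbook-faithful revised primal simplex with:

* **Sparse LU with threshold pivoting.**  A pivot is admissible when
  $|p| \ge \text{colmax}/\text{lu\_factor\_tol}$; among admissible
  candidates the sparsest row wins (Markowitz-style tie-break by
  magnitude).  Columns whose best pivot falls below
  $\varepsilon^{2/3}$ relative to the column norm are reported *dependent*
  rather than raising an error.
* **Basis repair.**  Dependent basic columns are replaced by the slack
  unit column of the failing pivot's row (another row's nonbasic slack if
  that one is basic); the displaced variable leaves at its nearer bound.
  The threshold $\varepsilon^{2/3}$ is this package's stand-in for an
  unpublished constant: it makes near-singularity precision-relative, so
  bases that look singular in double are clean in quad.
* **Bartels–Golub updates.**  Column replacement inserts the spike at the
  last position and eliminates the Hessenberg subdiagonals with threshold
  row interchanges governed by `lu_update_tol`; the factors are rebuilt
  from scratch every `refactor_frequency` iterations (default 100) or on
  an update's singularity signal.
* **Wilkinson iterative refinement** on each basis solve: the residual is
  evaluated in qd and a correction solved with the existing factors
  (`refine_passes`, default 1).
* **EXPAND anti-degeneracy.**  The working feasibility tolerance starts at
  $\delta_1/2$ and grows by $(\delta_1 - \delta_1/2)/K$ per iteration
  ($K$ = `expand_frequency`); the two-pass ratio test picks, among
  candidates blocking within the expanded step, the one with the largest
  pivot, and enforces a positive minimum step — so ties at a degenerate
  vertex cannot produce a zero-progress cycle.  Every $K$ iterations the
  tolerance resets and the basic values are recomputed.  With
  `expand = FALSE` the engine deliberately reverts to the classic
  smallest-ratio / lowest-index rule, which cycles on the canonical 3x7
  degenerate instance that `generate_degenerate_lp(level >= 0.75)` embeds;
  the contrast is part of the test suite.
* **Phase 1** minimizes the sum of bound infeasibilities with the same
  machinery (basic-variable costs $\pm 1$ by violation side); an
  infeasible verdict is accepted only after a fresh refactorization
  confirms it at the strict tolerance.
* **Pricing** is full Dantzig (most negative reduced cost, lowest index on
  ties), giving bit-reproducible runs.  Steepest edge is out of scope; the
  option slot is reserved.
* **Tolerances are relative** with the $(1+\|\cdot\|_\infty)$ convention,
  per-variable for bounds.  This matters on multiscale data, where an
  absolute $10^{-15}$ on a bound of magnitude $10^{8}$ would be
  unattainable in any finite precision.

All engine arithmetic flows through the selected type; there are no
hidden double shortcuts in the quad path.  Data enter the quad engine as
hi/lo double pairs added exactly, so problems can carry more than 16
digits (`read_mps(..., precision = "quad")` parses numeric fields with
`strtoflt128`).

## Scaling

`compute_scales()` is MINOS-style geometric-mean equilibration: each pass
replaces every row scale by $\sqrt{\max |a| \cdot \min |a|}$ over the
row's scaled entries, then columns likewise, stopping when a pass shrinks
the spread by a factor above 0.9 (a configurable constant chosen here; the
classical literature leaves it open) or after `max_passes = 10`.  Scales
are rounded to the nearest power of two **in both precisions**: scaling
and unscaling are then exact in binary floating point, the scaled
problem's data carry no scaling-induced rounding, and the Q2 step sees the
original data bit-for-bit.  The cost is at most a factor 2 of residual
equilibration quality, which the pass criterion absorbs.  (An earlier
design rounded only the double path; exactness in the quad path proved
more valuable than the marginal spread improvement.)

## The zoom strategy

`zoom_refine()` drives an ordinary fixed-precision solver far beyond its
native accuracy.  Given an incumbent $(x_1, y_1)$ with residuals
$r_1 = b - A x_1$ and $d_1 = c - A^\top y_1$ computed in qd, one round
solves the *zoomed* problem

$$\min_{\hat x} \; \sigma d_1^\top \hat x \quad \text{s.t.} \quad
A \hat x = \sigma r_1, \qquad \sigma(l - x_1) \le \hat x \le \sigma(u - x_1),$$

warm-started from the incumbent basis, with
$\sigma = 1/\max(\|r_1\|_\infty, \|d_1\|_{B,\infty})$ rounded to a power
of two (and floored, so an already-exact incumbent does not overflow it).
The corrected point is $x = x_1 + \hat x/\sigma$, $y = y_1 + \hat
y/\sigma$, accumulated in hi/lo pairs.  Scaling the zoomed *objective* by
$\sigma$ as well is this package's resolution of an ambiguity in the
formulation: it makes the primal and dual corrections share the same
$1/\sigma$ unzoom, and the geometric round-to-round contraction of
$\max(\text{Pinf}, \text{Dinf})$ asserted in the tests validates the
choice.  Residuals are evaluated in the fixed qd context (~68 digits,
i.e. more than twice the digits of any iterate stored in hi/lo pairs),
which supports targets down to about $10^{-30}$ — the regime the package
aims at; rational arithmetic is deliberately not used.

## The ME formulation layer

* `add_coupling_constraints()` turns a ratio bound
  $c_{\min} \le v_i/v_j \le c_{\max}$ on nonnegative fluxes into the
  linear pair $v_i - c_{\max} v_j \le 0$, $-v_i + c_{\min} v_j \le 0$
  (second row omitted when $c_{\min} = 0$); a $(i, j, k_{\text{eff}})$
  triple yields $c_{\max} = \mu/k_{\text{eff}}$.
* `lift_large_coefficients()` shrinks entries above a threshold $\tau$ by
  the auxiliary substitution $w = K_1 v_j$ with $K = K_1 K_2$,
  $K_1 = 2^{\mathrm{round}(\log_2 K / 2)}$.  A balanced *power-of-two*
  split is used instead of $\sqrt{K}$: the product reconstitutes $K$
  exactly in floating point, so lifted and original problems have
  *identical* optimal objectives, not merely close ones — the testable
  form of the equivalence that motivates lifting.
* `consistency_check()` screens for stoichiometric consistency (existence
  of strictly positive molecular masses $\ell$ with $S^\top \ell = 0$) via
  the linear relaxation: maximize $\sum_i z_i$ subject to
  $S^\top \ell = 0$, $z \le \ell$, $0 \le z \le \alpha$,
  $0 \le \ell \le \beta$ (defaults $\alpha = 10^{-4}$, $\beta = 10^{4}$,
  proportional to the smallest/largest admissible molecular mass).  Rows
  with $\ell_i < \alpha$ at the optimum are flagged.  Whether the original
  cardinality problem maximizes the consistent set or minimizes its
  complement is not decidable from the available description; this
  relaxation is the standard cardinality surrogate and is validated
  against hand-checkable networks in the tests.
* `flux_variability()` minimizes and maximizes each requested flux under
  the near-optimality row ($c^\top v \ge \gamma Z_0$ for maximization with
  $Z_0 \ge 0$; $Z_0/\gamma$ when $Z_0 < 0$, mirrored for minimization, so
  the restriction always contains the incumbent optimum and interval
  widths are monotone in $\gamma$), warm-starting each solve from the
  previous basis, min-then-max in ascending index order to maximize basis
  adjacency.
* `max_growth_bisection()` locates the growth-rate feasibility boundary
  $\mu^*$ of a $\mu$-parameterized family by bisection with warm-started
  quad phase-1 solves.  Feasibility is assumed monotone in $\mu$, and both
  orientations are accepted: physically, growth-rate-coupled dilution
  makes *higher* $\mu$ harder (largest feasible $\mu$ is returned), but
  capacity-style couplings relax with $\mu$, and the boundary is then the
  smallest feasible $\mu$.  A continuous interval with tolerance
  `tol_mu` generalizes a discrete grid search (pass grid points as the
  interval endpoints to recover it).

## Synthetic instances: what they emulate, and what not

`generate_multiscale_lp()` draws entry exponents as
$e_{ij} = \rho_i + \gamma_j + \eta_{ij}$ (row scale, column scale, small
jitter) and planted flux exponents as $f_j = -\gamma_j + \phi_j - 4$.
This reproduces the structure of real ME matrices — magnitudes are
attached to *species and reaction units* (large molecular compositions in
macromolecule rows, small inverse rate constants), not sprinkled iid —
while the defaults realize 12 decades of coefficient spread and 18 decades
of planted flux magnitudes ($\sim 10^{-10}$ to $10^{8}$).  All data and
planted values are signed powers of two with per-row activity spans below
106 bits, so each row activity $\,(S v^0)_i$ is *exactly* representable in
a hi/lo double pair; the generator stores the low half in `rhs_lo`, and
the planted point's residual is exactly zero even at 68-digit precision.
The steady-state variant adds one balancing column per row so that
$b = 0$ holds with the same exactness.  Row support is capped at 16
nonzeros — typical of sparse stoichiometries — to keep the span bound.

`generate_me_like_model()` adds the ME block structure explicitly:
an integer-stoichiometry metabolic block with $O(1)$ fluxes, macromolecule
rows balancing $2^{e} v_{\text{syn}} = v_{\text{dil}}$ with synthesis
fluxes down to $2^{-34}$, and coupling rows with
$k_{\text{eff}}$ drawn around $2.34 \times 10^{5}\,\mathrm{h}^{-1}$, the
magnitude typical of effective catalytic rate constants.

What the generators deliberately do **not** reproduce: degenerate
alternate optima of curated reconstructions, correlated objective
structure (biomass compositions), rational non-power-of-two
stoichiometry, and genome-scale dimensions.  Passing the synthetic suite
therefore demonstrates numerical behavior (certification, warm-start
economy, anti-degeneracy, refinement contraction) on desk-scale
multiscale structure, not biological fidelity or wall-clock performance
at $m \sim 70{,}000$.

Degeneracy is covered by `generate_degenerate_lp()`: at moderate levels a
random integer problem with a known unique optimum whose basis contains
the requested fraction of zero-valued variables; at levels $\ge 0.75$ the
classic cycling-prone core plus inert padding rows pinned at their bounds.
An infeasible family tightens the bounds on one row's support until the
row's attainable activity falls short of its right-hand side by a
recorded margin — a certificate carried with the instance.

Randomness: each generator seeds R's RNG once and draws in a fixed
documented order, which gives the required guarantee (bit-identical
instances for identical spec and seed) without a separate counter-based
stream.

## Numerical choices and degenerate inputs

* Infinity threshold $10^{30}$ in MPS bounds (conventional practice).
* Fixed-dialect MPS values are printed with the most digits that fit the
  12-character field; the free dialect prints 17 significant digits and
  round-trips doubles exactly.
* Empty constraint matrices skip scaling; explicit zero entries are
  dropped at construction.
* Degenerate steps are counted whenever the step length does not exceed
  the EXPAND increment; the count is reported because a large fraction of
  zero-progress iterations is the signature of the degenerate instances
  this solver targets.
* Problem sizes in the default test run: 200 oracle-checked LPs at
  $m+n = 10$; a 50-instance multiscale suite up to $80 \times 120$;
  refinement and formulation checks at $m \le 40$.  These sizes make the
  whole suite run in about a minute while exercising every code path; the
  engine itself is $O(m^2)$ per iteration with dense LU storage, adequate
  for desk-scale models (hundreds of rows), not genome scale.

## Known limitations

* The simplex is primal-only with Dantzig pricing; no dual simplex, no
  steepest edge, no presolve.
* LU working storage is dense ($m \times m$), so very large bases are out
  of reach; the *sparse* part of the design is pivot selection, not
  storage.
* Precision does not escalate beyond quad for solves (the qd context is
  used only for residuals and certification); optima are certified to
  $10^{-15}$ with observed surplus to $\sim 10^{-30}$, not to arbitrary
  accuracy.
* MILP constructs in MPS files (MARKER sections, integer bounds) are
  rejected.
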