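# dqqlp — multiscale linear optimization with a Double→Quad→Quad simplex pipeline

Genome-scale models that integrate metabolism with macromolecular
expression (ME models) lead to flux balance problems

```
min cᵀv   s.t.   S v = b,   l ≤ v ≤ u
```

whose data and solutions are *multiscale*: stoichiometric and coupling
coefficients span many orders of magnitude, and biochemically meaningful
fluxes range from ~1e-10 (transcription/translation) to ~1e8.  Standard
double-precision LP solvers on such instances can return badly infeasible
"optima", report false infeasibility, or lose every significant digit of
the objective, while exact rational solvers are orders of magnitude too
slow without a near-optimal warm start.

`dqqlp` is for modelers and numerical-optimization developers who need
*certified* solutions of such problems.  It implements one
precision-generic revised primal simplex engine — sparse LU with threshold
pivoting, Bartels–Golub updates, basis repair, Wilkinson iterative
refinement, EXPAND anti-degeneracy — compiled in both IEEE double and
`__float128` quadruple precision, and drives it with a three-step
procedure:

| step | precision | scaling | feas/opt tol | LU factor/update tol |
|------|-----------|---------|--------------|----------------------|
| D    | double    | yes     | 1e-7         | 1.9 / 1.9            |
| Q1   | quad      | yes     | 1e-15        | 10.0 / 10.0          |
| Q2   | quad      | no      | 1e-15        | 5.0 / 5.0            |

Step D does the bulk of the pivoting cheaply; Q1 warm-starts quad from
D's basis; Q2 re-solves without scaling so the 1e-15 tolerances provably
hold on the *original* data (unscaling alone can inflate residuals).  The
final maximum primal and dual infeasibilities (Pinf, Dinf) are certified
in ~68-digit compensated arithmetic.

Around the solver the package provides the ME formulation layer —
flux-ratio coupling constraints, exact power-of-two coefficient lifting,
stoichiometric-consistency screening, flux variability analysis (FVA)
with warm starts, growth-rate bisection — a zoom refinement strategy that
pushes a plain double solver to ~1e-30 accuracy, MPS fixed/free-format
I/O (with an optional 34-digit parse path), and seeded generators of
multiscale, ME-like, degenerate, and infeasible test instances whose
planted feasible points satisfy their constraints *exactly*.

## A worked example

Generate a 60×80 instance whose coefficients span 12 decades and whose
planted fluxes span 18 decades, then solve it with the pipeline:

```r
library(dqqlp)
gen <- generate_multiscale_lp(synthetic_spec(m = 60, n = 80, seed = 7))
problem_stats(gen$problem)
#> m=60 n=80 nnz=360 max|S_ij|=1.049e+06 min|S_ij|=9.537e-07 (12.0 decades)
rep <- run_dqq(gen$problem)
rep
#> DQQ procedure: optimal, final objective -52075585.2003
#>   step itns time objective Pinf Dinf
#> 1    D  495 0.23 -52075585  -13   -6
#> 2   Q1    0 0.01 -52075585  -30  -22
#> 3   Q2    0 0.01 -52075585  -30  -22
```

Reading the table: step D needed 495 simplex iterations and left a dual
infeasibility of order 1e-6 on the original data; the warm-started quad
steps needed **zero** further pivots and certify Pinf ≈ 1e-30,
Dinf ≈ 1e-22 — far below the requested 1e-15 (the cells are log10 values;
`—` would mean an exact zero).  `rep$v`, `rep$y`, `rep$z` hold the primal,
dual and reduced-cost vectors with low-order halves (`rep$v_lo`, ...)
carrying digits beyond double.

The same engine powers the formulation layer, e.g.

```r
fva <- flux_variability(gen$problem, gamma = 0.99, indices = 1:5)
mu  <- max_growth_bisection(planted_growth_builder(234000, 1e-6, 1)$builder,
                            0.001, 10, tol_mu = 1e-6)   # mu* = 0.234
```

and a command-line wrapper is installed at `inst/cli/dqq`:

```sh
Rscript inst/cli/dqq solve model.mps --table
Rscript inst/cli/dqq generate --kind me --seed 3 -o me.mps
```

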