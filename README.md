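# acwave

Symbolic and numerical toolkit for the **bistable Allen–Cahn equation
with quartic potential**, used as a model of microbial biofilm density
on a surface:

```
M_t − d (M_xx + M_yy) + γ M³ − γ(1+σ) M² + γσ M = 0,
```

with diffusion coefficient `d > 0`, growth rate `γ > 0` and survival
parameter `σ ∈ [0, 1]`.  The reaction factors as `γ M (M − 1)(M − σ)`:
the states 0 and 1 are stable, σ is the unstable threshold, and
travelling fronts connect pairs of these equilibria.

The package is for researchers in nonlinear waves and mathematical
biology who want the full analysis pipeline of this equation as tested,
reproducible code rather than one-off computer-algebra sessions:

* **Lie point symmetries** — second prolongation, determining equations,
  exact rational nullspace solving, generator basis
  `{∂t, ∂x, ∂y, y∂x − x∂y}` and the commutator table (antisymmetry,
  closure and Jacobi checked on construction).  A built-in exact
  polynomial/rational-function kernel does all of this without an
  external computer-algebra system.
* **Similarity and travelling-wave reductions** — with a provenance tag
  on every object: reductions obtained by exact substitution are
  `faithful`; published chains that are not are kept `as_printed` and
  audited, with the exact leftover reported.
* **Three expansion methods** — generalized auxiliary equation
  `(ς′)² = b₁ς² + b₂ς³ + b₃ς⁴`, modified (G′/G²) expansion
  `H′ = τ + κH²`, and extended modified tanh `ς′ = κ + ς²`: homogeneous
  balance, exact construction of the coefficient systems, a
  branch-complete structured solver, closed-form solution assembly, and
  numeric profile classification (kink, anti-kink, bright, dark,
  periodic, singular, rational).
* **Audit of published results** — the seven published parameter sets
  are stored verbatim and back-substituted: some verify exactly, the
  (G′/G²)/tanh sets carry a factor `σ²+6σ+1` where the exact solution
  requires `(σ−1)²` (they agree at σ = 0), and one set has a missing
  factor 3; nothing is silently repaired.
* **Finite-difference cross-check** — a 1-D simulator (central
  differences, Neumann walls, fixed-step RK4) launches the derived
  closed-form kink and confirms unit front speed and the σ–1 connection.

## Worked example

```r
library(acwave)

## symmetry algebra of the equation with symbolic d, gamma, sigma
sol <- solve_determining(determining_equations(bac_model()))
sol
#> Symmetry algebra: 4 free constants
#> General infinitesimals:
#>   chi1 = C1
#>   chi2 = C2 + C4 * -y
#>   chi3 = C3 + C4 * x
#>   phi = 0

commutator_table(generator_basis())
#>    X1 X2 X3  X4
#> X1 0  0  0   0
#> X2 0  0  0   -X3
#> X3 0  0  0   X2
#> X4 0  X3 -X2 0

## tanh expansion on the diagonal travelling-wave reduction
sys <- build_algebraic_system(paper_odes()[["28"]], "tanh")
sets <- solve_parameter_sets(sys)
sets$sets[[3]]
#> Parameter set [tanh, derived, branch: b1=0; a0 = (sigma+1)/2]
#>   gamma = 1/(d + 2 * (d * sigma) + d * sigma^2)
#>   a1 = -2 * d + -2 * (d * sigma)
#>   kappa = (1/16 + -1/16 * sigma + ... )/(-d^2 + -3 * (d^2 * sigma) + ...)
#>   a0 = 1/2 + 1/2 * sigma
#>   b1 = 0

## the kink this set assembles runs at unit speed in the simulator
k <- kink_front_check(d = 0.5, sigma = 0.3)
round(k$speed, 4)
#> [1] 1.0006
```

The third set is the exact single-tanh kink family: `γ = 1/(d(σ+1)²)`,
`a₁ = −2d(σ+1)`, `κ = −(σ−1)²/(16d²(σ+1)²)` — the profile
`u = (σ+1)/2 + ((1−σ)/2)·tanh(w r)` connecting σ to 1.  The front-speed
numbers say the simulated front moves at speed 1.0006 (exact value 1,
the travelling variable is `r = t − x`) and reaches the equilibria at
the domain ends to within 5·10⁻¹¹.

The methods vignette (`vignettes/biofilm-allen-cahn-waves.Rmd`) explains
the model, the solver design, the published-set audit and the
classification rules in detail.

## Command line

```sh
Rscript inst/cli/acwave.R symmetries
Rscript inst/cli/acwave.R solve --method tanh --ode 28
Rscript inst/cli/acwave.R simulate --d 0.5 --sigma 0.3
Rscript inst/cli/acwave.R report
```
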