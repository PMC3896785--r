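# kinmotif

Global profiling of kinetic parameters in adaptive enzyme networks.

Small enzyme circuits can show *perfect adaptation*: after a persistent
step in their input they respond transiently and then return to the
pre-stimulus output. The canonical example is *E. coli* chemotaxis, whose
machinery matches a three-node negative-feedback circuit (NFBLB: the
receptor complex A activates the buffer B and the output C; B feeds back
to deactivate A). Whether a particular instance of the circuit adapts
depends on its twelve Michaelis–Menten constants, and `kinmotif` is a tool
for asking **which parameter values the dynamics demand**. It is aimed at
systems biologists who want to go beyond "some parameter sets work" to a
statistical map of *where* in parameter space they work and *which part of
the dynamics* each parameter serves.

## The method

1. **Sample** `n` parameter sets by Latin hypercube on the log10 scale
   (`k` in [1e-1, 1e1], `K` in [1e-3, 1e2]).
2. **Screen** each set through the rate equations
   `dn/dt = Σ E·k·(1−n)/((1−n)+K) − Σ E·k·n/(n+K)` with a 0.5 → 0.6 input
   step, discard pathological trajectories, and score

   *sensitivity* = (|Op−O1|/O1) / (|I2−I1|/I1),
   *precision* = ((|O2−O1|/O1) / (|I2−I1|/I1))⁻¹,

   calling a set a **kinetic solution** when sensitivity > 1 and
   precision > 10 (equivalently: ≥ 20% peak excursion, ≤ 2% residual
   shift).
3. **Enrich**: bin values into decade classes and test each class for
   over-representation among solutions with a strict-tail hypergeometric
   test, `p = P(X > x)` for `X ~ Hypergeom(N, y, M)`; classes with
   `p < 1e-3` form the parameter's **kinetic motif**.
4. **Associate**: Mann–Whitney rank tests (z > 3.29) link each motif to
   the sensitivity and/or precision phase, giving a bipartite
   motif–functionality network; Pearson tests on the solution sets reveal
   cooperating parameter pairs.

## Worked example

Simulate one parameter set through the adaptation assay:

```r
library(kinmotif)
model <- build_nfblb_model()
params <- setNames(rep(1, 12), model$param_names)
resp <- simulate_step_response(model, params)
glance(resp)
#> # A tibble: 1 × 6
#>      O1    Op    O2 settle_time sensitivity precision
#>   <dbl> <dbl> <dbl>       <dbl>       <dbl>     <dbl>
#> 1   0.5 0.532 0.532        13.5       0.325      3.11
classify_outcome(resp)
#> [1] "OK"
```

The all-ones system starts at the symmetric steady state `O1 = 0.5`, rises
monotonically to `0.532` (so the peak equals the plateau), and settles in
about 13 time units. Its sensitivity (0.325) and precision (3.11) both
fall short of the solution criteria — it responds weakly and adapts
poorly, which is the typical fate of a random parameter set.

The statistical layer can be exercised without any ODE runs via the
synthetic fixture generator, here with motifs planted in `k_FBB` (class 3)
and `K_BA` (class 1) and a precision-score shift attached to both:

```r
fx <- generate_fixture(n = 20000, m = 74,
                       planted = c(k_FBB = 3, K_BA = 1),
                       planting_fraction = 0.85,
                       shift_precision = c(0.4, 0.4), seed = 2024)
motifs <- detect_motifs(enrich_classes(fx))
motifs
#> # A tibble: 2 × 3
#>   parameter classes   interval
#>   <chr>     <list>    <chr>
#> 1 K_BA      <int [1]> [1e-03,1e-02]
#> 2 k_FBB     <int [1]> [1e-01,1e+00]
tidy(associate_functions(fx, motifs))[, c("parameter", "motif",
                                          "z_precision", "functions")]
#> # A tibble: 2 × 4
#>   parameter motif         z_precision functions
#>   <chr>     <chr>               <dbl> <chr>
#> 1 K_BA      [1e-03,1e-02]        22.6 PR
#> 2 k_FBB     [1e-01,1e+00]        25.8 PR
```

Both planted motifs are recovered exactly, and the planted precision shift
is detected as a `PR` label with z-scores far above the 3.29 cutoff.

A complete screen is one call (minutes at `n = 1e5` thanks to the compiled
rate function), or one shell command via the bundled CLI:

```r
res <- run_pipeline(run_config(n_samples = 1e5, seed = 1, out_dir = "out"))
```

```sh
inst/scripts/kinmotif run-all --n 100000 --seed 1 --out out
```

which writes `parameters.csv`, `outcomes.csv`, `enrichment.csv`,
`motifs.json`, `association.csv`, `correlations.csv`, the bipartite
network (GraphML + JSON) and a run summary.

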