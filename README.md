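# dyadkin

Population-epigenetic modeling of global DNA demethylation at CpG dyad
resolution.

When mouse embryonic stem cells are switched from serum ("primed") to
2i ("naive") culture — and likewise in preimplantation embryos and
migratory primordial germ cells — the genome loses most of its
5-methylcytosine (5mC) over days. `dyadkin` is for quantitative
epigeneticists who want to ask *which pathway does it*: failing
maintenance methylation after replication (DNMT1/UHRF1), loss of de
novo methylation (DNMT3A/B), or TET-driven oxidation of 5mC to
5-hydroxymethylcytosine (5hmC) followed by replication dilution.

## The model

The population state is the distribution of CpG dyads over the six
unordered strand-pair states `uu, um, mm, uh, mh, hh` (u = unmodified,
m = 5mC, h = 5hmC). Each average cell division applies oxidation
(each m strand → h with probability *p₃*), semiconservative
replication (each dyad pairs one parent strand with a nascent
unmodified strand), maintenance (post-replication (m,u) → (m,m) with
probability *p₂*; (h,u) is never maintained), and de novo methylation
((u,u) → (m,u) with probability *p₁*, optionally relaxing over time as
DNMT3A/B decay).

For the strand-level fractions f (5mC) and h (5hmC) this induces the
exact per-division recursion

    f' = [ f (1 − p₃)(1 + p₂) + (1 − f − h) p₁ ] / 2
    h' = [ h + f p₃ ] / 2

with closed-form steady state f\* = p₁ / (2 − (1−p₃)(1+p₂) + p₁(1+p₃)),
h\* = p₃ f\*. Special cases used throughout the tests: with all rates
zero, 5mC exactly halves per division; with p₁ = p₃ = 0 the
per-division ratio is (1+p₂)/2.

On top of the model the package provides MMSE grid-search fitting with
error-surface export, R² reporting and local-minima (identifiability)
analysis; knockout and vitamin-C scenario predictions; and synthetic
generators for LC-MS-like global time courses, hairpin-bisulfite dyad
count tables, and a stochastic per-dyad simulator used as a
brute-force oracle.

## Worked example

Simulate the serum→2i conversion under the default study conditions,
then refit the free 2i parameters from a noisy synthetic course:

```r
library(dyadkin)

serum <- serum_params()          # p1 = 0.40, p2 = 0.90, p3 = 0.02
init  <- steady_state_dyads(serum)
print(init)
#> CpG dyad state (population fractions)
#>       uu       um       mm       uh       mh       hh
#> 0.151648 0.172894 0.646154 0.029304 0.000000 0.000000
#> strand 5mC = 0.7326, strand 5hmC = 0.0147

tr <- predict_scenario(init, serum, two_i_params(), scenario_spec(),
                       times = c(0, 24, 48, 96, 168, 336))
tr$levels
#>   time_h   five_mC    five_hmC
#> 1      0 0.7326007 0.014652015
#> 2     24 0.6251661 0.027474817
#> 3     48 0.5269890 0.029424515
#> 4     96 0.3694169 0.023227565
#> 5    168 0.2296461 0.014215572
#> 6    336 0.1390411 0.007295232

obs <- generate_timecourse(serum, two_i_params(),
                           times = c(0, 4, 8, 16, 24, 32, 48, 72, 96,
                                     168, 240, 336),
                           noise = noise_model(sd = 0.01, seed = 7))
fit <- grid_search(obs, init,
                   fit_spec(c("p1_final", "p2"), base = two_i_params(),
                            grid_n = 41L))
print(fit)
#> MMSE fit
#>   best: rates per division: p1 = 0.4 -> 0.0629805 (t1/2 = 24 h),
#>         p2 = 0.74267, p3 = 0.05 (T = 16 h)
#>   mmse = 0.000102138, R^2 = 0.9975, 1 local minimum on the grid
```

The trajectory shows the canonical phenotype: 5mC falls from 0.73 to
0.14 (a fifth of the serum level) over 14 days while 5hmC transiently
doubles, peaking near 48 h; the refit recovers the generating 2i
parameters (p₂ = 0.75, p1_final = 0.05) to within the noise and
explains 99.8% of the variance.

The numbered scripts under `analysis/` run the full set of analyses —
conversion simulation, parameter-recovery benchmarks, knockout
predictions, and the vitamin-C / identifiability study — writing their
tables under `results/`:

```sh
Rscript analysis/01_simulate_conversion.R
Rscript analysis/02_parameter_recovery.R
Rscript analysis/03_knockout_scenarios.R
Rscript analysis/04_vitc_and_degeneracy.R
```

The methods vignette (`vignettes/methylation-kinetics.Rmd`) documents
the model assumptions, parameter defaults, fitting and identifiability
behavior, and the limits of the synthetic-data generators.

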