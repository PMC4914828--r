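---
title: "Modeling global DNA demethylation at CpG dyad resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling global DNA demethylation at CpG dyad resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadkin)
```

## The model

When mouse embryonic stem cells move from serum ("primed") to 2i
("naive") culture, they lose most of their genomic 5-methylcytosine
(5mC) within about two weeks. Three enzymatic pathways could explain
the loss: failure of maintenance methylation after replication
(DNMT1/UHRF1), loss of de novo methylation (DNMT3A/B), and active
oxidation of 5mC to 5-hydroxymethylcytosine (5hmC) by the TET enzymes,
followed by replication dilution. `dyadkin` implements a discrete-
generation population model that separates these contributions and
supports fitting them to global time-course measurements.

The state of the population is the distribution of CpG *dyads* — the
palindromic CpG/CpG pair on complementary strands, each cytosine
independently modifiable. With strand marks u (unmodified), m (5mC) and
h (5hmC), the six unordered dyad states are `uu`, `um`, `mm`, `uh`,
`mh`, `hh` (`dyad_state()`). Each average cell division applies, in
order:

1. **Oxidation** — every m strand becomes h with probability $p_3$;
2. **Replication** — every dyad is replaced by a daughter pairing one
   parent strand (drawn uniformly) with a nascent unmodified strand;
3. **Maintenance** — each post-replication hemi-methylated dyad (m,u)
   is restored to (m,m) with probability $p_2$; (h,u) dyads are never
   maintained, because UHRF1/DNMT1 recognize hemi-*methylated*, not
   hemi-hydroxymethylated, substrates;
4. **De novo** — each unmodified dyad (u,u) gains one methyl with
   probability $p_1$, producing (m,u).

$p_1$, $p_2$, $p_3$ are dimensionless proportions per average division,
directly proportional to the abundance/activity of the corresponding
machinery. Global strand-level fractions, the quantities measured by
LC-MS, are `five_mC` $= mm + \tfrac12 um + \tfrac12 mh$ and `five_hmC`
$= hh + \tfrac12 uh + \tfrac12 mh$ (`strand_summary()`).

Writing $f$ and $h$ for the strand 5mC and 5hmC fractions, the step
above induces the exact recursion

$$f' = \tfrac12\left[f(1-p_3)(1+p_2) + (1-f-h)\,p_1\right],
\qquad h' = \tfrac12\left[h + f p_3\right],$$

with fixed point

$$f^* = \frac{p_1}{2 - (1-p_3)(1+p_2) + p_1(1+p_3)}, \qquad
h^* = p_3 f^*.$$

`steady_state()` evaluates the closed form; the test suite verifies it
against long iteration of the full dyad-state step and against a
stochastic per-dyad Monte-Carlo simulator. Useful special cases: with
$p_1 = p_2 = p_3 = 0$, 5mC exactly halves per division (pure
replication dilution, the *Dnmt1/Uhrf1*-null limit); with
$p_1 = p_3 = 0$ the per-division ratio is $(1+p_2)/2$; with $p_3 = 0$,
$f^* = p_1 / (1 - p_2 + p_1)$.

## Parameters, defaults, and why

`rate_params()` carries $p_1$, $p_2$, $p_3$, the division time in
hours, and an optional gradual $p_1$ transition
$p_1(t) = p_{1,\infty} + (p_{1,0} - p_{1,\infty})\,2^{-t/t_{1/2}}$
(`p1_at()`), reflecting that de novo methyltransferases decay over a
few cell cycles after the switch rather than disappearing instantly.

The package defaults (`serum_params()`, `two_i_params()`) describe the
two culture conditions:

| parameter | serum | 2i | meaning |
|---|---|---|---|
| $p_1$ | 0.40 | 0.40 → 0.05, $t_{1/2}$ = 24 h | de novo methylation per division |
| $p_2$ | 0.90 | 0.75 | maintenance efficiency per division |
| $p_3$ | 0.02 | 0.05 | 5mC → 5hmC oxidation per division |
| division time | 16 h | 16 h | hours per average division |

These are the package's own declared study conditions, anchored to the
well-established quantitative features of the system: serum maintenance
efficiency of about 90%; a roughly 4-fold stimulation of TET activity
by vitamin C (`vitc_params()`); two rounds of replication in the first
~32 h (16 h division time); an 8-fold drop of de novo activity in the
naive state, consistent with strong DNMT3A/B downregulation; and a
hypomethylated steady state, at roughly a fifth of the serum 5mC
level, effectively reached by day 14. Under these defaults the serum
steady state sits at strand 5mC ≈ 0.73 with 5hmC ≈ 2% of 5mC, the
2i trajectory shows the characteristic fast-then-gradual decay, and
5hmC transiently rises about 2-fold, peaking near 48–72 h, before
diluting away.

Two modeling commitments deserve emphasis. First, the within-division
event order is fixed (oxidation → replication → maintenance → de novo)
so that $p_3$ acts on the pre-replication methylated pool; the
alternative (`event_order = "oxidize_last"` in `division_step()` and
`simulate_trajectory()`) is provided for sensitivity checks and
differs only when $p_3 > 0$. Second, 5hmC is never maintained and
never created on the nascent strand; it is lost purely by replication
dilution. Further oxidation (5fC/5caC) and base-excision repair are
deliberately out of scope — deaminase/glycosylase knockouts are encoded
as exact identities on the parameters (`scenario_spec("aicda_or_tdg")`),
which the tests enforce bitwise.

Between division boundaries, reported levels are linearly interpolated
(`simulate_trajectory()`): the measured population is unsynchronized,
so the population average moves smoothly between the boundary values;
linear interpolation is the simplest surrogate that introduces no new
parameters. A division in progress when a phase switches (e.g. medium
change) completes under the parameters of the phase in which it
started.

## Fitting

`grid_search()` minimizes the mean squared error (MMSE) between
predicted and observed global 5mC over an exhaustive Cartesian grid of
the free parameters (default 101 points per axis on [0, 1]), then
polishes the best grid point with bounded L-BFGS-B. The 5mC channel
alone enters the default objective; 5hmC is reserved as a held-out
prediction, because that is the discipline that makes the 5hmC
forecast a genuine validation. A joint 5mC+5hmC objective is available
(`fit_spec(channels = c("five_mC", "five_hmC"))`) and is what the
vitamin-C benchmark uses, since $p_3$ is only weakly visible in 5mC.

Determinism is guaranteed: ties among equal-MMSE grid points break
toward the lexicographically smallest $(p_1, p_2, p_3)$ tuple, and
identical inputs yield identical results. Scaling (`normalize_series()`,
`scale_mode`) is applied identically to data and prediction, and both
channels are divided by the same 5mC reference so their ratio is
preserved; $R^2$ is computed on the fitted scale. An all-flat surface
is flagged (`degenerate = TRUE`) rather than treated as an error.

The retained error surface supports identifiability diagnostics.
`find_local_minima()` reports every grid point not exceeded by any
axis-neighbor, merging grid-adjacent candidates and discarding flat
plateaus that leak downhill. On fast-decay series fitted on 5mC alone
with $p_2$ and $p_3$ both free, the objective is nearly constant along
the ridge $(1-p_3)(1+p_2) \approx \text{const}$: impaired maintenance
and strong oxidation remove 5mC at indistinguishable rates. Measurement
noise breaks the ridge into several discrete minima whose 5mC curves
agree within noise while their predicted 5hmC peaks differ several-fold
— the two-solution situation familiar from primordial-germ-cell
demethylation, where only 5hmC data (or orthogonal evidence such as
UHRF1 levels and hemi-methylation fractions) can discriminate impaired
maintenance from TET-driven demethylation. `analysis/04_vitc_and_degeneracy.R`
reproduces this situation end to end.

## Synthetic data

The generators in this package produce every input the pipeline
consumes, so the whole analysis is testable without external data.

* `generate_timecourse()` emulates LC-MS global quantification:
  the model trajectory plus i.i.d. Gaussian noise (default sd 0.01,
  i.e. one percentage point of level, a typical replicate spread for
  triplicate LC-MS), clipped at zero.
* `generate_hairpin_counts()` emulates hairpin-bisulfite sequencing,
  which reads both strands of each dyad: multinomial dyad sampling
  with per-strand misreads (a modified strand reads methylated with
  probability `conversion_rate`; an unmodified strand reads methylated
  with probability `nonconversion_rate`). Bisulfite chemistry cannot
  separate 5hmC from 5mC, so h strands read as methylated; TAB-seq-
  style 5hmC levels enter as a separate optional channel.
  `estimate_state_from_counts()` inverts the misread model by a 3×3
  moment correction (clipping negative components with a warning) and
  optionally re-apportions modified-strand mass to 5hmC given an
  external level.
* `stochastic_dyad_simulator()` follows individual dyads through the
  per-division Bernoulli events and is the brute-force oracle against
  which the deterministic expectation step is verified (3-standard-
  error agreement at 100,000 dyads).

All generators are pure functions of their inputs and a seed, and they
restore the caller's RNG state. What the synthetic data do **not**
emulate: locus heterogeneity (the model is global; real genomes mix
promoter classes, enhancers and repeats with very different kinetics),
replicate-correlated batch error, cell-cycle desynchronization beyond
linear interpolation, and coverage bias in hairpin libraries. Passing
the recovery benchmarks therefore demonstrates the estimator's
correctness under the declared noise model, not robustness to every
artifact of real measurements.

## Numerical choices

* Sum-to-one validation tolerance is 1e-9 for user-supplied dyad
  states; internal steps renormalize only floating-point drift
  (clipping negatives above −1e-12).
* Grid fitting evaluates the strand-level recursion vectorized over
  all grid points; the tests pin it to the full dyad-state step at
  1e-12.
* `steady_state_dyads()` iterates to a 1e-13 state tolerance; the
  closed form and the simulation agree to 1e-6 over random parameter
  sets.
* Local refinement uses `stats::optim(method = "L-BFGS-B")` inside the
  declared bounds; a refined optimum is accepted only if it does not
  exceed the grid optimum.
* Output TSVs print `%.10g`; read–write round trips are exact at that
  precision. Times are hours everywhere; day-valued columns (`time_d`,
  `times_d`) are converted on read.

## Benchmarks and problem sizes

Three benchmarks (`benchmark_fit_quality()`, `benchmark_p2_recovery()`,
`benchmark_vitc_p3_ratio()`) regenerate synthetic data under the
default conditions and re-estimate what went in; `scripts/acceptance.R`
reports the latter two. The problem sizes — 8–12 time points per
course, 10 noise replicates for the $R^2$ benchmark, 100,000 hairpin
reads, 41–101 grid points per free axis — are the package's chosen
desk-scale study conditions: large enough that recovery error is
dominated by the declared noise level rather than by discretization,
small enough that the full suite runs in well under a minute.

```{r benchmarks, eval = FALSE}
benchmark_p2_recovery(seed = 1)$p2_percent   # ~90 (serum p2, percent)
benchmark_vitc_p3_ratio(seed = 1)$ratio      # ~4  (vitC p3 fold change)
benchmark_fit_quality(seed = 1)$median_r2    # >= 0.99
```

## Known limitations

* The model is a population expectation; it carries no cell-to-cell
  variance, so it cannot describe bimodal demethylation or clonal
  heterogeneity.
* $p_3$ lumps all oxidation-initiated removal into a single step;
  iterative oxidation and repair-mediated return to unmodified
  cytosine are not resolved.
* In vivo applications (preimplantation embryos, migratory PGCs)
  require user-supplied divisions-per-interval schedules
  (`scenario_spec(division_times = ...)`); the package ships no
  hard-coded in vivo division counts because such counts are
  stage- and study-specific.
* Identifiability of $p_3$ from 5mC alone is poor by construction (the
  degeneracy above); any serious estimate of oxidation activity needs
  5hmC measurements, which is why the benchmarks include them.
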