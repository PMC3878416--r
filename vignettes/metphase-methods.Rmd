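---
title: "Design and REML analysis of two-phase, multi-environment phenotype screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design and REML analysis of two-phase, multi-environment phenotype screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-throughput phenotype screens of crop germplasm — here, enzymatic
sugar release (saccharification) from barley straw, in nmol glucose/mg
dry matter — run in two randomisation phases. In the *field phase*,
cultivars are randomised to pots laid out on a row-by-column grid with
several replicate blocks (the biological replicates). In the *laboratory
phase*, the milled straw samples are re-randomised to 96-well plates,
each sample occupying one *plate plot* of four vertically consecutive
wells (the technical replicates), with standard samples confined to plate
columns 11–12 and a 3–5% subset of cultivars duplicated across plates
(a partially replicated, "p-rep", design). When the whole experiment is
repeated across years it becomes a multi-environment trial (MET).

Both phases inject non-genetic variation — watering failures show up as
block effects, reagent batches as day effects, pipetting geometry as
plate-row and plate-column effects — and a screen that simply averages a
cultivar's observations confounds all of it with the genetic signal.
`metphase` implements the full workflow: design generation, simulation
from a declared variance-component world, REML fitting of three nested
models, generalized heritability, and cross-trial ranking concordance.

## The model

For the stacked well-level data of $p$ trials,

$$ y = X\tau + Z_g g + Z_u u + \varepsilon $$

* $\tau$ — fixed overall mean per trial ($X$: one indicator column per
  trial);
* $g$ — random cultivar-by-trial effects with
  $\mathrm{var}(g) = G_e \otimes I_m$; for two trials $G_e$ holds the
  per-trial genetic variances on the diagonal and the cross-trial
  genetic covariance off it, so the genetic correlation between years is
  estimable. Cultivars present in a single trial contribute marginal
  effects only;
* $u$ — one independent random term per field/laboratory stratum and
  trial: field block, row, column, row-by-column (the pot), laboratory
  day, day-by-plate, plate-by-plot (the sample), plate row/column and
  their plate interactions, each with its own variance
  $\theta_i^2 I_{b_i}$;
* $\varepsilon$ — residual at the technical-replicate (well) level with
  a separate variance per trial.

Three model kinds express the methodological comparison: **A** drops all
field/laboratory terms and fixes the genetic covariance at zero (the
"average the observations" baseline), **B** adds the design strata, and
**C** additionally frees the cross-trial genetic covariance (the MET
model). Their variance-parameter counts under the realized term sets are
4, 26 and 27.

## REML machinery and numerical choices

The residual log likelihood is evaluated through Henderson's mixed-model
equations with sparse symmetric factorisation (`Matrix`/CHOLMOD):
$C = W'R^{-1}W + \mathrm{blockdiag}(0, G^{-1})$ and
$\ell_R = -\tfrac12[\log|C| + \log|G| + \log|R| + y'Py + (n-p)\log 2\pi]$,
which equals the direct dense formula on any instance small enough to
densify (the test suite certifies this to $10^{-7}$ on random instances
of all three model kinds). Per-trial cross-products are cached so each
evaluation only rescales numbers on a fixed sparsity pattern and re-runs
the numeric phase of a cached Cholesky analysis (~20 ms at the
2,400-equation acceptance scale).

Choices a maintainer should know:

* **Parameterisation.** Log variances; the genetic covariance is
  expressed as $\rho\sqrt{\theta_{g1}^2\theta_{g2}^2}$ with
  $\tanh^{-1}\rho$ unconstrained, so $G_e$ is positive definite at every
  iterate.
* **Optimiser.** `nlminb` (PORT) on the unconstrained scale with
  forward-difference gradients (step $10^{-5}$) that reuse the base
  evaluation, polished by `L-BFGS-B` if PORT does not report
  convergence. A derivative-free simplex with EM warm starts was
  considered and rejected: at 27 parameters it needed ~6× the runtime
  for the same optima, and exact EM updates would require selected
  inversion of $C$, which the available sparse libraries do not expose.
  Starting values are moment heuristics (fractions of the phenotypic
  variance; the cross-trial correlation starts at 0.3).
* **Boundary handling.** After convergence, any design-stratum variance
  below $10^{-8}\times\mathrm{var}(y)$ is treated as "tending to zero",
  dropped, and the model refitted; dropped terms are recorded on the
  fit. Consequently a fit's realized parameter count can be smaller than
  the nominal one, and `lrt()` uses realized counts.
* **Likelihood-ratio tests.** $2(\ell_f-\ell_n)$ against the chi-square
  upper tail; restrictions pinning variances at zero sit on the boundary
  of the parameter space, so the naive reference is conservative (a
  caveat attribute is attached rather than a mixture correction, which
  the comparison being reproduced did not use either).
* **Heritability.** Generalized heritability per trial,
  $H^2 = 1 - a/(2\theta_{gp}^2)$, with $a$ the average pairwise
  prediction error variance of cultivar effects computed by the identity
  $a = 2(m\,\mathrm{tr}(P) - \mathbf{1}'P\mathbf{1})/(m(m-1))$ on the
  within-trial PEV block (certified against a brute-force pair loop). In
  a balanced one-way design this reduces to
  $\theta_g^2/(\theta_g^2+\theta_\varepsilon^2/r)$, which the tests
  verify numerically.
* **Log-likelihood constant.** $-(n-p)/2\,\log 2\pi$ is included so
  values are comparable across nested fits on the same data; absolute
  values are not comparable to other software's conventions.

## Design generators

`generate_field_design()` randomises cultivars to pots independently
within each replicate block; blocks occupy contiguous global column
ranges of width $\lceil m/8\rceil$, and cultivar counts not divisible by
the row count leave EMPTY pots in the block's last column. The original
screen used proprietary design-optimisation software; this package
substitutes constrained randomisation with swap repair, because the
analysis model — not design optimality — is the point, and the
constraints preserved are the stated ones: every plate carries 1–2
duplicated-cultivar samples, the two copies of a duplicate sit on
different plates, and laboratory processing order is unconfounded with
field position (checked by `check_confounding()`: the Spearman
correlation between field column and plate order stays below 0.1 for
~99% of seeds at the full block size).

The duplicate-count chooser targets the 3–5% window and, by default,
makes the block's sample count a multiple of 20 so plates are full; the
published configurations are reproduced exactly (640 available + 20
duplicates = 660 samples in 33 plates per 2010 block; 836 + 44 = 880 in
44 plates for the short 2011 block, 900 in 45 otherwise). Note the
published 2011 duplicate count is itself 5.1% of cultivars — slightly
outside the stated window — so the window is a soft target, not a
validation error. Days group consecutive plates (default 4 per day) in
processing order.

## What the simulator does and does not emulate

`simulate_met()` draws exactly the model above: a joint bivariate draw
per shared cultivar (correlation $\rho_g$, default 0.66), independent
normal effects per realized term level, and iid residuals per well;
technical replicates share everything except the residual. Defaults are
the published world: trial means 93.3 and 54.0 nmol glucose/mg DM and
the full published variance-component table for 2010/2011. Standards are
simulated as four fixed labelled means (25/50/100/150 by default — the
true concentrations are not published, so these are arbitrary constants)
plus laboratory effects and residual, and are excluded from fitting.

Not emulated: assay chemistry and kinetics, non-Gaussian noise, spatial
(autoregressive) residual correlation, drift *within* a day beyond the
day/plate strata, and any cultivar-by-operator structure. A green test
therefore establishes that the estimation machinery is correct for the
declared variance-component world, not that real screens obey it — and
one known divergence matters:

**Model A heritability.** On the real data, ignoring the design strata
*halved-or-worse* the heritability (0.12/0.20 vs 0.37/0.43), and the
acceptance suite asserts that ordering. Under the declared generative
world the opposite happens: the between-cultivar variance of raw means
absorbs sample-level non-genetic variance (pot, plate-plot, plate and
day effects averaged over only a handful of samples), inflating model
A's genetic variance roughly threefold and with it the PEV-based
generalized heritability (~0.7 vs ~0.3 for model B at the reduced
scale). The real data evidently carried much less between-cultivar
signal in its raw means than the iid world implies. The corresponding
acceptance assertion is therefore expected to stay red, and is kept as
specified rather than weakened; the model-B-vs-C ordering and the
cross-trial top-40 concordance advantage of the MET model do reproduce.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `n_rows` | 8 | published pot grid height; rows run the field's length |
| `n_blocks` | 5 | biological replicates per trial |
| `dup_frac` | 0.04 | middle of the 3–5% duplicate window |
| `plates_per_day` | 4 | 3–4 plates were processed per day |
| `k` (ranking) | 40 | practical shortlist size used in the comparison |
| `boundary_tol` | 1e-8 | "tending to zero" threshold, × var(y) |
| `max_iter` | 400 | PORT iteration cap; fits use 100–300 gradients |
| genetic correlation | 0.66 | published cross-trial estimate, the simulation default |

## Scale-downs in the test suite

The full screen (13k–22k wells per trial) is fit-able but slow; the test
and acceptance harnesses use the spec's reduced world — 100 shared
cultivars × 3 blocks × 2 trials × 4 technical replicates (~2,500 wells,
~2,400 mixed-model equations) — for parameter recovery (10 seeds) and
the directional comparisons, and desk-scale constructed cases elsewhere.
Monte-Carlo screens of 100 seeds in the examples are run at 30–40 seeds
with the same proportional pass thresholds; each scale-down is noted
beside the test.

## Known limitations

* No spatial/autoregressive residual structures and no factor-analytic
  genetic structures for more than two trials; two-stage weighted
  analyses are out of scope.
* Gradients are finite differences; an average-information algorithm
  would converge in fewer, costlier iterations and could be added behind
  the same interface.
* PEV blocks are extracted densely per trial (fine to ~1,000 cultivars
  per trial; the full screen's 856 × 856 block is ~6 MB).
* `lrt()` p-values near variance boundaries are conservative (see
  above).
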