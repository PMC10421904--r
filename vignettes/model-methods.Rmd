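---
title: "Methods: the salt-responsive miR165/166-PHB-cytokinin model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the salt-responsive miR165/166-PHB-cytokinin model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsalt)
```

## The model and its assumptions

`mirsalt` models the core circuit by which salt stress remodels the
Arabidopsis root apical meristem: salt represses transcription of the
microRNAs miR165/166; the microRNAs degrade the transcript of the
HD-ZIPIII factor PHABULOSA (PHB); PHB promotes cytokinin (CK)
biosynthesis; and CK represses both PHB and miR165/166 transcription. CK
therefore acts on PHB through two opposing routes — direct repression and
microRNA-mediated de-repression — an incoherent feedforward loop.

Three ordinary differential equations track the pooled species in
arbitrary concentration and time units:

$$\frac{dCK}{dt} = \alpha_{CK} + \beta_{CK1}\,
  \frac{PHB^n}{\beta_{CK2}^n + PHB^n} - d_{CK}\,CK$$

$$\frac{dPHB}{dt} = \mathrm{prod}_{PHB}(CK) -
  \bigl(d_{PHB} + d_{PHBmiR}\, m \, miR166\bigr)\, PHB$$

$$\frac{dmiR166}{dt} = \mathrm{prod}_{miR}(CK, salt) - d_{miR}\, miR166$$

Assumptions worth making explicit: miR165 and miR166 are pooled into one
well-mixed variable; there is no spatial resolution, no transcriptional
delay, and no representation of the other hormones that interact with
this pathway in vivo (auxin, ABA, ethylene); salt is an external forcing
that enters only through the factor $\alpha_{miR}/(1+salt)$ on miR
transcription; and the genotype multiplier $m$ on microRNA-dependent PHB
degradation is 1 in the wild type and 0 in *phb-1d*, whose PHB transcript
carries a microRNA-resistant target site.

## The repression-term dialects

The published form of the two repression denominators is typographically
corrupted (a literal reading gives `beta1 / (1 * (CK/K)^n)`, which
diverges at CK = 0). Rather than hard-code one silent repair, the package
makes the choice explicit via `model_parameters(dialect = ...)`:

- **`multiplicative`** (default): $\alpha\,(1 - \frac{CK^n}{K^n + CK^n})$.
  Productions are nonnegative for every state and salt level, the
  semantics match "maximum rate of CK-inhibited transcription", and the
  form coincides with the subtractive one at the reference parameters
  (where $\alpha = \beta_1$, $n = 1$). Note $\beta_{PHB1}$ and
  $\beta_{miR1}$ are inert in this dialect.
- **`subtractive_clamped`**: $\max(0,\ \alpha - \beta_1
  \frac{CK^n}{K^n + CK^n})$, the printed minus-sign structure with a
  floor at zero so concentrations cannot be driven negative.
- **`literal_plus`**: $\alpha - \beta_1 / (1 + (CK/K)^n)$, the printed
  expression with `1 *` read as `1 +`. Provided for comparison; it can go
  negative and is not used by any default.

An algebraic identity makes the first two dialects coincide whenever
$\alpha = \beta_1$ and the clamp is inactive:
$\alpha - \alpha\,c/(K+c) = \alpha\,K/(K+c)$. The test suite asserts this
at the reference parameter point.

PHB degradation is likewise repaired from the printed product
$(d_{PHB}\, d_{PHBmiR}\, miR)\,PHB$ — under which the mutant ($m = 0$)
would never degrade PHB at all — to the additive form
$(d_{PHB} + d_{PHBmiR}\, m\, miR)\,PHB$, consistent with the parameter
table's wording of a *baseline* degradation rate distinct from the
microRNA-induced one, and yielding the reported mutant behaviour
(bounded PHB, elevated CK, salt resistance).

## Parameters

All reference values are 1 in arbitrary units except the apparent
dissociation constants $\beta_{CK2} = 0.5$, $\beta_{PHB2} = \beta_{miR2}
= 0.4$, and the Hill coefficient $n = 1$. The miR degradation rate
$d_{miR}$ is missing from the published table; it is set to 1, matching
every other unit-valued rate. The reference salt perturbation is a step
from 0 to 0.5 held for 50 time units; steady-state sweeps cover salt 0-10.

Parameters can be loaded from a flat `key: value` (DCF) text file whose
keys are exactly the symbols above plus `dialect`; defaults are embedded,
so nothing needs configuring to reproduce the reference results.

## Numerical methods

**Steady states.** A damped fixed-point iteration (damping 0.5) on the
steady-state relations exploits the near-triangular structure at $n = 1$
(miR and PHB are explicit in CK, CK in PHB), followed by Newton polishing
with a finite-difference Jacobian; convergence is declared at
$\|\mathrm{rhs}\|_\infty < 10^{-10}$ (configurable). Non-convergence is a
typed error carrying the best state and residual, never a silent return.
Sweeps use continuation (each grid point seeded from the previous
solution) on 101 evenly spaced points by default, and
`check_steady_state_unique()` verifies from an 8-point lattice of starts
in $[0.1, 3]^3$ that the fixed point is unique at the reference salt
levels. Local stability is checked in the tests by perturbing the fixed
point by 1% and integrating back.

**Integration.** No ODE solver package is assumed: the integrator is an
embedded Dormand-Prince 5(4) pair with standard PI-free step control
(safety 0.9, step factors clipped to [0.2, 5]), relative tolerance
$10^{-8}$ and absolute $10^{-10}$ by default. Steps land exactly on every
requested output time and on every protocol breakpoint, so the
piecewise-constant salt forcing introduces no interpolation error. The
system is non-stiff at reference parameters; should the step size ever
collapse, the affected subinterval is handed to an adaptive backward-Euler
fallback with Newton iterations. A halved-tolerance self-check in the
suite confirms sampled states move by less than $10^{-6}$. The integrator
was validated during development against an independent high-accuracy
reference implementation; the fixed points and trajectory values frozen
into the tests come from that independent run.

## The synthetic-data generator: what it emulates, and what not

The generator stands in for qRT-PCR fold-change (2^-ddCt) measurements of
the microRNA precursors and PHB relative to untreated controls, in the
two published designs: a 150 mM NaCl time course read at 0.5, 1, 1.5, 2,
3 and 4 h, and a dose response over 0/100/150/200 mM at 5 h, with 3
replicates each. Three bridging choices connect model and experiment:

- **Dose map**: the model's dimensionless salt is anchored linearly
  through the single published correspondence, 150 mM ↔ salt 0.5
  (`s_ref`); so salt = `s_ref` · dose/150.
- **Time scale**: the source never relates model time to hours; the
  default is 2 model-time units per hour, which puts the 4 h window at 8
  model units — well inside the 50-unit protocol and covering the
  transient (the miR response is ~80% complete by 1 h equivalent).
- **Noise**: multiplicative lognormal on fold change (measured FC = true
  FC · $2^\varepsilon$, $\varepsilon \sim N(0, 0.15)$ per replicate), the
  standard error structure for 2^-ddCt data; housekeeping-gene
  normalisation is assumed perfect, and no Ct-level artefacts (primer
  efficiency, technical replication) are simulated.

A green test on synthetic data therefore establishes that the pipeline is
self-consistent — generator, solver and fitter agree — not that the model
fits any real measurement. One known mismatch is structural: the ODEs
have no transcriptional delay, so the experimentally observed ~2 h lag
before PHB induction can only appear as a detection-threshold effect
under noise (the model's PHB starts rising immediately, just slowly),
never as a mechanistic lag.

## Inference

`fc_loss()` is the sum of squared log2 residuals between observed and
model fold changes — the maximum-likelihood loss under the generator's
noise model. `fit_parameters()` runs multi-start L-BFGS-B within bounds
(first start at the bounds' midpoint, the rest drawn uniformly from the
given seed), restricted to at most three of {`s_ref`, `dmiR`,
`alphamiR`, `time_scale`} — the structurally identifiable handful for
fold-change data; absolute production rates cancel in the
treated/control ratio and cannot be recovered. A 1-D exhaustive
`grid_fit()` serves as the optimiser's assumption-free oracle in tests.
Measured over 60 seeded replications at the default design (3 replicates,
noise SD 0.15), the `s_ref` estimator's bias is below 1% of the true
value and its RMSE shrinks with replicate count.

## Degenerate inputs and tie-breaks

Hill terms are defined only for nonnegative input and positive $K$;
solver-internal states may transiently dip a hair below zero and are
clamped at 0 inside the Hill evaluation only. With $\beta_{CK1} = 0$ the
CK equation decouples and the package matches the closed forms
$CK^* = \alpha_{CK}/d_{CK}$ (and, in *phb-1d*, explicit expressions for
the other two species) to $10^{-10}$. Fold changes at dose 0 or time 0
are exactly 1 by construction, with no integration performed.

## Known limitations

No bifurcation analysis or multistability survey at $n > 1$ (uniqueness
is only verified at the reference configuration); no spatial or
cell-number readout — the source defines no mapping from these three
concentrations to meristem cell counts, so none is invented; the
`literal_plus` dialect is intentionally allowed to produce negative
productions, as a faithful rendering of the printed algebra rather than a
usable model variant.
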