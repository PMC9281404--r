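---
title: "Quantifying lipid packing defect sensing: methods and design notes"
author: "chaoscalc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid packing defect sensing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaoscalc)
```

## The problem

Amphipathic helices such as ALPS or the antiviral HCV-AH motif are
recruited to stretched or highly curved membrane regions because
stretching (or bending) a leaflet disturbs head-group packing and
exposes transient hydrophobic *packing defects* that the peptide's
apolar face can occupy. A natural thermodynamic measure of this is the
relative binding free energy between a stretched and a tensionless
membrane,

$$\Delta\Delta F_{\mathrm{sensing}} = \Delta F_b' - \Delta F_b,$$

with $\Delta F_b'$ and $\Delta F_b$ the binding free energies toward
the defect-rich (stretched) and defect-poor (tensionless) bilayer.
A good sensor has $\Delta\Delta F_{\mathrm{sensing}} \ll 0$.

Computing the two binding free energies alchemically (thermodynamic
integration over a decoupling parameter $\lambda$) is accurate but
expensive: tens of $\lambda$ states per interaction class per tension
state. The package implements the *mechanical end-state* alternative:
by path independence of free energy around the bound/unbound ×
tensionless/stretched cycle, the same quantity is the change in the
work of stretching caused by the bound peptide,

$$\Delta\Delta F_{\mathrm{sensing}} = \Delta F_s' - \Delta F_s .$$

## The mechanical pathway

**Tension from the pressure tensor.** For a membrane spanning the
$x$–$y$ plane of a constant-area box, the surface tension is
$\sigma = L_z\,\bigl(P_{zz} - \tfrac{1}{2}(P_{xx}+P_{yy})\bigr)$,
evaluated per frame (the product stays inside the time average — the
tension is an ensemble average of a mechanical observable) and
averaged after discarding an equilibration transient. Units: bar nm
internally, reported as mN/m (1 bar nm = 0.1 mN/m). $\sigma$ is the
full-bilayer tension; no factor 1/2 for the two monolayer surfaces is
applied, which matters when comparing with monolayer conventions.

**Error bars.** Statistical errors use contiguous block averaging
(default 5 blocks; the sem is the sample sd of block means over
$\sqrt{n}$). Block length — not autocorrelation fitting — is the error
model: it is simple, reproducible, and standard in MD practice. When a
remainder is left over, frames are dropped from the *front* of the
series, keeping the best-equilibrated tail. Replica-based errors
(`estimate_tension_replicas()`) are available when independent runs
exist; which estimator underlies any given published error bar is
generally unknowable, so both are provided and neither is asserted as
canonical.

**Hookean regime and the end-state trick.** For small relative strain
$\epsilon = (A - A_0)/A_0$ the tension is linear,
$\sigma = \sigma(A_0) + K_A\,\epsilon$ with $K_A$ the area
compressibility modulus. Linearity makes the two-point trapezoid
*exact*:

$$\Delta F_s = \tfrac{1}{2}\,\bigl(\sigma(A) + \sigma(A_0)\bigr)(A - A_0),$$

so only the two end states need simulating. The package evaluates both
this end-state form and the composite trapezoid over a full area grid
(`mode = "multi_point"`); on Hookean data they agree to machine
precision, and on noisy data they must agree within the propagated
error of their difference. `endstate_multipoint_discrepancy()`
propagates that error exactly as a linear functional of the shared
tension estimates (the common end-point terms cancel); "agreement" is
declared within three standard errors of the difference — a
three-sigma criterion is used rather than two-sigma so that agreement
failures signal genuine non-linearity rather than ordinary noise.

Energy conversion uses 1 mN/m nm² = 0.602214076 kJ/mol (Avogadro
scaling of $10^{-21}$ J) at full precision.

**CHAOS.** The absolute $\Delta\Delta F_{\mathrm{sensing}}$ depends on
the (arbitrary) choice of end states. Normalizing by the peptide-free
tension difference $\Delta\sigma(A) = \sigma(A_0) - \sigma(A)$ gives
the *characteristic area of sensing*,

$$\mathrm{CHAOS} = \frac{\Delta\Delta F_{\mathrm{sensing}}}{\Delta\sigma(A)},$$

an end-state-invariant quantity with units of area per molecule:
roughly, the excess leaflet area a bound peptide injects, inflated by
its ability to soften the membrane. Sign conventions are fixed
throughout: $\epsilon \ge 0$ under stretching, sensing means
$\Delta\Delta F < 0$, $\Delta\sigma < 0$ under stretch, hence CHAOS
$> 0$ for sensors. Error propagation on all derived quantities is
first-order quadrature assuming independent tension estimates
(independent simulations per state); correlations between the
numerator and denominator of CHAOS, which share the reference
tensions, are neglected at first order.

## The alchemical cross-check

`ti_integrate()` integrates $\langle\partial V/\partial\lambda\rangle$
profiles by composite trapezoid (default; exact for affine profiles)
or Simpson (uniform odd grids), with sem quadrature using the
integration weights and a smoothness diagnostic (max second
difference), since a smooth profile is the precondition for trusting
the quadrature. One convention to note: the profiles ingested here are
oriented so that each leg's integral contributes *directly* to the
binding free energy of its tension state (negative when binding is
favourable); the $\lambda = 0 \to 1$ decoupling integral of a
simulation engine is the negative of this. `alchemical_sensing()`
subtracts the tensionless-state result from the stretched-state
result, guarded by the tension-state labels.

`cycle_closure()` compares the mechanical and alchemical estimates
with a two-tailed Welch's $t$ test (Welch–Satterthwaite degrees of
freedom from the supplied replicate counts) and reports the cycle as
closed when $p > 0.05$.

## The synthetic generator

All fixtures come from a Hookean membrane + peptide model
(`hookean_model()`): $\sigma(A) = s\,K_A\,(A - A_0 - \Delta A_p)/A_0$,
where the bound peptide injects excess area $\Delta A_p$ and softens
the modulus by $s \in (0, 1]$. Every estimator then has a closed form:

- end-state sensing free energy
  $\Delta\Delta F = (K_A/A_0)\,[(s-1)\Delta A^2/2 - s\,\Delta A_p\,\Delta A]$;
- $\mathrm{CHAOS} = (1-s)\,\Delta A/2 + s\,\Delta A_p$, reducing to
  exactly $\Delta A_p$ for a pure area-shift peptide ($s = 1$) — the
  end-state invariance made exact.

Pressure traces are generated by inverting the tension relation:
$P_{zz}$ is pinned at the 1 bar reference (mimicking z-only pressure
coupling of constant-area runs) and
$P_{xx} = P_{yy} = 1\,\mathrm{bar} - \sigma(t)/L_z$, so the estimator
recovers the injected tension series identically. Noise is stationary
AR(1) — amplitude 60 mN/m, correlation time 100 ps at one frame per
20 ps by default, chosen once as representative of per-frame tension
scatter in a 128-lipid box — the simplest process that makes block
averaging non-trivial. What the generator does *not* emulate: slow
collective modes (undulations), peptide binding/unbinding
non-stationarity, anharmonicity at large strain, and force-field
specifics. Passing tests therefore validate the estimators and their
error models, not any particular force field's physics.

TI legs are generated as
$f(\lambda) = \mathrm{target} + a\,[\lambda^2(1-\lambda)^2 - 1/30]$ —
a smooth quartic whose shape term integrates to zero — so each leg's
integral equals its target (a 60/40 vdW/Coulomb split of
solvation baseline $-80$ kJ/mol plus binding work $-20$ kJ/mol, plus
the closed-form $\Delta\Delta F$ in the stretched state). Because the
shape term is identical in both tension states, its quadrature error
cancels exactly in the sensing difference: cycle closure on noiseless
data holds to machine precision on any shared grid. Only the integral
of the profile is contractual; the quartic shape itself is an
arbitrary, documented choice.

Default study conditions: $A_0 = 42.4$ nm², areas 42.4–49.4 nm² in
1.4 nm² steps (16.5% maximal strain), $K_A = 240$ mN/m, 37-point
$\lambda$ grids. All randomness flows from explicit seeds through
isolated RNG scopes; the caller's RNG state is never disturbed.

## Geometry mappings

A cylindrical buckle of curvature $\kappa$ corresponds to a tube of
radius $1/\kappa$; a vesicle (curved in two dimensions) has half the
mean curvature of the cylinder, so buckle curvatures are halved before
converting to vesicle radii. The strain-to-vesicle map uses the
thin-shell form $\epsilon = 2d/R$ with $d$ the midplane-to-neutral-
plane offset of one leaflet; the default $d = 1.03$ nm is calibrated
so that 16.5% strain corresponds to a 25 nm-diameter vesicle and is
declared a model choice, configurable per lipid.

Buckle curvature profiles are computed as
$\kappa = -z''/(1+z'^2)^{3/2}$ (positive when the plane bulges toward
the peptide-bearing upper leaflet — note a crest has $z'' < 0$, hence
the sign) with derivatives from a smoothing spline; periodicity is
handled by fitting three replicated periods and evaluating the central
one, and the smoothing parameter is exposed (`NULL` = generalized
cross-validation). Raw finite differences are offered as a cross-check
mode only; on noisy planes they are unusable, which is why the spline
is the default. Degenerate inputs (fewer than 8 points, non-monotone
$x$) are rejected rather than guessed at.

## Directed evolution

`run_evolution()` implements the select–recombine–mutate loop used for
inverse design of sensing peptides: fixed-length sequences (default
24 aa), truncation selection of parents, single-point crossover,
infrequent per-residue point mutation, and elitism (which makes the
best fitness provably monotone). Fitness is minimized, matching the
convention that fitness *is* $\Delta\Delta F_{\mathrm{sensing}}$; an
MD-backed fitness plugs in through the same one-argument function
interface and is never executed in tests.

The built-in surrogate scores a sequence by its Wimley–White
interface-partitioning sum plus a bonus of $-0.5$ per large aromatic
(W, F). The Wimley–White scale was chosen over Kyte–Doolittle
deliberately: interface partitioning — not bulk hydrophobicity — is
what drives defect insertion, and it makes poly-tryptophan the global
optimum by construction, mirroring the aromatic-enrichment signature
of optimized sensors. The surrogate is a ranking device only.

A run is flagged *converged* when the best fitness is unchanged for 5
consecutive generations. On the additive surrogate landscape this flag
rarely fires within 25 generations: with ~30 offspring per generation
and a per-residue mutation rate of 0.02, some residue almost always
improves slightly each generation until the sequence is nearly
optimal. A plateau within ~25 generations is characteristic of bounded
noisy fitness functions (such as MD estimates), not of an additive
deterministic score; the convergence machinery is exercised by the
tests on enumerable toy problems, where the optimum is reached and
held.

## Numerical choices and limitations

- Multi-point grids must match to $10^{-6}$ nm²; no interpolation
  across mismatched grids — silent interpolation would hide setup
  errors.
- The $K_A$ fit is constrained through the measured
  $(0, \sigma(A_0))$; the anchor's sem is propagated into the slope
  error (sensitivity $-\sum w\epsilon / \sum w\epsilon^2$), without
  which the reported error is badly overconfident.
- Column matching in readers tries exact GROMACS energy names, then a
  case-insensitive punctuation-stripped match (announced via a
  message), then fails loudly; it never guesses silently.
- Equilibration trims keep the frame exactly at the cutoff; trims that
  empty a trace are errors, as are moving-average windows longer than
  a binding trace.
- Problem sizes used in the shipped checks (traces of $10^3$–$10^5$
  frames, 100-seed agreement sweeps, 20-seed closure sweeps) were
  chosen to give stable statistics at interactive runtimes.
- Binding classification cutoffs (fraction bound 0.9/0.5, threshold
  1.5 nm) are pragmatic defaults, flagged as such.
- The tool consumes *reduced* time series only; trajectory parsing,
  umbrella-sampling reweighting, constant-tension ensemble corrections
  and MD engine setup are out of scope.
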