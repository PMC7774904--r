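---
title: "Methods: the Pax6/Fst/Tgfb2 reaction-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Pax6/Fst/Tgfb2 reaction-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its numerical
choices, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

Five species live on a spatial grid: Pax6 (`P`, an intracellular
transcription factor), free Follistatin (`F`), free Tgfb2 (`T`), the
Fst:Tgfb2 complex (`C`) and the activated Tgfb2:receptor complex (`B`,
membrane bound). Pax6 autoactivates through a Hill function of its
*effective activity* `P* = P / (1 + beta B)`: receptor signalling
(Smad3) blocks Pax6-DNA binding, so inhibition acts on activity — the
same `P*` drives Fst and Tgfb2 production and Pax6's own
autoregulation, rather than adding a separate transcriptional
repression term. A static Shh field attenuates all Pax6 production by
`h = 1 / (1 + gamma S)`. Sequestration is reversible 1:1 mass action
(`k_on`, `k_off`); receptor binding conserves total receptor `R_tot`
pointwise; complex decay (`delta_C`) destroys both constituents, so
free ligand is released only by dissociation — this keeps the
conservation structure simple (`F + C` and `T + C + B` are conserved
when production and decay are switched off).

Only the secreted species diffuse. `P` and `B` have no diffusion term;
the reference set additionally fixes `D_T = 0`: free Tgfb2 is treated
as locally confined by receptor and matrix binding, with lateral
transport carried entirely by the fast-diffusing complex (`D_C = 30`
versus `D_F = 0.1`). This is the reversible-sequestration transport
regime; the irreversible alternative (`k_off = 0`, which would instead
require `D_T > D_F`) is available through the parameter interface but
is not the default, since reversibility of the Fst:Tgfb2 interaction is
biologically unresolved.

Model variants map onto the simulated experiments: **A** freezes Pax6
as a prescribed regional pattern (the secreted layer responds); **B**
is the full self-organising network with no Shh input; **C** is variant
B run on a masked 2D explant-shaped domain; **D** adds the static Shh
gradient. `reaction_rates()` for variant D with `S = 0` is exactly
variant B.

## How the instability works

At the Pax6-high uniform steady state, Fst capture dominates free-Tgfb2
turnover. A local Pax6 fluctuation raises Follistatin, which captures
Tgfb2 into complexes that diffuse away before dissociating: receptor
signalling drops locally (releasing Pax6 from inhibition — local
positive feedback) and rises at long range where the exported complex
dissociates (lateral inhibition). The unstable band is bounded below by
the complex transport scale `sqrt(D_C / (k_off + delta_C))` and above
by the Follistatin response scale `sqrt(D_F / (k_on T* + delta_F))`;
the band exists only because `D_C >> D_F`, and collapses entirely when
`D_C` is lowered to `D_F` (a package test and the acceptance script
verify both).

The eigenvector of the fastest-growing mode has Follistatin in phase
with Pax6 and free Tgfb2 and receptor signal in anti-phase: the
saturated pattern is a Pax6 pole flanked by receptor-signalling
territory, with `corr(P, B)` near -1.

## The reference parameter set and how it was chosen

No kinetic constants are published for this network, so the shipped set
(`inst/extdata/reference_params.yaml`) was located by a Latin-hypercube
sweep over the kinetic and diffusion constants followed by local
refinement, under the constraints the model must satisfy: a positive
uniform Pax6 steady state that is stable without diffusion;
Turing-unstable with `D_C >> D_F` and stable again at `D_C = D_F`; an
anti-phase fastest-growing mode (the flanking receptor poles); a
pattern wavelength comparable to the simulated tissue (about 38 length
units); and a *supercritical* bifurcation. The last constraint needs
explaining: with very low basal Pax6 production the Pax6 subsystem is
bistable and patterns form as localised large-amplitude spikes whose
spacing is set by front interactions rather than by the linear
wavelength — pole counts then decouple from the dispersion relation and
mode selection becomes seed-dependent. Raising basal production
(`sigma_P = 0.2 rho_P`) removes the fold; patterns stay
moderate-amplitude (final Pax6 contrast about 0.6), the realised
wavelength tracks the linear prediction, pole counts scale cleanly with
tissue size, and the grid-convergence error of the polarisation index
falls to a few parts in 1e5 at `dx = 0.25`. The feedback strength sits
at the centre of its instability window (`beta = 320`, window roughly
275-365), away from both the onset and the reentrant stabilisation.

Units of space, time and concentration are arbitrary but internally
consistent; one pattern wavelength is approximately 38 length units and
patterns saturate within about 4000 time units.

## Numerics

*Integrator.* The production integrator is `deSolve::lsodes` (sparse
BDF with a numerically estimated Jacobian structure), which handles the
stiffness of fast complex diffusion, the periodic wrap-around coupling,
and the masked-domain stencil uniformly; simulations integrate through
pattern saturation in seconds. A fixed-step explicit Euler loop is
retained as a selectable integrator; it enforces the diffusive
stability bound `dt <= dx^2 / (4 max D)` and serves as the independent
convergence oracle (the test suite checks that the two agree to 1e-4
relative on a coarse grid). Tolerances default to `rtol = 1e-6, atol =
1e-8`; oracle-grade runs use `1e-10/1e-12`.

*Spatial discretisation.* Cell-centred second-order stencils. Zero-flux
boundaries use ghost-cell reflection (the ghost takes the boundary-cell
value), which makes the boundary flux exactly zero and the operator
symmetric, hence mass-conserving; periodic grids wrap. On masked 2D
domains a neighbour outside the tissue is mirrored, giving zero normal
flux across the mask edge. Fields are clamped at zero if an excursion
below `-1e-9` .. 0 occurs; clamping events are counted and never occur
in the shipped scenarios.

*Boundary conditions and geometry.* De-novo patterning scenarios run on
periodic 1D rings (a closed organoid-like tissue): on a ring the
fastest-growing integer mode is unambiguous, so a one-wavelength ring
yields exactly one pole for every noise seed. Explant scenarios run
with zero flux on a 2:1 capsule (rectangle with semicircular caps — an
unambiguous long axis; an ellipse is available). The capsule is 16 x 8
length units: the short axis is chosen *below* `pi / k_top` of the
unstable band so no mode fits across it, while the long axis supports
its fundamental mode — this is what forces repolarisation along the
long axis regardless of the initial short-axis pre-pattern. Fixed
(Dirichlet) boundaries are deliberately not implemented.

*Dispersion sampling.* Wavenumbers are sampled on a log grid wide
enough to bracket every mode resolvable in the shipped scenarios, with
a dead-band of 1e-9 around zero growth to keep classifications stable
against round-off. Degenerate eigenvalue cases are left to the
numerical eigensolver; only maximal real parts are consumed.

## Scenario generators

The noisy initial condition multiplies the steady-state Pax6 by
uniform noise `1 + U(-a, a)` with `a = 0.05` (only Pax6 starts noisy;
the secreted species start exactly at steady state). The amplitude is a
convention — the source biology does not constrain it — and 5% is small
enough to stay in the linear regime yet large enough to seed every
mode. The explant pre-pattern grades Pax6 across the *short* axis
(explant collapse shortens the original proximal-distal dimension, so
the residual polarity runs perpendicular to the long axis) at +/- 5%
around steady state, with a 2% multiplicative noise floor: expression
is never perfectly graded in tissue, and a mathematically exact
symmetric profile would leave all transverse modes unseeded forever.
Shh gradients are linear by default (exponential available, decay
length half the domain extent), run along the explant's long axis, peak
0.5 in activity units (with `gamma = 1`, a 33% suppression of Pax6
production at the ventral end), and `inverted = TRUE` flips the ends.
Loss-of-function tags zero exactly one coupling each: `tgfb_lof` sets
`beta = 0` (Smad3 block), `shh_lof` sets `gamma = 0`, `double_lof`
both.

Run lengths are fixed per scenario (10000 time units, about 2.5x the
saturation time of the reference instability) so metric time series are
comparable across runs; snapshots are stored at fixed intervals.

## What the generators do and do not emulate

The scenarios reproduce the *simulated* experiments: regional
pre-patterns, noisy uniform starts, explant-shaped domains, static
morphogen gradients, and pharmacological loss of function as clean
parameter deletions. They do not emulate tissue growth or deformation,
three-dimensional geometry, gene-expression noise during the run
(noise enters only the initial condition), graded rather than binary
drug effects, or any downstream readout genes. Passing tests therefore
show that the network topology with the shipped constants can produce
the claimed patterning behaviours in idealised tissue — not that the
real tissue uses these constants.

## A structural property: anti-phase patterns are stationary

The package classifies the fastest-growing mode as `turing` (real) or
`oscillatory_turing` (complex — a wave instability). Extensive
parameter-space exploration during development located both regimes,
and they are structurally distinct in this network: the receptor row
gives `B' = k_b (R_tot - B*) T' / (lambda + k_b T* + k_u)`, so for any
mode `B` follows free Tgfb2 with a lag below 90 degrees. An anti-phase
receptor pattern therefore requires free Tgfb2 depleted where Pax6 is
high — capture-dominated perturbations, which make the destabilising
loop (Pax6 -> Fst -| Tgfb2 -> receptor -| Pax6) net positive, and
positive loops do not rotate: the mode is real. Conversely the rotating
modes found (e.g. `oscillatory_parameters()`) are production-dominated
and in-phase, require slow receptor kinetics, and their frequency is
comparable to their growth rate, so they complete about one cycle
during pattern formation before the nonlinear state locks. The
reference set is the anti-phase stationary regime — the configuration
that reproduces the flanking receptor poles. The oscillation-control
property (raising `beta` converts the wave instability into a
stationary one) holds in the wave corner and is demonstrated on the
secondary set with a 2% `beta` increase; it cannot be demonstrated on
the reference set, whose mode is already stationary. If the original
network's equations differ from this reconstruction (they are not
published in the text this model was built from), both properties might
coexist there; in this reconstruction they cannot.

## Known limitations

- Pole-count prediction (`predicted_pole_count`) uses the linear
  wavelength; deep in the nonlinear regime (strongly subcritical
  parameter sets) realised spacings can exceed it.
- The polarisation angle on periodic rings is a circular position, not
  an axis direction; comparisons across resolutions are index-based.
- Oscillation detection is a heuristic on probe time series: a
  flatness guard keeps solver ripple on locked patterns from reading
  as oscillation, at the cost of missing oscillations below 1e-4
  relative amplitude.
- Masked 2D domains are rasterised; principal-axis measurements carry
  O(dx) error, and very coarse masks (short axis below ~8 cells)
  distort the band structure.
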