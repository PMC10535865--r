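---
title: "Quantifying P-gp efflux inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying P-gp efflux inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgptools)
```

P-glycoprotein (P-gp, ABCB1) exports structurally unrelated
chemotherapeutics from cells and is a principal cause of multidrug
resistance (MDR) in tumours. `pgptools` implements the quantitative
backbone of a typical P-gp modulator study: the kinetics of
fluorescent-drug efflux in live cells, the cytotoxicity bookkeeping
that defines resistance and its pharmacological reversal, and the
post-simulation energetics used to rationalise where and how tightly a
modulator binds the pump. This vignette records the models, the
estimators, the numerical choices, and what the synthetic-data tests
do and do not demonstrate.

## The uptake assay and its compartmental model

In the spectrofluorometric transport assay, pirarubicin (THP, a
doxorubicin analogue) is added at `C_T` = 1 µM to a stirred suspension
of 2×10⁶ resistant cells in 2 mL. THP fluoresces in solution but is
quenched when intercalated into nuclear DNA, so the decline of the
590 nm signal reports nuclear accumulation. After a steady state is
reached (around 1600 s), Triton X-100 permeabilizes the membranes and
the signal drops further as the remaining free drug equilibrates with
DNA.

`simulate_uptake()` integrates a three-pool model (all concentrations
referred to the solution volume, in nM):

* extracellular free drug $C_e$, cytosolic free drug $C_c$, and
  nuclear-intercalated drug $C_n$;
* symmetric passive permeation $k_+\rho\,(C_e - C_c)$ with $\rho$ the
  cell density (cells/L) and $k_+$ the per-cell permeation coefficient
  (L·cell⁻¹·s⁻¹);
* active efflux $k_a\rho\,C_c$ acting on cytosolic free drug;
* saturable nuclear binding
  $k_{on} C_c (B_{max} - C_n) - k_{off} C_n$.

The observable is $F(t) = \mathrm{bg} + s\,(C_T - C_n)/C_T$: everything
that is not intercalated fluoresces. At the detergent step the
membrane barrier disappears; from then on the free drug forms a
*single* well-stirred pool that equilibrates with the nuclear site and
the pump is gone. Modelling permeabilization as a pool merger (rather
than as a very large permeation constant between two persistent pools)
matters: with two equal-weight free pools the post-Triton level
$C_T - C_N$ would double-count the free drug and the isotherm closure
below would be inconsistent with the forward model by a factor of two.

## From fluorescence levels to transport coefficients

Three background-subtracted levels summarise a trace: $F_0$ at drug
addition, $F_n$ at the pre-Triton steady state, and $F_N$ after
permeabilization. They convert to concentrations as

$$C_n = C_T\,\frac{F_0 - F_n}{F_0}, \qquad
  C_N = C_T\,\frac{F_0 - F_N}{F_0},$$

clamped to $[0, C_T]$ with a warning when noise pushes them outside.
The remaining quantities are closed in `estimate_active_efflux()`:

* **Cytosolic free drug.** At steady state the nuclear bound/free
  ratio equals the bound/free ratio after permeabilization (a linear
  intercalation isotherm), giving
  $C_i = C_n (C_T - C_N)/C_N$. This is exact in the linear binding
  regime ($C_n \ll B_{max}$, free drug $\ll K_d$) and reduces to
  $C_i = C_e$ when there is no pump.
* **Extracellular free drug.** $C_{e,ss} = C_T - C_n - C_i$ — what is
  neither intercalated nor cytosolic. (Defining it as $C_T - C_n$
  would fold the cytosolic pool into the "extracellular" term; in the
  pump-free limit that definition equals $2C_i$ and the balance below
  would report a spurious efflux equal to the passive influx, so the
  pool-resolved definition is used.)
* **Active efflux.** At steady state the net passive influx balances
  the pump: $V_a = k_+\rho\,(C_{e,ss} - C_i)$ and
  $k_a = V_a/(C_i\rho)$.

The inhibition ratio $r = k_a^{i}/k_a^{0}$ compares the efflux
coefficient under a modulator with the control: 1 means no inhibition,
0 a completely blocked pump.

### Estimating $F_n$: extrapolation, not a window mean

The steady state is only *approached* by the detergent step: with
realistic rate constants the trace is still ~2–5 % away from its
plateau at 1600 s. Because $V_a$ is a small difference of large
numbers ($C_{e,ss} - C_i$, tens of nM out of 1000), taking $F_n$ as
the plain mean over a late window injects that residual transient
directly into $k_a$, with errors that can exceed 50 % for slow
parameter sets. `concentrations_from_trace()` therefore fits the tail
of the pre-Triton record (from 40 % of the way to the detergent step)
with $F = a + b\,e^{-(t-t_1)/\tau}$ and uses the plateau $a$ as $F_n$.
The fit is accepted only if it is a genuine decay ($b > 0$,
$\tau > 0$) whose plateau lies at or below the window mean and not
below the post-permeabilization level (the physical constraint
$C_n \le C_N$); otherwise the method falls back to the window mean,
which remains available as `method = "mean"`.

### Estimating $V_+$: initial rate from an exponential fit

The classical estimator of the initial uptake rate — the steepest
20-second regression slope slid across the early trace — is retained
(`method = "sliding"`), but it is a maximum over many noisy,
overlapping slope estimates: at 1 Hz sampling with 0.5 % noise its
selection bias is +10–20 % with a standard deviation near 9 % for slow
uptake. The default therefore fits $F = a + b\,e^{-(t-t_0)/\tau}$ over
the influx window (300 s) and reports the initial slope $b/\tau$; the
early decay of the model is exponential to high accuracy once the fast
binding transient (sub-second here) has passed, so this estimator uses
every sample and is unbiased by noise. Both estimators share the
normalisation $V_+ = (C_T/F_0)\,\max(-dF/dt)$ and
$k_+ = V_+/(C_T\rho)$.

## What the trace generator emulates

`gen_uptake_trace()` reproduces the assay protocol: 1 µM drug, 2×10⁶
cells in 2 mL ($\rho = 10^9$ cells/L), 1 Hz sampling over 2000 s,
Triton at 1600 s, and additive i.i.d. Gaussian noise (default SD 0.5 %
of the initial span). Default transport parameters were fixed once
from the physics of the assay:

| parameter | default | rationale |
|---|---|---|
| $k_+$ | 3×10⁻¹² L·cell⁻¹·s⁻¹ | $k_+\rho$ of a few 10⁻³ s⁻¹ so the steady state is reached by ≈1600 s |
| $k_a$ | 6×10⁻¹² L·cell⁻¹·s⁻¹ | active/passive ratio ≈ 2–3, the trend of published efflux tables |
| $B_{max}$ | 3×10⁴ nM | deep quenching (≈93 % of drug nuclear-bound) while staying in the near-linear isotherm regime ($C_n/B_{max}\approx3\%$) assumed by the $C_i$ closure |
| $K_d = k_{off}/k_{on}$ | 600 nM | same regime; binding equilibrates in ≪1 s, far faster than transport |

Parameter-recovery tests run a 3×3 grid around these defaults
($k_+ \in \{2,3,4\}$, $k_a \in \{3,6,12\}$ ×10⁻¹²). Noise-free
recovery of both coefficients is within ~2.6 % (the residual is the
bound fraction $B_{max}/(B_{max}+K_d)$ of the initial rate); with
0.5 % noise, estimates are averaged over triplicate assays per
condition — as in the emulated experiment — and stay within ~10 %.
The generator does not emulate photobleaching, inner-filter effects,
lamp drift or drug metabolism, so passing these tests shows the
*estimators* are consistent with the *stated* transport model, not
that the model captures every artefact of a real fluorimeter record.
Absolute published coefficient values are not reproducible without the
original raw traces; only units, magnitudes and trends are meaningful
targets.

## Dose–response, resistance and reversal

`fit_dose_response()` fits the four-parameter logistic
$v(c) = \mathrm{bottom} + (\mathrm{top} -
\mathrm{bottom})/(1 + (c/\mathrm{IC}_{50})^h)$ by least squares
(log-scale IC50, Levenberg–Marquardt). For percent-of-control
viability the constrained fit (`fix_top_bottom = TRUE`, top = 100,
bottom = 0) is strongly recommended and is what the recovery tests
use at realistic noise: with 8 doses, triplicates and 5-point noise
the free 4PL's bottom is unidentifiable (median IC50 error ≈30 %)
while the constrained fit stays within ~15 %. When no dose depresses
mean viability below 50 % the IC50 is not identifiable; the fit is
flagged `converged = FALSE` and the maximum dose is reported as a
bound rather than a number that looks trustworthy.

`ic_level(fit, level)` returns
$\mathrm{IC}_{50}\,(\mathrm{level}/(100-\mathrm{level}))^{1/h}$, with
`level` read as percent of the fitted top-to-bottom span so that
`ic_level(fit, 50)` is the IC50 for any fit.

The resistance index divides the resistant-line IC50 (with or without
modulator) by the sensitive-line IC50 without modulator; the reversal
index divides the no-modulator resistance index by the with-modulator
one. Published tables of this kind are internally consistent only when
the reversal quotient is taken on resistance indices *already rounded*
to one decimal (e.g. 7.1/0.3 = 23.7, whereas the unrounded quotient is
20.6), with ties rounded away from zero. That rounded-intermediate
convention is the default; `exact = TRUE` gives unrounded arithmetic.
Relative expression from qPCR uses the standard
$2^{-\Delta\Delta C_t}$ (the occasional "−2^ΔΔCt" typography in print
denotes the same quantity).

## Binding energetics bookkeeping

`mmgbsa_total()` aggregates end-state components:
$\Delta E_{MM} = \Delta E_{vdw} + \Delta E_{elect}$,
$\Delta G_{sol} = \Delta G_{polar} + \Delta G_{nonpolar}$,
$\Delta H = \Delta E_{MM} + \Delta G_{sol}$ and
$\Delta G_{bind} = \Delta H + (-T\Delta S)$, with the entropic penalty
stored as the additive non-negative term as tabulated. Per-frame
component energies are *inputs*: no force field or GB model is
evaluated here, and upstream settings such as the internal dielectric
live with the upstream engine.

The entropy term uses the interaction-entropy estimator over the
per-frame gas-phase interaction energy $E_{int} = E_{vdw} + E_{elect}$:

$$-T\Delta S = \frac{1}{\beta}\,\ln\left\langle
  e^{\beta\,(E_{int} - \langle E_{int}\rangle)}\right\rangle,
  \qquad \beta = 1/k_B T,$$

computed with log-sum-exp so large fluctuations cannot overflow. It is
non-negative (Jensen), zero only for a constant series, equals
$\beta^{-1}\ln\cosh(\beta\delta)$ on a two-point series
$\{m\pm\delta\}$, and approaches $\beta\sigma^2/2$ for Gaussian
fluctuations — all used as analytic test anchors. When a single frame
dominates the exponential average (fluctuations ≫ $k_BT$) a
`pgptools_ie_unstable` warning flags the estimate as unreliable; no
block averaging is applied. Replica statistics are the plain mean ±
SEM across replica copies; per-residue decompositions are filtered at
a strict −0.5 kcal/mol threshold (a residue at exactly the threshold
is excluded).

## Hydrogen bonds and RMSD

A bond is counted when the donor–acceptor distance is < 3.5 Å and the
donor–hydrogen–acceptor angle is > 120° for at least one hydrogen on
the donor. Published criteria of this kind sometimes say
"donor–acceptor angle"; the geometric D–H–A angle is the standard
reading and the default, with a distance-only mode (`angle_def =
"none"`) for bond-count monitoring. Atom-pair occupancy is the
percentage of frames in which the pair is bonded (0–100 %);
residue-pair occupancy *sums* the atom-pair occupancies of the
residue, the only convention under which per-residue occupancies
above 100 % (as in published tables) arise. Records under 30 % are
suppressed from the default report. Reported distances are
hydrogen–acceptor distances over bonded frames, matching the 1.7–2.9 Å
range of published tables.

The toy-trajectory generator plants bonds at 2.8 Å/170° and opens them
to 4.5 Å with ≤0.05 Å jitter, spacing pairs 12 Å apart so schedules
translate exactly into occupancies. It is a bookkeeping fixture, not a
physical structure — two donors of one residue are placed
schematically, and no steric environment exists.

RMSD uses the orthogonal-Procrustes (Kabsch) superposition via SVD
with the usual determinant correction so reflections are never
applied. It is implemented in-package because the established
reference implementation rounds to three decimals, which is too coarse
for the rigid-motion identity (≤10⁻⁹ Å) asserted in the tests; that
reference still serves as an independent cross-check, together with a
rotation-grid brute-force oracle.

## Numerical choices and degenerate inputs

* ODE integration: `deSolve::lsoda`, `rtol` 10⁻¹⁰ / `atol` 10⁻⁸; mass
  conservation is asserted to 10⁻⁶·`C_T` in the tests. The detergent
  step is integrated as a separate phase from the pre-Triton state.
* Nonlinear fits: `minpack.lm::nlsLM` throughout, with log-scale
  positivity for IC50 and explicit fallbacks when a fit fails or
  violates its sanity constraints.
* Flat traces return $V_+ = 0$ with a warning, not an error; $F_0 \le
  0$, missing event markers, empty trajectories, $C_N = 0$ and
  non-positive controls raise errors that name the offending quantity.
* Rounding of indices is half-away-from-zero at one decimal by
  default, the convention that reproduces published tables.
* Problem sizes in the shipped tests and acceptance script: 2000-point
  traces, a 3×3 recovery grid (plus triplicates at the noisy
  setting), 10⁵-sample Gaussian series for the interaction-entropy
  limit, and 100-frame toy trajectories.

## Known limitations

The transport model treats the cytosol as a well-stirred pool of the
same effective volume as the medium; absolute per-cell coefficients
therefore carry that convention and should be compared between
conditions, not across bookkeeping conventions. The $C_i$ closure
assumes near-linear intercalation; strongly saturated binding breaks
it. The interaction-entropy estimator is known to converge slowly when
interaction-energy fluctuations are large relative to $k_BT$; the
package warns but does not repair this. Free-energy components are
consumed, never computed: docking, MD engines, GB/SASA evaluation and
free-energy-landscape analysis are out of scope.
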