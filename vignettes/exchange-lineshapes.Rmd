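---
title: "Three-state exchange line shapes: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state exchange line shapes: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exchline)
```

## The model

`exchline` models the observed amide resonance of a protein P binding a
peptide ligand L whose complex PL additionally exchanges with a transiently
(partially) unbound conformer PL*:

$$\mathrm{P} + \mathrm{L}
  \underset{k_{1,\mathrm{off}}}{\overset{k_{1,\mathrm{on}}}{\rightleftharpoons}}
  \mathrm{PL}
  \underset{k_2'}{\overset{k_2}{\rightleftharpoons}}
  \mathrm{PL}^*$$

The physical picture: in ultra-tight repeat-protein/peptide complexes,
individual side-chain contacts break and reform on the millisecond scale
while the peptide stays bound. PL* is therefore assigned the *free-protein*
chemical shift (the local environment of the reporter amide is free-like),
while the binding step carries the full shift difference
$\Delta\omega = \Omega_{PL} - \Omega_P$. A single transverse relaxation
rate $R_2$ is shared by all three states. Both are model assumptions, fixed
in the code rather than exposed as knobs.

Transverse magnetization evolves under the Bloch–McConnell equations,
a linear system $\dot{M} = K M$ with
$M = (M_P, M_{PL}, M_{PL^*})^T$, diagonal entries
$-i\,2\pi\Omega - R_2 - (\text{outflow})$ and exchange rates on the
off-diagonals. The bimolecular step enters pseudo-first-order at the fixed
equilibrium free-ligand concentration $[L]$; ligand magnetization is never
tracked (protein-observed experiment). Because exchange conserves
magnetization, the real parts of the column sums of $K$ equal $-R_2$ — an
invariant asserted in the tests.

### Equilibrium

Initial magnetization is proportional to the equilibrium concentrations.
Substituting $[PL^*] = (k_2/k_2')[PL]$ into the mass balances gives the
quadratic

$$k_{1,\mathrm{on}} A^2 [PL]^2
 - \left(k_{1,\mathrm{off}} + k_{1,\mathrm{on}} A ([P_0]+[L_0])\right)[PL]
 + k_{1,\mathrm{on}}[P_0][L_0] = 0,
 \qquad A = 1 + k_2/k_2'$$

The smaller root is always the physical one (the larger violates
$A[PL] \le \min(P_0, L_0)$). It is evaluated in the Citardauq form
$2c/(-b+\sqrt{b^2-4ac})$, which remains accurate when
$k_{1,\mathrm{off}} \ll k_{1,\mathrm{on}}P_0$ — at $K_d = 484$ fM and
$P_0 = 250\,\mu$M the naive formula would lose all significant digits.
Round-off no larger than $10^{-15} P_0$ in magnitude is clamped to zero.
Units are molar and seconds throughout; "equivalents" ($L_0/P_0$) exists
only at the interface.

### Propagation, echo and processing

The FID $s(t) = M_P + M_{PL} + M_{PL^*}$ is sampled at multiples of the
dwell time from the *exact* solution of the linear system
(eigen-decomposition of $K$; the generator is generically diagonalizable).
Generic ODE stepping would be both slower and less accurate; the contract —
agreement with a fine-step explicit integrator to $10^{-8}$ relative — is
what the tests enforce, using an independent fixed-step RK4 oracle.

Losses during the HSQC transfer periods are modeled by an ideal spin echo
of total duration 11 ms preceding acquisition:
$M \mapsto U\,\overline{U M_0}$ with $U = e^{K\tau/2}$ and element-wise
conjugation standing in for an instantaneous 180° pulse. Shift evolution
refocuses; relaxation and exchange between states of unequal shift
attenuate. With no exchange the attenuation is exactly $e^{-R_2\tau}$ with
zero net phase (tested to $10^{-10}$). Pulse imperfections are out of
scope.

Processing follows the standard pipeline: apodization with a shifted
cosine bell over the acquired points (unity at $t=0$, zero at the end of
acquisition; the exact window parameters used on the original spectrometer
data are unpublished, so this common choice is the default and `"none"` is
available), zero filling, discrete Fourier transform, real part. The first
FID point is halved — the textbook correction that removes the baseline
offset of the one-sided sampled transform, needed for the Lorentzian
width tests to be clean. The sign convention (a species at $+\Omega$ Hz
peaks at $+\Omega$ Hz) is pinned by a single-species test. Real-part
detection is the default; magnitude mode is an option since the processing
mode of the compared traces is not stated in the source experiments.

Default acquisition is 4000 Hz spectral width, 2048 complex points,
zero-fill factor 2. These resolve sub-Hz peak positions after
interpolation and are fully configurable; tests and the acceptance script
use 512 points where speed matters, which at these linewidths (16–95 Hz)
loses nothing of substance.

### Peak measurement

`measure_peak()` refines the discrete maximum by parabolic interpolation
and measures FWHM by linear interpolation of the half-height crossings. It
deliberately performs no baseline correction: a constant offset leaves the
position invariant but biases the width, so callers window appropriately.

## Titration series and CSP

The default equivalents grid is the published titration protocol: 0.1-step
from 0 to 1.5, then 0.5-step to 5.5 (24 points). Chemical shift
perturbations use the weighted Euclidean form
$\sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N/4)^2}$. Two readings of the
printed formula differ in whether the nitrogen scaling is $1/4$ inside the
square or $1/4$ applied to the squared difference; the first is
implemented as the default and the second is available as
`nitrogen_weighting = "quarter_squared"`. The nitrogen divisor 4 (rather
than the also-common 5) is kept as printed. Residues unassigned in either
state get CSP 0 by definition, but records carry the assignment flags so
"zero" and "unknown" stay distinguishable downstream.

Bin boundaries are stated in the source as strict inequalities, which
leaves the boundary points unassigned; we impose half-open-up bins
uniformly: $[1,\infty)$ very strong, $[0.5,1)$ strong, $[0.25,0.5)$
moderate, $[0.11,0.25)$ weak, $[0,0.11)$ none. Classification is a total
function on $[0,\infty)$.

## Fitting

The original analysis judged agreement between simulated and experimental
traces by visual inspection of peak positions and line widths. To make
acceptance mechanical, two objectives are provided:

* **pointwise** — sum of squared differences of the real spectra over the
  analysis window, each *series* normalized by its own global maximum.
  Normalizing per slice instead would be closer to one reading of the
  procedure, but it destroys the relative-intensity information across
  titration points (on which the slow-exchange buildup argument rests)
  and makes strongly exchange-broadened slices noise-dominated, since
  their own maximum is mostly noise at realistic noise levels. The global
  normalization keeps the objective invariant to a common amplitude scale
  of the data, which also makes the `scale` parameter exactly flat — the
  identifiability scan reports it as such rather than hiding it.
* **feature** — squared errors of peak position and FWHM per slice, in
  units of the axis step; the direct translation of "optimize agreement of
  peak position and line-widths".

Optimization is multi-start local least squares: rates, $R_2$ and scale in
log space (they span decades), offsets linearly scaled to comparable
magnitude; starts are the user's guess plus seeded log-uniform draws
within finite bounds; Nelder–Mead (Brent in one dimension) with an
out-of-box quadratic penalty. The Kd constraint
$k_{1,\mathrm{off}} = K_d \cdot k_{1,\mathrm{on}}$ mirrors how the original
rates were chosen ("ratio in the range of the measured or predicted Kd").

Whether slices are fitted jointly or per point was not stated in the
source; joint fitting over a user-chosen window and slice subset is the
default, per-point fitting is a one-line `subset_titration()` away. In
practice including the apo (0 equivalents) slice matters: it pins $R_2$,
which otherwise trades off against exchange broadening and biases the
recovered $k_2, k_2'$.

**Identifiability.** After convergence the finite-difference Hessian of
the objective (step 0.05 in transformed units) is eigen-decomposed;
directions with curvature below $10^{-4}$ of the largest eigenvalue are
declared near-flat and every parameter loading $>0.3$ on such a direction
is flagged. The threshold was calibrated once against the two known sloppy
configurations — the exactly-flat amplitude scale, and the
$(\Omega_{PL}, k_2, k_2')$ ridge that appears when only a saturated slice
constrains a free bound-state shift (relative curvature $\sim 4\times
10^{-5}$, versus $>10^{-3}$ for well-posed directions) — and is exposed as
a default, not a moving part. Flat directions are *reported*, never
silently resolved.

**Model comparison** fits the two-state restriction ($k_2 = 0$) and the
full model with shared settings and reports both objectives and their
ratio. The three-state fit is additionally started from the two-state
optimum with $k_2$ at its lower bound, so nestedness (three-state
objective ≤ two-state objective) holds up to optimizer tolerance by
construction on any data.

## The synthetic-data world

The generator's defaults are the stated experimental conditions:
$P_0 = 250\,\mu$M, the 24-point equivalents grid, 11 ms echo, and the two
published preset parameter sets (Kd = 300 nM with $k_2 = 30$,
$k_2' = 700$ s⁻¹, $\Delta\omega = 294$ Hz; Kd = 484 fM with $k_2 = 30$,
$k_2' = 100$ s⁻¹, $\Delta\omega = 246$ Hz). Two quantities are not printed
anywhere and were chosen once:

* $R_2 = 50$ s⁻¹ — a typical amide transverse relaxation rate for a
  35–55 kDa protein complex at 310 K on a 600–700 MHz spectrometer.
* noise $\sigma = 0.01$ of the global maximum height — conservative for
  cryoprobe HSQC titration data; the acceptance criteria quote 1–2%.

The free-protein offset is anchored at 0 Hz: only $\Delta\omega$ is
physically constrained, absolute offsets are irrelevant to the exchange
physics. Noise is injected in the frequency domain (the compared traces
are processed frequency-domain data), independent Gaussian per frequency
point, seeded; a time-domain complex-noise option was considered and
rejected as default because it would couple noise across the spectrum
without changing any tested conclusion. The generator restores the
session RNG state, so fixture generation does not perturb user code.

What the generator does *not* emulate: 2D spectral structure and
$^{15}$N-dimension noise correlations, baseline distortions, solvent
artifacts, temperature drift across titration points, and peak overlap
from neighboring residues. A green recovery test therefore establishes
that the estimator is consistent and well-conditioned under the stated
world, not that real spectra of arbitrary quality will yield 10%-accurate
rates.

## Numerical choices, degenerate inputs, limitations

* $k_2 > 0$ with $k_2' = 0$ is rejected (PL* would be absorbing and the
  equilibrium ratio undefined); $k_2 = 0$ cleanly reduces to two-state
  exchange, which the tests pin against an independent closed-form
  two-site solution built from the $2\times2$ partial-fraction propagator.
* $L_0 = 0$ and $k_{1,\mathrm{on}} = 0$ short-circuit to $[PL] = 0$ before
  the quadratic is touched.
* The eigen-propagator assumes a diagonalizable generator; exact Jordan
  degeneracy occupies a measure-zero parameter set and does not occur for
  physical inputs with distinct shifts or nonzero exchange.
* Spectral windows must satisfy
  $SW > 2\max(|\Omega_P|,|\Omega_{PL}|) + 10 R_2/\pi$, enforced at
  simulation time, so peaks and their tails stay inside the window.
* The magnitude-spectrum integral is *not* invariant under exchange (it
  grows logarithmically with linewidth); the conserved quantity is the
  integral of the complex (or real-part) spectrum, which equals the first
  FID point — that is what the signal-conservation property test asserts.
* The two-peptide sequential-binding regime observed for short peptides on
  the seven-module protein is out of scope, as are 2D simulation,
  structure refinement and any vendor binary formats.
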