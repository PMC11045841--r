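---
title: "Trajectory-ensemble analysis of photoisomerization quantum efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-ensemble analysis of photoisomerization quantum efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodyn)
```

## The problem

Light-driven molecular rotors — the 11-cis retinal protonated Schiff base
(rPSB11) in rhodopsin and its synthetic indanylidene–pyrrolinium mimics
(NAIPs) — convert photons into unidirectional rotation about an ethylenic
double bond.  Their photoisomerization quantum efficiency
$\Phi^{\mathrm{iso}}$ (the fraction of excited molecules that reach the
isomerized product) differs sharply between the natural pigment
(measured and computed near 67%) and the solvated synthetic rotor (near
20–30%).  Quantum-classical surface-hopping trajectory ensembles explain
this difference through the kinematics of a handful of internal
coordinates at the moment of S$_1 \to$ S$_0$ decay.  `isodyn` implements
that analysis as a reusable, tested pipeline, together with synthetic
ensemble generators so that every stage can be exercised — and the
statistical machinery validated — without any quantum-chemistry compute.

## Internal coordinates

For the reactive fragment C1–C2(R1)=C3(R4)–C4 the pipeline measures, per
1 fs frame:

* $\alpha$ — the C1–C2–C3–C4 dihedral, the double-bond twist and reaction
  coordinate.  A counterclockwise (CCW) isomerization runs
  $0 \to -90 \to -180^\circ$; the series is therefore unwrapped so that
  consecutive differences stay below $180^\circ$ in magnitude.
* $\beta$ — the R1–C2–C3–R4 dihedral, the wag of the ethylenic
  substituents relative to the backbone.
* $\delta_{\mathrm{op}} = \alpha - \beta$ — the out-of-plane wag
  coordinate.
* $\tau = \alpha - \tfrac12\,\delta_{\mathrm{op}} = (\alpha + \beta)/2$
  — the dihedral tracking the overlap of the C2/C3 $p$-orbitals:
  $\tau = 0$ at the cis reactant, $-90^\circ$ where the overlap vanishes
  at the conical intersection, $-180^\circ$ at the trans product.  This
  definition reproduces all three calibration geometries and gives the
  exact velocity identity
  $\dot\tau = \dot\alpha - \tfrac12\,\dot\delta_{\mathrm{op}}$, which the
  test suite asserts to $10^{-9}$ on every frame.
* $\rho$, $\gamma$ — ring-inversion dihedrals of the pyrroline and
  indanylidene five-membered rings (when mapped), and BLA, the
  bond-length alternation of the conjugated path (mean formal single
  minus mean formal double bond length); the bond partition comes from
  the user's map, not hard-coded chemistry.

Velocities are forward differences over the actual frame spacing
(deg/fs), except at the decay point, where the backward difference into
the last S$_1$ frame is used so the velocity is defined before the
ground-state force field acts.

## Decay detection and classification

Each trajectory contributes one decay point: the first S$_1 \to$ S$_0$
transition of the per-frame state sequence (S$_2 \to$ S$_1$ relaxation is
ignored; re-crossings after the first hop are not counted).  When a file
carries no state labels, an explicit hop sidecar table is required — the
reader never infers hops from geometry.

A trajectory is *reactive* when its final unwrapped twist lies within
$\pm 45^\circ$ of $-180^\circ$ (CCW product), *unreactive* within
$\pm 45^\circ$ of $0^\circ$ (regenerated reactant), and *undecided*
otherwise (reported separately and excluded from fractions).  The
$\pm45^\circ$ window is a design choice: the source analysis classifies
"by the configuration reached after the hop" without a numeric rule, and
$\pm45^\circ$ separates the three basins unambiguously.  The comparison
uses circular distance, so the label is invariant under whole-series
$360^\circ$ shifts.  Trajectories that never decay are excluded by
default (`undecayed = "exclude"`); a switch counts them as unreactive
instead, because how undecayed trajectories were treated in the original
tables is not documented.

## Condition statistics

`condition_table()` computes, over classified records,
$\Phi^{\mathrm{iso}}$ and the conditional fractions that link reactivity
to the decay velocity $\dot\tau^{\mathrm{decay}}$: the full-population
fraction with $\dot\tau^{\mathrm{decay}} < 0$, the fraction of the
reactive population with $\dot\tau^{\mathrm{decay}} < 0$, the reactive
fraction of the negative-velocity population, and the occupancy and
reactivity of the low-amplitude band $(-0.8, 0)$ deg/fs where the sign
condition loses predictive power.  An exact zero counts as non-negative.
The law of total probability
$\Phi = P(\mathrm{react}\mid\dot\tau<0)\,P(\dot\tau<0) +
P(\mathrm{react}\mid\dot\tau\ge 0)\,P(\dot\tau\ge 0)$ holds exactly and
is asserted in the tests.  Wilson 95% score intervals accompany
$\Phi^{\mathrm{iso}}$ (the original tables report no uncertainties;
intervals are needed to compare runs honestly).  Decay-velocity
histograms use 1 deg/fs bins from $-10$, with a 0.2 deg/fs inset on
$(-1, 1)$; out-of-range values are clipped into the end bins and
counted.

Ensemble-average series (`ensemble_average()`) are survivor averages:
each time bin averages only trajectories still excited at that time.
This matches the visual convention of average curves drawn over the
undecayed population; it is stated here because it is a convention, not
a theorem, and empty bins are masked rather than zero-filled.

## Kinetic and oscillation fits

The S$_1$ population curve (fraction of trajectories still excited;
exactly $1 - $ ECDF of the first-S$_0$ times) is fitted with the
lag-plus-two-channel decay law

$$f(t) = a_1 e^{-((t-t_1)/t_2)^2} + y_0 + ((1-a_1)-y_0)\,
  e^{-(t-t_1)/t_2},$$

in which a Gaussian and an exponential channel *share* the lag $t_1$ and
decay time $t_2$.  The shared-$t_2$ form is implemented exactly as
printed in the source; because the accompanying text speaks of two decay
times, an optional third parameter (`separate_exp_tau = TRUE`) gives the
exponential channel its own $t_3$.  Both factors are clamped to 1 before
the lag so the curve is flat at 1 until $t_1$.  Fitting is bounded
Levenberg–Marquardt with multi-start initialisation ($t_1$ from the
decay onset, $t_2$ from the $1/e$ crossing, three $a_1$ starts); on
noiseless synthetic curves the parameters are recovered to better than
1%.  The characteristic "fitted S$_1$ lifetime" is reported as
$t_1 + t_2$ — an interpretive choice (lag plus decay constant), flagged
as such — alongside the assumption-free mean decay time.

Oscillation periods (wag, ring inversion) come from bounded
least-squares sinusoid fits $A\sin(2\pi t/T + \varphi) + c$, initialised
from the dominant discrete-spectrum frequency or a caller hint and
normalised to $A \ge 0$.  `decompose_alpha()` splits a survivor-averaged
twist curve into a monotonic component $\alpha_I$ (robust linear fit)
and an oscillatory component $\alpha_{II}$ (sinusoid of the residual,
typically at the wag period), followed by a joint nonlinear refinement —
the two-stage split alone leaves a small bias whenever the window covers
a non-integer number of periods.  The phase of $\alpha_{II}$ is
queryable at any time for synchronization analysis.  Sinusoid fits on
averaged series are restricted to times where at least 25% of the
ensemble survives; beyond that the survivor average is dominated by a
few stragglers.

`dominant_frequency()` reports spectral peaks of mean-removed series as
wavenumbers, $\tilde\nu = 1/(T c)$ with $T$ in fs and $c$ in cm/fs
(33.356 fs $\leftrightarrow$ 1000 cm$^{-1}$), refining the peak bin by
parabolic interpolation; peaks that barely rise above the median
spectral level (as for white noise) are flagged unstable.

## The synthetic ensemble generator

`generate_ensemble()` prescribes, per trajectory,

$$\alpha(t) = d\,t + A_\alpha \sin(\omega_f t + \varphi), \qquad
\delta_{\mathrm{op}}(t) = A_w \sin(\omega_f t + \varphi + \psi) +
A_p \sin(\omega_s t + \varphi_s),$$

with the per-trajectory drift $d < 0$ and oscillation phases drawn from
the configuration ($\beta = \alpha - \delta_{\mathrm{op}}$); frames are
embedded as a 6-atom C1,C2,C3,C4,R1,R4 fragment whose dihedral readback
reproduces the prescribed angles to $10^{-6}$ degrees.  Once the twist
reaches a (jittered) crossing level near $-90^\circ$, the trajectory
lingers in the intersection region and hops with a per-frame
probability — with a monotonic drift a rejected "first crossing" would
otherwise never recur, and lingering also produces physical hop-time
scatter.  The relative phase $\psi$ between the twist oscillation and
the wag is the promoter-synchronization knob: hops are selected at
*downward* twist crossings, so the wag phase encountered at decay is not
uniform, and $\psi$ controls whether the wag velocity adds to or
cancels the drift in $\dot\tau^{\mathrm{decay}}$.

The outcome rule is Landau–Zener-motivated and three-zoned:
$\dot\tau^{\mathrm{decay}} < -\theta$ (default $\theta = 1$ deg/fs) is
deterministically reactive; $-\theta < \dot\tau^{\mathrm{decay}} < 0$ is
Bernoulli with $q_{\mathrm{neg}} = 0.5$ (sub-threshold crossings are
randomized — the reported reactivity in the $(-0.8, 0)$ band is close to
50%); $\dot\tau^{\mathrm{decay}} \ge 0$ is Bernoulli with
$q_{\mathrm{pos}} = 0.12$ (bond re-making occasionally still yields
product — roughly 10% of reactive trajectories carry a small positive
decay velocity).  A symmetric rule (deterministic outside $\pm\theta$,
fair coin inside) was considered and rejected: with a negative drift it
can never produce $\Phi^{\mathrm{iso}} < 0.5$, which contradicts the
slow rotor's efficiency.  After the hop the twist relaxes exponentially
to $-180^\circ$ or $0^\circ$ according to the drawn label, the state
flips to S$_0$, and the ground truth (prescribed series, hop frame,
decay velocity, label) is recorded in a ledger against which the
pipeline is validated — classifier labels agree with the ledger for
100% of classified trajectories by construction.

### Presets

* `rh_like` — fast coherent rotor: drift $-1.5 \pm 0.5$ deg/fs (capped
  at $-0.55$), 40 fs wag of amplitude 30° with phase jitter 0.9 rad and
  offset $\psi = 1.1$ rad, twist oscillation 8°, 220 fs horizon.  Chosen
  by Monte-Carlo design over seeds so the ensemble lands at
  $\Phi^{\mathrm{iso}} \approx 0.71$, first hops near 30 fs and a decay
  window near 150 fs, with the negative-velocity and band statistics in
  the ranges reported for the natural pigment.
* `naip_like` — slow, promoter-quenched rotor: drift $-0.32 \pm 0.10$
  (capped at $-0.16$), weak 6° wag, incoherent quenched 250 fs promoter
  (10°), 620 fs horizon: $\Phi^{\mathrm{iso}} \approx 0.42$, first hops
  near 150 fs, decay window ≈ 450 fs.
* `naip_gas_like` — isolated rotor: as above but with a coherent 250 fs
  ring-inversion promoter of 40° (phase jitter 0.3 rad), giving
  $\Phi^{\mathrm{iso}} \approx 0.5$ and a single reactive wave; a ring
  dihedral series proportional to the slow promoter is emitted so the
  ring-velocity/wag-velocity correlation analysis can run.

What the generator emulates: barrierless monotonic twist progression,
superimposed fast and slow wag oscillations, hops near $-90^\circ$,
outcome governed by the sign and amplitude of
$\dot\tau^{\mathrm{decay}}$, and the two decay-timing regimes.  What it
does not emulate: bond-length dynamics, pyramidalization, charge
transfer, multi-bond (bicycle-pedal) isomerization, or any force-field
physics — passing tests on generated ensembles validate the *analysis*,
not the electronic-structure claims, which is exactly the role the
generator is meant to play.

## The surface-hopping model

`fssh_trajectory()` implements fewest-switches surface hopping for a
two-state, two-mode model: a periodic twist $\theta$ with cosine
diabatic potentials (lower state with minima at 0/$\pm180^\circ$, upper
state barrierless from the Franck–Condon region towards the crossing)
and a harmonic wag $q$, linearly coupled through $V_{12} = \lambda q$
(so a conical intersection sits at $q = 0$ near
$\theta \approx -72^\circ$ for the default `de = 0.8`; with an optional
constant coupling for 1-D avoided-crossing studies).  Model units are
$\hbar = 1$, time in fs, energy in $\hbar$/fs; no chemical accuracy is
claimed — the model is the package's own stand-in reproducing the
topography that matters (barrierless upper surface, twist-located
intersection).

Numerics: velocity-Verlet nuclear propagation on the current adiabatic
surface with analytic gradients; electronic amplitudes propagated on
substeps (default 1:20) by a norm-conserving phase/rotation/phase
splitting, with the nonadiabatic coupling from finite-difference
eigenvector overlaps (the mixing-angle difference is folded modulo
$\pi$ for sign consistency); fewest-switches hop probability
accumulated per substep; on a hop the velocity is rescaled along the
nonadiabatic coupling vector, and frustrated hops reverse that velocity
component (one documented choice among the standard conventions).
Energy-based decoherence damps the inactive amplitude with time constant
$(1/|\Delta E|)(1 + C/E_{\mathrm{kin}})$, $C = 0.1$ model-energy units
by default.  Total energy between hops is monitored and an integration
error is raised beyond a tolerance; near the intersection the
velocity-Verlet error grows with the surface curvature, so ensemble runs
use $dt \le 0.1$ fs.  In the 1-D constant-coupling limit the
single-passage hop fraction reproduces the closed-form Landau–Zener
probability within Monte-Carlo error; the test stops the trajectory
right after one seam passage, because longer horizons re-cross the seam
and mix in a second passage.  With $V_{12} \equiv 0$ the decoupled limit
is checked with a gap that never closes (`de = 2`): at an exact
degeneracy of uncoupled diabats the adiabatic labels swap and trivial-
crossing hops would fire, which is a representation artifact rather than
physics.

## Numerical choices and degenerate inputs

* Dihedrals use the atan2 two-plane construction (IUPAC sign); collinear
  triples raise rather than return garbage.
* Exact $\dot\tau = 0$ at decay counts as non-negative; hops at the very
  first frame leave velocities undefined and the record is excluded from
  velocity statistics; fewer than 5 post-hop frames set a `short_tail`
  flag.
* Constant series: sinusoid fits return amplitude 0 with the period
  flagged undefined; a constant population curve is a fit failure, not a
  silent $t_2 \to \infty$.
* Problem sizes: the study conditions use 200 trajectories per ensemble
  (as in the source data); unit tests run 3–50-trajectory ensembles, the
  quantum-efficiency window checks run ten 200-trajectory seeds, and the
  Landau–Zener check uses 200 single-passage trajectories.

## Known limitations

* The reader supports multi-frame XYZ (directory-per-trajectory or
  concatenated) with `time=`/`state=` comment tokens and a hop sidecar;
  the exact dialect of the deposited archive for the original study is
  unknown, so an adapter should be written after inspecting it rather
  than guessed at.
* The bicycle-pedal (two-bond) isomerization channel is only a counting
  hook; no second twist series is generated by the presets.
* The surface-hopping model is two-state/two-mode; three-state effects
  and explicit environments are out of scope.
* Survivor averages late in the decay rest on few trajectories; fits are
  truncated at 25% survival, and conclusions drawn past that point
  should not be trusted.
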