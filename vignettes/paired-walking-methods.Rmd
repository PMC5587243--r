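---
title: "Methods: coupled-SLIP walking and gait-synchronization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled-SLIP walking and gait-synchronization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the mechanical
model, the scores built on it, the analysis pipeline for trajectory data,
and the numerical and design choices made where the problem left them
open. Every empirical statement here is one that the test suite or
`scripts/acceptance.R` computes.

## 1. The question

When two people carry a stretcher-like object, one walking in front of the
other, their gaits change (longer gait cycle, shorter steps, lower speed)
and in a large fraction of the time they synchronize: equal stride
durations with a constant phase lag between homologous legs. Viewing the
subject-object-subject system as one four-legged body, the phase lag maps
the emergent patterns onto quadrupedal gaits - pace near 0 degrees, trot
near 180, diagonal-sequence near 225. The package asks how much of that
coordination passive mechanics alone can produce, by coupling two minimal
walking models through a spring-damper-carried mass, and provides the
analysis pipeline needed to quantify synchronization in (real or
synthetic) motion-capture trajectories.

## 2. The mechanical model

Each walker is a spring-loaded inverted pendulum (SLIP): a point mass $m$
on massless spring legs of rest length $l_0$ and stiffness $k_{leg}$, with
the swing leg held at a fixed angle of attack $\alpha$. Walking (unlike
running) alternates single and double support; per pendulum the support
state is encoded by two switches $(\gamma, \beta)$: $(1,0)$ single support
after the apex, $(1,1)$ double support, $(0,1)$ single support before the
apex. With $P_i = k_{leg}(l_0/\sqrt{x_i^2+z_i^2} - 1)$ the back-leg spring
force coefficient and $Q_i$ the same expression for the front leg (foot
separation $a_i$), the sagittal-plane equations of motion are

$$m_i \ddot x_i = P_i x_i \gamma - Q_i (a_i - x_i)\beta - F_{it}, \qquad
  m_i \ddot z_i = P_i z_i \gamma + Q_i z_i \beta - m_i g,$$

and the carried object of mass $m_t$ obeys
$m_t \ddot X_t = F_{1t} + F_{2t}$ with horizontal arm forces
$F_{1t} = -k_1 (L_1 - L_{01}) - b_1 \dot L_1$ and
$F_{2t} = +k_2 (L_2 - L_{02}) + b_2 \dot L_2$, where $L_1, L_2$ are the
horizontal distances between each walker's CoM and the near end of the
rigid object (length $L_t$). Vertical interaction forces are neglected:
measured handle forces vary far more along the direction of travel than
vertically. Because the arms always start at their equilibrium lengths,
only the deviations $L_i - L_{0i}$ matter and the specific $L_{0i}$ are
irrelevant.

**A sign choice, flagged prominently.** A literal transcription of the
vertical equations would subtract the front-leg term ($-Q_i z_i \beta$),
which makes the front stance leg push the centre of mass *downwards* while
its horizontal component pushes backwards - a leg that pulls along half
its axis and pushes along the other half. The package default uses
$+Q_i z_i \beta$, so both stance legs exert force along the leg away from
the foot, consistent with the horizontal components and with energy
accounting. The literal variant remains available
(`strict_signs = TRUE`); a test documents its signature consequence: in a
symmetric double support the two vertical leg forces then cancel exactly
and the CoM is momentarily in free fall.

**Hybrid events.** `simulate_paired()` integrates the smooth dynamics
between events and localizes events by root-finding
(`deSolve::lsodar`): touchdown when a descending CoM reaches
$z = l_0\sin\alpha$ (the new foot is planted $l_0\cos\alpha$ ahead);
liftoff when the trailing leg extends back to $l_0$; apex when $\dot z$
crosses zero from above while vaulting over the leading leg. At apex the
stance reference is relabelled and the apex state recorded - the Poincare
section of the return map. Both engagement events happen at exactly rest
length, so spring forces are continuous across every transition and the
mechanical energy ledger closes. The spring law is bilateral while a leg
is engaged (engagement is governed solely by the events, not by the sign
of the deflection); a stance leg momentarily stretched past $l_0$ pulls.

**Failure.** A trial is truncated, and scored as non-periodic, when a CoM
falls below $0.2\,l_0$, an engaged leg compresses below $0.1\,l_0$, or
the forward velocity stays negative for more than 0.2 s. The truncated
trace is still returned: falling cells must score 0, not error out.

**Apex initial conditions - the one genuinely contested reading.** An
apex state is fixed by the pendulum's energy $E_0$ and the apex position
$(x_{apex}, z_{apex})$, with $z_{apex}$ measured "with respect to the
height reached by the CoM when the leg's spring is at rest". Two heights
satisfy that description: the standing height $l_0$ (CoM atop a vertical
rest-length leg) and the touchdown height $l_0\sin\alpha$ (at touchdown
the landing leg is exactly at rest length). The package default is the
touchdown reference, for two reasons that the test suite reproduces.
First, feasibility: with the rest-length reading, the documented
asymmetric starting energies (810 J at an apex of +2.5 cm for an 80 kg,
1 m-leg walker) are below the potential-plus-spring energy of the state
they are supposed to define. Second, behaviour: under the rest-length
reading the initial forward velocity is 0.61 m/s and no sustained gait
exists anywhere near the reference stiffness and angle of attack, while
under the touchdown reading (initial speeds 0.95-1.33 m/s) the reference
parameter set walks the full 100 s window with post-transient apex
residuals of order $10^{-5}$ m. Both conventions are implemented
(`slip_init(reference = )`); the rest-length energy balance is tested in
its own mode.

## 3. Scores and the systematic search

**Periodicity** $S_P$. Per pendulum, the residuals are the Euclidean
apex-to-apex changes $r_i = |(x_{apex}, z_{apex})_{i+1} -
(x_{apex}, z_{apex})_i|$. The transient index $j$ is the smallest index
such that $r_i < \xi$ for all $i > j$ (both pendulums at once);
$\xi = 10^{-3}$ m by default, the order of the apex-height variability of
human walkers. $RMS_k$ is the RMS of pendulum $k$'s post-transient
residuals, $RMS = \sqrt{RMS_1^2 + RMS_2^2}$, and
$S_P = \log_{10}(\xi / RMS)$; gaits with no such $j$ score 0. The RMS is
floored at $10^{-12}$ so numerically exact periodicity yields a large
finite score; the floor is reported. $S_P$ decreases monotonically in
$\xi$ while the transient index is unchanged; across a $\xi$ range wide
enough to move $j$, the post-transient set itself changes and strict
monotonicity is not guaranteed - the test pins the fixed-$j$ case.

**Synchronization** $S_S$ and **data agreement** $S_R$. The exact forms
used by the original study live in supplementary material that is not
available; the package implements documented stand-ins honouring their
verbal definitions, and both are plain R functions that can be swapped.
$S_S = \min(\bar T_1, \bar T_2)/\max(\bar T_1, \bar T_2)$, the ratio of
mean post-transient apex-to-apex periods.
$S_R = \exp(-\sum_k |z_k - z^{ref}_k|/\sigma_z + |v_k - v^{ref}_k|/\sigma_v)$
with scales $\sigma_z = 0.01$ m and $\sigma_v = 0.1$ m/s, the order of
between-trial variability of apex height and speed. The reference
velocity is the forward CoM velocity *at apex*, not the cycle mean: only
the apex velocity closes the energy balance that reconstructs a
pendulum's initial energy from its reference gait (using the cycle mean
misstates the energy by several joules and visibly degrades fitting).
The global score is $S_G = S_S \cdot S_R \cdot S_P$.

**Three-step search.** Searching four parameters at once is wasteful;
the search holds two fixed while sweeping two: step 1 sweeps
$(k_{leg}, \alpha)$ for a solo pendulum; step 2 sweeps the shared arm
impedance $(k_{arm}, b_{arm})$ with legs fixed, starting the two
pendulums from *different* energies (810/840 J) so the arms are
dynamically loaded and entrainment is actually exercised; step 3
re-sweeps the legs with arms fixed. Every cell simulates 100 s (the
analysis scripts use 60 s and 7x7 grids at the desk scale; finer grids
only sharpen the maps). Ties break deterministically toward the smallest
parameter values. Equal-score plateaus are real, not numerical: the arm
impedance direction is nearly flat in $S_G$ because entrainment erases
the initial asymmetry, which is why the fitting tests assert exact
recovery of the identifiable leg parameters and plateau-closeness - not
cell identity - for the arms. The two arm optima shipped as presets
(`reference_gait_parameters(arms = )`, 3100 N/m with 200 N s/m and
3500 N/m with 320 N s/m) reflect that same flatness.

**Trial fitting.** `trial_fitting()` runs the three steps with the
pendulums' mass and leg length pinned to the subjects'. Solo fitting
derives each pendulum's energy from the subject's solo apex height and
apex velocity and maximizes $S_P$ only - the resulting paired simulation
is a *prediction* of paired behaviour. Paired fitting maximizes $S_G$
against paired-trial references, forcing the model to reproduce the
observed paired gait.

## 4. The analysis pipeline

**Preprocessing.** Trajectory CSVs (`time,<name>_x,_y,_z`; seconds and
meters; empty cells are gaps) are validated on read: strictly increasing
uniform time base (tolerance $10^{-9}$ s), one sample per channel per
time point. Gaps shorter than 0.2 s are filled by linear interpolation;
longer gaps, and gaps touching the recording edge, are errors - no
extrapolation, ever. Filtering is zero-phase Butterworth (default 4th
order, 10 Hz at 100 Hz sampling - standard gait practice; a nominal
"300 Hz" cutoff cannot be taken literally at mocap rates and any cutoff
is configurable), with reflection padding because a zero-state
forward-backward pass would otherwise distort even a constant signal near
the edges.

**Heel strikes.** Strikes are local minima of heel height, selected by
prominence (at least 20% of the peak-to-peak range) and separation (at
least 0.5 s), then refined in two stages: the weighted centroid of the
valley floor (the contiguous region within 10% of the range above the
minimum), then the point minimizing the left/right mirror mismatch of
the signal around it. The refinement matters: heel-height valleys are
nearly flat around ground contact, so a raw argmin wanders by several
samples under millimetre noise, while the symmetry point stays
sub-sample accurate (the suite checks recovered strike times to within
one sample at 2 mm noise). Valleys clipped by the recording edge are
dropped for the same reason edge gaps are not extrapolated.

**Stride metrics.** GCT is the interval between consecutive same-foot
strikes; step length the forward-axis distance between the two heels at
each strike instant; velocity the mean central-difference derivative of
the forward CoM coordinate (one-sided at the ends; vertical and lateral
velocities are not analyzed). CoM itself comes from anthropometric
segment weights: a mass-fraction-weighted sum of segment CoM positions,
each a fixed fraction along its proximal-distal marker pair; the default
table uses standard adult (Dempster) coefficients for a reduced marker
set and is fully overridable, since the exact table behind any given lab
pipeline varies.

**Phase lag.** The trial is cut into one window per stride of the
reference walker. In each window both heel-height signals are
mean-removed (raw positive signals bias an un-normalized correlation
toward zero lag) and cross-correlated with the definitional sequence
$c(m) = \hat R_{xy}(m - N)$, computed directly, without FFT or
normalization - the implementation is checked elementwise against a
double-loop evaluation of the definition. For the argmax the two linear
halves one window length apart are folded together
($c(\ell) + c(\ell - N)$, the circular correlation of the stride
window): the raw linear argmax carries a finite-window truncation bias
that pulls harmonic-rich heel waveforms several samples inward (about 24
degrees at a half-stride delay for the generator's waveform), while the
folded estimator is exact for any periodic waveform and identical to the
raw rule for sinusoids. The raw behaviour is kept under `fold = FALSE`.
The lag $\ell^*$ maximizing the folded correlation gives
$\phi = (-360\,\ell^*/N) \bmod 360$, so a walker trailing by half a
stride shows $\phi = 180$ degrees; delays of 0, 1/2 and 5/8 of a stride
map exactly onto the pace/trot/diagonal-sequence anchors 0, 180 and 225.

**Synchronization and gait classes.** A stride window is synchronized
when (i) the two walkers' stride durations differ by less than 4% of
their mean - a threshold comparable to a healthy walker's stride-time
variability - and (ii) the window's phase lag deviates circularly by at
most 10 degrees from the running circular mean of the preceding windows
(the first defined window anchors the reference; deviations are
circular, so 355 and 5 degrees differ by 10). Gait classes use a half
width of 22.5 degrees - half the 45-degree trot/diagonal-sequence
spacing - with trot taking precedence where bands overlap; the
classification is invariant under full turns. The synchronized fraction
is monotone non-increasing as the phase tolerance shrinks because the
reference does not depend on the tolerance.

**Shape comparison.** Vertical CoM curves are stride-normalized: each
stride linearly resampled onto 1000 points of percent gait cycle, then
averaged and mean-centered. The dissimilarity measure is the square root
of the summed squared pointwise differences after centering both curves
- translation removal in the spirit of Procrustes analysis; scaling and
rotation have no meaning for 1-D functions of cycle percent, and a raw
uncentered variant is available. Centering before or after averaging is
equivalent for the mean curve.

**Interlimb coordination.** The arm oscillation is the forward relative
displacement between the object's CoM and a walker's CoM; its per-cycle
periods (differences of consecutive local maxima) are paired with the
step periods containing them and summarized by a Pearson correlation and
a least-squares line, both delegated to base R.

## 5. The synthetic-trial generator

With the original recordings undeposited, every pipeline stage is
exercised on generated trials with known ground truth. Per subject the
generator emits heel channels (vertical: raised $|\sin|^4$, whose flat
sharp-bottomed valleys deliberately stress minima detection the way real
heel trajectories do; forward: a smoothed staircase advancing one step
per half stride with a 60% duty factor) and a CoM channel (forward:
linear progression plus a small in-step oscillation; vertical: a
sinusoid at twice the stride frequency, 3 cm half-amplitude). Subject B
trails subject A by a configurable constant or drifting phase lag;
paired trials add an object channel whose forward oscillation periods
jitter around the step period (SD 0.02 s). Defaults - 8 strides per
trial, stride 1.1 s, step 0.65 m, 100 Hz, Gaussian marker noise up to a
few millimetres - match a short laboratory walkway protocol of about
eight steps per pass. Identical seeds give bit-identical trials, and the
recorded truth (strike times, stride periods, a time-indexed per-stride
phase-lag table) is exactly what the emitted channels realize.

What passing these tests does *not* show about real data: the generator
has no marker occlusion or relabelling artefacts, no soft-tissue or
footwear variation in the valley shape, no speed drift within a pass,
and its waveforms are exactly periodic between strikes. Recovery
tolerances met on it (strikes within one sample, phase within 5 degrees,
step length within 2% at 2 mm noise) are therefore necessary, not
sufficient, for field performance.

## 6. Numerical choices

* Integrator: `lsodar` with `rtol` $10^{-9}$, `atol` $10^{-11}$;
  return-map residuals at the $10^{-3}$ m scale demand much tighter
  integration than the trajectories themselves. Root crossings in the
  non-triggering direction (e.g. the liftoff root touched while the leg
  is still shortening) are stepped past with a $10^{-9}$ s nudge.
* Event bookkeeping stores absolute CoM and foot positions; the
  foot-relative coordinates of the equations are derived views, so
  repeated stance relabelling accumulates no error.
* $g = 9.81$ m/s$^2$. Object defaults $m_t = 7.5$ kg, $L_t = 2$ m (the
  modelled object; the experimental one weighed 8 kg over 1.5 m) - both
  configurable.
* The object starts at the mean of the two walkers' apex velocities;
  with asymmetric energies some initial damper loading is unavoidable
  and this choice splits it evenly.
* Energy audits: with undamped arms the coupled system conserves energy
  to better than $10^{-8}$ relative over 10 s; with damping, the energy
  decrease matches the trapezoidal integral of
  $b_1\dot L_1^2 + b_2\dot L_2^2$ to 1%. Even the symmetric pair
  dissipates slowly (about 2.3 J over 100 s) because the object rides on
  springs against the within-step speed oscillation - which is exactly
  why the model's periodic orbits are approximate, and why the scores
  are built around a tolerance rather than exact recurrence.
* Problem sizes: module tests run seconds-long simulations and small
  grids; the acceptance checks run one 100 s paired simulation (about
  4 s of wall time) and fitting on 3-4 point grids per axis at a 40 s
  horizon. The analysis scripts use 7x7 grids at 60 s per cell.

## 7. Known limitations

* Sagittal-plane only: pace and trot are distinguished by bookkeeping
  (which "side" each pendulum's legs are assigned to), not by lateral
  dynamics, and the model cannot produce a genuine diagonal-sequence
  gait - dissipation drives the two pendulums toward identical motion.
* Massless legs: no swing dynamics, so angle of attack is a parameter,
  not a control outcome.
* The S_S/S_R stand-ins are faithful to their verbal definitions but not
  to unavailable exact formulas; they are pluggable by construction.
* The arm-impedance direction of the search is weakly identifiable (a
  score plateau); report arm estimates with that caveat.
* The walking SLIP's basin is narrow: small changes in $(k_{leg},
  \alpha, E_0)$ turn walking into falling within a step or two. That is
  a property of the model family, and the search exists precisely to map
  the viable region.
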