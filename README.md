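# pairedslip

Mechanics and analysis of *paired walking*: two people carrying a rigid,
stretcher-like object, one in front of the other. Walkers in that
situation slow down, shorten their steps, and - strikingly - tend to
synchronize, settling into footfall patterns that look like quadrupedal
gaits (pace, trot, diagonal sequence) when the subject-object-subject
system is read as one four-legged body. `pairedslip` is for locomotion
researchers who want to ask, at the desk, how much of that coordination
passive mechanics alone explains, and to quantify synchronization in
motion-capture-style trajectory data.

The package has two halves:

* **Model.** A hybrid-dynamics simulator of two spring-loaded inverted
  pendulums (SLIPs) coupled through a carried mass by horizontal
  spring-damper "arms". Per pendulum $i$, with leg-spring coefficients
  $P_i = k_{leg}(l_0/\sqrt{x_i^2+z_i^2}-1)$ (back leg) and $Q_i$ (front
  leg), support switches $(\gamma,\beta)$ and arm forces $F_{it}$:

  $$m_i\ddot x_i = P_i x_i\gamma - Q_i(a_i - x_i)\beta - F_{it},\quad
    m_i\ddot z_i = P_i z_i\gamma + Q_i z_i\beta - m_i g,\quad
    m_t\ddot X_t = F_{1t} + F_{2t}.$$

  Touchdown ($z = l_0\sin\alpha$), liftoff (trailing leg back at $l_0$)
  and apex ($\dot z = 0$) are localized by root-finding; apex states form
  the Poincare return map. On top of it: the periodicity score
  $S_P = \log_{10}(\xi/RMS)$ of post-transient apex residuals, a
  synchronization score $S_S$ (step-period ratio), a data-agreement score
  $S_R$, the global score $S_G = S_S S_R S_P$, a three-step systematic
  parameter search, and solo-/paired-trial fitting.

* **Pipeline.** Trajectory-table I/O and preprocessing (zero-phase
  Butterworth, gap filling), heel-strike detection, gait cycle time /
  step length / forward velocity, windowed cross-correlation phase lags
  $\phi$ with quadrupedal gait classification ($\phi\approx 0$ pace,
  $180$ trot, $225$ diagonal sequence), synchronization reports (4%
  stride rule, +-10 degree phase constancy), stride-normalized CoM curves
  with a Procrustes-style dissimilarity measure, interlimb (arm)
  coordination, and a seeded synthetic-trial generator with ground truth.

## Worked example

Simulate the documented periodic paired gait - two identical 80 kg,
1 m-leg walkers (leg stiffness 17.9 kN/m, angle of attack 72.4 degrees,
arm impedance 3100 N/m with 200 N s/m) carrying a 7.5 kg object - and
score it:

```r
library(pairedslip)

ref <- reference_gait_parameters()
ic  <- search_initial_conditions(3)     # 825 J each, apex (0, 2.5 cm)
tr  <- simulate_paired(ref$p1, ref$p2, ref$coupling,
                       ic$init1, ic$init2, t_max = 100)
tr
#> <slip_trace> coupled pair, t = [0, 100.000] s, 11363 samples
#>   apexes: 271 / 271; events: 1628; completed

periodicity_score(tr)
#> <periodicity_result> S_P = 0.9210 (xi = 0.001, RMS = 1.199e-04, j = 10)
synchronization_score(tr)
#> [1] 1
round(gait_summary(tr), 4)[, c("z_apex", "vx_apex", "step_period", "velocity", "step_length")]
#>   z_apex vx_apex step_period velocity step_length
#> 1 0.9832  1.1228      0.3681   1.1544       0.425
#> 2 0.9832  1.1228      0.3681   1.1544       0.425
```

Each walker settles at a 0.37 s step period (0.74 s gait cycle), 1.15 m/s,
and the pair stays synchronized for the whole 100 s window: the largest
post-transient apex-to-apex change is 6.3e-4 m (below the periodicity
tolerance $\xi = 10^{-3}$) and apex states change by at most 0.048% step
to step. Starting the two walkers with *different* energies (810/840 J,
`search_initial_conditions(2)`) still ends in a common entrained gait -
the spring-damper arms dissipate the asymmetry (5.1 J over 100 s).

On the analysis side, a two-line check of the phase-lag machinery:

```r
time    <- seq(0, 15, by = 0.01)                    # 100 Hz
heel    <- function(d) 0.08 * abs(sin(pi * (time - 0.25 - d) / 1.2))^4
strikes <- 0.25 + 1.2 * (0:10)
pl <- phase_lag_series(time, heel(0), heel(0.6), strikes)
table(pl$phi)
#> 180
#>  10
classify_gait_type(180)
#> [1] "trot"
```

A walker trailing by half a stride is a trot; delays of 0 and 5/8 stride
give 0 degrees (pace) and 225 degrees (diagonal sequence).

## Analysis workflow

The `analysis/` scripts run the study end to end on synthetic data and
write their tables under `results/`:

1. `01_synthesize_trials.R` - a 7-pair cohort of solo + paired trials
   with known stride periods, phase lags (two drifting) and 2 mm noise.
2. `02_gait_analysis.R` - the full pipeline per trial; cohort deltas
   (paired minus solo GCT/step/speed), synchronization fractions and
   gait shares, CoM shape dissimilarities, interlimb coordination.
3. `03_model_gait.R` - reference simulations (solo, identical pair,
   entrained pair) with energy audits.
4. `04_systematic_search.R` - the three-step grid search (7x7 grids,
   60 s per cell at the desk scale).
5. `05_trial_fitting.R` - solo- and paired-trial fitting against
   model-generated reference gaits, reporting parameter recovery.

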