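test_that("apex state from energy solves the energy balance", {
  p <- slip_params(80, 1, 17.9e3, 72.4 * pi / 180, warn_range = FALSE)

  # all-potential configuration: E = m g l0 at x = z_apex = 0 leaves no
  # kinetic energy (rest-length apex reference)
  s0 <- initial_state_from_energy(p, 80 * 9.81 * 1, x_apex = 0, z_apex = 0,
                                  reference = "rest_length")
  expect_equal(s0$vx, 0, tolerance = 1e-9)
  expect_equal(s0$z, 1)

  # closed-form energy balance, rest-length reference, 2.5 cm apex
  s1 <- initial_state_from_energy(p, 825, 0, 0.025,
                                  reference = "rest_length")
  want <- sqrt(2 * (825 - 80 * 9.81 * 1.025 -
                      0.5 * 17.9e3 * 0.025^2) / 80)
  expect_equal(s1$vx, want, tolerance = 1e-12)
  expect_equal(s1$vx, 0.612, tolerance = 1e-3)

  # touchdown reference puts the same 2.5 cm apex at walking speed
  s2 <- initial_state_from_energy(p, 825, 0, 0.025)
  expect_equal(s2$z, sin(p$alpha) + 0.025, tolerance = 1e-12)
  expect_gt(s2$vx, 1)

  # insufficient energy reports the deficit
  expect_error(initial_state_from_energy(p, 100, 0, 0.025,
                                         reference = "rest_length"),
               class = "pairedslip_energy_error")
})

test_that("equations of motion satisfy closed-form force balances", {
  p <- slip_params(80, 1, 17.9e3, 72.4 * pi / 180, warn_range = FALSE)

  # spring at rest length, single support: free-fall acceleration
  d <- paired_derivatives(list(x1 = 0, z1 = 1, vx1 = 0, vz1 = 0),
                          list(mode = 1L, fb = 0, ff = NA), p)
  expect_equal(d$dvx1, 0, tolerance = 1e-12)
  expect_equal(d$dvz1, -9.81, tolerance = 1e-12)

  # symmetric double support: horizontal forces cancel
  a <- 0.6
  ds <- paired_derivatives(list(x1 = a / 2, z1 = 0.9, vx1 = 0, vz1 = 0),
                           list(mode = 2L, fb = 0, ff = a), p)
  expect_equal(ds$dvx1, 0, tolerance = 1e-10)

  # vertical equilibrium height in symmetric double support matches an
  # independent bisection on 2 k (l0/L - 1) z = m g, L = sqrt(0.09 + z^2)
  bal <- function(z) {
    L <- sqrt(0.3^2 + z^2)
    2 * p$k_leg * (p$leg_length / L - 1) * z - p$mass * 9.81
  }
  lo <- 0.8; hi <- 0.999
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (bal(mid) > 0) lo <- mid else hi <- mid
  }
  z_eq <- (lo + hi) / 2
  deq <- paired_derivatives(list(x1 = 0.3, z1 = z_eq, vx1 = 0, vz1 = 0),
                            list(mode = 2L, fb = 0, ff = 0.6), p)
  expect_equal(deq$dvz1, 0, tolerance = 1e-10)

  # printed-sign mode flips the front-leg vertical term: in a symmetric
  # double support the two legs then cancel exactly, leaving free fall
  dstrict <- paired_derivatives(list(x1 = 0.3, z1 = z_eq, vx1 = 0,
                                     vz1 = 0),
                                list(mode = 2L, fb = 0, ff = 0.6), p,
                                strict_signs = TRUE)
  expect_equal(dstrict$dvz1, -9.81, tolerance = 1e-10)

  expect_error(paired_derivatives(list(x1 = 0, z1 = 1e-14, vx1 = 0,
                                       vz1 = 0),
                                  list(mode = 1L, fb = 0, ff = NA), p),
               class = "pairedslip_singularity_error")
})

test_that("the solo reference configuration walks and conserves energy", {
  tr <- ref_solo_trace(40)
  expect_false(tr$failed)
  expect_gt(nrow(tr$apex1), 20)
  expect_gt(periodicity_score(tr)$S_P, 0)   # apex sequence settles below xi
  # mechanical energy equals E0 throughout (conservative solo walker)
  E <- mechanical_energy(tr)
  expect_equal(E[1], 825, tolerance = 1e-9)
  expect_lt(max(E) - min(E), 825 * 1e-6)
  # event bookkeeping: touchdown places the new leg exactly at rest length
  td <- tr$events[tr$events$type == "touchdown", ]
  s <- tr$state
  for (t in td$time[1:5]) {
    i <- which.min(abs(s$time - t))
    expect_equal(s$z1[i], sin(tr$p1$alpha) * tr$p1$leg_length,
                 tolerance = 2e-2)
  }
  # apexes coincide with vanishing vertical velocity
  expect_lt(max(abs(stats::approx(s$time, s$vz1,
                                  xout = tr$apex1$time)$y)), 1e-3)
  # event log is time-ordered
  expect_true(!is.unsorted(tr$events$time))
})

test_that("identical coupled pendulums stay mirror-identical", {
  tr <- ref_paired_trace(100)
  s <- tr$state
  expect_false(tr$failed)
  gap <- s$x2 - s$x1
  expect_lt(max(abs(gap - gap[1])), 1e-8)
  expect_lt(max(abs(s$z2 - s$z1)), 1e-8)
  expect_lt(max(abs(s$vx2 - s$vx1)), 1e-7)
})

test_that("energy is conserved without damping and audited with damping", {
  ref <- reference_gait_parameters()
  ic2 <- search_initial_conditions(2)
  # undamped arms: conservative coupled system (asymmetric energies so the
  # arms actually move)
  cp0 <- coupling_params(k1 = 3100, b1 = 0)
  tr0 <- simulate_paired(ref$p1, ref$p2, cp0, ic2$init1, ic2$init2,
                         t_max = 10)
  E0 <- mechanical_energy(tr0)
  expect_lt((max(E0) - min(E0)) / E0[1], 1e-6)

  # damped arms: energy decrease equals the integrated damper dissipation
  tr <- ref_step2_trace(30)
  expect_false(tr$failed)
  E <- mechanical_energy(tr)
  s <- tr$state
  expect_true(all(diff(E) <= 1e-7))      # non-increasing within tolerance
  p_diss <- tr$coupling$b1 * (s$vxt - s$vx1)^2 +
    tr$coupling$b2 * (s$vx2 - s$vxt)^2
  dt <- diff(s$time)
  dissipated <- cumsum(dt * (p_diss[-1] + p_diss[-length(p_diss)]) / 2)
  drop <- E[1] - E[-1]
  expect_lt(max(abs(drop - dissipated)) / (E[1] - E[length(E)]), 0.01)
})

test_that("wrong parameter choices make the pair fall and the trace is scored 0", {
  ref <- reference_gait_parameters()
  bad <- slip_params(80, 1, 1.2e4, 1.36, warn_range = FALSE)
  ic <- search_initial_conditions(2)
  tr <- simulate_paired(bad, bad, ref$coupling, ic$init1, ic$init2,
                        t_max = 30)
  expect_true(tr$failed)
  expect_true("failure" %in% tr$events$type)
  expect_equal(periodicity_score(tr)$S_P, 0)
})
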