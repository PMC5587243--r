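test_that("periodicity score components match brute-force re-evaluation", {
  xi <- 1e-3

  # residuals never settle: score 0 by definition
  never <- fake_trace(apex_df(x = cumsum(rep(0.01, 20)), z = rep(0, 20)))
  pr0 <- periodicity_score(never, xi = xi)
  expect_equal(pr0$S_P, 0)
  expect_true(is.na(pr0$j))

  # closed form: residuals constant at 1e-4 on both pendulums
  xs <- cumsum(c(0, rep(1e-4, 10)))
  const <- fake_trace(apex_df(xs, rep(0, 11)), apex_df(xs, rep(0, 11)))
  prc <- periodicity_score(const, xi = xi)
  expect_equal(prc$j, 0L)
  expect_equal(prc$RMS, sqrt(2) * 1e-4, tolerance = 1e-12)
  expect_equal(prc$S_P, log10(1e-3 / (sqrt(2) * 1e-4)), tolerance = 1e-12)
  expect_equal(prc$S_P, 0.8495, tolerance = 1e-4)

  # random residual sequences vs the definitional oracle
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    r1 <- abs(stats::rnorm(n, sd = 1e-3)) *
      exp(-seq_len(n) / sample(3:20, 1))
    r2 <- abs(stats::rnorm(n, sd = 1e-3)) *
      exp(-seq_len(n) / sample(3:20, 1))
    tr <- fake_trace(apex_df(cumsum(c(0, r1)), rep(0, n + 1)),
                     apex_df(cumsum(c(0, r2)), rep(0, n + 1)))
    got <- periodicity_score(tr, xi = xi)
    want <- periodicity_oracle(list(r1, r2), xi)
    if (is.na(want$j)) {
      expect_equal(got$S_P, 0)
    } else {
      expect_equal(got$j, want$j)
      expect_equal(got$RMS_k, want$rms_k, tolerance = 1e-12)
      expect_equal(got$S_P, want$S_P, tolerance = 1e-12)
    }
  }

  # numerically exact periodicity hits the documented RMS floor
  exact <- fake_trace(apex_df(rep(0.1, 8), rep(0.02, 8)))
  expect_equal(periodicity_score(exact, xi = xi)$S_P, log10(xi / 1e-12))

  # S_P decreases monotonically as xi shrinks while the transient index
  # stays fixed (a settled trace with a constant residual tail)
  rtail <- c(0.5, 0.2, rep(2e-5, 20))
  tdec <- fake_trace(apex_df(cumsum(c(0, rtail)), rep(0, 23)))
  sps <- vapply(c(1e-2, 3e-3, 1e-3, 3e-4, 1e-4),
                function(x) periodicity_score(tdec, xi = x)$S_P, 0)
  expect_true(all(diff(sps) < 0))
  expect_equal(sps, log10(c(1e-2, 3e-3, 1e-3, 3e-4, 1e-4) / 2e-5),
               tolerance = 1e-9)
})

test_that("synchronization score is a label-symmetric period ratio", {
  a1 <- apex_df(x = rep(0.1, 6), z = rep(0, 6), times = seq(0, 5, by = 1))
  a2 <- apex_df(x = rep(0.1, 5), z = rep(0, 5),
                times = seq(0, 5, by = 1.25))
  expect_equal(synchronization_score(fake_trace(a1, a1)), 1)
  expect_equal(synchronization_score(fake_trace(a1, a2)), 0.8)
  expect_equal(synchronization_score(fake_trace(a2, a1)), 0.8)
  # a pendulum without two apexes scores 0
  expect_equal(synchronization_score(fake_trace(a1, a2[1, ])), 0)
  expect_error(synchronization_score(fake_trace(a1)),
               class = "pairedslip_parameter_error")
})

test_that("real-conditions score decays with each discrepancy", {
  tr <- ref_step2_trace(30)
  sm <- gait_summary(tr)
  ref_exact <- list(z_apex = sm$z_apex, velocity = sm$vx_apex)
  expect_equal(real_conditions_score(tr, ref_exact), 1, tolerance = 1e-9)

  # one apex height off by exactly sigma_z: e^-1
  ref_z <- list(z_apex = sm$z_apex + c(0.01, 0), velocity = sm$vx_apex)
  expect_equal(real_conditions_score(tr, ref_z), exp(-1),
               tolerance = 1e-9)

  # strictly decreasing along a discrepancy ramp
  svals <- vapply(seq(0, 0.05, by = 0.01), function(dv)
    real_conditions_score(tr, list(z_apex = sm$z_apex,
                                   velocity = sm$vx_apex + c(dv, 0))), 0)
  expect_true(all(diff(svals) < 0))

  expect_error(real_conditions_score(tr, list(z_apex = 1,
                                              velocity = c(1, 2))),
               class = "pairedslip_parameter_error")
  expect_error(real_conditions_score(tr, list(z_apex = c(1, NA),
                                              velocity = c(1, 1))),
               class = "pairedslip_parameter_error")
})

test_that("global score factors combine multiplicatively", {
  tr <- ref_step2_trace(30)
  sp <- periodicity_score(tr)$S_P
  ss <- synchronization_score(tr)
  sm <- gait_summary(tr)
  sr <- real_conditions_score(tr, list(z_apex = sm$z_apex,
                                       velocity = sm$vx_apex))
  expect_gt(sp, 0)
  expect_gt(ss, 0.96)
  expect_equal(ss * sr * sp, sp * sr * ss)
  expect_equal(0 * sr * sp, 0)
})
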