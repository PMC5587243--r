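test_that("generation is deterministic in the seed and validates its config", {
  cf <- synthetic_trial_config(n_strides = 5, noise_sd = 0.002, seed = 17)
  t1 <- generate_trial(cf)
  t2 <- generate_trial(cf)
  expect_identical(t1$A$channels, t2$A$channels)
  expect_identical(t1$B$channels, t2$B$channels)
  expect_identical(t1$object$channels, t2$object$channels)
  t3 <- generate_trial(synthetic_trial_config(n_strides = 5,
                                              noise_sd = 0.002, seed = 18))
  expect_false(identical(t1$A$channels, t3$A$channels))

  # inconsistent speed vs step geometry is rejected
  expect_error(synthetic_trial_config(forward_speed = 2.0),
               class = "pairedslip_config_error")
  # solo trials carry no partner or object
  solo <- generate_trial(synthetic_trial_config(kind = "solo", seed = 2))
  expect_null(solo$B)
  expect_null(solo$object)
})

test_that("the pipeline recovers the generator's ground truth", {
  cf <- synthetic_trial_config(n_strides = 10, stride_period = 1.1,
                               step_length = 0.65, phase_lag = 180,
                               noise_sd = 0.002, seed = 23)
  trial <- generate_trial(cf)
  evA <- gait_events(trial$A)
  # detected strikes match the interior true strikes within one sample
  match_err <- function(got, truth) {
    vapply(got, function(g) min(abs(truth - g)), 0)
  }
  errR <- match_err(evA$right, trial$truth$strikes$A$right)
  expect_lt(max(errR), 1 / cf$sample_rate)
  # GCT within one sample of the true stride period
  smA <- stride_metrics(evA, trial$A)
  expect_lt(max(abs(smA$gct$gct - 1.1)), 1 / cf$sample_rate)
  # step length within 2%
  expect_lt(abs(mean(smA$step_length$length) - 0.65) / 0.65, 0.02)
  # forward speed within 2%
  expect_lt(abs(smA$velocity - cf$forward_speed[1]) / cf$forward_speed[1],
            0.02)
  # phase lag within +-5 degrees of the configured 180
  pl <- phase_lag_series(trial$A$time,
                         traj_channel(trial$A, "heelR", "z"),
                         traj_channel(trial$B, "heelR", "z"),
                         evA$right)
  expect_lt(max(abs(pl$phi - 180)), 5)

  # drifting lag: recovery tracks the time-indexed ground truth
  cfd <- synthetic_trial_config(n_strides = 10, stride_period = 1.2,
                                phase_lag = 0, phase_drift = 9,
                                noise_sd = 0.001, seed = 5)
  trd <- generate_trial(cfd)
  evd <- gait_events(trd$A)
  pld <- phase_lag_series(trd$A$time,
                          traj_channel(trd$A, "heelR", "z"),
                          traj_channel(trd$B, "heelR", "z"), evd$right)
  want <- stats::approx(trd$truth$phi$t_mid, trd$truth$phi$phi,
                        xout = (pld$t_start + pld$t_end) / 2, rule = 2)$y
  expect_lt(max(abs(pld$phi - want)), 5)
})

test_that("constructed trials produce the expected synchronization verdicts", {
  # noiseless, zero lag: fully synchronized, pace everywhere
  cf0 <- synthetic_trial_config(n_strides = 8, phase_lag = 0,
                                noise_sd = 0, seed = 3)
  tr0 <- generate_trial(cf0)
  ev0 <- gait_events(tr0$A)
  rep0 <- classify_synchronization(
    stride_metrics(ev0, tr0$A),
    stride_metrics(gait_events(tr0$B), tr0$B),
    phase_lag_series(tr0$A$time, traj_channel(tr0$A, "heelR", "z"),
                     traj_channel(tr0$B, "heelR", "z"), ev0$right))
  expect_equal(rep0$fraction_synchronized, 100)
  expect_true(all(rep0$windows$gait == "pace"))

  # 10% stride-period mismatch: the 4% rule rejects every window
  cfm <- synthetic_trial_config(n_strides = 8,
                                stride_period = c(1.0, 1.1),
                                step_length = c(0.6, 0.66),
                                noise_sd = 0, seed = 4)
  trm <- generate_trial(cfm)
  evm <- gait_events(trm$A)
  repm <- classify_synchronization(
    stride_metrics(evm, trm$A),
    stride_metrics(gait_events(trm$B), trm$B),
    phase_lag_series(trm$A$time, traj_channel(trm$A, "heelR", "z"),
                     traj_channel(trm$B, "heelR", "z"), evm$right))
  expect_equal(repm$fraction_synchronized, 0)
})
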