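make_marker_table <- function(time, markers) {
  trajectory_table(time, markers)
}

test_that("CoM computation matches the weighted-sum definition", {
  time <- seq(0, 1, by = 0.01)
  n <- length(time)
  rnd <- function() cbind(stats::rnorm(n), stats::rnorm(n), stats::rnorm(n))
  set.seed(42)
  mk <- list(a = rnd(), b = rnd(), c = rnd(), d = rnd())
  tab <- make_marker_table(time, mk)

  # single segment, comfrac 0 -> com is the proximal marker exactly
  w1 <- segment_weight_table(data.frame(
    segment = "s", mass_fraction = 1, proximal = "a", distal = "b",
    com_fraction = 0))
  expect_equal(traj_channel(compute_com(tab, w1), "com"), mk$a,
               ignore_attr = TRUE)

  # two equal segments at midpoints -> mean of the four markers' midpoints
  w2 <- segment_weight_table(data.frame(
    segment = c("s1", "s2"), mass_fraction = c(0.5, 0.5),
    proximal = c("a", "c"), distal = c("b", "d"),
    com_fraction = c(0.5, 0.5)))
  expect_equal(traj_channel(compute_com(tab, w2), "com"),
               ((mk$a + mk$b) / 2 + (mk$c + mk$d) / 2) / 2,
               ignore_attr = TRUE)

  # three unequal segments vs brute-force sample-by-sample summation
  w3 <- segment_weight_table(data.frame(
    segment = c("s1", "s2", "s3"), mass_fraction = c(0.6, 0.3, 0.1),
    proximal = c("a", "b", "c"), distal = c("b", "c", "d"),
    com_fraction = c(0.25, 0.7, 0.5)))
  got <- traj_channel(compute_com(tab, w3), "com")
  want <- matrix(0, n, 3)
  for (s in 1:3)
    for (i in 1:n)
      for (ax in 1:3) {
        p <- mk[[w3$proximal[s]]][i, ax]
        d <- mk[[w3$distal[s]]][i, ax]
        want[i, ax] <- want[i, ax] +
          w3$mass_fraction[s] * (p + w3$com_fraction[s] * (d - p))
      }
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)

  # linearity in marker positions
  mk2 <- lapply(mk, function(m) 2 * m + 1)
  tab2 <- make_marker_table(time, mk2)
  expect_equal(traj_channel(compute_com(tab2, w3), "com"),
               2 * got + 1, ignore_attr = TRUE, tolerance = 1e-12)

  # validation
  expect_error(segment_weight_table(data.frame(
    segment = "s", mass_fraction = 0.9, proximal = "a", distal = "b",
    com_fraction = 0)), class = "pairedslip_parameter_error")
  expect_error(compute_com(tab, segment_weight_table(data.frame(
    segment = "s", mass_fraction = 1, proximal = "nope", distal = "b",
    com_fraction = 0))), class = "pairedslip_missing_channel_error")
  expect_equal(sum(default_segment_weights()$mass_fraction), 1,
               tolerance = 1e-6)
})

test_that("heel strikes sit at the analytic minima of a sinusoidal heel signal", {
  fs <- 100
  time <- seq(0, 6, by = 1 / fs)
  z <- heel_sine(time)                 # minima at 0.9 + 1.2 k
  got <- detect_heel_strikes(time, z)
  want <- seq(0.9, max(time) - 0.2, by = 1.2)
  expect_equal(length(got), length(want))
  expect_lt(max(abs(got - want)), 1 / fs)
  # all spacings one stride period
  expect_lt(max(abs(diff(got) - 1.2)), 2 / fs)

  # with mm noise the events stay within 0.02 s of a windowed argmin oracle
  set.seed(3)
  zn <- z + stats::rnorm(length(z), sd = 0.001)
  gotn <- detect_heel_strikes(time, zn)
  oracle <- vapply(want, function(w) {
    idx <- which(abs(time - w) <= 0.3)
    time[idx[which.min(z[idx])]]      # argmin of the clean signal
  }, 0)
  expect_equal(length(gotn), length(oracle))
  expect_lt(max(abs(gotn - oracle)), 0.02)

  expect_error(detect_heel_strikes(time, rep(1, length(time))),
               class = "pairedslip_no_strides_error")
})

test_that("stride metrics recover GCT, speed and step length", {
  # GCT is a plain difference of same-foot strike times
  trial <- generate_trial(synthetic_trial_config(n_strides = 6, seed = 5))
  ev <- structure(list(left = c(0.5, 1.6, 2.7), right = c(0.0, 1.1, 2.2)),
                  class = "gait_events")
  sm <- stride_metrics(ev, trial$A)
  expect_equal(sm$gct$gct[sm$gct$foot == "right"], c(1.1, 1.1))

  # linear CoM ramp gives its slope as mean forward velocity
  time <- seq(0, 5, by = 0.01)
  tabl <- trajectory_table(time, list(
    heelL = cbind(heel_sine(time, t0 = 0.6), 0, 0)[, c(1, 2, 3)],
    heelR = cbind(heel_sine(time), 0, 0),
    com = cbind(1.3 * time, 0, 1)))
  # reuse the heel height as z so strikes exist
  tabl$channels$heelL[, 3] <- heel_sine(time, t0 = 0.6)
  tabl$channels$heelR[, 3] <- heel_sine(time)
  evl <- gait_events(tabl)
  sml <- stride_metrics(evl, tabl)
  expect_equal(sml$velocity, 1.3, tolerance = 1e-6)

  # generator ground truth: step length 0.65 m within 1 cm
  trial2 <- generate_trial(synthetic_trial_config(n_strides = 8,
                                                  step_length = 0.65,
                                                  noise_sd = 0.001,
                                                  seed = 9))
  ev2 <- gait_events(trial2$A)
  sm2 <- stride_metrics(ev2, trial2$A)
  expect_equal(mean(sm2$step_length$length), 0.65, tolerance = 0.01)

  expect_error(stride_metrics(structure(list(left = 1, right = 2),
                                        class = "gait_events"), trial2$A),
               class = "pairedslip_insufficient_strides_error")
})
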