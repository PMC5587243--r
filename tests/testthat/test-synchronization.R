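test_that("cross-correlation equals the definitional double-loop oracle", {
  # hand example: x = y = (1, 1) has c = (1, 2, 1); below the length-4
  # guard, so check via the oracle mapping directly
  expect_equal(xcorr_oracle(c(1, 1), c(1, 1)), c(1, 2, 1))

  set.seed(101)
  for (N in c(5, 17, 64, 256)) {
    x <- stats::rnorm(N)
    y <- stats::rnorm(N)
    expect_length(cross_correlation(x, y), 2 * N - 1)
    expect_equal(cross_correlation(x, y), xcorr_oracle(x, y),
                 tolerance = 1e-12)
  }

  # impulse alignment: the argmax sits at the lag aligning the impulses
  x <- c(1, 0, 0, 0)
  y <- c(0, 0, 0, 1)
  cc <- cross_correlation(x, y)
  lags <- -(3):(3)
  expect_equal(lags[which.max(cc)], -3)   # x leads y by 3 samples

  expect_error(cross_correlation(1:5, 1:4),
               class = "pairedslip_parameter_error")
})

test_that("phase lag recovery is exact for integer-sample delays", {
  fs <- 100
  period <- 1.2
  N <- as.integer(period * fs)
  time <- seq(0, 14, by = 1 / fs)
  strikes <- 0.25 + period * (0:9)
  # random periodic signal: exact recovery phi = 360 k / N for any shift k
  set.seed(7)
  base <- stats::rnorm(N)
  sig_at <- function(k) base[((seq_along(time) - 1 + 10000L * N - k) %% N) + 1]
  for (k in c(0L, 13L, 60L, 75L, 119L)) {
    pl <- phase_lag_series(time, sig_at(0L), sig_at(k), strikes)
    expect_equal(unique(pl$phi), 360 * k / N, tolerance = 1e-12,
                 label = sprintf("shift %d", k))
  }

  # identical heel signals: zero lag in every window
  A <- heel_quartic(time, 0.25)
  plA <- phase_lag_series(time, A, A, strikes)
  expect_true(all(plA$phi == 0))

  # half-stride delay on noiseless heel waveforms: a trot-like 180 degrees
  B <- heel_quartic(time, 0.25 + 0.6)
  plB <- phase_lag_series(time, A, B, strikes)
  expect_true(all(abs(plB$phi - 180) <= 4))

  # degenerate (constant) window flagged, not fatal
  C <- A
  C[time >= strikes[1] & time < strikes[2]] <- 0.03
  expect_warning(plC <- phase_lag_series(time, C, B, strikes),
                 class = "pairedslip_phase_undefined")
  expect_true(is.na(plC$phi[1]) && !is.na(plC$phi[2]))
})

test_that("gait classes map phase-lag anchors with trot precedence", {
  expect_equal(classify_gait_type(5), "pace")
  expect_equal(classify_gait_type(225), "diagonal_sequence")
  expect_equal(classify_gait_type(120), "unclassified")
  expect_equal(classify_gait_type(180), "trot")
  expect_equal(classify_gait_type(202.5), "trot")      # overlap -> trot
  # invariance under full turns
  phis <- c(0, 5, 120, 180, 202.5, 225, 300)
  expect_equal(classify_gait_type(phis + 360), classify_gait_type(phis))
  expect_equal(classify_gait_type(355), "pace")        # circular distance
})

test_that("synchronization windows apply the stride and phase-constancy rules", {
  fake_stride <- function(times, gct) {
    structure(list(gct = data.frame(foot = "right", time = times,
                                    gct = gct)),
              class = "stride_series")
  }
  fake_lags <- function(phi, T = 1) {
    n <- length(phi)
    structure(data.frame(window = seq_len(n), t_start = (seq_len(n) - 1) * T,
                         t_end = seq_len(n) * T,
                         n_samples = rep(100L, n),
                         lag_samples = rep(0L, n), phi = phi),
              class = c("phase_lag_series", "data.frame"))
  }
  # equal constant GCTs, constant phase: fully synchronized
  sA <- fake_stride(1:10, rep(1, 10))
  sB <- fake_stride(1:10, rep(1, 10))
  rep100 <- classify_synchronization(sA, sB, fake_lags(rep(90, 10)))
  expect_equal(rep100$fraction_synchronized, 100)

  # 10% stride mismatch violates the 4% rule everywhere
  sB10 <- fake_stride(seq(1.1, 11, by = 1.1), rep(1.1, 10))
  rep0 <- classify_synchronization(sA, sB10, fake_lags(rep(90, 10)))
  expect_equal(rep0$fraction_synchronized, 0)

  # drifting phase 0 -> 90 degrees: window-by-window cross-check against a
  # direct evaluation of the documented rule
  phi <- seq(0, 90, length.out = 10)
  rep_d <- classify_synchronization(sA, sB, fake_lags(phi),
                                    phase_tol = 10)
  want <- logical(10)
  seen <- numeric()
  for (i in 1:10) {
    want[i] <- if (!length(seen)) TRUE else {
      ref <- atan2(mean(sin(seen * pi / 180)),
                   mean(cos(seen * pi / 180))) * 180 / pi
      abs((phi[i] - ref + 180) %% 360 - 180) <= 10
    }
    seen <- c(seen, phi[i])
  }
  expect_equal(rep_d$windows$synchronized, want)

  # fraction is monotone non-increasing as the phase tolerance shrinks
  set.seed(12)
  phi_n <- (90 + cumsum(stats::rnorm(20, sd = 6))) %% 360
  fr <- vapply(c(20, 10, 5, 2),
               function(tol) classify_synchronization(
                 fake_stride(1:20, rep(1, 20)),
                 fake_stride(1:20, rep(1, 20)),
                 fake_lags(phi_n), phase_tol = tol)$fraction_synchronized,
               0)
  expect_true(all(diff(fr) <= 0))

  expect_error(classify_synchronization(sA, sB,
                                        fake_lags(numeric())),
               class = "pairedslip_insufficient_strides_error")
})

test_that("interlimb coordination extracts arm periods and their correlation with steps", {
  fs <- 100
  time <- seq(0, 12, by = 1 / fs)
  # relative displacement: pure 0.62 s sinusoid; steps every 0.62 s
  com_subj <- 1.2 * time
  com_obj <- com_subj + 0.03 * cos(2 * pi * time / 0.62)
  strikes <- seq(0.31, 11.5, by = 0.62)
  stride <- structure(list(gct = data.frame(
    foot = rep(c("right", "left"), length.out = length(strikes) - 1),
    time = strikes[-1], gct = diff(strikes) * 2)),
    class = "stride_series")
  # reconstructed step periods are diffs of merged strikes = 0.62
  il <- interlimb_coordination(time, com_subj, com_obj, stride)
  expect_lt(max(abs(il$arm_periods$period - 0.62)), 1 / fs + 1e-9)

  # Pearson r equals the textbook covariance formula on jittered data:
  # strikes and arm maxima both wander around a 0.62 s step period
  set.seed(21)
  strikes_j <- cumsum(c(0.31, 0.62 + stats::rnorm(17, sd = 0.02)))
  nj <- length(strikes_j)
  stride_j <- structure(list(gct = data.frame(
    foot = rep(c("right", "left"), length.out = nj - 2),
    time = strikes_j[3:nj],
    gct = strikes_j[3:nj] - strikes_j[1:(nj - 2)])),
    class = "stride_series")
  n_cyc <- 14
  periods <- 0.62 + stats::rnorm(n_cyc, sd = 0.02)
  maxima <- cumsum(c(0.3, periods))
  phase <- stats::approx(maxima, seq(0, n_cyc) * 2 * pi, xout = time,
                         rule = 2)$y
  com_obj2 <- com_subj + 0.03 * cos(phase)
  il2 <- interlimb_coordination(time, com_subj, com_obj2, stride_j)
  p <- il2$pairs
  r_direct <- sum((p$step_period - mean(p$step_period)) *
                    (p$arm_period - mean(p$arm_period))) /
    sqrt(sum((p$step_period - mean(p$step_period))^2) *
           sum((p$arm_period - mean(p$arm_period))^2))
  expect_equal(il2$r, r_direct, tolerance = 1e-12)
  expect_true(abs(il2$r) <= 1)

  expect_error(interlimb_coordination(time, com_subj,
                                      com_subj + 0.5, stride),
               class = "pairedslip_no_oscillation_error")
})
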