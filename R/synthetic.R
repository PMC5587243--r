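#' Configuration for a synthetic walking trial
#'
#' Defines the statistical structure of a generated motion-capture-style
#' trial: per-subject stride period, step length and speed, CoM and heel
#' waveform amplitudes, the inter-subject phase-lag profile, additive
#' noise and the sampling rate. Defaults emulate comfortable adult walking
#' in a short laboratory walkway (about 8 steps per pass): stride 1.1 s,
#' step 0.65 m, speed 2 * step / stride.
#'
#' @param n_strides strides per subject.
#' @param stride_period stride period(s) (s); length-2 vector for distinct
#'   subjects.
#' @param step_length step length(s) (m).
#' @param forward_speed forward speed(s) (m/s); default consistent with
#'   `2 * step_length / stride_period`. A mismatch above 20% between the
#'   given speed and the step geometry is rejected.
#' @param com_vertical_amplitude vertical CoM half-amplitude (m); the CoM
#'   oscillates twice per stride (once per step).
#' @param heel_amplitude heel-lift amplitude (m).
#' @param phase_lag inter-subject phase lag (degrees): subject B's gait
#'   trails subject A's by `phase_lag / 360` strides.
#' @param phase_drift linear phase drift (degrees per stride) added to
#'   `phase_lag`.
#' @param noise_sd additive Gaussian noise SD (m) on every coordinate.
#' @param sample_rate sampling rate (Hz).
#' @param kind `"solo"` or `"paired"`.
#' @param arm_jitter_sd SD (s) of the per-step jitter of the object's
#'   oscillation periods around the subjects' step period (paired trials).
#' @param seed integer seed making the trial reproducible.
#' @return object of class `synthetic_trial_config` (a validated list).
#' @export
synthetic_trial_config <- function(n_strides = 8,
                                   stride_period = 1.1,
                                   step_length = 0.65,
                                   forward_speed = NULL,
                                   com_vertical_amplitude = 0.03,
                                   heel_amplitude = 0.08,
                                   phase_lag = 0,
                                   phase_drift = 0,
                                   noise_sd = 0,
                                   sample_rate = 100,
                                   kind = c("paired", "solo"),
                                   arm_jitter_sd = 0.02,
                                   seed = 1L) {
  kind <- match.arg(kind)
  stride_period <- rep(stride_period, length.out = 2)
  step_length <- rep(step_length, length.out = 2)
  geom_speed <- 2 * step_length / stride_period
  if (is.null(forward_speed)) forward_speed <- geom_speed
  forward_speed <- rep(forward_speed, length.out = 2)
  if (n_strides < 1 || any(stride_period <= 0) || any(step_length <= 0) ||
      any(forward_speed <= 0) || com_vertical_amplitude < 0 ||
      heel_amplitude <= 0 || noise_sd < 0 || sample_rate <= 0)
    ps_abort("all magnitudes must be positive", "config_error")
  if (any(abs(forward_speed - geom_speed) / geom_speed > 0.2))
    ps_abort(sprintf(
      "forward_speed inconsistent with 2*step_length/stride_period (%s vs %s; >20%%)",
      paste(signif(forward_speed, 4), collapse = "/"),
      paste(signif(geom_speed, 4), collapse = "/")), "config_error")
  structure(list(n_strides = as.integer(n_strides),
                 stride_period = stride_period, step_length = step_length,
                 forward_speed = forward_speed,
                 com_vertical_amplitude = com_vertical_amplitude,
                 heel_amplitude = heel_amplitude,
                 phase_lag = circ_wrap(phase_lag),
                 phase_drift = phase_drift,
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 kind = kind, arm_jitter_sd = arm_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_trial_config")
}

# heel height waveform: raised |sin|^4 gives realistically flat, sharp
# valleys at ground contact, one per stride
heel_wave <- function(t, t0, period, amplitude) {
  amplitude * abs(sin(pi * (t - t0) / period))^4
}

# heel forward staircase: stationary during stance (60% of the stride),
# advancing 2 * step_length during swing
heel_forward <- function(t, t0, period, step_length, x0, duty = 0.6) {
  phase <- (t - t0) / period
  cyc <- floor(phase)
  frac <- phase - cyc
  swing <- pmin(pmax((frac - duty) / (1 - duty), 0), 1)
  # smoothstep avoids velocity discontinuities at the staircase corners
  swing <- swing^2 * (3 - 2 * swing)
  x0 + 2 * step_length * (cyc + swing)
}

#' Generate a synthetic solo or paired walking trial with ground truth
#'
#' Emits, per subject, heel left/right channels (vertical: periodic
#' raised-|sin|^4 waveform with sharp minima at the strikes; forward:
#' staircase advancing one step per half-stride) and a CoM channel
#' (forward: linear progression plus a small in-step oscillation;
#' vertical: sinusoid at twice the stride frequency). For paired trials
#' subject B's waveforms trail subject A's by the configured phase-lag
#' profile, and an object-CoM channel oscillates forward relative to the
#' subjects with per-step periods jittered around the step period.
#' Seeded Gaussian noise is added to every coordinate. The emitted ground
#' truth records the exact strike times, stride periods and per-window
#' phase lags the generator used.
#'
#' @param config a [synthetic_trial_config()].
#' @return list with `A`, `B` (the latter `NULL` for solo trials):
#'   [trajectory_table()]s with channels `heelL`, `heelR`, `com`;
#'   `object`: single-channel table (paired only); `truth`: list with
#'   per-subject strike times, stride periods, a per-stride phase-lag
#'   table (`t_start`, `t_mid`, `phi`, evaluated at window midpoints), and
#'   the config.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  cf <- config
  set.seed(cf$seed)
  fs <- cf$sample_rate
  # time range covers all strides of the slower subject plus the lag
  t_end <- max(cf$stride_period) * (cf$n_strides + 1.5) +
    max(cf$phase_lag + cf$phase_drift * cf$n_strides, 0) / 360 *
      max(cf$stride_period)
  time <- seq(0, t_end, by = 1 / fs)
  lead_in <- 0.25  # first right strike (s); keeps minima away from edges

  subject <- function(i, delay) {
    Tp <- cf$stride_period[i]
    sl <- cf$step_length[i]
    v <- cf$forward_speed[i]
    t0R <- lead_in + delay
    t0L <- t0R + Tp / 2
    heelR_z <- heel_wave(time, t0R, Tp, cf$heel_amplitude)
    heelL_z <- heel_wave(time, t0L, Tp, cf$heel_amplitude)
    heelR_x <- heel_forward(time, t0R, Tp, sl, x0 = 0)
    heelL_x <- heel_forward(time, t0L, Tp, sl, x0 = sl)
    com_x <- v * (time - t0R) + 0.01 * sin(4 * pi * (time - t0R) / Tp)
    com_z <- 0.95 + cf$com_vertical_amplitude *
      sin(4 * pi * (time - t0R) / Tp - pi / 2)
    ch <- function(x, z) {
      m <- cbind(x, 0, z) + matrix(stats::rnorm(3 * length(time),
                                                sd = cf$noise_sd),
                                   ncol = 3)
      m
    }
    strikesR <- t0R + Tp * seq(0, floor((max(time) - 0.1 - t0R) / Tp))
    strikesL <- t0L + Tp * seq(0, floor((max(time) - 0.1 - t0L) / Tp))
    list(table = trajectory_table(time, list(heelL = ch(heelL_x, heelL_z),
                                             heelR = ch(heelR_x, heelR_z),
                                             com = ch(com_x, com_z))),
         strikesR = strikesR, strikesL = strikesL,
         com_x = com_x)
  }

  A <- subject(1, delay = 0)
  truth <- list(config = cf,
                strikes = list(A = list(left = A$strikesL,
                                        right = A$strikesR)),
                stride_periods = cf$stride_period,
                seed = cf$seed)
  if (cf$kind == "solo") {
    return(list(A = A$table, B = NULL, object = NULL, truth = truth))
  }
  # per-stride phase lag of B relative to A (degrees), possibly drifting;
  # evaluated at each stride window's midpoint so it can be aligned with
  # recovered per-window estimates by time
  nwinA <- length(A$strikesR) - 1L
  t_start <- A$strikesR[seq_len(nwinA)]
  t_mid <- t_start + cf$stride_period[1] / 2
  phi_true <- data.frame(
    t_start = t_start, t_mid = t_mid,
    phi = circ_wrap(cf$phase_lag +
                      cf$phase_drift * (t_mid - lead_in) /
                        cf$stride_period[1]))
  # constant-lag delay; drifting lag realized as slowly varying delay
  delay0 <- cf$phase_lag / 360 * cf$stride_period[2]
  B <- subject(2, delay = delay0)
  if (cf$phase_drift != 0) {
    # regenerate B with a time-varying delay via phase warping
    Tp <- cf$stride_period[2]
    drift_rate <- cf$phase_drift / 360 * Tp / cf$stride_period[1]  # s per s
    warp <- function(t) t - (delay0 + drift_rate * pmax(t - lead_in, 0))
    tabB <- B$table
    for (nm in names(tabB$channels)) {
      for (a in 1:3) {
        base <- stats::approx(time, B$table$channels[[nm]][, a],
                              xout = warp(time) + delay0, rule = 2)$y
        tabB$channels[[nm]][, a] <- base
      }
    }
    B$table <- tabB
  }
  truth$strikes$B <- list(left = B$strikesL, right = B$strikesR)
  truth$phi <- phi_true

  # object CoM: midpoint of the two subjects' CoM forward positions plus an
  # oscillation whose per-cycle periods jitter around subject A's step period
  step_p <- cf$stride_period[1] / 2
  n_cycles <- ceiling(max(time) / step_p) + 2L
  periods <- pmax(step_p + stats::rnorm(n_cycles, sd = cf$arm_jitter_sd),
                  0.3 * step_p)
  cycle_ends <- cumsum(periods)
  phase_at <- function(t) {
    k <- findInterval(t, c(0, cycle_ends))
    start <- c(0, cycle_ends)[k]
    2 * pi * (k - 1L + (t - start) / periods[pmin(k, length(periods))])
  }
  com_mid <- (A$com_x + stats::approx(time, B$com_x, xout = time)$y) / 2
  obj_x <- com_mid + 0.02 * cos(phase_at(time))
  obj <- trajectory_table(time, list(
    object = cbind(obj_x + stats::rnorm(length(time), sd = cf$noise_sd),
                   0, 0.95)))
  truth$arm_periods <- periods
  list(A = A$table, B = B$table, object = obj, truth = truth)
}
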