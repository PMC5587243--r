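# Shared fixtures (memoised: the 100 s reference simulation is reused by
# several files) and independent oracles used to cross-check operations.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# coupled pair at the reference parameter set, step-3 initial conditions
ref_paired_trace <- function(t_max = 100) {
  memo(paste0("paired", t_max), {
    ref <- reference_gait_parameters()
    ic <- search_initial_conditions(3)
    simulate_paired(ref$p1, ref$p2, ref$coupling, ic$init1, ic$init2,
                    t_max = t_max)
  })
}

# step-2 initial conditions (different energies): the arms work visibly
ref_step2_trace <- function(t_max = 30) {
  memo(paste0("step2_", t_max), {
    ref <- reference_gait_parameters()
    ic <- search_initial_conditions(2)
    simulate_paired(ref$p1, ref$p2, ref$coupling, ic$init1, ic$init2,
                    t_max = t_max)
  })
}

ref_solo_trace <- function(t_max = 40) {
  memo(paste0("solo", t_max), {
    ref <- reference_gait_parameters()
    simulate_paired(ref$p1, init1 = search_initial_conditions(1)$init1,
                    t_max = t_max)
  })
}

# minimal trace stand-in for score functions that only read apex tables
fake_trace <- function(apex1, apex2 = NULL) {
  structure(list(apex1 = apex1, apex2 = apex2,
                 paired = !is.null(apex2)),
            class = "slip_trace")
}

apex_df <- function(x, z, times = seq_along(x) * 0.5, vx = 1) {
  data.frame(time = times, x_apex = x, z_apex = z,
             vx = rep(vx, length.out = length(x)))
}

# ---- oracles -------------------------------------------------------------

# definitional double-loop cross-correlation (O(N^2))
xcorr_oracle <- function(x, y) {
  N <- length(x)
  out <- numeric(2 * N - 1)
  for (m in seq_len(2 * N - 1)) {
    l <- m - N
    s <- 0
    for (n in 0:(N - 1)) {
      k <- n + l
      if (k >= 0 && k <= N - 1) s <- s + x[k + 1] * y[n + 1]
    }
    out[m] <- s
  }
  out
}

# brute-force re-evaluation of transient index, RMS_k and S_P
periodicity_oracle <- function(residuals, xi, rms_floor = 1e-12) {
  m <- vapply(residuals, length, 0L)
  for (j in 0:(min(m) - 1L)) {
    ok <- all(vapply(residuals,
                     function(r) all(r[(j + 1L):length(r)] < xi), TRUE))
    if (ok) {
      rms_k <- vapply(residuals,
                      function(r) sqrt(mean(r[(j + 1L):length(r)]^2)), 0)
      rms <- sqrt(sum(rms_k^2))
      return(list(j = j, rms_k = rms_k,
                  S_P = log10(xi / max(rms, rms_floor))))
    }
  }
  list(j = NA_integer_, rms_k = rep(NA_real_, length(residuals)), S_P = 0)
}

# sinusoidal heel-height test signal
heel_sine <- function(time, period = 1.2, t0 = 0, amp = 0.05, base = 0.07) {
  base + amp * sin(2 * pi * (time - t0) / period)
}

# quartic-valley heel waveform (the generator's shape)
heel_quartic <- function(time, t0, period = 1.2, amp = 0.08) {
  amp * abs(sin(pi * (time - t0) / period))^4
}
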