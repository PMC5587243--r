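#' Periodicity score of a simulated gait
#'
#' Scores how closely the apex return map settles onto a fixed point.
#' For each pendulum k the residual sequence is the Euclidean step-to-step
#' change of the apex point,
#' `r_i = |(x_apex, z_apex)_{i+1} - (x_apex, z_apex)_i|`.
#' The transient index `j` is the smallest integer such that `r_i < xi`
#' for every residual with index `i > j` (for both pendulums in a paired
#' trace). If no such index exists - including traces that fall before
#' producing two apexes - the gait is not periodic and the score is 0.
#' Otherwise `RMS_k` is the root mean square of the post-transient
#' residuals of pendulum k, `RMS = sqrt(RMS_1^2 + RMS_2^2)` (or `RMS_1`
#' for a solo trace), and
#' `S_P = log10(xi / RMS)`.
#'
#' `RMS` is floored at 1e-12 so that numerically exact periodicity yields a
#' large finite score (at most `log10(xi) + 12`) rather than an infinite
#' one; the floor is reported alongside the score.
#'
#' @param trace a `slip_trace` from [simulate_paired()].
#' @param xi apex-variation tolerance (m); ~1e-3, set to match the apex
#'   height variability observed in human trials.
#' @param rms_floor lower bound applied to RMS before taking the log.
#' @return an object of class `periodicity_result`: list with `S_P`, `RMS`
#'   (combined), `RMS_k` (per pendulum), transient index `j` (`NA` when the
#'   gait never settles), `xi`, `rms_floor`, `n_apex` and the per-pendulum
#'   residual sequences.
#' @export
periodicity_score <- function(trace, xi = 1e-3, rms_floor = 1e-12) {
  stopifnot(inherits(trace, "slip_trace"))
  if (xi <= 0) ps_abort("xi must be positive", "parameter_error")
  apexes <- list(trace$apex1, if (trace$paired) trace$apex2)
  apexes <- apexes[!vapply(apexes, is.null, TRUE)]
  residuals <- lapply(apexes, function(a) {
    if (nrow(a) < 2) return(numeric())
    sqrt(diff(a$x_apex)^2 + diff(a$z_apex)^2)
  })
  zero <- structure(list(S_P = 0, RMS = NA_real_,
                         RMS_k = rep(NA_real_, length(residuals)),
                         j = NA_integer_, xi = xi, rms_floor = rms_floor,
                         n_apex = vapply(apexes, nrow, 0L),
                         residuals = residuals),
                    class = "periodicity_result")
  m <- vapply(residuals, length, 0L)
  if (any(m < 1L)) return(zero)
  # smallest j with r_i < xi for all i > j, simultaneously for all pendulums
  j_k <- vapply(residuals, function(r) {
    bad <- which(r >= xi)
    if (length(bad)) max(bad) else 0L
  }, 0L)
  j <- max(j_k)
  if (j >= min(m)) return(zero)  # some pendulum has no post-transient residual
  rms_k <- vapply(residuals, function(r)
    sqrt(mean(r[(j + 1L):length(r)]^2)), 0)
  rms <- sqrt(sum(rms_k^2))
  structure(list(S_P = log10(xi / max(rms, rms_floor)),
                 RMS = rms, RMS_k = rms_k, j = j,
                 xi = xi, rms_floor = rms_floor,
                 n_apex = vapply(apexes, nrow, 0L),
                 residuals = residuals),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  if (is.na(x$j)) {
    cat(sprintf("<periodicity_result> not periodic (S_P = 0), xi = %g\n",
                x$xi))
  } else {
    cat(sprintf(
      "<periodicity_result> S_P = %.4f (xi = %g, RMS = %.3e, j = %d)\n",
      x$S_P, x$xi, x$RMS, x$j))
  }
  invisible(x)
}

#' Synchronization score of a paired trace
#'
#' Ratio of the two pendulums' mean apex-to-apex periods,
#' `S_S = min(T1, T2) / max(T1, T2)`, computed over the post-transient
#' portion of the trace (apexes after the transient index of
#' [periodicity_score()] when it exists, the full trace otherwise).
#' Equal mean step periods give 1; a pendulum with fewer than two apexes
#' gives 0. The score is symmetric in the pendulum labels.
#'
#' @param trace a paired `slip_trace`.
#' @param xi tolerance forwarded to [periodicity_score()] for locating the
#'   transient.
#' @return `S_S` in `[0, 1]`.
#' @export
synchronization_score <- function(trace, xi = 1e-3) {
  stopifnot(inherits(trace, "slip_trace"))
  if (!trace$paired)
    ps_abort("synchronization score requires a paired trace",
             "parameter_error")
  if (nrow(trace$apex1) < 2 || nrow(trace$apex2) < 2) return(0)
  pr <- periodicity_score(trace, xi = xi)
  from <- if (is.na(pr$j)) 1L else pr$j + 1L
  mean_period <- function(a) {
    tt <- a$time[min(from, nrow(a) - 1L):nrow(a)]
    mean(diff(tt))
  }
  t1 <- mean_period(trace$apex1)
  t2 <- mean_period(trace$apex2)
  min(t1, t2) / max(t1, t2)
}

#' Agreement of a simulated gait with reference (experimental) conditions
#'
#' Measures how close the simulated post-transient apex height and apex
#' forward velocity are to per-subject reference values:
#' `S_R = exp(-sum_k(|z_k - z_ref_k| / sigma_z + |v_k - v_ref_k| / sigma_v))`.
#' Equal values give 1; each discrepancy of one scale unit divides the
#' score by e. The scales are documented package choices:
#' `sigma_z` = 0.01 m (the order of between-trial apex-height variability)
#' and `sigma_v` = 0.1 m/s (the order of between-trial speed variability).
#'
#' Simulated values are post-transient means of the per-apex CoM height
#' and forward velocity.
#'
#' @param trace a `slip_trace`.
#' @param reference data.frame or list with numeric `z_apex` (absolute CoM
#'   apex height, m) and `velocity` (forward CoM velocity at apex, m/s),
#'   one entry per pendulum in the trace.
#' @param sigma_z,sigma_v discrepancy scales (m, m/s).
#' @param xi tolerance used to locate the transient.
#' @return `S_R` in `(0, 1]`.
#' @export
real_conditions_score <- function(trace, reference,
                                  sigma_z = 0.01, sigma_v = 0.1,
                                  xi = 1e-3) {
  stopifnot(inherits(trace, "slip_trace"))
  zr <- as.numeric(reference$z_apex)
  vr <- as.numeric(reference$velocity)
  np <- if (trace$paired) 2L else 1L
  if (length(zr) != np || length(vr) != np)
    ps_abort("reference must supply z_apex and velocity per pendulum",
             "parameter_error")
  if (!all(is.finite(zr)) || !all(is.finite(vr)))
    ps_abort("reference values must be finite", "parameter_error")
  sm <- gait_summary(trace, xi = xi)
  d <- sum(abs(sm$z_apex - zr) / sigma_z + abs(sm$vx_apex - vr) / sigma_v)
  exp(-d)
}

#' Post-transient gait summary of a simulated trace
#'
#' Per pendulum: mean absolute CoM apex height, mean forward velocity at
#' apex, mean apex-to-apex period (the model's step period; twice this is
#' the gait cycle time of one "foot"), mean forward velocity, and step
#' length (forward distance travelled per apex-to-apex interval). Computed over the post-transient
#' apexes when [periodicity_score()] finds a transient index, else the
#' whole trace.
#'
#' @param trace a `slip_trace`.
#' @param xi tolerance used to locate the transient.
#' @return data.frame with one row per pendulum: `pendulum`, `z_apex` (m,
#'   absolute), `vx_apex` (m/s, at apex), `step_period` (s), `gct` (s),
#'   `velocity` (mean forward, m/s), `step_length` (m), `n_apex`.
#' @export
gait_summary <- function(trace, xi = 1e-3) {
  stopifnot(inherits(trace, "slip_trace"))
  pr <- periodicity_score(trace, xi = xi)
  from <- if (is.na(pr$j)) 1L else pr$j + 1L
  apexes <- list(trace$apex1, if (trace$paired) trace$apex2)
  apexes <- apexes[!vapply(apexes, is.null, TRUE)]
  l0 <- c(trace$p1$leg_length,
          if (trace$paired) trace$p2$leg_length)
  xs <- list(trace$state$x1, if (trace$paired) trace$state$x2)
  out <- lapply(seq_along(apexes), function(i) {
    a <- apexes[[i]]
    if (nrow(a) < 2)
      return(data.frame(pendulum = i, z_apex = NA_real_,
                        vx_apex = NA_real_,
                        step_period = NA_real_, gct = NA_real_,
                        velocity = NA_real_, step_length = NA_real_,
                        n_apex = nrow(a)))
    lo <- min(from, nrow(a) - 1L)
    tt <- a$time[lo:nrow(a)]
    # forward distance per step from the trace positions at apex times
    x_at <- stats::approx(trace$state$time, xs[[i]], xout = tt)$y
    data.frame(pendulum = i,
               z_apex = mean(a$z_apex[lo:nrow(a)]) + l0[i],
               vx_apex = mean(a$vx[lo:nrow(a)]),
               step_period = mean(diff(tt)),
               gct = 2 * mean(diff(tt)),
               velocity = (x_at[length(x_at)] - x_at[1]) /
                 (tt[length(tt)] - tt[1]),
               step_length = mean(diff(x_at)),
               n_apex = nrow(a))
  })
  do.call(rbind, out)
}

#' Post-transient apex variation of a simulated gait
#'
#' Two views of how strongly the settled gait still varies step to step:
#' the largest post-transient apex-to-apex residual
#' `max_i |(x_apex, z_apex)_{i+1} - (x_apex, z_apex)_i|` (m), and the
#' largest relative change of the full apex state
#' `max_i |s_{i+1} - s_i| / |s_i|` (percent), where `s_i` is the state
#' vector `(x_apex, z, vx)` at the i-th apex (absolute CoM height; the
#' vertical velocity is identically zero at apex). Both maxima are taken
#' over every apex after the transient index `j` of [periodicity_score()]
#' and over both pendulums.
#'
#' @param trace a `slip_trace`.
#' @param xi tolerance used to locate the transient.
#' @return list with `max_residual` (m), `max_rel_change_pct` (%),
#'   transient index `j` and `n_used` (post-transient apex count per
#'   pendulum). `NA`s when the gait never settles.
#' @export
apex_state_variation <- function(trace, xi = 1e-3) {
  stopifnot(inherits(trace, "slip_trace"))
  pr <- periodicity_score(trace, xi = xi)
  if (is.na(pr$j))
    return(list(max_residual = NA_real_, max_rel_change_pct = NA_real_,
                j = NA_integer_, n_used = NA_integer_))
  apexes <- list(trace$apex1, if (trace$paired) trace$apex2)
  apexes <- apexes[!vapply(apexes, is.null, TRUE)]
  l0 <- c(trace$p1$leg_length, if (trace$paired) trace$p2$leg_length)
  max_res <- 0
  max_rel <- 0
  n_used <- integer(length(apexes))
  for (k in seq_along(apexes)) {
    a <- apexes[[k]]
    rows <- (pr$j + 1L):nrow(a)
    n_used[k] <- length(rows)
    s <- cbind(a$x_apex[rows], a$z_apex[rows] + l0[k], a$vx[rows])
    ds <- diff(s)
    if (!nrow(ds)) next
    res <- sqrt(diff(a$x_apex[rows])^2 + diff(a$z_apex[rows])^2)
    rel <- sqrt(rowSums(ds^2)) /
      sqrt(rowSums(s[-nrow(s), , drop = FALSE]^2))
    max_res <- max(max_res, res)
    max_rel <- max(max_rel, rel)
  }
  list(max_residual = max_res, max_rel_change_pct = 100 * max_rel,
       j = pr$j, n_used = n_used)
}
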