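#' Raw cross-correlation sequence between two equal-length windows
#'
#' Implements the definitional (un-normalized) cross-correlation used for
#' phase-lag estimation: for windows of length N the returned sequence is
#' `c(m) = Rxy(m - N)`, `m = 1, ..., 2N - 1`, with
#' `Rxy(l) = sum_{n=0}^{N-l-1} x[n+l] y[n]` for `l >= 0` and
#' `Rxy(-l) = Ryx(l)`. Computed directly (no FFT), exact to floating
#' point.
#'
#' @param x,y numeric vectors of equal length `N >= 4`.
#' @return numeric vector of length `2N - 1`; element `m` corresponds to
#'   lag `m - N` in samples.
#' @export
cross_correlation <- function(x, y) {
  N <- length(x)
  if (length(y) != N)
    ps_abort("x and y must have equal length", "parameter_error")
  if (N < 4)
    ps_abort("windows must contain at least 4 samples", "parameter_error")
  lags <- seq.int(-(N - 1L), N - 1L)
  vapply(lags, function(l) {
    if (l >= 0) sum(x[(1L + l):N] * y[seq_len(N - l)])
    else sum(y[(1L - l):N] * x[seq_len(N + l)])
  }, 0)
}

# circular helpers (degrees)
circ_wrap <- function(deg) deg %% 360
circ_dist <- function(a, b) abs((a - b + 180) %% 360 - 180)
circ_mean <- function(deg) {
  r <- deg * pi / 180
  circ_wrap(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Per-stride phase lag between two walkers' heel trajectories
#'
#' The trial is cut into one time window per stride of the reference
#' walker (subject A; windows are delimited by consecutive reference-foot
#' heel strikes). In each window the two heel-height signals are
#' mean-removed and cross-correlated with [cross_correlation()]; the lag
#' `l*` (in samples) maximizing the correlation, scaled by the window
#' length N, gives the phase lag
#' `phi = (-360 l* / N) mod 360`, so a walker B that trails A by half a
#' stride shows `phi = 180` degrees.
#'
#' Windows in which either signal is constant have no defined phase; they
#' are flagged (`phi = NA`) with a warning rather than failing the trial.
#'
#' @param time shared sample times (s).
#' @param heelA,heelB heel-height series of the two walkers (m).
#' @param strikesA reference heel-strike times of walker A (s), e.g. the
#'   right-foot component of [gait_events()].
#' @param demean remove each window's mean before correlating (default
#'   `TRUE`; raw positive signals bias the argmax toward zero lag).
#' @param fold fold the linear correlation into a circular one before the
#'   argmax: lags one window length apart describe the same within-stride
#'   phase, so their correlation sums are combined (`c(l) + c(l - N)`).
#'   This removes the finite-window truncation bias that otherwise pulls
#'   the argmax toward small lags for harmonic-rich heel waveforms
#'   (default `TRUE`; `FALSE` gives the raw linear argmax).
#' @return object of class `phase_lag_series`: data.frame with `window`,
#'   `t_start`, `t_end`, `n_samples`, `lag_samples`, `phi` (degrees in
#'   `[0, 360)`).
#' @export
phase_lag_series <- function(time, heelA, heelB, strikesA, demean = TRUE,
                             fold = TRUE) {
  stopifnot(length(time) == length(heelA), length(time) == length(heelB))
  if (length(strikesA) < 2)
    ps_abort("need at least one full stride (two reference strikes)",
             "insufficient_strides_error")
  nwin <- length(strikesA) - 1L
  out <- data.frame(window = seq_len(nwin), t_start = strikesA[-length(strikesA)],
                    t_end = strikesA[-1], n_samples = NA_integer_,
                    lag_samples = NA_integer_, phi = NA_real_)
  for (w in seq_len(nwin)) {
    idx <- which(time >= out$t_start[w] & time < out$t_end[w])
    N <- length(idx)
    out$n_samples[w] <- N
    if (N < 4) next
    xw <- heelA[idx]
    yw <- heelB[idx]
    if (diff(range(xw)) == 0 || diff(range(yw)) == 0) {
      ps_warn(sprintf("window %d: constant signal, phase undefined", w),
              "phase_undefined")
      next
    }
    if (demean) {
      xw <- xw - mean(xw)
      yw <- yw - mean(yw)
    }
    cc <- cross_correlation(xw, yw)
    if (fold) {
      # circular lag l in 0..N-1 combines linear lags l and l - N
      circ <- cc[N:(2 * N - 1)]
      circ[2:N] <- circ[2:N] + cc[1:(N - 1)]
      lag <- which.max(circ) - 1L
    } else {
      lag <- which.max(cc) - N
    }
    out$lag_samples[w] <- lag
    out$phi[w] <- circ_wrap(-360 * lag / N)
  }
  structure(out, class = c("phase_lag_series", "data.frame"))
}

#' Classify a phase lag as a quadrupedal-like footfall pattern
#'
#' Treating the subject-object-subject system as one four-legged body, the
#' inter-subject phase lag maps onto quadrupedal gaits: lateral pairs in
#' phase (`phi ~ 0` degrees) resemble a pace, diagonal pairs alternating
#' (`phi ~ 180`) a trot, and `phi ~ 225` a diagonal-sequence gait. The
#' half-width of each class band defaults to 22.5 degrees (half the 45
#' degree trot / diagonal-sequence spacing); at band overlap trot takes
#' precedence. Distances are circular, so the classification is invariant
#' under `phi -> phi + 360`.
#'
#' @param phi phase lag(s), degrees.
#' @param tol class half-width, degrees.
#' @return character vector: `"pace"`, `"trot"`, `"diagonal_sequence"` or
#'   `"unclassified"` (`NA` input propagates).
#' @export
classify_gait_type <- function(phi, tol = 22.5) {
  vapply(phi, function(p) {
    if (is.na(p)) return(NA_character_)
    if (circ_dist(p, 0) <= tol) return("pace")
    if (circ_dist(p, 180) <= tol) return("trot")
    if (circ_dist(p, 225) <= tol) return("diagonal_sequence")
    "unclassified"
  }, "")
}

#' Synchronization report for a paired trial
#'
#' A stride window counts as synchronized when both walkers hold the same
#' stride duration and the phase lag is steady:
#' \itemize{
#'   \item stride agreement: `|GCT_A - GCT_B| < stride_tol * mean(GCT_A,
#'     GCT_B)` for the strides spanning the window (default 4%, comparable
#'     to a healthy walker's stride-time variability);
#'   \item phase constancy: the window's phase lag deviates (circularly) by
#'     at most `phase_tol` degrees (default 10) from the running circular
#'     mean of the preceding windows' lags; the first defined window
#'     anchors the reference.
#' }
#'
#' @param strideA,strideB [stride_metrics()] results for the two walkers.
#' @param lags a [phase_lag_series()].
#' @param stride_tol relative stride-duration tolerance.
#' @param phase_tol phase-constancy tolerance (degrees).
#' @param gait_tol class half-width forwarded to [classify_gait_type()].
#' @return object of class `sync_report`: list with `windows` (per-window
#'   data.frame: GCTs, conditions, `synchronized`, `phi`, `gait`),
#'   `fraction_synchronized` (percent), `gait_shares` (percent of
#'   synchronized windows per gait class) and the thresholds used.
#' @export
classify_synchronization <- function(strideA, strideB, lags,
                                     stride_tol = 0.04, phase_tol = 10,
                                     gait_tol = 22.5) {
  stopifnot(inherits(strideA, "stride_series"),
            inherits(strideB, "stride_series"),
            inherits(lags, "phase_lag_series"))
  if (!nrow(lags))
    ps_abort("empty phase-lag series", "insufficient_strides_error")
  gct_at <- function(stride, t) {
    g <- stride$gct
    g <- g[g$foot == "right", , drop = FALSE]
    if (!nrow(g)) g <- stride$gct
    lo <- g$time - g$gct
    inside <- which(lo <= t & t < g$time)
    if (length(inside)) return(g$gct[inside[1]])
    g$gct[which.min(pmin(abs(t - g$time), abs(t - lo)))]
  }
  w <- as.data.frame(lags)
  mid <- (w$t_start + w$t_end) / 2
  w$gct_A <- w$t_end - w$t_start
  w$gct_B <- vapply(mid, function(t) gct_at(strideB, t), 0)
  w$stride_ok <- abs(w$gct_A - w$gct_B) <
    stride_tol * (w$gct_A + w$gct_B) / 2
  w$phase_ok <- NA
  w$phase_ref <- NA_real_
  seen <- numeric()
  for (i in seq_len(nrow(w))) {
    if (is.na(w$phi[i])) {
      w$phase_ok[i] <- FALSE
      next
    }
    if (!length(seen)) {
      w$phase_ok[i] <- TRUE
      w$phase_ref[i] <- w$phi[i]
    } else {
      ref <- circ_mean(seen)
      w$phase_ref[i] <- ref
      w$phase_ok[i] <- circ_dist(w$phi[i], ref) <= phase_tol
    }
    seen <- c(seen, w$phi[i])
  }
  w$synchronized <- w$stride_ok & w$phase_ok
  w$gait <- classify_gait_type(w$phi, tol = gait_tol)
  sync <- w$synchronized
  shares <- if (any(sync)) {
    g <- factor(w$gait[sync],
                levels = c("pace", "trot", "diagonal_sequence",
                           "unclassified"))
    100 * as.vector(table(g)) / sum(sync)
  } else rep(0, 4)
  names(shares) <- c("pace", "trot", "diagonal_sequence", "unclassified")
  structure(list(windows = w,
                 fraction_synchronized = 100 * mean(sync),
                 gait_shares = shares,
                 thresholds = list(stride_tol = stride_tol,
                                   phase_tol = phase_tol,
                                   gait_tol = gait_tol)),
            class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("<sync_report> %d windows, %.1f%% synchronized\n",
              nrow(x$windows), x$fraction_synchronized))
  sh <- x$gait_shares
  cat(sprintf("  gait shares: pace %.1f%%, trot %.1f%%, D-S %.1f%%\n",
              sh[["pace"]], sh[["trot"]], sh[["diagonal_sequence"]]))
  invisible(x)
}

#' Write a synchronization report to JSON (and optionally CSV)
#'
#' @param report a `sync_report`.
#' @param json_path output JSON path.
#' @param csv_path optional per-window CSV path.
#' @return `json_path`, invisibly.
#' @export
write_sync_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "sync_report"))
  jsonlite::write_json(
    list(thresholds = report$thresholds,
         fraction_synchronized = report$fraction_synchronized,
         gait_shares = as.list(report$gait_shares),
         windows = report$windows),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$windows, csv_path, row.names = FALSE)
  invisible(json_path)
}

# interior local maxima with prominence and separation filters
local_maxima <- function(time, v, min_separation = 0.25,
                         min_prominence_frac = 0.2) {
  p2p <- diff(range(v))
  if (p2p <= 1e-9) return(numeric())  # sub-nanometre ripple is no oscillation
  d <- sign(diff(v))
  d[d == 0] <- NA
  d <- zoo_locf(d)
  cand <- which(diff(d) < 0) + 1L
  cand <- cand[cand > 1L & cand < length(v)]
  if (!length(cand)) return(numeric())
  prom <- vapply(cand, function(i) {
    val <- v[i]
    left <- v[seq_len(i - 1L)]
    right <- v[(i + 1L):length(v)]
    hi_l <- which(left > val)
    hi_r <- which(right > val)
    ll <- if (length(hi_l)) min(left[(max(hi_l) + 1L):(i - 1L)]) else
      min(left)
    lr <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1L)]) else
      min(right)
    val - max(ll, lr)
  }, 0)
  keep <- cand[prom >= min_prominence_frac * p2p]
  if (!length(keep)) return(numeric())
  ord <- keep[order(-v[keep])]
  sel <- integer()
  for (i in ord)
    if (!length(sel) || all(abs(time[i] - time[sel]) >= min_separation))
      sel <- c(sel, i)
  sort(time[sel])
}

#' Interlimb (arm) coordination between a walker and the carried object
#'
#' The arm oscillation is read from the forward relative displacement
#' between the object's CoM and the walker's CoM; its per-cycle periods
#' are the differences between consecutive local maxima. Each oscillation
#' period is paired with the step period (interval between successive
#' heel strikes of either foot) containing its midpoint, and the linear
#' association between the two is summarized by the Pearson correlation
#' and a least-squares line (arm period ~ step period).
#'
#' @param time sample times (s).
#' @param com_subject,com_object forward (x) CoM series (m).
#' @param stride a [stride_metrics()] result for the walker.
#' @param min_separation,min_prominence_frac peak-picking controls for the
#'   relative-displacement maxima.
#' @return object of class `interlimb_report`: list with `arm_periods`
#'   (data.frame `t_mid`, `period`), `pairs` (matched step/arm periods),
#'   `r` (Pearson), `slope`, `intercept`.
#' @export
interlimb_coordination <- function(time, com_subject, com_object, stride,
                                   min_separation = 0.25,
                                   min_prominence_frac = 0.2) {
  stopifnot(inherits(stride, "stride_series"),
            length(time) == length(com_subject),
            length(time) == length(com_object))
  rel <- com_object - com_subject
  mx <- local_maxima(time, rel, min_separation, min_prominence_frac)
  if (length(mx) < 2)
    ps_abort("fewer than two oscillation maxima in the relative displacement",
             "no_oscillation_error")
  arm <- data.frame(t_mid = (mx[-1] + mx[-length(mx)]) / 2,
                    period = diff(mx))
  strikes <- sort(c(stride$gct$time - stride$gct$gct, stride$gct$time))
  strikes <- sort(unique(strikes))
  if (length(strikes) < 2)
    ps_abort("not enough heel strikes for step periods",
             "insufficient_strides_error")
  steps <- data.frame(t_mid = (strikes[-1] + strikes[-length(strikes)]) / 2,
                      period = diff(strikes))
  k <- vapply(arm$t_mid, function(t) which.min(abs(steps$t_mid - t)), 0L)
  pairs <- data.frame(step_period = steps$period[k],
                      arm_period = arm$period)
  step_const <- stats::sd(pairs$step_period) <=
    1e-12 * mean(abs(pairs$step_period))
  degenerate <- step_const || stats::sd(pairs$arm_period) == 0
  r <- if (degenerate) NA_real_ else
    stats::cor(pairs$step_period, pairs$arm_period)
  if (step_const) {
    slope <- NA_real_
    intercept <- mean(pairs$arm_period)
  } else {
    fit <- stats::lsfit(pairs$step_period, pairs$arm_period)
    slope <- unname(fit$coefficients[2])
    intercept <- unname(fit$coefficients[1])
  }
  structure(list(arm_periods = arm, pairs = pairs, r = r,
                 slope = slope, intercept = intercept),
            class = "interlimb_report")
}

#' @export
print.interlimb_report <- function(x, ...) {
  cat(sprintf(
    "<interlimb_report> %d oscillation cycles, r = %.3f, fit y = %.3f x + %.3f\n",
    nrow(x$arm_periods), x$r, x$slope, x$intercept))
  invisible(x)
}
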