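#' Anthropometric segment weight table
#'
#' Whole-body CoM is estimated as a mass-fraction-weighted sum of segment
#' CoM positions, each segment CoM lying a fixed fraction of the way from
#' its proximal to its distal marker.
#'
#' @param segments data.frame with columns `segment` (name), `mass_fraction`
#'   (dimensionless, must sum to 1), `proximal`, `distal` (marker channel
#'   names) and `com_fraction` (position of the segment CoM along
#'   proximal -> distal, in `[0, 1]`).
#' @return object of class `segment_weight_table`.
#' @export
segment_weight_table <- function(segments) {
  stopifnot(is.data.frame(segments))
  need <- c("segment", "mass_fraction", "proximal", "distal", "com_fraction")
  if (!all(need %in% names(segments)))
    ps_abort(paste("segment table needs columns:",
                   paste(need, collapse = ", ")), "parameter_error")
  if (abs(sum(segments$mass_fraction) - 1) > 1e-6)
    ps_abort("segment mass fractions must sum to 1 (tolerance 1e-6)",
             "parameter_error")
  if (any(segments$mass_fraction < 0) ||
      any(segments$com_fraction < 0 | segments$com_fraction > 1))
    ps_abort("fractions must lie in [0, 1]", "parameter_error")
  structure(segments, class = c("segment_weight_table", "data.frame"))
}

#' Default segment weights for a reduced marker set
#'
#' Standard adult cadaver-study mass fractions (Dempster's coefficients,
#' merged for a reduced head-trunk / thigh / shank / foot / arm marker
#' set). The exact table behind any given lab pipeline varies; this default
#' is fully overridable via [segment_weight_table()].
#'
#' @return a [segment_weight_table()]. Marker channels expected:
#'   `head`, `hipC` (mid-pelvis), `hipL`/`hipR`, `kneeL`/`kneeR`,
#'   `ankleL`/`ankleR`, `toeL`/`toeR`, `shoulderL`/`shoulderR`,
#'   `wristL`/`wristR`.
#' @export
default_segment_weights <- function() {
  segment_weight_table(data.frame(
    segment = c("head_trunk", "thighL", "thighR", "shankL", "shankR",
                "footL", "footR", "armL", "armR"),
    mass_fraction = c(0.578, 0.100, 0.100, 0.0465, 0.0465,
                      0.0145, 0.0145, 0.050, 0.050),
    proximal = c("head", "hipL", "hipR", "kneeL", "kneeR",
                 "ankleL", "ankleR", "shoulderL", "shoulderR"),
    distal = c("hipC", "kneeL", "kneeR", "ankleL", "ankleR",
               "toeL", "toeR", "wristL", "wristR"),
    com_fraction = c(0.66, 0.433, 0.433, 0.433, 0.433,
                     0.5, 0.5, 0.53, 0.53)))
}

#' Whole-body CoM trajectory from markers
#'
#' `com(t) = sum_s massfrac_s * (proximal_s + comfrac_s * (distal_s -
#' proximal_s))`, evaluated per sample and coordinate. Linear in the marker
#' positions.
#'
#' @param table a [trajectory_table()] containing every marker named in
#'   `weights`.
#' @param weights a [segment_weight_table()].
#' @return `trajectory_table` with the single channel `"com"`.
#' @export
compute_com <- function(table, weights = default_segment_weights()) {
  stopifnot(inherits(table, "trajectory_table"))
  if (!inherits(weights, "segment_weight_table"))
    ps_abort("weights must be a segment_weight_table", "parameter_error")
  com <- matrix(0, nrow = length(table$time), ncol = 3)
  for (i in seq_len(nrow(weights))) {
    p <- traj_channel(table, weights$proximal[i])
    d <- traj_channel(table, weights$distal[i])
    com <- com + weights$mass_fraction[i] *
      (p + weights$com_fraction[i] * (d - p))
  }
  trajectory_table(table$time, list(com = com))
}

#' Heel-strike times from a heel-height series
#'
#' Heel strikes are estimated as the local minima of the (vertical) heel
#' trajectory. Minima are accepted when their prominence is at least
#' `min_prominence_frac` of the signal's peak-to-peak range (rejecting
#' noise wiggles) and successive accepted minima are at least
#' `min_separation` apart (deeper minima win).
#'
#' @param time sample times (s).
#' @param heel_z heel height series (m), gap-free.
#' @param min_separation minimum spacing between strikes (s); default
#'   0.5 s, below any plausible walking stride.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   peak-to-peak range.
#' @param refine refine each strike to the weighted centroid of its valley
#'   floor (the contiguous region within 5% of the peak-to-peak range above
#'   the minimum). Heel-height valleys are nearly flat around ground
#'   contact, so a raw argmin wanders by several samples under millimetre
#'   noise while the centroid stays sub-sample accurate. Default `TRUE`.
#' @return numeric vector of heel-strike times.
#' @export
detect_heel_strikes <- function(time, heel_z, min_separation = 0.5,
                                min_prominence_frac = 0.2, refine = TRUE) {
  stopifnot(length(time) == length(heel_z))
  if (anyNA(heel_z))
    ps_abort("heel series has gaps", "parameter_error")
  n <- length(heel_z)
  p2p <- diff(range(heel_z))
  if (p2p <= 0)
    ps_abort("no heel strikes: signal is constant", "no_strides_error")
  # interior local minima (plateau-tolerant: first sample of a flat valley)
  d <- diff(heel_z)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_locf(s)
  cand <- which(diff(s) > 0) + 1L
  cand <- cand[cand > 1L & cand < n]
  if (!length(cand))
    ps_abort("no local minima found in heel series", "no_strides_error")
  prom <- vapply(cand, function(i) {
    v <- heel_z[i]
    left <- heel_z[seq_len(i - 1L)]
    right <- heel_z[(i + 1L):n]
    lower_l <- which(left < v)
    lower_r <- which(right < v)
    hl <- if (length(lower_l)) max(left[(max(lower_l) + 1L):(i - 1L)]) else
      max(left)
    hr <- if (length(lower_r)) max(right[seq_len(min(lower_r) - 1L)]) else
      max(right)
    min(hl, hr) - v
  }, 0)
  keep <- cand[prom >= min_prominence_frac * p2p]
  if (!length(keep))
    ps_abort("no sufficiently prominent minima found", "no_strides_error")
  # enforce separation, deepest minima first
  ord <- keep[order(heel_z[keep])]
  sel <- integer()
  for (i in ord)
    if (!length(sel) || all(abs(time[i] - time[sel]) >= min_separation))
      sel <- c(sel, i)
  sel <- sort(sel)
  if (!refine) return(time[sel])
  # valley floor: contiguous region within 10% of the range above the
  # minimum; a single noisy sample does not terminate the region
  thr_off <- 0.1 * p2p
  coarse <- vapply(sel, function(i) {
    thr <- heel_z[i] + thr_off
    below <- function(k) !is.na(heel_z[k]) && heel_z[k] <= thr
    lo <- i
    while (lo > 1L && (below(lo - 1L) || (lo > 2L && below(lo - 2L))))
      lo <- lo - 1L
    hi <- i
    while (hi < n && (below(hi + 1L) || (hi < n - 1L && below(hi + 2L))))
      hi <- hi + 1L
    # a valley floor clipped by the recording edge cannot be located
    # reliably; drop the event (no-extrapolation policy)
    if (lo == 1L || hi == n) return(NA_real_)
    w <- pmax(thr - heel_z[lo:hi], 0)
    if (sum(w) <= 0) return(time[i])
    sum(time[lo:hi] * w) / sum(w)
  }, 0)
  coarse <- coarse[!is.na(coarse)]
  if (!length(coarse))
    ps_abort("no interior heel-strike valleys found", "no_strides_error")
  # sub-sample stage: heel valleys are locally even around ground contact,
  # so the strike is located as the time minimizing the left/right mirror
  # mismatch of the signal; this averages the noise over the whole valley
  # instead of trusting a single (noise-dominated) minimum sample
  vapply(coarse, function(tc)
    refine_symmetric(time, heel_z, tc, half_window = 0.06,
                     ks_max = 0.7 * min_separation), 0)
}

# symmetry-point refinement: argmin_s sum_k (v(s - k) - v(s + k))^2,
# scanned on a 1 ms grid and polished by a 3-point parabola
refine_symmetric <- function(time, v, t0, half_window = 0.06,
                             ks_max = 0.35) {
  dt <- time[2] - time[1]
  ks <- seq(2 * dt, ks_max, by = dt)
  ss <- seq(t0 - half_window, t0 + half_window, by = min(1e-3, dt / 2))
  grid <- outer(ss, ks, "-")
  left <- matrix(stats::approx(time, v, xout = grid)$y, nrow = length(ss))
  grid <- outer(ss, ks, "+")
  right <- matrix(stats::approx(time, v, xout = grid)$y, nrow = length(ss))
  d2 <- (left - right)^2
  ok_k <- colSums(is.na(d2)) == 0
  if (!any(ok_k)) return(t0)
  E <- rowSums(d2[, ok_k, drop = FALSE])
  i <- which.min(E)
  if (i == 1L || i == length(E)) return(ss[i])
  # parabolic interpolation of the discrete minimum
  denom <- E[i - 1] - 2 * E[i] + E[i + 1]
  if (denom <= 0) return(ss[i])
  ss[i] + 0.5 * (E[i - 1] - E[i + 1]) / denom * (ss[2] - ss[1])
}

# last-observation-carried-forward for the sign vector (plateau handling)
zoo_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  x[pmax(idx, 1L)]
}

#' Heel-strike events for both feet
#'
#' Convenience wrapper running [detect_heel_strikes()] on the vertical
#' coordinate of the left and right heel channels.
#'
#' @param table a [trajectory_table()] with the two heel channels.
#' @param left,right heel channel names.
#' @param ... passed to [detect_heel_strikes()].
#' @return object of class `gait_events`: list with numeric `left`,
#'   `right` strike times (s), strictly increasing per foot.
#' @export
gait_events <- function(table, left = "heelL", right = "heelR", ...) {
  ev <- list(left = detect_heel_strikes(table$time,
                                        traj_channel(table, left, "z"), ...),
             right = detect_heel_strikes(table$time,
                                         traj_channel(table, right, "z"), ...))
  structure(ev, class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> left: %d strikes, right: %d strikes\n",
              length(x$left), length(x$right)))
  invisible(x)
}

#' Per-stride gait metrics
#'
#' Computes, from heel-strike events and the heel/CoM channels:
#' \itemize{
#'   \item gait cycle time (GCT): interval between consecutive same-foot
#'     heel strikes, per foot;
#'   \item step length: forward-axis distance between the two heels at
#'     each heel-strike instant;
#'   \item forward velocity: mean central-difference derivative of the CoM
#'     forward coordinate (one-sided at the ends). Only the forward
#'     component is computed.
#' }
#'
#' @param events a [gait_events()] object.
#' @param table a [trajectory_table()] with both heel channels and a CoM
#'   channel.
#' @param heel_left,heel_right,com channel names.
#' @return object of class `stride_series`: list with `gct` (data.frame
#'   `foot`, `time`, `gct`), `step_length` (data.frame `foot`, `time`,
#'   `length`; foot = striking foot), `velocity` (mean, m/s),
#'   `velocity_series`, `n_strides`, and `summary` (means and SDs).
#' @export
stride_metrics <- function(events, table, heel_left = "heelL",
                           heel_right = "heelR", com = "com") {
  stopifnot(inherits(events, "gait_events"),
            inherits(table, "trajectory_table"))
  if (length(events$left) < 2 && length(events$right) < 2)
    ps_abort("need at least two heel strikes on a foot",
             "insufficient_strides_error")
  gct <- do.call(rbind, lapply(c("left", "right"), function(f) {
    tt <- events[[f]]
    if (length(tt) < 2) return(NULL)
    data.frame(foot = f, time = tt[-1], gct = diff(tt))
  }))
  hx <- list(left = traj_channel(table, heel_left, "x"),
             right = traj_channel(table, heel_right, "x"))
  step_len <- do.call(rbind, lapply(c("left", "right"), function(f) {
    other <- if (f == "left") "right" else "left"
    tt <- events[[f]]
    x_self <- stats::approx(table$time, hx[[f]], xout = tt)$y
    x_other <- stats::approx(table$time, hx[[other]], xout = tt)$y
    data.frame(foot = f, time = tt, length = abs(x_self - x_other))
  }))
  step_len <- step_len[order(step_len$time), ]
  cx <- traj_channel(table, com, "x")
  n <- length(cx)
  dt <- 1 / table$sample_rate
  vel <- c(cx[2] - cx[1],
           (cx[3:n] - cx[1:(n - 2)]) / 2,
           cx[n] - cx[n - 1]) / dt
  structure(list(
    gct = gct,
    step_length = step_len,
    velocity = mean(vel),
    velocity_series = vel,
    n_strides = sum(vapply(events, function(e) max(length(e) - 1L, 0L), 0L)),
    summary = data.frame(
      metric = c("gct", "step_length", "velocity"),
      mean = c(mean(gct$gct), mean(step_len$length), mean(vel)),
      sd = c(stats::sd(gct$gct), stats::sd(step_len$length),
             stats::sd(vel)))),
    class = "stride_series")
}

#' @export
print.stride_series <- function(x, ...) {
  cat(sprintf(
    "<stride_series> %d strides: GCT %.3f +- %.3f s, step %.3f +- %.3f m, speed %.3f m/s\n",
    x$n_strides, x$summary$mean[1], x$summary$sd[1],
    x$summary$mean[2], x$summary$sd[2], x$velocity))
  invisible(x)
}
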