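#' Zero-phase Butterworth low-pass filter
#'
#' Filters every coordinate of every channel forward and backward
#' (zero-phase), leaving the time base untouched and preserving the DC
#' component. Defaults follow standard gait-analysis practice for 100 Hz
#' motion capture: 4th-order Butterworth, 10 Hz cutoff.
#'
#' @param table a gap-free [trajectory_table()].
#' @param cutoff cutoff frequency (Hz), must be below the Nyquist
#'   frequency.
#' @param order filter order of the underlying Butterworth design (the
#'   forward-backward pass doubles the effective attenuation).
#' @return filtered `trajectory_table`.
#' @export
butterworth_lowpass <- function(table, cutoff = 10, order = 4) {
  stopifnot(inherits(table, "trajectory_table"))
  nyq <- table$sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq)
    ps_abort(sprintf("cutoff must lie in (0, %g) Hz (Nyquist)", nyq),
             "parameter_error")
  if (has_gaps(table))
    ps_abort("table has gaps; fill them before filtering",
             "parameter_error")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  # reflection padding: filtfilt starts from zero initial conditions, so an
  # unpadded pass leaves edge transients (and even a constant signal would
  # be distorted near the ends)
  n_pad <- function(n) min(n - 1L, as.integer(ceiling(10 * table$sample_rate / cutoff)))
  filt1 <- function(v) {
    n <- length(v)
    np <- n_pad(n)
    ext <- c(2 * v[1] - v[(np + 1L):2L], v, 2 * v[n] - v[(n - 1L):(n - np)])
    out <- signal::filtfilt(bf, ext)
    out[(np + 1L):(np + n)]
  }
  channels <- lapply(table$channels, function(ch) apply(ch, 2, filt1))
  trajectory_table(table$time, channels)
}

#' Fill short gaps by linear interpolation
#'
#' Gaps (runs of `NA`) shorter than `max_gap` are filled by linear
#' interpolation between the surrounding samples, per coordinate. Longer
#' gaps, and gaps touching either end of the recording (which would
#' require extrapolation), raise an error naming the channel and interval.
#'
#' @param table a [trajectory_table()].
#' @param max_gap longest fillable gap (s); a gap of duration `>= max_gap`
#'   is an error. Default 0.2 s, a conservative bound at walking cadence.
#' @return gap-free `trajectory_table`.
#' @export
fill_short_gaps <- function(table, max_gap = 0.2) {
  stopifnot(inherits(table, "trajectory_table"))
  dt <- 1 / table$sample_rate
  channels <- table$channels
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    for (a in 1:3) {
      v <- ch[, a]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i0 <- starts[k]; i1 <- ends[k]
        dur <- (r$lengths[k] + 1L) * dt  # span between flanking samples
        at_edge <- i0 == 1L || i1 == length(v)
        if (at_edge || dur >= max_gap)
          ps_abort(sprintf(
            "gap in channel '%s' over [%.4f, %.4f] s (%s)",
            nm, table$time[i0], table$time[i1],
            if (at_edge) "at series edge, no extrapolation"
            else sprintf("duration %.3f s >= max_gap %.3f s", dur, max_gap)),
            "gap_too_large_error")
      }
      ok <- !is.na(v)
      ch[, a] <- stats::approx(table$time[ok], v[ok],
                               xout = table$time)$y
    }
    channels[[nm]] <- ch
  }
  trajectory_table(table$time, channels)
}
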