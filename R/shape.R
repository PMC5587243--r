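#' Stride-normalized vertical CoM curve
#'
#' Each complete stride (between consecutive same-foot heel strikes) is
#' resampled by linear interpolation onto 1000 points spanning 0-100% of
#' the gait cycle; the output is the pointwise mean across strides,
#' mean-centered. Centering removes the absolute CoM height so that only
#' the waveform shape is compared (centering before or after averaging is
#' equivalent for the mean curve).
#'
#' @param time sample times (s).
#' @param com_z vertical CoM series (m).
#' @param strikes same-foot heel-strike times delimiting the strides (s).
#' @param n_points resampling resolution (default 1000).
#' @param center mean-center the averaged curve (default `TRUE`).
#' @return object of class `normalized_curve`: numeric vector of length
#'   `n_points` with attributes `cycle_percent` and `n_strides`.
#' @export
normalize_strides <- function(time, com_z, strikes, n_points = 1000,
                              center = TRUE) {
  stopifnot(length(time) == length(com_z))
  strikes <- sort(strikes)
  if (length(strikes) < 2)
    ps_abort("need at least one complete stride", "insufficient_strides_error")
  phases <- seq(0, 1, length.out = n_points + 1L)[seq_len(n_points)]
  curves <- vapply(seq_len(length(strikes) - 1L), function(i) {
    tt <- strikes[i] + phases * (strikes[i + 1] - strikes[i])
    stats::approx(time, com_z, xout = tt)$y
  }, numeric(n_points))
  curve <- rowMeans(curves)
  if (anyNA(curve))
    ps_abort("strides extend beyond the sampled time range",
             "insufficient_strides_error")
  if (center) curve <- curve - mean(curve)
  structure(curve, cycle_percent = 100 * phases,
            n_strides = length(strikes) - 1L,
            class = "normalized_curve")
}

#' Dissimilarity measure between two stride-normalized curves
#'
#' Shape comparison in the spirit of Procrustes analysis for 1-D curves:
#' both curves are mean-centered (translation removal; no scaling or
#' rotation applies to 1-D functions of cycle percent) and the square root
#' of the sum of squared pointwise differences is returned:
#' `DM = sqrt(sum_i (za_i - zb_i)^2)`.
#'
#' @param a,b numeric curves of equal length (typically
#'   [normalize_strides()] outputs).
#' @param center mean-center both curves first (default `TRUE`; set
#'   `FALSE` for the raw sum-of-squares variant).
#' @return dissimilarity (m); 0 iff the centered curves are identical.
#' @export
dissimilarity_measure <- function(a, b, center = TRUE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b))
    ps_abort("curves must have equal length", "parameter_error")
  if (center) {
    a <- a - mean(a)
    b <- b - mean(b)
  }
  sqrt(sum((a - b)^2))
}

#' Write a normalized curve as CSV (`cycle_percent,z_m`)
#'
#' @param curve a `normalized_curve`.
#' @param path output path.
#' @export
write_normalized_curve <- function(curve, path) {
  stopifnot(inherits(curve, "normalized_curve"))
  utils::write.csv(data.frame(cycle_percent = attr(curve, "cycle_percent"),
                              z_m = as.numeric(curve)),
                   path, row.names = FALSE)
  invisible(path)
}
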