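#' Uniformly sampled table of 3-D trajectory channels
#'
#' The pipeline's universal input: a strictly increasing, uniformly sampled
#' time base plus named channels (markers, CoM), each an `n x 3` matrix of
#' coordinates in meters. Axis convention: x = forward direction of travel,
#' y = lateral, z = vertical (up). Missing samples (`NA`) mark gaps; most
#' operations require gap-free input (see [fill_short_gaps()]).
#'
#' @param time numeric vector of sample times (s), strictly increasing with
#'   uniform step (tolerance 1e-9 s).
#' @param channels named list of `n x 3` numeric matrices (columns x, y, z).
#' @return object of class `trajectory_table` with fields `time`,
#'   `channels`, `sample_rate` (Hz).
#' @export
trajectory_table <- function(time, channels) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 2) ps_abort("need at least two samples", "format_error")
  dt <- diff(time)
  if (any(dt <= 0))
    ps_abort("time must be strictly increasing", "time_base_error")
  if (any(abs(dt - dt[1]) >= 1e-9))
    ps_abort("time base is not uniform (tolerance 1e-9 s)",
             "time_base_error")
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    ps_abort("channels must be a non-empty named list", "format_error")
  channels <- lapply(channels, function(ch) {
    ch <- as.matrix(ch)
    if (nrow(ch) != n || ncol(ch) != 3)
      ps_abort("every channel needs one (x, y, z) sample per time point",
               "format_error")
    colnames(ch) <- c("x", "y", "z")
    storage.mode(ch) <- "double"
    ch
  })
  structure(list(time = time, channels = channels,
                 sample_rate = 1 / dt[1]),
            class = "trajectory_table")
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf(
    "<trajectory_table> %d samples @ %g Hz, %d channel(s): %s%s\n",
    length(x$time), round(x$sample_rate, 6), length(x$channels),
    paste(names(x$channels), collapse = ", "),
    if (has_gaps(x)) " [has gaps]" else ""))
  invisible(x)
}

#' @rdname trajectory_table
#' @param table a `trajectory_table`.
#' @export
has_gaps <- function(table) {
  stopifnot(inherits(table, "trajectory_table"))
  any(vapply(table$channels, anyNA, TRUE))
}

#' Extract a channel or single coordinate
#'
#' @param table a `trajectory_table`.
#' @param name channel name.
#' @param coord optional `"x"`, `"y"` or `"z"`; if given, returns the
#'   coordinate vector instead of the `n x 3` matrix.
#' @export
traj_channel <- function(table, name, coord = NULL) {
  stopifnot(inherits(table, "trajectory_table"))
  if (!name %in% names(table$channels))
    ps_abort(sprintf("channel '%s' not present (have: %s)", name,
                     paste(names(table$channels), collapse = ", ")),
             "missing_channel_error")
  ch <- table$channels[[name]]
  if (is.null(coord)) ch else ch[, coord]
}

#' Read a trajectory CSV
#'
#' Expected header: `time,<name>_x,<name>_y,<name>_z,...`; units seconds
#' and meters; empty cells mark gaps (kept as `NA`, never dropped).
#'
#' @param path CSV file path.
#' @param expected_channels channel names that must be present.
#' @return a [trajectory_table()].
#' @export
read_trajectory_table <- function(path, expected_channels = NULL) {
  if (!file.exists(path))
    ps_abort(sprintf("file '%s' does not exist", path), "format_error")
  df <- utils::read.csv(path, check.names = FALSE)
  if (!ncol(df) || names(df)[1] != "time")
    ps_abort("first column must be named 'time'", "format_error")
  cn <- names(df)[-1]
  m <- regmatches(cn, regexec("^(.*)_([xyz])$", cn))
  if (any(vapply(m, length, 0L) != 3L))
    ps_abort("channel columns must be named <channel>_x/_y/_z",
             "format_error")
  base <- vapply(m, `[[`, "", 2L)
  ax <- vapply(m, `[[`, "", 3L)
  chn <- unique(base)
  channels <- lapply(chn, function(nm) {
    cols <- vapply(c("x", "y", "z"), function(a) {
      k <- which(base == nm & ax == a)
      if (length(k) != 1L)
        ps_abort(sprintf(
          "channel '%s' must have exactly one _%s column", nm, a),
          "format_error")
      k + 1L
    }, 0L)
    as.matrix(df[, cols])
  })
  names(channels) <- chn
  if (!is.null(expected_channels)) {
    missing <- setdiff(expected_channels, chn)
    if (length(missing))
      ps_abort(sprintf("required channel(s) absent: %s",
                       paste(missing, collapse = ", ")),
               "missing_channel_error")
  }
  trajectory_table(df$time, channels)
}

#' Write a trajectory CSV
#'
#' Inverse of [read_trajectory_table()]; round-trips values to better than
#' 1e-9 m. Gaps are written as empty cells.
#'
#' @param table a [trajectory_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(table, path) {
  stopifnot(inherits(table, "trajectory_table"))
  cols <- list(time = table$time)
  for (nm in names(table$channels))
    for (a in c("x", "y", "z"))
      cols[[paste0(nm, "_", a)]] <- table$channels[[nm]][, a]
  df <- as.data.frame(cols, check.names = FALSE)
  # as.character keeps 15 significant digits, ample for the 1e-9 m contract
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
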