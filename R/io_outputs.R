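#' Trial metadata
#'
#' Identity and anthropometrics of a recorded trial: pair and subject ids,
#' the walker's role (in front of / behind the carried object, or solo),
#' body mass and hip-to-ankle leg length.
#'
#' @param pair_id,subject_id identifiers (text).
#' @param role `"A_front"`, `"B_behind"` or `"solo"`.
#' @param mass body mass (kg), positive.
#' @param leg_length hip-to-ankle leg length (m), in (0.5, 1.2).
#' @return object of class `trial_metadata`.
#' @export
trial_metadata <- function(pair_id, subject_id, role, mass, leg_length) {
  role <- match.arg(role, c("A_front", "B_behind", "solo"))
  if (!is.numeric(mass) || mass <= 0)
    ps_abort("mass must be positive", "parameter_error")
  if (!is.numeric(leg_length) || leg_length <= 0.5 || leg_length >= 1.2)
    ps_abort("leg length must lie in (0.5, 1.2) m", "parameter_error")
  structure(list(pair_id = as.character(pair_id),
                 subject_id = as.character(subject_id),
                 role = role, mass = mass, leg_length = leg_length),
            class = "trial_metadata")
}

#' Read/write trial metadata as a YAML sidecar
#'
#' @param meta a [trial_metadata()] object.
#' @param path YAML file path.
#' @return the metadata object ([read_trial_metadata()]) or `path`.
#' @export
write_trial_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "trial_metadata"))
  if (!requireNamespace("yaml", quietly = TRUE))
    ps_abort("the 'yaml' package is required for metadata sidecars",
             "parameter_error")
  yaml::write_yaml(unclass(meta), path)
  invisible(path)
}

#' @rdname write_trial_metadata
#' @export
read_trial_metadata <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    ps_abort("the 'yaml' package is required for metadata sidecars",
             "parameter_error")
  m <- yaml::read_yaml(path)
  trial_metadata(m$pair_id, m$subject_id, m$role, m$mass, m$leg_length)
}

#' Write heel-strike events as CSV (`foot,time_s`)
#'
#' @param events a [gait_events()] object.
#' @param path output path.
#' @export
write_gait_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  df <- rbind(data.frame(foot = "left", time_s = events$left),
              data.frame(foot = "right", time_s = events$right))
  utils::write.csv(df[order(df$time_s), ], path, row.names = FALSE)
  invisible(path)
}

#' Write per-stride metrics as CSV (per-stride rows plus summary rows)
#'
#' @param stride a [stride_metrics()] result.
#' @param path output path.
#' @export
write_stride_series <- function(stride, path) {
  stopifnot(inherits(stride, "stride_series"))
  rows <- rbind(
    data.frame(record = "gct", foot = stride$gct$foot,
               time_s = stride$gct$time, value = stride$gct$gct),
    data.frame(record = "step_length", foot = stride$step_length$foot,
               time_s = stride$step_length$time,
               value = stride$step_length$length),
    data.frame(record = paste0("summary_mean_", stride$summary$metric),
               foot = NA, time_s = NA, value = stride$summary$mean),
    data.frame(record = paste0("summary_sd_", stride$summary$metric),
               foot = NA, time_s = NA, value = stride$summary$sd))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation trace (states + support flags) and its event log
#'
#' @param trace a `slip_trace`.
#' @param state_path CSV path for the sampled state.
#' @param events_path optional CSV path for the event log.
#' @export
write_trace <- function(trace, state_path, events_path = NULL) {
  stopifnot(inherits(trace, "slip_trace"))
  utils::write.csv(trace$state, state_path, row.names = FALSE)
  if (!is.null(events_path))
    utils::write.csv(trace$events, events_path, row.names = FALSE)
  invisible(state_path)
}

#' Write a score grid as long-format CSV plus a JSON summary
#'
#' @param grid a `score_grid`.
#' @param csv_path long-format CSV (`<param1>,<param2>,score`).
#' @param json_path optional JSON summary (argmax + fixed parameters).
#' @export
write_score_grid <- function(grid, csv_path, json_path = NULL) {
  stopifnot(inherits(grid, "score_grid"))
  utils::write.csv(score_grid_table(grid), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(step = grid$step, objective = grid$objective,
           param_names = grid$param_names, best = grid$best,
           fixed = grid$fixed, t_max = grid$t_max, xi = grid$xi),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Write a trial-fitting result as JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(mode = fit$mode,
         parameters = list(k_leg = fit$p1$k_leg, alpha = fit$p1$alpha,
                           k_arm = fit$coupling$k1, b_arm = fit$coupling$b1),
         scores = list(S_P = fit$S_P, S_S = fit$S_S,
                       S_R = fit$S_R, S_G = fit$S_G),
         gait = fit$summary,
         subjects = fit$subjects),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
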