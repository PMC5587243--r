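#' Simulate one SLIP or the coupled pair as a hybrid dynamical system
#'
#' Event-driven integration of the sagittal-plane equations of motion with
#' exact event localization. Per pendulum the support state cycles through
#' single support after the apex (gamma = 1, beta = 0), double support
#' (1, 1) and single support before the apex (0, 1):
#' \itemize{
#'   \item touchdown: descending through `z = l0 sin(alpha)` plants the new
#'     foot `l0 cos(alpha)` ahead of the CoM;
#'   \item liftoff: the trailing leg extends back to its rest length `l0`;
#'   \item apex: vertical velocity crosses zero from above while vaulting
#'     over the leading leg; the stance reference is relabelled to that
#'     foot and the apex state is recorded (the return-map section).
#' }
#' The two pendulums' support states evolve independently; the carried
#' object couples them through horizontal spring-damper arm forces only.
#' Leg springs are bilateral while engaged: engagement is governed solely by
#' the touchdown/liftoff events, so a stance leg momentarily stretched past
#' `l0` (as at the reference apex initial condition) still pulls.
#'
#' A trial is truncated with a `failure` event when a CoM drops below
#' `0.2 l0`, an engaged leg compresses below `0.1 l0`, or forward velocity
#' stays negative for more than 0.2 s; the truncated trace is still
#' returned so it can be scored (such gaits score 0 for periodicity).
#'
#' @param p1 [slip_params()] of the rear pendulum.
#' @param p2 [slip_params()] of the front pendulum, or `NULL` for a solo
#'   simulation.
#' @param coupling [coupling_params()], or `NULL` for mechanically
#'   uncoupled pendulums.
#' @param init1,init2 [slip_init()] apex initial conditions.
#' @param t_max simulation horizon (s). 100 s is the reference window used
#'   for periodicity scoring.
#' @param d0 initial horizontal offset between the two stance feet (m).
#'   Default places the arms exactly at their equilibrium lengths:
#'   `L01 + L_object + L02` (adjusted for the apex offsets).
#' @param dt_out sampling step of the returned trace (s).
#' @param rtol,atol integrator tolerances. Return-map residuals at the 1e-3
#'   scale require tight tolerances; defaults 1e-9 / 1e-11.
#' @param strict_signs use the printed-sign variant of the front-leg
#'   vertical force (see vignette); default `FALSE`.
#' @return an object of class `slip_trace`: list with `time`, `state`
#'   (data.frame of absolute positions/velocities, support flags and foot
#'   positions per sample), `events` (data.frame `time`, `pendulum`,
#'   `type`), `apex1`/`apex2` (data.frames `time`, `x_apex`, `z_apex`,
#'   `vx`), `failed`, `t_end`, and the parameter objects.
#' @export
simulate_paired <- function(p1, p2 = NULL, coupling = NULL,
                            init1, init2 = init1,
                            t_max = 100, d0 = NULL, dt_out = 0.01,
                            rtol = 1e-9, atol = 1e-11,
                            strict_signs = FALSE) {
  stopifnot(inherits(p1, "slip_params"), inherits(init1, "slip_init"))
  if (t_max <= 0) ps_abort("t_max must be positive", "parameter_error")
  paired <- !is.null(p2)
  coupled <- paired && !is.null(coupling)
  if (coupled) stopifnot(inherits(coupling, "coupling_params"))
  g <- PS_GRAVITY

  s1 <- initial_state_from_energy(p1, init1$E0, init1$x_apex, init1$z_apex,
                                  init1$reference)
  mode <- c(1L, 1L)
  fb <- c(-init1$x_apex, NA_real_)
  ff <- c(NA_real_, NA_real_)
  if (paired) {
    stopifnot(inherits(p2, "slip_params"), inherits(init2, "slip_init"))
    s2 <- initial_state_from_energy(p2, init2$E0, init2$x_apex, init2$z_apex,
                                    init2$reference)
    if (is.null(d0)) {
      d0 <- if (coupled) {
        coupling$L01 + coupling$L_object + coupling$L02 +
          init1$x_apex - init2$x_apex
      } else 1.5
    }
    fb[2] <- fb[1] + d0
  }

  # continuous state vector (absolute coordinates)
  if (coupled) {
    xt0 <- 0 + coupling$L01 + coupling$L_object / 2  # X1(0) = 0
    y <- c(0, s1$z, s1$vx, 0,
           fb[2] + init2$x_apex, s2$z, s2$vx, 0,
           xt0, (s1$vx + s2$vx) / 2)
  } else if (paired) {
    y <- c(0, s1$z, s1$vx, 0, fb[2] + init2$x_apex, s2$z, s2$vx, 0)
  } else {
    y <- c(0, s1$z, s1$vx, 0)
  }

  np <- if (paired) 2L else 1L
  l0 <- c(p1$leg_length, if (paired) p2$leg_length else NA)
  kl <- c(p1$k_leg, if (paired) p2$k_leg else NA)
  al <- c(p1$alpha, if (paired) p2$alpha else NA)
  ms <- c(p1$mass, if (paired) p2$mass else NA)
  off <- function(i) (i - 1L) * 4L   # state offset of pendulum i

  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    F1t <- 0; F2t <- 0
    if (coupled) {
      af <- ps_arm_forces(y[1], y[3], y[5], y[7], y[9], y[10], coupling)
      F1t <- af[[1L]]; F2t <- af[[2L]]
      dy[9] <- y[10]
      dy[10] <- (F1t + F2t) / coupling$m_object
    }
    Farm <- c(F1t, F2t)
    for (i in seq_len(np)) {
      o <- off(i)
      f <- ps_leg_force(y[o + 1], y[o + 2], fb[i], ff[i], mode[i],
                        kl[i], l0[i], strict_signs)
      dy[o + 1] <- y[o + 3]
      dy[o + 2] <- y[o + 4]
      dy[o + 3] <- (f[1] - Farm[i]) / ms[i]
      dy[o + 4] <- f[2] / ms[i] - g
    }
    list(dy)
  }

  # root layout: per pendulum (r, r+1, r+2, r+3) =
  #   gait event, fall (z - 0.2 l0), back-leg compression, front-leg compression
  rootfun <- function(t, y, parms) {
    r <- numeric(4L * np)
    for (i in seq_len(np)) {
      o <- off(i); b <- (i - 1L) * 4L
      X <- y[o + 1]; Z <- y[o + 2]
      r[b + 1] <- switch(mode[i],
        Z - l0[i] * sin(al[i]),                       # touchdown
        sqrt((X - fb[i])^2 + Z^2) - l0[i],            # liftoff
        y[o + 4])                                     # apex (vz = 0)
      r[b + 2] <- Z - 0.2 * l0[i]
      r[b + 3] <- if (mode[i] <= 2L)
        sqrt((X - fb[i])^2 + Z^2) - 0.1 * l0[i] else 1
      r[b + 4] <- if (mode[i] >= 2L)
        sqrt((ff[i] - X)^2 + Z^2) - 0.1 * l0[i] else 1
    }
    r
  }

  out_times <- seq(0, t_max, by = dt_out)
  rows <- vector("list", 256L); nrows <- 0L
  events <- list(); apex <- list(list(), list())
  failed <- FALSE; fail_reason <- NULL
  vx_neg_since <- c(NA_real_, NA_real_)

  push_rows <- function(m) {
    nrows <<- nrows + 1L
    if (nrows > length(rows)) length(rows) <<- 2L * nrows
    sup <- c(mode[1], fb[1], ff[1],
             if (paired) c(mode[2], fb[2], ff[2]))
    rows[[nrows]] <<- cbind(m, matrix(rep(sup, each = nrow(m)),
                                      nrow = nrow(m)))
  }
  log_event <- function(time, pend, type) {
    events[[length(events) + 1L]] <<- list(time = time, pendulum = pend,
                                           type = type)
  }

  # direction-validity of a triggered gait root at state y
  gait_root_valid <- function(i, y) {
    o <- off(i)
    X <- y[o + 1]; Z <- y[o + 2]; VX <- y[o + 3]; VZ <- y[o + 4]
    switch(mode[i],
      VZ < 0,                                            # touchdown: descending
      {                                                   # liftoff: extending
        xb <- X - fb[i]
        (xb * VX + Z * VZ) > 0
      },
      deriv(0, y, NULL)[[1L]][o + 4] < 0)                 # apex: vz decreasing
  }

  check_vx_failure <- function(seg, t_hi) {
    # seg: matrix time + states; returns failure time or NA
    for (i in seq_len(np)) {
      vx <- seg[, 1L + off(i) + 3L]
      tt <- seg[, 1L]
      for (k in seq_along(tt)) {
        if (vx[k] < 0) {
          if (is.na(vx_neg_since[i])) vx_neg_since[i] <<- tt[k]
          if (tt[k] - vx_neg_since[i] >= 0.2) return(c(tt[k], i))
        } else {
          vx_neg_since[i] <<- NA_real_
        }
      }
    }
    NULL
  }

  t_cur <- 0
  y_cur <- y
  eps <- 1e-9
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200000L)
      ps_abort("event loop failed to advance", "integration_error")
    if (t_cur >= t_max - 1e-12) break
    times <- out_times[out_times > t_cur + 1e-12]
    times <- c(t_cur, times)
    if (times[length(times)] < t_max - 1e-12) times <- c(times, t_max)
    out <- try(deSolve::lsodar(y = y_cur, times = times, func = deriv,
                               parms = NULL, rootfunc = rootfun,
                               rtol = rtol, atol = atol, maxsteps = 100000),
               silent = TRUE)
    if (inherits(out, "try-error"))
      ps_abort(paste0("integration failed at t = ", signif(t_cur, 10),
                      ": ", attr(out, "condition")$message),
               "integration_error")
    m <- unclass(out)
    troot <- attr(out, "troot")
    iroot <- attr(out, "iroot")
    t_seg_end <- m[nrow(m), 1L]
    # rows strictly inside the segment (skip the duplicated start row)
    seg <- m[-1L, , drop = FALSE]
    if (nrow(seg)) push_rows(seg)
    vxf <- if (nrow(seg)) check_vx_failure(seg, t_seg_end) else NULL
    if (!is.null(vxf)) {
      failed <- TRUE; fail_reason <- "backward"
      log_event(vxf[1], as.integer(vxf[2]), "failure")
      break
    }
    y_end <- as.numeric(m[nrow(m), -1L])
    if (is.null(troot) || length(troot) == 0L) {
      t_cur <- t_seg_end; y_cur <- y_end
      next
    }
    # an event fired at troot
    trig <- which(iroot != 0L)
    handled <- FALSE
    for (r in trig) {
      i <- ((r - 1L) %/% 4L) + 1L
      kind <- ((r - 1L) %% 4L) + 1L
      if (kind == 1L) {
        if (!gait_root_valid(i, y_end)) next
        handled <- TRUE
        o <- off(i)
        if (mode[i] == 1L) {          # touchdown
          ff[i] <- y_end[o + 1] + l0[i] * cos(al[i])
          mode[i] <- 2L
          log_event(troot, i, "touchdown")
        } else if (mode[i] == 2L) {   # liftoff
          fb[i] <- NA_real_
          mode[i] <- 3L
          log_event(troot, i, "liftoff")
        } else {                      # apex: relabel stance foot
          apex[[i]][[length(apex[[i]]) + 1L]] <-
            c(time = troot,
              x_apex = y_end[o + 1] - ff[i],
              z_apex = y_end[o + 2] - l0[i],
              vx = y_end[o + 3])
          fb[i] <- ff[i]
          ff[i] <- NA_real_
          mode[i] <- 1L
          log_event(troot, i, "apex")
        }
      } else {                        # failure roots
        valid <- if (kind == 2L) y_end[off(i) + 4L] < 0 else TRUE
        if (!valid) next
        handled <- TRUE
        failed <- TRUE
        fail_reason <- if (kind == 2L) "fall" else "leg_collapse"
        log_event(troot, i, "failure")
      }
    }
    if (failed) break
    t_cur <- troot
    y_cur <- y_end
    if (!handled) {
      # root crossed in the non-triggering direction: nudge past it
      h <- eps
      d <- deriv(t_cur, y_cur, NULL)[[1L]]
      y_cur <- y_cur + h * d
      t_cur <- t_cur + h
    }
  }

  state <- do.call(rbind, rows[seq_len(nrows)])
  sn <- c("x1", "z1", "vx1", "vz1")
  if (paired) sn <- c(sn, "x2", "z2", "vx2", "vz2")
  if (coupled) sn <- c(sn, "xt", "vxt")
  supn <- c("mode1", "fb1", "ff1", if (paired) c("mode2", "fb2", "ff2"))
  state <- as.data.frame(state)
  names(state) <- c("time", sn, supn)
  state$gamma1 <- as.integer(state$mode1 <= 2)
  state$beta1 <- as.integer(state$mode1 >= 2)
  if (paired) {
    state$gamma2 <- as.integer(state$mode2 <= 2)
    state$beta2 <- as.integer(state$mode2 >= 2)
  }
  apex_df <- lapply(apex, function(a)
    if (length(a)) as.data.frame(do.call(rbind, a)) else
      data.frame(time = numeric(), x_apex = numeric(),
                 z_apex = numeric(), vx = numeric()))
  ev <- if (length(events)) {
    data.frame(time = vapply(events, `[[`, 0, "time"),
               pendulum = vapply(events, `[[`, 0L, "pendulum"),
               type = vapply(events, `[[`, "", "type"))
  } else data.frame(time = numeric(), pendulum = integer(),
                    type = character())
  structure(list(time = state$time, state = state, events = ev,
                 apex1 = apex_df[[1L]],
                 apex2 = if (paired) apex_df[[2L]] else NULL,
                 failed = failed, fail_reason = fail_reason,
                 t_end = if (nrow(state)) state$time[nrow(state)] else 0,
                 p1 = p1, p2 = p2, coupling = coupling,
                 paired = paired, coupled = coupled,
                 strict_signs = strict_signs),
            class = "slip_trace")
}

#' @export
print.slip_trace <- function(x, ...) {
  cat(sprintf("<slip_trace> %s, t = [0, %.3f] s, %d samples\n",
              if (x$paired) if (x$coupled) "coupled pair" else
                "uncoupled pair" else "solo SLIP",
              x$t_end, nrow(x$state)))
  cat(sprintf("  apexes: %d%s; events: %d; %s\n",
              nrow(x$apex1),
              if (x$paired) sprintf(" / %d", nrow(x$apex2)) else "",
              nrow(x$events),
              if (x$failed) paste0("FAILED (", x$fail_reason, ")")
              else "completed"))
  invisible(x)
}

#' Mechanical energy along a simulated trace
#'
#' Sums, per sample: each pendulum's kinetic and gravitational energy and
#' the elastic energy of every engaged leg spring, the arm spring energies,
#' and the object's kinetic energy. With zero arm damping this total is
#' conserved (the model has no energy source); with damping it decreases
#' exactly by the integral of the damper dissipation.
#'
#' @param trace a `slip_trace` from [simulate_paired()].
#' @return numeric vector of energies (J), one per trace sample.
#' @export
mechanical_energy <- function(trace) {
  stopifnot(inherits(trace, "slip_trace"))
  s <- trace$state
  g <- PS_GRAVITY
  leg_pe <- function(X, Z, foot, engaged, k, l0) {
    L <- sqrt((X - foot)^2 + Z^2)
    ifelse(engaged, 0.5 * k * (L - l0)^2, 0)
  }
  p1 <- trace$p1
  E <- 0.5 * p1$mass * (s$vx1^2 + s$vz1^2) + p1$mass * g * s$z1 +
    leg_pe(s$x1, s$z1, s$fb1, s$mode1 <= 2, p1$k_leg, p1$leg_length) +
    leg_pe(s$x1, s$z1, s$ff1, s$mode1 >= 2, p1$k_leg, p1$leg_length)
  if (trace$paired) {
    p2 <- trace$p2
    E <- E + 0.5 * p2$mass * (s$vx2^2 + s$vz2^2) + p2$mass * g * s$z2 +
      leg_pe(s$x2, s$z2, s$fb2, s$mode2 <= 2, p2$k_leg, p2$leg_length) +
      leg_pe(s$x2, s$z2, s$ff2, s$mode2 >= 2, p2$k_leg, p2$leg_length)
  }
  if (trace$coupled) {
    cp <- trace$coupling
    half <- cp$L_object / 2
    L1 <- (s$xt - half) - s$x1
    L2 <- s$x2 - (s$xt + half)
    E <- E + 0.5 * cp$k1 * (L1 - cp$L01)^2 + 0.5 * cp$k2 * (L2 - cp$L02)^2 +
      0.5 * cp$m_object * s$vxt^2
  }
  E
}
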