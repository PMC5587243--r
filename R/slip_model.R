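#' Gravitational acceleration used throughout the model (m/s^2)
#' @keywords internal
PS_GRAVITY <- 9.81

#' Parameters of a single spring-loaded inverted pendulum (SLIP)
#'
#' A walker is reduced to a point mass on massless spring legs. The swing leg
#' is held at a fixed angle of attack; at touchdown the foot is planted
#' `leg_length * cos(alpha)` ahead of the centre of mass.
#'
#' @param mass point mass of the walker (kg).
#' @param leg_length rest length of the leg spring, hip-to-ankle (m).
#' @param k_leg leg spring stiffness (N/m).
#' @param alpha angle of attack (rad), in (0, pi/2].
#' @param warn_range warn when stiffness/angle leave the mechanically
#'   plausible ranges used for the systematic search (see
#'   [search_parameter_ranges()]). Out-of-range values are allowed.
#' @return an object of class `slip_params`.
#' @export
slip_params <- function(mass, leg_length, k_leg, alpha, warn_range = TRUE) {
  stopifnot(is.numeric(mass), is.numeric(leg_length), is.numeric(k_leg),
            is.numeric(alpha))
  if (mass <= 0 || leg_length <= 0 || k_leg <= 0)
    ps_abort("mass, leg_length and k_leg must be positive", "parameter_error")
  if (alpha <= 0 || alpha > pi / 2)
    ps_abort("alpha must lie in (0, pi/2] radians", "parameter_error")
  if (warn_range) {
    rng <- search_parameter_ranges()
    if (k_leg < rng$k_leg[1] || k_leg > rng$k_leg[2])
      ps_warn(sprintf("k_leg = %g N/m outside the usual range [%g, %g]",
                      k_leg, rng$k_leg[1], rng$k_leg[2]), "range_warning")
    if (alpha < rng$alpha[1] || alpha > rng$alpha[2])
      ps_warn(sprintf("alpha = %g rad outside the usual range [%g, %g]",
                      alpha, rng$alpha[1], rng$alpha[2]), "range_warning")
  }
  structure(list(mass = mass, leg_length = leg_length,
                 k_leg = k_leg, alpha = alpha),
            class = "slip_params")
}

#' Spring-damper coupling between the two walkers and the carried object
#'
#' Each walker's arms are modelled as a horizontal spring-damper of constant
#' impedance between the walker's CoM and the near end of a rigid carried
#' object. Only horizontal arm forces act on the gait; vertical interaction
#' forces are neglected.
#'
#' Because the arms always start at their equilibrium lengths, the specific
#' values of `L01`/`L02` do not affect the dynamics; only deviations
#' (L - L0) enter the equations of motion.
#'
#' @param k1,k2 arm spring stiffness for the rear (1) and front (2) walker
#'   (N/m).
#' @param b1,b2 arm damping coefficients (N s/m).
#' @param L01,L02 equilibrium arm lengths (m).
#' @param m_object mass of the carried object (kg). Default 7.5 kg, the value
#'   used for the model study (the experimental object weighed 8 kg).
#' @param L_object total length of the carried object (m). Default 2 m
#'   (experimental object: 1.5 m).
#' @return an object of class `coupling_params`.
#' @export
coupling_params <- function(k1, k2 = k1, b1 = 0, b2 = b1,
                            L01 = 0.5, L02 = 0.5,
                            m_object = 7.5, L_object = 2) {
  if (k1 < 0 || k2 < 0 || b1 < 0 || b2 < 0)
    ps_abort("arm stiffness and damping must be >= 0", "parameter_error")
  if (m_object <= 0 || L_object <= 0)
    ps_abort("object mass and length must be positive", "parameter_error")
  structure(list(k1 = k1, k2 = k2, b1 = b1, b2 = b2,
                 L01 = L01, L02 = L02,
                 m_object = m_object, L_object = L_object),
            class = "coupling_params")
}

#' Initial apex conditions of one pendulum
#'
#' The state of a SLIP at apex (maximal CoM height, vertical velocity zero)
#' is fixed by the energy `E0` and the apex position. `x_apex` is horizontal
#' position relative to the stance foot. `z_apex` is the apex height above a
#' reference height at which the leg spring is at its rest length:
#' \describe{
#'   \item{`"touchdown"` (default)}{the height `l0 sin(alpha)` at which
#'     touchdown occurs, where the landing leg is exactly at rest length.
#'     With the reference apex conditions (2.5 cm, 810-840 J, 80 kg, 1 m
#'     legs) this yields walking-speed initial velocities of 0.95-1.33 m/s
#'     and the documented periodic gaits; it is the reading under which
#'     every tabulated energy is feasible.}
#'   \item{`"rest_length"`}{the standing height `l0` (CoM atop a vertical
#'     rest-length leg). Provided for comparison; at the reference energies
#'     this leaves almost no kinetic energy and no sustained gait exists.}
#' }
#'
#' @param E0 total mechanical energy of the pendulum (J).
#' @param x_apex horizontal CoM position at apex relative to the stance
#'   foot (m).
#' @param z_apex vertical apex height relative to the chosen reference (m).
#' @param reference `"touchdown"` or `"rest_length"` (see above).
#' @return an object of class `slip_init`.
#' @export
slip_init <- function(E0, x_apex = 0, z_apex = 0.025,
                      reference = c("touchdown", "rest_length")) {
  stopifnot(is.numeric(E0), is.numeric(x_apex), is.numeric(z_apex))
  reference <- match.arg(reference)
  structure(list(E0 = E0, x_apex = x_apex, z_apex = z_apex,
                 reference = reference),
            class = "slip_init")
}

#' Full state of one pendulum at apex from its energy
#'
#' Solves the energy balance
#' `E0 = m g z + 1/2 k_leg (L - l0)^2 + 1/2 m vx^2` for the forward velocity,
#' with `L = sqrt(x_apex^2 + z^2)` and zero vertical velocity; the absolute
#' apex height `z` is `z_apex` above the chosen reference height (see
#' [slip_init()]). The support state at apex is single support just after
#' the apex (gamma = 1, beta = 0).
#'
#' @param params a [slip_params()] object.
#' @param E0 total mechanical energy (J).
#' @param x_apex,z_apex apex position, as in [slip_init()].
#' @param reference apex-height reference, as in [slip_init()].
#' @return list with `x`, `z` (m, relative to the stance foot), `vx`, `vz`
#'   (m/s), `gamma`, `beta`.
#' @export
initial_state_from_energy <- function(params, E0, x_apex = 0, z_apex = 0.025,
                                      reference = c("touchdown",
                                                    "rest_length")) {
  stopifnot(inherits(params, "slip_params"))
  reference <- match.arg(reference)
  z0 <- if (reference == "touchdown")
    params$leg_length * sin(params$alpha) else params$leg_length
  z <- z0 + z_apex
  L <- sqrt(x_apex^2 + z^2)
  spring <- 0.5 * params$k_leg * (L - params$leg_length)^2
  kinetic <- E0 - params$mass * PS_GRAVITY * z - spring
  if (kinetic < -1e-12)
    ps_abort(sprintf(
      "E0 = %g J is too small: potential + spring energy exceed it by %g J",
      E0, -kinetic), "energy_error")
  vx <- sqrt(max(2 * kinetic / params$mass, 0))
  list(x = x_apex, z = z, vx = vx, vz = 0, gamma = 1, beta = 0)
}

# Horizontal and vertical leg-spring force acting on one pendulum's CoM.
# mode: 1 = single support after apex (gamma=1,beta=0), 2 = double support,
# 3 = single support before apex (gamma=0,beta=1).
# Returns c(Fx, Fz) excluding gravity. With `strict_signs` the printed
# "-Q z beta" vertical term is used instead of the physically consistent
# "+Q z beta" (see the package vignette).
ps_leg_force <- function(X, Z, fb, ff, mode, k, l0, strict_signs = FALSE) {
  Fx <- 0
  Fz <- 0
  if (mode <= 2L) {
    xb <- X - fb
    Lb <- sqrt(xb * xb + Z * Z)
    P <- k * (l0 / Lb - 1)
    Fx <- Fx + P * xb
    Fz <- Fz + P * Z
  }
  if (mode >= 2L) {
    xf <- ff - X
    Lf <- sqrt(xf * xf + Z * Z)
    Q <- k * (l0 / Lf - 1)
    Fx <- Fx - Q * xf
    Fz <- Fz + (if (strict_signs) -1 else 1) * Q * Z
  }
  c(Fx, Fz)
}

# Arm forces applied by each pendulum to the object.
# Positive forces push the object forward.
ps_arm_forces <- function(X1, V1, X2, V2, XT, VT, cp) {
  half <- cp$L_object / 2
  L1 <- (XT - half) - X1
  L2 <- X2 - (XT + half)
  F1t <- -cp$k1 * (L1 - cp$L01) - cp$b1 * (VT - V1)
  F2t <- cp$k2 * (L2 - cp$L02) + cp$b2 * (V2 - VT)
  c(F1t = F1t, F2t = F2t, L1 = L1, L2 = L2)
}

#' Time derivatives of the paired-SLIP state
#'
#' Evaluates the equations of motion of the coupled system for a given
#' continuous state and support state. Intended for inspection and testing;
#' the integrator uses the same force terms internally.
#'
#' @param state named list/vector with absolute positions and velocities:
#'   `x1, z1, vx1, vz1`, optionally `x2, z2, vx2, vz2, xt, vxt` (object
#'   position absolute).
#' @param support list with per-pendulum `mode` (1 = single support after
#'   apex, 2 = double support, 3 = single support before apex), `fb`
#'   (back/stance foot position) and `ff` (front foot position, `NA` unless
#'   in double or leading single support).
#' @param p1,p2 [slip_params()] for each pendulum (`p2 = NULL` for a solo
#'   walker).
#' @param coupling a [coupling_params()] object, or `NULL` for mechanically
#'   uncoupled pendulums (all arm forces identically zero).
#' @param strict_signs use the printed-sign variant of the front-leg
#'   vertical force term (see vignette).
#' @return named list of derivatives, plus arm forces `F1t`, `F2t` when
#'   coupled.
#' @export
paired_derivatives <- function(state, support, p1, p2 = NULL, coupling = NULL,
                               strict_signs = FALSE) {
  g <- PS_GRAVITY
  getv <- function(n) as.numeric(state[[n]])
  x1 <- getv("x1"); z1 <- getv("z1"); vx1 <- getv("vx1"); vz1 <- getv("vz1")
  if (z1 <= 0) ps_abort("z1 must be positive", "parameter_error")
  chk_len <- function(X, Z, fb, ff, mode) {
    if (mode <= 2L && sqrt((X - fb)^2 + Z^2) < 1e-12)
      ps_abort("leg length is zero", "singularity_error")
    if (mode >= 2L && sqrt((ff - X)^2 + Z^2) < 1e-12)
      ps_abort("leg length is zero", "singularity_error")
  }
  chk_len(x1, z1, support$fb[1], support$ff[1], support$mode[1])
  f1 <- ps_leg_force(x1, z1, support$fb[1], support$ff[1], support$mode[1],
                     p1$k_leg, p1$leg_length, strict_signs)
  if (is.null(p2)) {
    return(list(dx1 = vx1, dz1 = vz1,
                dvx1 = f1[1] / p1$mass, dvz1 = f1[2] / p1$mass - g))
  }
  x2 <- getv("x2"); z2 <- getv("z2"); vx2 <- getv("vx2"); vz2 <- getv("vz2")
  chk_len(x2, z2, support$fb[2], support$ff[2], support$mode[2])
  f2 <- ps_leg_force(x2, z2, support$fb[2], support$ff[2], support$mode[2],
                     p2$k_leg, p2$leg_length, strict_signs)
  if (is.null(coupling)) {
    return(list(dx1 = vx1, dz1 = vz1,
                dvx1 = f1[1] / p1$mass, dvz1 = f1[2] / p1$mass - g,
                dx2 = vx2, dz2 = vz2,
                dvx2 = f2[1] / p2$mass, dvz2 = f2[2] / p2$mass - g,
                F1t = 0, F2t = 0))
  }
  xt <- getv("xt"); vxt <- getv("vxt")
  af <- ps_arm_forces(x1, vx1, x2, vx2, xt, vxt, coupling)
  list(dx1 = vx1, dz1 = vz1,
       dvx1 = (f1[1] - af[["F1t"]]) / p1$mass,
       dvz1 = f1[2] / p1$mass - g,
       dx2 = vx2, dz2 = vz2,
       dvx2 = (f2[1] - af[["F2t"]]) / p2$mass,
       dvz2 = f2[2] / p2$mass - g,
       dxt = vxt,
       dvxt = (af[["F1t"]] + af[["F2t"]]) / coupling$m_object,
       F1t = af[["F1t"]], F2t = af[["F2t"]])
}
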