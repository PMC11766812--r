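## Bead transport: point-dipole magnetic force, rectangular-duct flow, and
## overdamped capture / retention on the magnetized wire.
##
## Dynamics are inertialess: a 3-um bead in water has a microsecond momentum
## relaxation time, so bead velocity = fluid velocity + mobility * force,
## with Stokes mobility 1 / (6 pi eta R).

#' Microfluidic channel geometry
#'
#' Rectangular duct with the microwire strung along the symmetry axis.
#'
#' @param width duct width, um.
#' @param height duct height, um.
#' @param length duct length, cm.
#' @param n_channels number of parallel channels on the device.
#' @param wire a [microwire()] on the channel axis.
#' @return object of class `channel_geometry`.
#' @export
channel_geometry <- function(width = 400, height = 600, length = 6,
                             n_channels = 5, wire = microwire()) {
  if (width <= 0 || height <= 0 || length <= 0)
    .stopf("channel dimensions must be > 0")
  if (wire$glass_outer_radius >= min(width, height) / 2)
    .stopf("wire does not fit in the channel cross-section")
  structure(list(width = width, height = height, length = length,
                 n_channels = n_channels, wire = wire),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %g um x %g um x %g cm, %d channels, wire d = %g um\n",
              x$width, x$height, x$length, x$n_channels,
              2 * x$wire$glass_outer_radius))
  invisible(x)
}

#' Volumetric flow description
#'
#' @param volumetric_rate flow rate, uL/min.
#' @param profile_kind `"duct"` (no-slip rectangular-duct series solution) or
#'   `"plug"` (uniform).
#' @param series_terms number of odd Fourier terms in the duct series.
#' @return object of class `flow_field`.
#' @export
flow_field <- function(volumetric_rate, profile_kind = c("duct", "plug"),
                       series_terms = 25) {
  if (volumetric_rate < 0) .stopf("volumetric_rate must be >= 0")
  structure(list(volumetric_rate = volumetric_rate,
                 profile_kind = match.arg(profile_kind),
                 series_terms = series_terms),
            class = "flow_field")
}

## unnormalized duct profile and its exact cross-section integral.
## Coordinates x across the width w, z across the height h, centered; SI (m).
.duct_profile_raw <- function(x, z, w, h, nterms) {
  u <- numeric(length(x))
  for (n in seq(1, 2 * nterms - 1, by = 2)) {
    u <- u + (-1)^((n - 1) / 2) / n^3 *
      (1 - cosh(n * pi * x / h) / cosh(n * pi * w / (2 * h))) *
      cos(n * pi * z / h)
  }
  u
}

.duct_integral_raw <- function(w, h, nterms) {
  s <- 0
  for (n in seq(1, 2 * nterms - 1, by = 2)) {
    s <- s + 1 / n^3 * (2 * h / (n * pi)) *
      (w - (2 * h / (n * pi)) * tanh(n * pi * w / (2 * h)))
  }
  s
}

#' Axial velocity in the rectangular duct
#'
#' No-slip pressure-driven profile (truncated double-odd Fourier series),
#' scaled so that its exact cross-sectional integral equals the volumetric
#' rate. The wire's perturbation of the duct flow is ignored (documented
#' fidelity limit).
#'
#' @param flow a [flow_field()].
#' @param channel a [channel_geometry()].
#' @param x,z cross-section coordinates, um, origin on the channel axis
#'   (x across the width, z across the height); vectorized.
#' @return axial velocity, um/s.
#' @export
duct_velocity <- function(flow, channel, x, z) {
  .check_finite(c(x, z), "cross-section point")
  w <- channel$width * 1e-6; h <- channel$height * 1e-6
  xm <- x * 1e-6; zm <- z * 1e-6
  if (any(abs(xm) > w / 2 + 1e-15) || any(abs(zm) > h / 2 + 1e-15))
    .stopf("point outside the duct cross-section")
  Q <- flow$volumetric_rate * 1e-9 / 60            # uL/min -> m^3/s
  if (flow$profile_kind == "plug") return(rep(Q / (w * h) * 1e6, length(xm)))
  u <- .duct_profile_raw(xm, zm, w, h, flow$series_terms)
  scale <- Q / .duct_integral_raw(w, h, flow$series_terms)
  u * scale * 1e6                                   # m/s -> um/s
}

#' Magnetic force on a bead
#'
#' Point-dipole force `F = mu0 m(|H|) grad|H|`, directed along the gradient
#' of the field magnitude (radially toward the wire in the wire-dominated
#' region).
#'
#' @param bead a [bead_model()].
#' @param field a [field_sample()] carrying a gradient.
#' @param policy moment policy, see [bead_moment()].
#' @return force 3-vector, N.
#' @export
magnetic_force <- function(bead, field, policy = "operating-point") {
  if (is.null(field$grad_H_magnitude))
    .stopf("field sample carries no gradient")
  m <- bead_moment(bead, field$H_magnitude, policy = policy)
  MU0 * m * field$grad_H_magnitude
}

## wire-dominated radial bead speed (um/s) at radius r_um from the wire axis;
## H_app is the (locally uniform) applicator magnitude at the wire.
.radial_speed <- function(r_um, bead, wire_M, core_radius_um, H_app, eta) {
  a <- core_radius_um * 1e-6; r <- r_um * 1e-6
  h_loc <- wire_M * a^2 / (2 * r^2)
  m <- bead_moment(bead, H_app + h_loc)
  grad <- wire_M * a^2 / r^3
  Fr <- MU0 * m * grad
  Rb <- bead$diameter / 2 * 1e-6
  Fr / (6 * pi * eta * Rb) * 1e6
}

#' Simulate bead capture in channel flow
#'
#' Integrates overdamped bead trajectories `dx/dt = v_fluid + F_mag /
#' (6 pi eta R)` around the magnetized wire until each bead either contacts
#' the capture envelope (glass radius + bead radius) or leaves the channel.
#' The magnetic actuation uses the wire-dominated landscape: the applicator
#' supplies a locally uniform bias field that sets the wire and bead
#' operating points, while the force gradient is the wire's analytic
#' dipole-line gradient (the applicator gradient is two to three orders of
#' magnitude smaller). The time step adapts to the local radial speed so the
#' trajectory never crosses the wire envelope.
#'
#' @param positions n x 3 matrix of initial bead positions, um: columns
#'   `x` (across width), `z` (across height), `y` (axial, 0 at inlet); see
#'   [gen_bead_positions()].
#' @param flow a [flow_field()].
#' @param channel a [channel_geometry()].
#' @param bead a [bead_model()].
#' @param assembly an [applicator_assembly()] or `NULL` for no applied field
#'   (unmagnetized wire: no capture beyond geometric interception).
#' @param duration simulated time, s.
#' @param step far-field maximum time step, s.
#' @param eta dynamic viscosity, Pa s.
#' @param wire_x channel position on the device x axis, mm (sets the local
#'   applicator field).
#' @return list with `fraction` (captured fraction), `fates` (data frame:
#'   initial position, fate `"captured"`/`"lost"`/`"suspended"`, event time,
#'   final radius) and the operating magnetizations used.
#' @export
simulate_capture <- function(positions, flow, channel, bead = bead_model(),
                             assembly = applicator_assembly(),
                             duration = 10, step = 1e-3, eta = 1e-3,
                             wire_x = 0) {
  if (step <= 0) .stopf("step must be > 0")
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) .stopf("positions must be an n x 3 matrix")
  wire <- channel$wire
  H_app <- if (is.null(assembly)) 0 else
    applicator_field(assembly, c(wire_x, 0, 0))$H_magnitude
  wire_M <- wire_operating_magnetization(wire, H_app)
  r_cap <- wire$glass_outer_radius + bead$diameter / 2
  L_um <- channel$length * 1e4
  scale_u <- NULL
  w <- channel$width * 1e-6; h <- channel$height * 1e-6
  Q <- flow$volumetric_rate * 1e-9 / 60
  if (flow$profile_kind == "duct" && Q > 0)
    scale_u <- Q / .duct_integral_raw(w, h, flow$series_terms) * 1e6
  n <- nrow(positions)
  fate <- rep("suspended", n); t_event <- rep(NA_real_, n)
  r_final <- numeric(n)
  for (i in seq_len(n)) {
    x <- positions[i, 1]; z <- positions[i, 2]; y <- positions[i, 3]
    t <- 0
    repeat {
      r <- sqrt(x^2 + z^2)
      if (r <= r_cap + 1e-9) { fate[i] <- "captured"; t_event[i] <- t; break }
      if (y > L_um)          { fate[i] <- "lost";     t_event[i] <- t; break }
      if (t >= duration) break
      vr <- if (wire_M > 0)
        .radial_speed(r, bead, wire_M, wire$core_radius, H_app, eta) else 0
      u <- if (Q <= 0) 0
           else if (flow$profile_kind == "plug") Q / (w * h) * 1e6
           else .duct_profile_raw(x * 1e-6, z * 1e-6, w, h,
                                  flow$series_terms) * scale_u
      ## adaptive step: at most 20% of the remaining radial distance per step
      dt <- step
      if (vr > 0) dt <- min(dt, 0.2 * (r - r_cap) / vr)
      dt <- min(dt, duration - t)
      dt <- max(dt, 1e-9)
      if (r > 0 && vr > 0) {
        dr <- min(vr * dt, r - r_cap)
        x <- x * (1 - dr / r); z <- z * (1 - dr / r)
      }
      y <- y + u * dt
      t <- t + dt
    }
    r_final[i] <- sqrt(x^2 + z^2)
  }
  list(fraction = mean(fate == "captured"),
       fates = data.frame(x0 = positions[, 1], z0 = positions[, 2],
                          y0 = positions[, 3], fate = fate,
                          t_event = t_event, r_final = r_final),
       wire_M = wire_M, H_applicator = H_app)
}

#' Retention of a captured bead under wash flow
#'
#' A bead sitting on the wire envelope is retained when the Stokes drag from
#' the local axial velocity (evaluated one bead radius off the wire surface,
#' on the widthwise side of the wire where the unperturbed duct flow is
#' fastest) is smaller than the magnetic holding force at contact. An
#' optional friction coefficient scales the holding force.
#'
#' @param flow a [flow_field()].
#' @param channel a [channel_geometry()].
#' @param bead a [bead_model()].
#' @param assembly an [applicator_assembly()] or `NULL`.
#' @param eta viscosity, Pa s.
#' @param friction optional multiplier on the holding force (default 1:
#'   direct drag-vs-holding comparison).
#' @param wire_x channel x position, mm.
#' @return list with `retained` flag, `drag_N` and `holding_N`.
#' @export
retention_check <- function(flow, channel, bead = bead_model(),
                            assembly = applicator_assembly(), eta = 1e-3,
                            friction = 1, wire_x = 0) {
  wire <- channel$wire
  H_app <- if (is.null(assembly)) 0 else
    applicator_field(assembly, c(wire_x, 0, 0))$H_magnitude
  wire_M <- wire_operating_magnetization(wire, H_app)
  r_cap <- wire$glass_outer_radius + bead$diameter / 2
  Rb <- bead$diameter / 2
  u <- duct_velocity(flow, channel, r_cap + Rb, 0) * 1e-6   # m/s
  drag <- 6 * pi * eta * (Rb * 1e-6) * u
  holding <- if (wire_M > 0) {
    a <- wire$core_radius * 1e-6; r <- r_cap * 1e-6
    h_loc <- wire_M * a^2 / (2 * r^2)
    MU0 * bead_moment(bead, H_app + h_loc) * wire_M * a^2 / r^3
  } else 0
  list(retained = drag < friction * holding, drag_N = drag,
       holding_N = holding)
}

#' Channel liquid capacity
#'
#' Duct volume minus the wire envelope.
#'
#' @param channel a [channel_geometry()].
#' @param subtract_wire subtract the wire envelope volume (default `TRUE`).
#' @return volume, uL.
#' @export
channel_volume <- function(channel, subtract_wire = TRUE) {
  L <- channel$length * 1e-2                       # m
  duct <- channel$width * 1e-6 * channel$height * 1e-6 * L
  wirev <- if (subtract_wire)
    pi * (channel$wire$glass_outer_radius * 1e-6)^2 * L else 0
  (duct - wirev) * 1e9                              # m^3 -> uL
}

#' Export a capture curve (flow rate vs captured fraction)
#'
#' @param rates flow rates, uL/min.
#' @param fractions captured fractions.
#' @param path output CSV path.
#' @export
write_capture_curve <- function(rates, fractions, path) {
  utils::write.csv(data.frame(Q_uL_per_min = rates, captured_fraction = fractions),
                   path, row.names = FALSE)
  invisible(path)
}
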