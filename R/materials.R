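## Magnetization models: soft microwire core and superparamagnetic beads.
## Hysteresis is ignored throughout (soft core, superparamagnetic beads):
## M(H) is single-valued, monotone, clamped at saturation.

#' Monotone magnetization curve
#'
#' Ordered (H, M) samples with piecewise-linear interpolation and a hard
#' clamp at saturation. Units A/m on both axes.
#'
#' @param H,M sample vectors, A/m; must be non-decreasing in both.
#' @param saturation_M saturation magnetization, default `max(M)`.
#' @param saturation_H field at which saturation is reached, default `max(H)`.
#' @return object of class `magnetization_curve`.
#' @export
magnetization_curve <- function(H, M, saturation_M = max(M),
                                saturation_H = max(H)) {
  if (length(H) == 0L) .stopf("empty magnetization curve")
  .check_finite(H, "H"); .check_finite(M, "M")
  if (length(H) != length(M)) .stopf("H and M must have equal length")
  o <- order(H); H <- H[o]; M <- M[o]
  if (any(diff(M) < 0)) .stopf("M must be non-decreasing in H")
  if (any(M < 0)) .stopf("M must be >= 0")
  if (any(M > saturation_M + 1e-9 * saturation_M))
    .stopf("curve samples exceed saturation_M")
  structure(list(samples = data.frame(H = H, M = M),
                 saturation_M = saturation_M, saturation_H = saturation_H),
            class = "magnetization_curve")
}

#' @export
print.magnetization_curve <- function(x, ...) {
  cat(sprintf("<magnetization_curve> %d knots, Msat = %.4g kA/m at H >= %.4g kA/m\n",
              nrow(x$samples), x$saturation_M / 1e3, x$saturation_H / 1e3))
  invisible(x)
}

#' Evaluate a magnetization curve
#'
#' Piecewise-linear interpolation clamped at the saturation magnetization for
#' fields at or beyond `saturation_H`. Exactly reproduces tabulated knots.
#'
#' @param curve a [magnetization_curve()].
#' @param H applied field(s), A/m, >= 0.
#' @return magnetization, A/m (vectorized).
#' @export
magnetization_at <- function(curve, H) {
  .check_finite(H, "H")
  if (any(H < 0)) .stopf("H must be >= 0")
  s <- curve$samples
  M <- if (nrow(s) == 1L) rep(s$M, length(H))
       else stats::approx(s$H, s$M, xout = pmin(H, max(s$H)), rule = 2)$y
  M[H >= curve$saturation_H] <- curve$saturation_M
  pmin(M, curve$saturation_M)
}

#' Default transverse magnetization curve of the microwire
#'
#' Piecewise-linear through the published anchors of the soft FeCuNbSiB core:
#' origin, the applicator operating point (106 kA/m, 524 kA/m) -- about 55%
#' of saturation -- and perpendicular saturation (300 kA/m, 954 kA/m).
#' Measured curves can be supplied instead via [magnetization_curve()].
#'
#' @return a [magnetization_curve()].
#' @export
default_wire_curve <- function() {
  magnetization_curve(H = c(0, 106e3, 300e3), M = c(0, 524e3, 954e3))
}

#' Glass-coated soft magnetic microwire
#'
#' @param core_radius metallic core radius, um (core diameter 25 um).
#' @param glass_outer_radius outer radius including the glass shell, um
#'   (total diameter 55 um).
#' @param saturation_M core saturation magnetization, A/m.
#' @param transverse_curve perpendicular-direction [magnetization_curve()].
#' @return object of class `microwire`.
#' @export
microwire <- function(core_radius = 12.5, glass_outer_radius = 27.5,
                      saturation_M = 954e3,
                      transverse_curve = default_wire_curve()) {
  if (!(glass_outer_radius > core_radius && core_radius > 0))
    .stopf("need glass_outer_radius > core_radius > 0")
  if (saturation_M <= 0) .stopf("saturation_M must be > 0")
  structure(list(core_radius = core_radius,
                 glass_outer_radius = glass_outer_radius,
                 saturation_M = saturation_M,
                 transverse_curve = transverse_curve),
            class = "microwire")
}

#' @export
print.microwire <- function(x, ...) {
  cat(sprintf("<microwire> core d = %g um, total d = %g um, Msat = %g kA/m\n",
              2 * x$core_radius, 2 * x$glass_outer_radius, x$saturation_M / 1e3))
  invisible(x)
}

#' Operating transverse magnetization of the wire
#'
#' Magnetization reached by the wire core when the applicator applies
#' `H_applied` across it. With the default curve the applicator operating
#' point H = 106 kA/m yields 524 kA/m (about 55% of the 954 kA/m saturation).
#'
#' @param wire a [microwire()].
#' @param H_applied applied transverse field, A/m.
#' @return magnetization, A/m.
#' @export
wire_operating_magnetization <- function(wire, H_applied) {
  M <- magnetization_at(wire$transverse_curve, H_applied)
  pmin(M, wire$saturation_M)
}

## Default bead saturation, back-calibrated so that a bead at 80% of
## saturation in the wire-surface gradient of the default landscape feels the
## design holding force F0 = 13 nN:
##   F0 = mu0 * (0.8 Msat_bead * V_bead) * M_H0 a^2 / r_w^3
.bead_default_saturation <- function(diameter = 3, force = 13e-9,
                                     operating_fraction = 0.8,
                                     wire_M = 524e3, core_radius = 12.5,
                                     glass_radius = 27.5) {
  V <- pi * (diameter * 1e-6)^3 / 6
  grad <- wire_M * (core_radius * 1e-6)^2 / (glass_radius * 1e-6)^3
  force / (operating_fraction * MU0 * V * grad)
}

#' Default bead magnetization curve
#'
#' Piecewise-linear: origin, the wire-surface operating point (160 kA/m --
#' the applicator field plus the wire's own surface contribution -- at 80% of
#' saturation, as the measured bead curve suggests), and saturation at
#' 400 kA/m.
#'
#' @param saturation_M bead saturation magnetization, A/m.
#' @param operating_fraction fraction of saturation reached at the wire
#'   surface field.
#' @return a [magnetization_curve()].
#' @export
default_bead_curve <- function(saturation_M = .bead_default_saturation(),
                               operating_fraction = 0.8) {
  magnetization_curve(H = c(0, 160e3, 400e3),
                      M = c(0, operating_fraction, 1) * saturation_M)
}

#' Superparamagnetic bead model
#'
#' 3-um porous-polymer beads loaded with iron-oxide nanoparticles. The
#' default saturation magnetization is back-calibrated so that a bead at 80%
#' of saturation in the default wire-surface gradient feels the design
#' holding force of 13 nN; it is documented as larger than typical vendor
#' figures for such beads (see the methods vignette).
#'
#' @param diameter bead diameter, um.
#' @param saturation_M saturation magnetization, A/m.
#' @param operating_fraction fraction of saturation assumed reached at the
#'   operating point (default 0.8).
#' @param curve a [magnetization_curve()].
#' @return object of class `bead_model`.
#' @export
bead_model <- function(diameter = 3,
                       saturation_M = .bead_default_saturation(),
                       operating_fraction = 0.8,
                       curve = default_bead_curve(saturation_M,
                                                  operating_fraction)) {
  if (diameter <= 0) .stopf("diameter must be > 0")
  if (!(operating_fraction > 0 && operating_fraction <= 1))
    .stopf("operating_fraction must be in (0, 1]")
  structure(list(diameter = diameter, saturation_M = saturation_M,
                 operating_fraction = operating_fraction, curve = curve),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("<bead_model> d = %g um, Msat = %.4g kA/m, operating fraction %.2f\n",
              x$diameter, x$saturation_M / 1e3, x$operating_fraction))
  invisible(x)
}

#' Magnetic moment of a bead
#'
#' Point-dipole moment `m = V * M_eff`. Under the default "operating-point"
#' policy the effective magnetization is capped at
#' `operating_fraction * saturation_M` (the bead is assumed to sit at its
#' operating point when the local field is at or above the wire-surface
#' value); the "curve" policy uses the magnetization curve alone.
#'
#' @param bead a [bead_model()].
#' @param H_local local field magnitude, A/m.
#' @param policy `"operating-point"` or `"curve"`.
#' @return magnetic moment, A m^2.
#' @export
bead_moment <- function(bead, H_local,
                        policy = c("operating-point", "curve")) {
  policy <- match.arg(policy)
  V <- pi * (bead$diameter * 1e-6)^3 / 6
  M <- magnetization_at(bead$curve, H_local)
  if (policy == "operating-point")
    M <- pmin(M, bead$operating_fraction * bead$saturation_M)
  V * M
}

#' Read / write magnetization curves as two-column text
#'
#' Plain two-column tables `H_kA_per_m, M_kA_per_m` (header included).
#'
#' @param path file path.
#' @return for the reader, a [magnetization_curve()].
#' @export
read_magnetization_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("H_kA_per_m", "M_kA_per_m") %in% names(df)))
    .stopf("curve file must have columns H_kA_per_m, M_kA_per_m")
  magnetization_curve(df$H_kA_per_m * 1e3, df$M_kA_per_m * 1e3)
}

#' @rdname read_magnetization_curve
#' @param curve a [magnetization_curve()].
#' @export
write_magnetization_curve <- function(curve, path) {
  utils::write.csv(data.frame(H_kA_per_m = curve$samples$H / 1e3,
                              M_kA_per_m = curve$samples$M / 1e3),
                   path, row.names = FALSE)
  invisible(path)
}
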