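## Magnetostatics of the field applicator and the microwire.
##
## Conventions: positions in mm, H fields in A/m, gradients of |H| in A/m^2.
## The coordinate origin sits at the center of the midplane between the two
## applicator magnets; x runs across the device (channels at 0, +-5, +-10 mm),
## y along the channels, z along the magnetization (through-thickness) axis.

#' Cuboid permanent magnet
#'
#' A uniformly magnetized block magnet, magnetized through its thickness
#' (the z dimension). The external field is the exact charge-sheet solution
#' for a uniformly magnetized prism.
#'
#' @param length_x,length_y,thickness_z block dimensions in mm; magnetization
#'   lies along the thickness.
#' @param remanence remanent induction Br in tesla; the equivalent
#'   magnetization is `Br / mu0`.
#' @param center_position 3-vector, mm.
#' @param magnetization_axis unit 3-vector; must be `c(0, 0, 1)` or
#'   `c(0, 0, -1)` (blocks are axis-aligned, thickness along z).
#' @return object of class `cuboid_magnet`.
#' @export
cuboid_magnet <- function(length_x = 38.1, length_y = 76.2, thickness_z = 6.35,
                          remanence = 1.3, center_position = c(0, 0, 0),
                          magnetization_axis = c(0, 0, 1)) {
  .check_finite(c(length_x, length_y, thickness_z, remanence), "magnet geometry")
  if (length_x <= 0 || length_y <= 0 || thickness_z <= 0)
    .stopf("all magnet dimensions must be > 0")
  if (remanence <= 0) .stopf("remanence must be > 0")
  .check_finite(center_position, "center_position")
  if (length(center_position) != 3L) .stopf("center_position must be a 3-vector")
  axis <- as.numeric(magnetization_axis)
  if (length(axis) != 3L || abs(sqrt(sum(axis^2)) - 1) > 1e-9)
    .stopf("magnetization_axis must have unit norm")
  if (abs(axis[1]) > 1e-12 || abs(axis[2]) > 1e-12)
    .stopf("magnetization_axis must be +z or -z (axis-aligned blocks)")
  structure(list(length_x = length_x, length_y = length_y,
                 thickness_z = thickness_z, remanence = remanence,
                 center_position = as.numeric(center_position),
                 magnetization_axis = axis),
            class = "cuboid_magnet")
}

#' @export
print.cuboid_magnet <- function(x, ...) {
  cat(sprintf("<cuboid_magnet> %.1f x %.1f x %.2f mm, Br = %.2f T, center (%g, %g, %g) mm, M along %+dz\n",
              x$length_x, x$length_y, x$thickness_z, x$remanence,
              x$center_position[1], x$center_position[2], x$center_position[3],
              as.integer(sign(x$magnetization_axis[3]))))
  invisible(x)
}

#' Field sample
#'
#' Carrier for a field evaluation: position (mm), H vector (A/m), magnitude,
#' and the gradient of |H| (A/m^2) when available.
#'
#' @param position 3-vector, mm.
#' @param H 3-vector, A/m.
#' @param grad_H 3-vector gradient of |H| in A/m^2, or `NULL`.
#' @param interior `TRUE` if evaluated inside a source body.
#' @return object of class `field_sample` with elements `position`,
#'   `H_vector`, `H_magnitude`, `grad_H_magnitude`, `interior`.
#' @export
field_sample <- function(position, H, grad_H = NULL, interior = FALSE) {
  .check_finite(H, "H")
  structure(list(position = as.numeric(position), H_vector = as.numeric(H),
                 H_magnitude = sqrt(sum(H^2)),
                 grad_H_magnitude = if (is.null(grad_H)) NULL else as.numeric(grad_H),
                 interior = isTRUE(interior)),
            class = "field_sample")
}

#' @export
print.field_sample <- function(x, ...) {
  cat(sprintf("<field_sample> |H| = %.4g kA/m at (%g, %g, %g) mm%s\n",
              x$H_magnitude / 1e3, x$position[1], x$position[2], x$position[3],
              if (x$interior) " [interior]" else ""))
  invisible(x)
}

## charge-sheet H of a unit cuboid centered at origin, magnetization M along
## +z; x, y, z in meters (vectorized over points)
.cuboid_H_raw <- function(x, y, z, Lx, Ly, Lz, M) {
  Hx <- Hy <- Hz <- numeric(length(x))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    sgn <- (-1)^(i + j + k)
    xi  <- x + (-1)^i * Lx / 2
    eta <- y + (-1)^j * Ly / 2
    zet <- z + (-1)^k * Lz / 2
    r <- sqrt(xi^2 + eta^2 + zet^2)
    Hx <- Hx + sgn * log(eta + r)
    Hy <- Hy + sgn * log(xi + r)
    Hz <- Hz - sgn * atan2(xi * eta, zet * r)
  }
  cbind(Hx, Hy, Hz) * M / (4 * pi)
}

.inside_cuboid <- function(magnet, point) {
  d <- abs(point - magnet$center_position)
  all(d < c(magnet$length_x, magnet$length_y, magnet$thickness_z) / 2)
}

## H vector (A/m) of one magnet at points (n x 3 matrix, mm)
.cuboid_H_vec <- function(magnet, pts) {
  p <- (sweep(pts, 2, magnet$center_position)) * 1e-3
  M <- magnet$remanence / MU0 * magnet$magnetization_axis[3]
  .cuboid_H_raw(p[, 1], p[, 2], p[, 3],
                magnet$length_x * 1e-3, magnet$length_y * 1e-3,
                magnet$thickness_z * 1e-3, M)
}

## |H| of a list of magnets at points (mm matrix)
.magnets_H_mag <- function(magnets, pts) {
  H <- matrix(0, nrow(pts), 3)
  for (m in magnets) H <- H + .cuboid_H_vec(m, pts)
  sqrt(rowSums(H^2))
}

## central-difference gradient of |H| for a magnet list; step in mm
.magnets_gradH <- function(magnets, point, step = 0.01) {
  g <- numeric(3)
  for (d in 1:3) {
    e <- numeric(3); e[d] <- step
    pts <- rbind(point + e, point - e)
    h <- .magnets_H_mag(magnets, pts)
    g[d] <- (h[1] - h[2]) / (2 * step * 1e-3)
  }
  g
}

#' Field of a single cuboid magnet
#'
#' Exact analytic (charge-sheet) H field of a uniformly magnetized cuboid.
#' Outside the body the field is both curl- and divergence-free; interior
#' evaluations are permitted but flagged.
#'
#' @param magnet a [cuboid_magnet()].
#' @param point 3-vector, mm.
#' @param grad_step central-difference step for the gradient of |H|, mm.
#' @return a [field_sample()].
#' @export
cuboid_field <- function(magnet, point, grad_step = 0.01) {
  .check_finite(point, "point")
  if (length(point) != 3L) .stopf("point must be a 3-vector")
  point <- as.numeric(point)
  H <- .cuboid_H_vec(magnet, matrix(point, 1))[1, ]
  g <- .magnets_gradH(list(magnet), point, grad_step)
  field_sample(point, H, g, interior = .inside_cuboid(magnet, point))
}

#' Two-magnet field applicator
#'
#' Two identical block magnets facing each other across a gap, magnetized
#' along the same direction ("North-South-North-South"), so their fields add
#' in the gap. The microfluidic device sits in the midplane.
#'
#' @param magnet prototype [cuboid_magnet()]; both magnets share its
#'   dimensions and remanence.
#' @param gap face-to-face distance in mm.
#' @return object of class `applicator_assembly` with the two positioned
#'   magnets in `$magnet_pair`.
#' @export
applicator_assembly <- function(magnet = cuboid_magnet(), gap = 34) {
  if (!is.finite(gap) || gap <= 0) .stopf("gap must be > 0")
  zc <- gap / 2 + magnet$thickness_z / 2
  m1 <- magnet; m1$center_position <- c(0, 0, -zc)
  m2 <- magnet; m2$center_position <- c(0, 0, +zc)
  structure(list(magnet_pair = list(m1, m2), gap = gap,
                 configuration = "like-directed"),
            class = "applicator_assembly")
}

#' @export
print.applicator_assembly <- function(x, ...) {
  cat(sprintf("<applicator_assembly> gap %.1f mm, %s;\n  ", x$gap, x$configuration))
  print(x$magnet_pair[[1]])
  invisible(x)
}

#' Field of the applicator assembly
#'
#' Vector superposition of the two magnets' charge-sheet fields, with the
#' gradient of |H| by central differences (default step 10 um).
#'
#' @inheritParams cuboid_field
#' @param assembly an [applicator_assembly()].
#' @return a [field_sample()].
#' @export
applicator_field <- function(assembly, point, grad_step = 0.01) {
  .check_finite(point, "point")
  point <- as.numeric(point)
  pts <- matrix(point, 1)
  H <- .cuboid_H_vec(assembly$magnet_pair[[1]], pts)[1, ] +
       .cuboid_H_vec(assembly$magnet_pair[[2]], pts)[1, ]
  g <- .magnets_gradH(assembly$magnet_pair, point, grad_step)
  interior <- any(vapply(assembly$magnet_pair, .inside_cuboid, logical(1),
                         point = point))
  field_sample(point, H, g, interior = interior)
}

#' Dipole-line field of the transversely magnetized microwire
#'
#' External field of an infinite cylinder of radius `core_radius` uniformly
#' magnetized across its axis (2-D dipole): at radius r >= a and angle theta
#' from the magnetization direction,
#' `h_r = (M a^2 / (2 r^2)) cos(theta)`, `h_theta = (M a^2 / (2 r^2)) sin(theta)`,
#' so the magnitude `M a^2 / (2 r^2)` is independent of angle and decays as
#' the inverse square of r.
#'
#' @param wire_magnetization transverse magnetization M of the core, A/m.
#' @param core_radius metallic core radius a, um.
#' @param point_radius evaluation radius r >= a, um.
#' @param angle polar angle from the magnetization direction, rad.
#' @return a [field_sample()]; the position is `(r sin angle, 0, r cos angle)`
#'   in um with the wire axis along y and the magnetization along z, and the
#'   gradient of |h| is the analytic radial `-M a^2 / r^3`.
#' @export
wire_external_field <- function(wire_magnetization, core_radius, point_radius,
                                angle = 0) {
  .check_finite(c(wire_magnetization, core_radius, point_radius, angle),
                "wire field arguments")
  if (core_radius <= 0) .stopf("core_radius must be > 0")
  if (point_radius < core_radius)
    .stopf("point_radius < core_radius: interior of the wire (uniform field) is not covered by the dipole-line model")
  a <- core_radius * 1e-6; r <- point_radius * 1e-6
  amp <- wire_magnetization * a^2 / (2 * r^2)
  hr <- amp * cos(angle); ht <- amp * sin(angle)
  ## radial unit (sin t, 0, cos t), tangential (cos t, 0, -sin t); wire axis y
  rad <- c(sin(angle), 0, cos(angle))
  tan <- c(cos(angle), 0, -sin(angle))
  H <- hr * rad + ht * tan
  grad <- -(wire_magnetization * a^2 / r^3) * rad
  field_sample(position = point_radius * rad, H = H, grad_H = grad)
}

#' Total field: applicator plus magnetized wire
#'
#' Superposes the applicator field and the dipole-line field of a microwire
#' running along y at cross-section position `wire_x` (mm) in the midplane.
#' The wire's transverse magnetization is taken from its operating point in
#' the local applicator field (see [wire_operating_magnetization()]), unless
#' given explicitly. Near the glass surface the wire's field gradient exceeds
#' the applicator's by more than two orders of magnitude, so bead actuation
#' is wire-dominated.
#'
#' @param assembly an [applicator_assembly()].
#' @param wire a [microwire()].
#' @param point 3-vector, mm.
#' @param wire_x wire position on the x axis, mm.
#' @param wire_M transverse wire magnetization A/m; default: operating point
#'   in the local applicator field at the wire location.
#' @param grad_step step for the |H| gradient, mm; default 1e-4 mm (0.1 um)
#'   within ten wire radii of the wire, else 0.01 mm.
#' @return a [field_sample()].
#' @export
total_field <- function(assembly, wire, point, wire_x = 0, wire_M = NULL,
                        grad_step = NULL) {
  .check_finite(point, "point")
  point <- as.numeric(point)
  if (is.null(wire_M)) {
    happ <- applicator_field(assembly, c(wire_x, point[2], 0))
    wire_M <- wire_operating_magnetization(wire, happ$H_magnitude)
  }
  a_m <- wire$core_radius * 1e-6
  Hfun <- function(p) {                      # p in mm -> H vector A/m
    H <- .cuboid_H_vec(assembly$magnet_pair[[1]], matrix(p, 1))[1, ] +
         .cuboid_H_vec(assembly$magnet_pair[[2]], matrix(p, 1))[1, ]
    dx <- (p[1] - wire_x) * 1e-3; dz <- p[3] * 1e-3
    r2 <- dx^2 + dz^2
    if (r2 >= a_m^2 && wire_M != 0) {
      ## 2-D dipole with moment along +z: h = (M a^2 / (2 r^2)) *
      ##   (2 (m.rhat) rhat - m), rhat = (dx, dz)/r, m = +z
      amp <- wire_M * a_m^2 / (2 * r2)
      ct <- dz / sqrt(r2); st <- dx / sqrt(r2)
      H <- H + amp * c(2 * ct * st, 0, 2 * ct^2 - 1)
    }
    H
  }
  H <- Hfun(point)
  r_um <- sqrt((point[1] - wire_x)^2 + point[3]^2) * 1e3
  if (is.null(grad_step))
    grad_step <- if (r_um < 10 * wire$glass_outer_radius) 1e-4 else 0.01
  g <- numeric(3)
  for (d in 1:3) {
    e <- numeric(3); e[d] <- grad_step
    g[d] <- (sqrt(sum(Hfun(point + e)^2)) - sqrt(sum(Hfun(point - e)^2))) /
      (2 * grad_step * 1e-3)
  }
  field_sample(point, H, g)
}

#' Dipole-grid discretization of a cuboid magnet (numerical oracle)
#'
#' Brute-force check of the charge-sheet solution: the magnet is split into
#' `n^3` cells, each replaced by a point dipole at its center. Agrees with
#' [cuboid_field()] to better than 1% a couple of mm outside the body. Kept
#' as an independent cross-check, not as a production field engine.
#'
#' @param magnet a [cuboid_magnet()].
#' @param point 3-vector, mm.
#' @param n cells per edge; a scalar or a 3-vector `(nx, ny, nz)` (near-field
#'   accuracy wants near-cubic cells, so match the counts to the aspect
#'   ratio).
#' @return a [field_sample()] (no gradient).
#' @export
dipole_grid_field <- function(magnet, point, n = c(20, 40, 4)) {
  .check_finite(point, "point")
  point <- as.numeric(point)
  if (length(n) == 1L) n <- rep(n, 3)
  Lx <- magnet$length_x * 1e-3; Ly <- magnet$length_y * 1e-3
  Lz <- magnet$thickness_z * 1e-3
  cx <- ((seq_len(n[1]) - 0.5) / n[1] - 0.5) * Lx
  cy <- ((seq_len(n[2]) - 0.5) / n[2] - 0.5) * Ly
  cz <- ((seq_len(n[3]) - 0.5) / n[3] - 0.5) * Lz
  g <- expand.grid(x = cx, y = cy, z = cz)
  M <- magnet$remanence / MU0 * magnet$magnetization_axis[3]
  m_cell <- M * Lx * Ly * Lz / prod(n)
  p <- (point - magnet$center_position) * 1e-3
  rx <- p[1] - g$x; ry <- p[2] - g$y; rz <- p[3] - g$z
  r2 <- rx^2 + ry^2 + rz^2; r <- sqrt(r2)
  mdotr <- m_cell * rz
  H <- c(sum(3 * mdotr * rx / (r2 * r^3)),
         sum(3 * mdotr * ry / (r2 * r^3)),
         sum((3 * mdotr * rz / r2 - m_cell) / r^3)) / (4 * pi)
  field_sample(point, H, interior = .inside_cuboid(magnet, point))
}

#' Export a field map as tabular text
#'
#' Evaluates the applicator (optionally plus wire) on a set of points and
#' writes a whitespace-free CSV with columns
#' `x,y,z,Hx,Hy,Hz,H_mag,gradH_mag` (mm, A/m, A/m^2).
#'
#' @param assembly an [applicator_assembly()].
#' @param points matrix with 3 columns, mm.
#' @param path output file.
#' @param wire optional [microwire()]; if supplied the total field is mapped.
#' @param wire_x wire x position, mm.
#' @return the data frame, invisibly.
#' @export
write_field_map <- function(assembly, points, path, wire = NULL, wire_x = 0) {
  points <- as.matrix(points)
  rows <- lapply(seq_len(nrow(points)), function(i) {
    fs <- if (is.null(wire)) applicator_field(assembly, points[i, ])
          else total_field(assembly, wire, points[i, ], wire_x = wire_x)
    c(fs$position, fs$H_vector, fs$H_magnitude, sqrt(sum(fs$grad_H_magnitude^2)))
  })
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("x", "y", "z", "Hx", "Hy", "Hz", "H_mag", "gradH_mag")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
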