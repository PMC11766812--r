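# Magnetostatics: charge-sheet cuboid, two-magnet applicator, dipole-line
# wire field. Closed-form anchor values were frozen from a 40-digit
# arbitrary-precision evaluation of the same formulas.

test_that("cuboid pole-face field reproduces the design surface field", {
  m <- cuboid_magnet()   # 38.1 x 76.2 x 6.35 mm, Br = 1.3 T
  fs <- cuboid_field(m, c(0, 0, m$thickness_z / 2))
  expect_equal(fs$H_vector[3] / 1e3, 118.65919748425958, tolerance = 1e-10)
  # design anchor: "about 120 kA/m" surface field
  expect_lt(abs(fs$H_magnitude / 1e3 - 120) / 120, 0.03)
  expect_false(fs$interior)
})

test_that("cuboid field has axial symmetry and matches a far point dipole", {
  m <- cuboid_magnet()
  on_axis <- cuboid_field(m, c(0, 0, 12))
  expect_equal(on_axis$H_vector[1], 0, tolerance = 1e-6 * on_axis$H_magnitude)
  expect_equal(on_axis$H_vector[2], 0, tolerance = 1e-6 * on_axis$H_magnitude)

  mom <- m$remanence / (4e-7 * pi) *
    (m$length_x * m$length_y * m$thickness_z) * 1e-9       # A m^2
  for (p in list(c(500, 0, 0), c(300, 200, 400), c(0, 0, 800))) {
    got <- cuboid_field(m, p)$H_vector
    want <- point_dipole_H(c(0, 0, mom), p * 1e-3)
    expect_lt(sqrt(sum((got - want)^2)) / sqrt(sum(want^2)), 0.01)
  }
})

test_that("cuboid analytic field agrees with the dipole-grid oracle", {
  m <- cuboid_magnet()
  pts <- list(c(0, 0, 6), c(10, 5, 8), c(25, 0, 0), c(0, 45, 2),
              c(-12, -20, -10), c(30, 30, 30))
  for (p in pts) {
    ana <- cuboid_field(m, p)$H_vector
    ora <- dipole_grid_field(m, p, n = c(36, 72, 6))$H_vector
    expect_lt(sqrt(sum((ana - ora)^2)) / sqrt(sum(ana^2)), 0.01)
  }
})

test_that("field is divergence- and curl-free outside the body", {
  m <- cuboid_magnet()
  h <- 0.02                                 # mm
  for (p in list(c(8, 4, 7), c(0, 0, 10), c(22, 10, 3))) {
    J <- matrix(0, 3, 3)                    # dH_i / dx_j, SI
    for (j in 1:3) {
      e <- numeric(3); e[j] <- h
      J[, j] <- (cuboid_field(m, p + e)$H_vector -
                 cuboid_field(m, p - e)$H_vector) / (2 * h * 1e-3)
    }
    scale <- cuboid_field(m, p)$H_magnitude / 1e-3   # |H| / 1 mm
    expect_lt(abs(sum(diag(J))) / scale, 1e-5)
    curl <- c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
    expect_lt(max(abs(curl)) / scale, 1e-5)
  }
})

test_that("applicator superposition is exact and midplane-symmetric", {
  asm <- default_assembly()
  p <- c(4, -7, 2)
  single <- cuboid_field(asm$magnet_pair[[1]], p)$H_vector +
            cuboid_field(asm$magnet_pair[[2]], p)$H_vector
  expect_equal(applicator_field(asm, p)$H_vector, single,
               tolerance = 1e-12)

  fs0 <- applicator_field(asm, c(0, 0, 0))
  # design anchor H0 = 106 kA/m holds within 15% (known model/print gap)
  expect_lt(abs(fs0$H_magnitude / 1e3 - 106) / 106, 0.15)
  # mirror symmetry: z-gradient of |H| vanishes on the midplane
  for (p in list(c(0, 0, 0), c(6, 3, 0), c(-10, 12, 0)))
    expect_lt(abs(applicator_field(asm, p)$grad_H_magnitude[3]),
              1e-4 * fs0$H_magnitude / 1e-3)
})

test_that("midplane field decreases toward the device edge with growing gradient", {
  asm <- default_assembly()
  xs <- seq(0, 12.5, length.out = 24)
  H <- vapply(xs, function(x)
    applicator_field(asm, c(x, 0, 0))$H_magnitude, numeric(1))
  expect_true(all(diff(H) < 0))
  g <- abs(diff(H) / diff(xs))
  expect_true(all(diff(g) > 0))
  # design landscape: |grad H| ~ 4.8e3 kA/m^2 at x = 10 mm, max ~ 5.2e3
  # near the edge; analytic model agrees to ~15% (same scale gap as H0)
  ge <- applicator_field(asm, c(12.5, 0, 0))$grad_H_magnitude
  expect_lt(abs(sqrt(sum(ge^2)) / 1e6 - 5.2) / 5.2, 0.2)
})

test_that("wire dipole-line field matches its closed form and is isotropic", {
  h0 <- wire_external_field(524e3, 12.5, 27.5)
  expect_equal(h0$H_magnitude / 1e3, 54.132231404958678, tolerance = 1e-12)
  for (th in c(0, pi / 4, pi / 2, 2.1))
    expect_equal(wire_external_field(524e3, 12.5, 27.5, th)$H_magnitude,
                 h0$H_magnitude, tolerance = 1e-12)
  # inverse-square decay: fitted log-log slope on [2a, 20a]
  r <- seq(25, 250, length.out = 40)
  h <- vapply(r, function(ri)
    wire_external_field(524e3, 12.5, ri)$H_magnitude, numeric(1))
  slope <- coef(lm(log(h) ~ log(r)))[2]
  expect_equal(unname(slope), -2, tolerance = 0.01)
  expect_lt(wire_external_field(524e3, 12.5, 1e6)$H_magnitude, 1e-2)
  expect_error(wire_external_field(524e3, 12.5, 10), "interior")
})

test_that("total field superposes and is wire-dominated at the surface", {
  asm <- default_assembly()
  w <- microwire()
  p_surface <- c(27.5e-3, 0, 0)     # on the glass shell, midplane
  tot <- total_field(asm, w, p_surface)
  app <- applicator_field(asm, p_surface)
  ratio <- sqrt(sum(tot$grad_H_magnitude^2)) /
    sqrt(sum(applicator_field(asm, c(12.5, 0, 0))$grad_H_magnitude^2))
  expect_gt(ratio, 100)
  # unmagnetized wire: total equals applicator exactly
  tot0 <- total_field(asm, w, p_surface, wire_M = 0)
  expect_equal(tot0$H_vector, app$H_vector, tolerance = 1e-12)
})

test_that("wire |h| gradient matches a 4th-order finite-difference oracle", {
  M <- 524e3; a <- 12.5
  f <- function(r_um) wire_external_field(M, a, r_um)$H_magnitude
  r0 <- 2 * a
  got <- -M * (a * 1e-6)^2 / (r0 * 1e-6)^3          # analytic d|h|/dr
  ora <- fd_grad4(f, r0, 0.05) / 1e-6               # per um -> per m
  expect_equal(got, ora, tolerance = 1e-3 * abs(got))
})

test_that("inputs are validated and field maps export", {
  expect_error(cuboid_magnet(length_x = -1), "dimensions")
  expect_error(cuboid_magnet(remanence = 0), "remanence")
  expect_error(cuboid_field(cuboid_magnet(), c(NA, 0, 0)), "finite")
  expect_error(applicator_assembly(gap = 0), "gap")
  inside <- cuboid_field(cuboid_magnet(), c(0, 0, 0))
  expect_true(inside$interior)

  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_field_map(default_assembly(),
                        rbind(c(0, 0, 0), c(5, 0, 0)), path)
  re <- read.csv(path)
  expect_equal(nrow(re), 2)
  expect_equal(re$H_mag, df$H_mag, tolerance = 1e-8)
})
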