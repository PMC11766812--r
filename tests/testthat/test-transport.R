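# Duct flow, magnetic force, capture and retention.

test_that("duct profile is no-slip and integrates to the volumetric rate", {
  ch <- channel_geometry()
  fl <- flow_field(50)
  expect_equal(duct_velocity(fl, ch, 200, 0), 0, tolerance = 1e-6)
  expect_equal(duct_velocity(fl, ch, 0, 300), 0, tolerance = 1e-4)
  expect_error(duct_velocity(fl, ch, 300, 0), "outside")

  # numerical quadrature oracle (midpoint rule on a fine grid)
  n <- 201
  xs <- (seq_len(n) - 0.5) / n * ch$width - ch$width / 2
  zs <- (seq_len(n) - 0.5) / n * ch$height - ch$height / 2
  g <- expand.grid(x = xs, z = zs)
  u <- duct_velocity(fl, ch, g$x, g$z)                       # um/s
  cell <- (ch$width / n) * (ch$height / n)                   # um^2
  Q_num <- sum(u) * cell * 1e-18 * 1e9 * 60                  # -> uL/min
  expect_equal(Q_num, 50, tolerance = 5e-4)

  u0 <- duct_velocity(fl, ch, 0, 0)
  u_mean <- 50 * 1e9 / 60 / (ch$width * ch$height)           # uL/min -> um/s
  expect_gt(u0, u_mean)
  expect_gt(u_mean, 0)
})

test_that("magnetic force is calibrated, linear in moment, zero at zero gradient", {
  b <- bead_model()
  w <- microwire()
  fs <- wire_external_field(524e3, w$core_radius, w$glass_outer_radius)
  fs$H_magnitude <- fs$H_magnitude + 106e3
  F <- magnetic_force(b, fs)
  expect_equal(sqrt(sum(F^2)) * 1e9, 13, tolerance = 0.05)

  flat <- field_sample(c(0, 0, 0), c(1e5, 0, 0), grad_H = c(0, 0, 0))
  expect_equal(magnetic_force(b, flat), c(0, 0, 0))

  # halving the moment (via saturation) at fixed gradient halves the force
  b_half <- bead_model(saturation_M = b$saturation_M / 2)
  F_half <- magnetic_force(b_half, fs)
  expect_equal(sqrt(sum(F^2)) / sqrt(sum(F_half^2)), 2, tolerance = 1e-9)
  expect_error(magnetic_force(b, field_sample(c(0,0,0), c(1,0,0))),
               "gradient")
})

test_that("all beads are captured at rest and capture is monotone in flow", {
  ch <- channel_geometry()
  pos <- gen_bead_positions(40, ch, seed = 301)
  res0 <- simulate_capture(pos, flow_field(0), ch, duration = 8)
  expect_equal(res0$fraction, 1)
  expect_true(all(res0$fates$fate == "captured"))

  fr <- vapply(c(0, 25, 50, 100), function(Q)
    simulate_capture(pos, flow_field(Q), ch, duration = 8)$fraction,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
  # beads never end up inside the wire envelope
  r_cap <- ch$wire$glass_outer_radius + 1.5
  expect_true(all(res0$fates$r_final >= r_cap - 1e-6))
})

test_that("capture is reproducible, convergent, and vanishes without a field", {
  ch <- channel_geometry()
  pos <- gen_bead_positions(30, ch, seed = 302)
  a <- simulate_capture(pos, flow_field(50), ch, duration = 6)
  b <- simulate_capture(pos, flow_field(50), ch, duration = 6)
  expect_identical(a$fates, b$fates)

  fine <- simulate_capture(pos, flow_field(50), ch, duration = 6,
                           step = 5e-4)
  expect_lt(abs(fine$fraction - a$fraction), 0.01 + 1e-12)

  off <- simulate_capture(pos, flow_field(50), ch, assembly = NULL,
                          duration = 6)
  expect_equal(off$fraction, 0)
  expect_error(simulate_capture(pos, flow_field(50), ch, step = 0), "step")
})

test_that("retention compares drag against the magnetic holding force", {
  ch <- channel_geometry()
  r0 <- retention_check(flow_field(0), ch)
  expect_true(r0$retained)
  expect_equal(r0$drag_N, 0)

  drags <- vapply(c(10, 50, 100, 500), function(Q)
    retention_check(flow_field(Q), ch)$drag_N, numeric(1))
  expect_true(all(diff(drags) > 0))
  # calibrated defaults hold the bead at the highest protocol wash rate
  expect_true(retention_check(flow_field(100), ch)$retained)
  # no field, any flow: nothing holds the bead
  expect_false(retention_check(flow_field(10), ch, assembly = NULL)$retained)
})

test_that("channel volume matches the design capacity", {
  ch <- channel_geometry()
  expect_equal(channel_volume(ch, subtract_wire = FALSE), 14.4)
  wire_term <- pi * (27.5e-6)^2 * 0.06 * 1e9
  expect_equal(channel_volume(ch), 14.4 - wire_term)
  expect_equal(wire_term, 0.1425, tolerance = 1e-3)
  # design capacity "15 uL", coarse consistency
  expect_lt(abs(channel_volume(ch, subtract_wire = FALSE) - 15) / 15, 0.06)
  tiny <- channel_geometry(length = 1e-9)
  expect_lt(channel_volume(tiny), 1e-8)
})
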