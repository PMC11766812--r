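# Gating, doublet correction, background subtraction, event I/O.

test_that("gating against trivial and oracle cases", {
  withr::local_seed(7)
  ev <- event_table(runif(500, 0, 100), runif(500, 0, 100),
                    rexp(500, 1 / 50))
  everything <- gate("all", rbind(c(-1, -1), c(101, -1), c(101, 101),
                                  c(-1, 101)))
  res <- apply_gate(ev, everything)
  expect_equal(res$count, 500)
  expect_equal(res$mean_FL4, mean(ev$FL4))

  nothing <- gate("none", rbind(c(200, 200), c(300, 200), c(250, 300)))
  res0 <- apply_gate(ev, nothing)
  expect_equal(res0$count, 0)
  expect_true(res0$empty)
  expect_true(is.nan(res0$mean_FL4))
})

test_that("point-in-polygon matches the winding-number oracle", {
  withr::local_seed(8)
  polys <- list(
    rbind(c(20, 20), c(80, 25), c(50, 90)),                 # triangle
    rbind(c(10, 10), c(90, 15), c(85, 85), c(15, 80)),      # convex quad
    rbind(c(10, 50), c(45, 15), c(85, 50), c(60, 50),       # concave
          c(50, 85)))
  for (v in polys) {
    px <- runif(1000, 0, 100); py <- runif(1000, 0, 100)
    got <- magwire:::.points_in_polygon(px, py, v)
    want <- pip_winding(px, py, v)
    expect_identical(got, want)
  }
  # boundary inclusivity: vertices and edge midpoints are inside
  v <- polys[[2]]
  mids <- (v + v[c(2:4, 1), ]) / 2
  expect_true(all(magwire:::.points_in_polygon(v[, 1], v[, 2], v)))
  expect_true(all(magwire:::.points_in_polygon(mids[, 1], mids[, 2], v)))
  expect_error(gate("bow", rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))),
               "self-intersecting")
  expect_error(gate("line", rbind(c(0, 0), c(1, 1))), "vertices")
})

test_that("doublet correction follows the bead-count arithmetic", {
  expect_equal(doublet_corrected_mean(gating_result(1000, 110, 100)), 100)
  expect_equal(doublet_corrected_mean(gating_result(500, 42.5, 0)), 42.5)
  expect_error(doublet_corrected_mean(gating_result(0, NaN, 0)), "Ntot")
})

test_that("doublet correction equals the brute-force bead-level mean", {
  withr::local_seed(9)
  for (rep in 1:25) {
    ns <- sample(10:400, 1); nd <- sample(0:150, 1)
    singlets <- rexp(ns, 1 / 100)
    doublets <- if (nd > 0) rexp(nd, 1 / 100) + rexp(nd, 1 / 100)
                else numeric(0)
    gr <- gating_result(N_tot = ns + nd,
                        I_FL4 = mean(c(singlets, doublets)), N_2 = nd)
    expect_equal(doublet_corrected_mean(gr),
                 expanded_bead_mean(singlets, doublets), tolerance = 1e-12)
    # permutation invariance and bounds
    fl <- sample(c(singlets, doublets))
    expect_equal(mean(fl), gr$I_FL4, tolerance = 1e-12)
    expect_gte(doublet_corrected_mean(gr), min(c(singlets, doublets)))
    expect_lte(doublet_corrected_mean(gr), max(c(singlets, doublets)))
  }
})

test_that("background subtraction uses the stock replicate mean", {
  ref <- background_reference(c(9, 10, 11))
  expect_equal(ref$I_stock, 10)
  expect_equal(background_subtract(100, ref), 90)
  expect_equal(background_subtract(10, ref), 0)
  expect_equal(background_subtract(5, ref), -5)     # unclipped by default
  expect_equal(background_subtract(5, ref, clip = TRUE), 0)
  expect_error(background_reference(numeric(0)), "replicate")
})

test_that("event tables round-trip bit-exactly through CSV", {
  withr::local_seed(10)
  ev <- event_table(rnorm(200, 1000, 80), rnorm(200, 800, 70),
                    rexp(200, 1 / 180), sample_id = "s1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_identical(back$FSC, ev$FSC)
  expect_identical(back$SSC, ev$SSC)
  expect_identical(back$FL4, ev$FL4)
})

test_that("FCS round trip with instrument-style channel names", {
  withr::local_seed(11)
  df <- data.frame(`FSC-H` = rnorm(150, 1000, 50),
                   `SSC-H` = rnorm(150, 700, 40),
                   `FL4-H` = rexp(150, 1 / 120), check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".fcs")
  magwire:::.write_fcs(df, path)
  ev <- read_events(path, format = "fcs",
                    columns = c(FSC = "FSC-H", SSC = "SSC-H", FL4 = "FL4-H"))
  expect_equal(nrow(ev), 150)
  # float32 storage: values agree to single precision
  expect_equal(ev$FSC, df$`FSC-H`, tolerance = 1e-6)
  expect_equal(ev$FL4, df$`FL4-H`, tolerance = 1e-6)
  expect_error(read_events(path, format = "fcs"), "FSC")
})

test_that("read_events reports malformed inputs", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_events(empty), "empty")
  expect_error(read_events("no/such/file.csv"), "not found")
  partial <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(FSC = 1:3, SSC = 1:3), partial, row.names = FALSE)
  expect_error(read_events(partial), "FL4")
})
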