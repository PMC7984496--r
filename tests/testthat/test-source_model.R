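test_that("point-source geometry factor is inverse square", {
  expect_equal(geometry_factor(2, 90, 0, "point"), 0.25)
  expect_equal(geometry_factor(c(1, 4), 45, 0, "point"), c(1, 1 / 16))
  expect_error(geometry_factor(0, 90, 0, "point"), "singular")
})

test_that("line-source geometry factor matches numerical quadrature", {
  for (case in list(c(1, 90), c(1.7, 35), c(0.5, 120), c(2.5, 10), c(3, 170))) {
    g <- geometry_factor(case[1], case[2], 0.36, "line")
    q <- oracle_geom_quadrature(case[1], case[2], 0.36)
    expect_equal(g, q, tolerance = 1e-6)
  }
  # longer active lengths too
  expect_equal(geometry_factor(1.2, 60, 1, "line"),
               oracle_geom_quadrature(1.2, 60, 1), tolerance = 1e-6)
})

test_that("line-source geometry factor is continuous through the axis", {
  L <- 0.36
  near <- geometry_factor(2, c(0.0005, 0.01, 0.1), L, "line")
  on_axis <- 1 / (2^2 - L^2 / 4)
  expect_equal(near[1], on_axis, tolerance = 1e-5)
  expect_true(all(diff(abs(near - on_axis)) > 0))  # deviation grows smoothly
  # same at the distal end
  near180 <- geometry_factor(2, 180 - 0.0005, L, "line")
  expect_equal(near180, on_axis, tolerance = 1e-5)
})

test_that("vanishing active length recovers the point source", {
  expect_equal(geometry_factor(1.7, 35, 1e-6, "line"), 1 / 1.7^2,
               tolerance = 1e-5)
})

test_that("radial dose function interpolates log-linearly and is normalized", {
  src <- synthetic_ir192_source()
  expect_equal(radial_dose(src, 1), 1)
  # node identity
  expect_equal(radial_dose(src, src$g_r), src$g)
  # midway between nodes: independent recomputation
  rmid <- (src$g_r[4] + src$g_r[5]) / 2
  expect_equal(radial_dose(src, rmid), oracle_gL(src, rmid), tolerance = 1e-14)
  expect_error(radial_dose(src, -1), "positive")
  # extrapolation: constant below, log-linear above
  expect_equal(radial_dose(src, 0.1), src$g[1])
  n <- length(src$g_r)
  slope <- (log(src$g[n]) - log(src$g[n - 1])) / (src$g_r[n] - src$g_r[n - 1])
  expect_equal(radial_dose(src, src$g_r[n] + 2),
               exp(log(src$g[n]) + 2 * slope), tolerance = 1e-12)
})

test_that("anisotropy function is normalized at 90 degrees and bilinear", {
  src <- synthetic_ir192_source()
  expect_equal(anisotropy(src, src$F_r, 90), rep(1, length(src$F_r)))
  # grid nodes
  expect_equal(anisotropy(src, src$F_r[3], src$F_th[2]), src$F_val[3, 2])
  # off-grid: 4-point hand-computed weighted average
  r0 <- (src$F_r[2] + src$F_r[3]) / 2; t0 <- (src$F_th[4] + src$F_th[5]) / 2
  expect_equal(anisotropy(src, r0, t0), oracle_F(src, r0, t0),
               tolerance = 1e-14)
  expect_error(anisotropy(src, 1, 200), "0, 180")
})

test_that("source_spec enforces TG-43 normalization invariants", {
  bad_g <- data.frame(r_cm = c(0.5, 1, 2), g = c(1.1, 1.01, 0.9))
  at <- expand.grid(r_cm = c(0.5, 1, 2), theta_deg = c(0, 90, 180))
  at$F <- 1
  expect_error(source_spec(0.36, 1.109, bad_g, at), "g_L\\(1\\) = 1")
  good_g <- data.frame(r_cm = c(0.5, 1, 2), g = c(1.1, 1, 0.9))
  at_bad <- at; at_bad$F[at_bad$theta_deg == 90] <- c(1, 1.05, 1)
  expect_error(source_spec(0.36, 1.109, good_g, at_bad), "90 deg")
  expect_s3_class(source_spec(0.36, 1.109, good_g, at), "source_spec")
})

test_that("dose rate reproduces the TG-43 reference normalization", {
  for (src in list(unit_test_source(),
                   unit_test_source(mode = "line"),
                   synthetic_ir192_source())) {
    dw <- dwell_source(c(0, 0, 0), c(0, 0, 1), S_K = 17.3)
    # field point at 1 cm on the transverse axis
    expect_equal(dose_rate(src, dw, c(10, 0, 0)), 17.3 * src$lambda,
                 tolerance = 1e-12)
  }
})

test_that("unit-test source reduces to pure inverse square", {
  src <- unit_test_source()
  dw <- dwell_source(c(0, 0, 0), c(0, 1, 0), S_K = 8)
  expect_equal(dose_rate(src, dw, c(0, 0, 20)), 8 * src$lambda / 4)
  expect_error(dose_rate(src, dw, c(0, 0, 0)), "singular")
})

test_that("dose rate is invariant under rigid rotations", {
  src <- synthetic_ir192_source()
  p <- c(13, -4, 22); ax <- c(0, 1, 0); orig <- c(2, 3, 5)
  base <- dose_rate(src, dwell_source(orig, ax, 10), p)
  for (s in 1:5) {
    R <- random_rotation(s)
    dwr <- dwell_source(as.numeric(R %*% orig), as.numeric(R %*% ax), 10)
    expect_equal(dose_rate(src, dwr, as.numeric(R %*% p)), base,
                 tolerance = 1e-9)
  }
})

test_that("line mode converges to point mode for tiny active length", {
  at <- expand.grid(r_cm = c(0.5, 1, 2, 5), theta_deg = c(0, 90, 180))
  at$F <- 1
  g <- data.frame(r_cm = c(0.5, 1, 2, 5), g = 1)
  line <- source_spec(1e-5, 1.109, g, at, mode = "line")
  point <- source_spec(0, 1.109, g, at, mode = "point")
  dw <- dwell_source(c(0, 0, 0), c(0, 0, 1), 10)
  for (p in list(c(5, 0, 0), c(20, 10, 5), c(0, 7, 7)))
    expect_equal(dose_rate(line, dw, p), dose_rate(point, dw, p),
                 tolerance = 1e-4)
})

test_that("arbitrary line-mode dose rate matches the term-by-term oracle", {
  src <- synthetic_ir192_source()
  dw <- dwell_source(c(3, -2, 11), c(0.6, 0.8, 0), 23)
  for (p in list(c(17, 4, 20), c(-8, -15, 2), c(3, 30, 11)))
    expect_equal(dose_rate(src, dw, p),
                 oracle_dose_rate(src, dw$position, dw$axis, dw$S_K, p),
                 tolerance = 1e-12)
})

test_that("source CSV dialect round-trips", {
  src <- synthetic_ir192_source()
  dir <- file.path(tempdir(), "srccsv")
  write_source_csv(src, dir)
  back <- read_source_csv(file.path(dir, "radial.csv"),
                          file.path(dir, "anisotropy.csv"),
                          file.path(dir, "source_meta.json"))
  expect_equal(back$g, src$g)
  expect_equal(back$F_val, src$F_val)
  expect_equal(back$L, src$L)
  expect_equal(back$mode, src$mode)
})
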