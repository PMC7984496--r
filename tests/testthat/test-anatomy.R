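test_that("margin expansion reproduces analytic sphere volumes", {
  grid <- voxel_grid(c(-40, -40, -40), c(1, 1, 1), c(81, 81, 81))
  co <- grid_coords(grid)
  sphere <- sqrt(rowSums(co^2)) <= 10
  grown <- expand_margin(sphere, 20, grid)
  vol <- mask_volume_cc(grown, grid)
  expect_equal(vol, 4 / 3 * pi * 30^3 / 1000, tolerance = 0.02)
  # margin 0 is the identity
  expect_equal(as.vector(expand_margin(sphere, 0, grid)), as.vector(sphere))
  expect_error(expand_margin(rep(FALSE, n_voxels(grid)), 5, grid), "empty")
  # clinical slice thickness: the digitized seed sphere loses part of its
  # polar caps, so the voxelization tolerance widens accordingly
  ga <- voxel_grid(c(-40, -40, -40), c(1, 1, 2.5), c(81, 81, 33))
  ca <- grid_coords(ga)
  sa <- sqrt(rowSums(ca^2)) <= 10
  va <- mask_volume_cc(expand_margin(sa, 20, ga), ga)
  expect_equal(va, 4 / 3 * pi * 30^3 / 1000, tolerance = 0.04)
})

test_that("margin expansion equals the brute-force distance check", {
  grid <- voxel_grid(c(0, 0, 0), c(2, 2, 2.5), c(14, 12, 10))
  set.seed(42)
  co <- grid_coords(grid)
  seeds <- sample(n_voxels(grid), 15)
  mask <- rep(FALSE, n_voxels(grid)); mask[seeds] <- TRUE
  grown <- expand_margin(mask, 7, grid)
  # all-pairs oracle
  d2 <- matrix(Inf, n_voxels(grid), 1)
  for (s in seeds) {
    ds <- (co[, 1] - co[s, 1])^2 + (co[, 2] - co[s, 2])^2 + (co[, 3] - co[s, 3])^2
    d2 <- pmin(d2, ds)
  }
  expect_equal(as.vector(grown), as.vector(d2 <= 49 + 1e-9))
})

test_that("margin expansion is monotone in the margin", {
  grid <- voxel_grid(c(0, 0, 0), c(2, 2, 2), c(20, 20, 20))
  co <- grid_coords(grid)
  mask <- sqrt(rowSums((co - 20)^2)) <= 6
  prev <- expand_margin(mask, 0, grid)
  for (m in c(3, 6, 12)) {
    cur <- expand_margin(mask, m, grid)
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("skin region reproduces the quadrilateral construction", {
  grid <- voxel_grid(c(-49.5, -49.5, 0.5), c(1, 1, 1), c(100, 100, 40))
  mk <- function(x, span) catheter(paste0("c", x),
                                   rbind(c(x, -span / 2, 15), c(x, span / 2, 15)))
  caths <- list(mk(-10, 80), mk(10, 80))
  mask <- build_skin_region(caths, grid)
  # footprint 8 cm x (2+1+1) cm extruded 3 mm = 9.6 cc
  expect_equal(mask_volume_cc(mask, grid), 9.6, tolerance = 0.02)
  z <- grid_coords(grid)[, 3]
  expect_true(all(z[as.vector(mask)] <= 3 + 1e-9))
  # single catheter degenerates to a 2 cm strip
  m1 <- build_skin_region(caths[1], grid)
  x <- grid_coords(grid)[, 1]
  expect_equal(range(x[as.vector(m1)]), c(-19.5, -0.5))
})

test_that("skin-region volume scales linearly with button span", {
  grid <- voxel_grid(c(-50, -80, 0.5), c(2, 2, 1), c(51, 81, 10))
  vols <- vapply(c(40, 80, 120, 160), function(span) {
    caths <- list(
      catheter("a", rbind(c(-10, -span / 2, 15), c(-10, span / 2, 15))),
      catheter("b", rbind(c(10, -span / 2, 15), c(10, span / 2, 15))))
    mask_volume_cc(build_skin_region(caths, grid), grid)
  }, numeric(1))
  ratios <- vols / c(40, 80, 120, 160)
  expect_equal(max(ratios) / min(ratios), 1, tolerance = 0.05)
})

test_that("involved ribs are the rib slab under the skin footprint", {
  grid <- voxel_grid(c(-30, -30, 0.5), c(2, 2, 2), c(31, 31, 30))
  co <- grid_coords(grid)
  rib <- co[, 3] > 40 & co[, 3] <= 45
  caths <- list(
    catheter("a", rbind(c(-10, -20, 15), c(-10, 20, 15))),
    catheter("b", rbind(c(10, -20, 15), c(10, 20, 15))))
  skin <- build_skin_region(caths, grid)
  inv <- involved_ribs(skin, rib, grid)
  # counting oracle: voxel is involved iff it is rib and its (x, y) column
  # intersects the skin footprint
  skin_arr <- array(as.vector(skin), grid$shape)
  fp_cols <- apply(skin_arr, c(1, 2), any)
  prism <- array(rep(as.vector(fp_cols), grid$shape[3]), grid$shape)
  expect_equal(sum(inv), sum(prism & array(rib, grid$shape)))
  expect_gt(sum(inv), 0)
  # footprint off the slab: empty
  none <- involved_ribs(skin, co[, 3] > 100, grid)
  expect_equal(sum(none), 0)
})

test_that("skin measurement point sits 2 cm from the scar midpoint", {
  straight <- rbind(c(0, -30, 0), c(0, 30, 0))
  p <- skin_measurement_point(straight, 20, side = 1)
  expect_equal(p, c(-20, 0, 0))
  expect_equal(skin_measurement_point(straight, 20, side = -1), c(20, 0, 0))
  expect_equal(skin_measurement_point(straight, 0)[1:2], c(0, 0))
  # curved scar: distance check
  t <- seq(0, pi, length.out = 50)
  curved <- cbind(20 * cos(t), 20 * sin(t), 0)
  mid <- curved[which.min(abs(t - pi / 2)), ]
  p2 <- skin_measurement_point(curved, 20)
  expect_equal(sqrt(sum((p2[1:2] - mid[1:2])^2)), 20, tolerance = 1e-3)
})

test_that("structure nesting is enforced and holds for generated anatomy", {
  grid <- voxel_grid(c(-20, -20, 0.5), c(4, 4, 4), c(11, 11, 11))
  co <- grid_coords(grid)
  big <- sqrt(rowSums((co - 10)^2)) <= 15
  small <- sqrt(rowSums((co - 10)^2)) <= 8
  expect_error(structure_set(grid, list(tumor_bed = big, ctv = small)),
               "nesting")
  grid2 <- voxel_grid(c(-80, -80, 1.25), c(2.5, 2.5, 2.5), c(65, 65, 46))
  anat <- synthetic_anatomy(grid2, 50, c(0, 0, 26), 7)
  m <- anat$structures$masks
  expect_true(all(m$tumor_bed[m$tumor_bed] & m$ctv[m$tumor_bed]))
  expect_true(!any(m$ctv & !m$ptv))
  expect_true(!any(m$tumor_bed & !m$ctv))
  expect_true(anat$cropped_fraction >= 0 && anat$cropped_fraction < 1)
})
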