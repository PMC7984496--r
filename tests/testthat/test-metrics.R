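toy_grid <- function(nv, vox_cc = 0.1) {
  # nv voxels of vox_cc each, laid out along x
  voxel_grid(c(0, 0, 0), c(10, 10, vox_cc * 10), c(nv, 1, 1))
}

toy_dvh <- function(doses, vox_cc = 0.1) {
  g <- toy_grid(length(doses), vox_cc)
  cumulative_dvh(array(doses, g$shape), rep(TRUE, length(doses)), g)
}

test_that("cumulative DVH counts voxels exactly", {
  dvh <- toy_dvh(rep(100, 20))
  expect_equal(dvh$volume_cc[1], 2)                  # value at 0 = volume
  expect_equal(volume_at_dose(dvh, 100), 2)
  expect_equal(volume_at_dose(dvh, 100.5), 0)
  expect_true(all(diff(dvh$volume_cc) <= 0))         # nonincreasing
  g <- toy_grid(5)
  expect_error(cumulative_dvh(array(1, g$shape), rep(FALSE, 5), g), "empty")
})

test_that("DVH matches brute-force counting on random grids", {
  set.seed(7)
  for (rep in 1:3) {
    g <- voxel_grid(c(0, 0, 0), c(2, 2, 2.5), c(30, 30, 30))
    d <- array(runif(n_voxels(g), 0, 600), g$shape)
    mask <- array(runif(n_voxels(g)) < 0.4, g$shape)
    dvh <- cumulative_dvh(d, mask, g, bin_width_cgy = 10)
    counts <- oracle_dvh_counts(d, mask, dvh$dose_cgy)
    expect_equal(dvh$volume_cc, counts * voxel_volume_cc(g))
  }
})

test_that("halving the bin width leaves shared edges unchanged", {
  set.seed(11)
  g <- voxel_grid(c(0, 0, 0), c(5, 5, 5), c(10, 10, 10))
  d <- array(runif(1000, 0, 50), g$shape)
  mask <- rep(TRUE, 1000)
  coarse <- cumulative_dvh(d, mask, g, bin_width_cgy = 2)
  fine <- cumulative_dvh(d, mask, g, bin_width_cgy = 1)
  shared <- intersect(coarse$dose_cgy, fine$dose_cgy)
  expect_gt(length(shared), 10)
  expect_equal(coarse$volume_cc[match(shared, coarse$dose_cgy)],
               fine$volume_cc[match(shared, fine$dose_cgy)])
})

test_that("Dx and Vx behave as inverses on the two-level toy", {
  # 1 cc total: half at 100, half at 200
  dvh <- toy_dvh(c(rep(100, 5), rep(200, 5)))
  expect_equal(dose_at_volume(dvh, 0.5), 200)
  expect_equal(volume_at_dose(dvh, 150), 0.5)
  expect_equal(dose_at_volume_percent(dvh, 50), 200)
  # uniform dose: D at any volume is that dose
  u <- toy_dvh(rep(340, 10))
  for (v in c(0.1, 0.55, 1)) expect_equal(dose_at_volume(u, v), 340)
  expect_error(dose_at_volume(u, 2), "exceeds")
  # D and V are inverse within one bin
  set.seed(3)
  rd <- toy_dvh(sort(runif(40, 50, 400)))
  for (v in c(0.5, 1.7, 3.1)) {
    d <- dose_at_volume(rd, v)
    expect_gte(dose_at_volume(rd, volume_at_dose(rd, d)), d - 1e-9)
  }
})

test_that("coverage and conformal indices follow their definitions", {
  full <- toy_dvh(rep(400, 10))
  expect_equal(coverage_index(full, 340), 1)
  none <- toy_dvh(rep(100, 10))
  expect_equal(coverage_index(none, 340), 0)
  part <- toy_dvh(c(rep(400, 90), rep(100, 10)))
  expect_equal(coverage_index(part, 340), 0.9)
  expect_equal(conformal_index(90, 100, 120), 0.675)
  expect_equal(conformal_index(5, 5, 5), 1)
  expect_error(conformal_index(10, 8, 12), "exceed")
  # COIN <= CI always, since PTV_PD / V_PD <= 1
  set.seed(5)
  for (i in 1:20) {
    v_ptv <- runif(1, 30, 120)
    ptv_pd <- runif(1, 0, v_ptv)
    v_pd <- runif(1, ptv_pd, 200)
    expect_lte(conformal_index(ptv_pd, v_ptv, v_pd), ptv_pd / v_ptv + 1e-12)
  }
})

test_that("homogeneity indices sum to one and match the footnote formulas", {
  h <- homogeneity_indices(80.48, 26.53)
  expect_equal(h$DNR, 26.53 / 80.48)
  expect_equal(h$DHI, 1 - 26.53 / 80.48)
  expect_equal(h$DHI + h$DNR, 1, tolerance = 1e-15)
  expect_equal(homogeneity_indices(50, 0), list(DHI = 1, DNR = 0))
  expect_error(homogeneity_indices(0, 0), "positive")
  expect_error(homogeneity_indices(10, 11), "V_PD")
})

test_that("overdose index and totals follow the definitions", {
  expect_equal(overdose_index(0, 70), 0)
  expect_equal(overdose_index(8.3, 73.34), 8.3 / 73.34)
  expect_lte(overdose_index(8.3, 73.34), 1)
  expect_equal(total_dose(340, 10), 3400)
  expect_equal(total_dose(250, 0), 0)
  expect_equal(total_dose(250, 1), 250)
})

test_that("overestimation ratio is the relative TPS excess in percent", {
  expect_equal(overestimation_ratio(100, 100), 0)
  expect_equal(overestimation_ratio(100, 79.9), 20.1)
  expect_error(overestimation_ratio(0, 10), "positive")
  set.seed(9)
  tps <- runif(17, 150, 300)
  meas <- tps * runif(17, 0.6, 1)
  r <- overestimation_ratio(tps, meas)
  expect_equal(median(r), sort(r)[9])  # sort-based median oracle (odd n)
  expect_true(all(r <= 100))
})

test_that("constraint checker derives thresholds as percent of PD", {
  metrics <- list(
    skin_D0.2cc_cgy = 0, skin_D1cc_cgy = 0, rib_D0.1cc_cgy = 0,
    rib_D1cc_cgy = 0, breast_D90pct_cgy = 0, heart_mean_cgy = 0,
    heart_D0.1cc_cgy = 0, lung_mean_cgy = 0, lung_D0.1cc_cgy = 0)
  rep <- check_constraints(metrics, 340)
  thr <- setNames(rep$threshold_cgy, rep$label)
  expect_equal(thr[["skin D1cc"]], 306)
  expect_equal(thr[["skin D0.2cc"]], 340)
  expect_equal(thr[["rib D1cc"]], 272)
  expect_equal(thr[["rib D0.1cc"]], 306)
  expect_equal(thr[["heart mean"]], 27.2)
  expect_equal(thr[["lung D0.1cc"]], 204)
  expect_true(attr(rep, "overall_pass"))    # all metrics at zero pass
  expect_error(check_constraints(metrics[-1], 340), "skin_D0.2cc_cgy")
})

test_that("plan metrics satisfy the index identities on a computed plan", {
  grid <- voxel_grid(c(-40, -40, 0.5), c(2.5, 2.5, 2.5), c(33, 33, 28))
  src <- synthetic_ir192_source()
  plan <- small_test_plan(n_dwell_per = 7)
  co <- grid_coords(grid)
  ptv <- sqrt(co[, 1]^2 + co[, 2]^2 + (co[, 3] - 15)^2) <= 20
  plan <- normalize_to_coverage(plan, src, ptv, grid)
  dose <- compute_dose_grid(plan, src, grid)
  ss <- structure_set(grid, list(ptv = ptv, body = rep(TRUE, n_voxels(grid))))
  pm <- plan_metrics(dose, ss, 340)
  expect_equal(pm$DHI + pm$DNR, 1, tolerance = 1e-15)
  expect_lte(pm$COIN, pm$CI + 1e-12)
  expect_lte(pm$V200_cc, pm$V150_cc)
  expect_lte(pm$V150_cc, pm$V100_cc)
  expect_lte(pm$PTV_PD_cc, min(pm$V_PTV_cc, pm$V_PD_cc))
  expect_gte(pm$CI, 0); expect_lte(pm$CI, 1)
  # uniform-dose sanity for the skin D50% definition
  skin_dvh <- toy_dvh(rep(123, 10))
  expect_equal(dose_at_volume_percent(skin_dvh, 50), 123)
})

test_that("DVH CSV export has the documented columns", {
  dvh <- toy_dvh(rep(100, 10))
  f <- tempfile(fileext = ".csv")
  write_dvh_csv(dvh, "ptv", f)
  df <- read.csv(f)
  expect_named(df, c("structure", "dose_cgy", "volume_cc"))
  expect_equal(df$volume_cc[1], 1)
})
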