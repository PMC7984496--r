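test_that("geometric weights respect symmetry and center suppression", {
  src <- synthetic_ir192_source()
  mk_plan <- function(pos) {
    plan <- small_test_plan()
    plan$dwells <- list(positions = pos,
                        axes = matrix(rep(c(0, 1, 0), nrow(pos)),
                                      ncol = 3, byrow = TRUE),
                        catheter = rep(1L, nrow(pos)))
    plan$times_s <- rep(1, nrow(pos))
    plan
  }
  # symmetric pair
  w2 <- geometric_weights(mk_plan(rbind(c(-5, 0, 0), c(5, 0, 0))), src)
  expect_equal(w2[1], w2[2], tolerance = 1e-12)
  # three collinear equispaced dwells: middle sees both neighbours
  pos3 <- rbind(c(0, -10, 0), c(0, 0, 0), c(0, 10, 0))
  w3 <- geometric_weights(mk_plan(pos3), src)
  expect_lt(w3[2], w3[1])
  expect_equal(w3[1], w3[3], tolerance = 1e-12)
  # direct evaluation of the inverse-rate rule
  rate_at <- function(i) {
    sum(vapply(setdiff(1:3, i), function(j)
      dose_rate(src, dwell_source(pos3[j, ], c(0, 1, 0), 40000),
                pos3[i, ]) / 3600, numeric(1)))
  }
  w_expected <- 1 / vapply(1:3, rate_at, numeric(1))
  w_expected <- w_expected / mean(w_expected)
  expect_equal(w3, w_expected, tolerance = 1e-10)
  # permutation equivariance under dwell relabeling
  perm <- c(3, 1, 2)
  wp <- geometric_weights(mk_plan(pos3[perm, ]), src)
  expect_equal(wp, w3[perm], tolerance = 1e-12)
  # single dwell: uniform
  expect_equal(geometric_weights(mk_plan(matrix(c(0, 0, 0), 1, 3)), src), 1)
})

test_that("dose-point least squares solves the toy problems", {
  src <- unit_test_source()
  plan <- small_test_plan()
  plan$dwells <- list(positions = matrix(c(0, 0, 0), 1, 3),
                      axes = matrix(c(0, 1, 0), 1, 3), catheter = 1L)
  plan$times_s <- 1
  # one dwell, one point: exact closed form t = target / rate
  pt <- matrix(c(10, 0, 0), 1, 3)
  rate_per_s <- plan$S_K * src$lambda / 3600
  t1 <- fit_dose_points(plan, src, pt, 340)
  expect_equal(as.numeric(t1), 340 / rate_per_s, tolerance = 1e-9)
  # homogeneity: doubling the target doubles the times
  t2 <- fit_dose_points(plan, src, pt, 680)
  expect_equal(as.numeric(t2), 2 * as.numeric(t1), tolerance = 1e-9)
})

test_that("overdetermined NNLS matches the normal-equations oracle", {
  src <- unit_test_source()
  plan <- small_test_plan()
  plan$dwells <- list(positions = rbind(c(-10, 0, 0), c(10, 0, 0)),
                      axes = rbind(c(0, 1, 0), c(0, 1, 0)),
                      catheter = c(1L, 1L))
  plan$times_s <- c(1, 1)
  pts <- rbind(c(0, 0, 15), c(-20, 0, 0), c(25, 5, 0))
  target <- c(200, 300, 250)
  sol <- fit_dose_points(plan, src, pts, target)
  # dense oracle: unconstrained normal equations; if nonnegative it is the
  # NNLS solution (checked); otherwise enumerate the active sets
  A <- matrix(0, 3, 2)
  for (k in 1:2) for (p in 1:3)
    A[p, k] <- dose_rate(src, dwell_source(plan$dwells$positions[k, ],
                                           c(0, 1, 0), plan$S_K),
                         pts[p, ]) / 3600
  cand <- list(solve(t(A) %*% A, t(A) %*% target))
  for (k in 1:2) {
    one <- rep(0, 2)
    one[k] <- sum(A[, k] * target) / sum(A[, k]^2)
    cand <- c(cand, list(one))
  }
  feas <- Filter(function(x) all(x >= -1e-9), cand)
  resid <- vapply(feas, function(x) sum((A %*% x - target)^2), numeric(1))
  best <- feas[[which.min(resid)]]
  expect_equal(as.numeric(sol), pmax(as.numeric(best), 0), tolerance = 1e-6)
  # residual no worse than the optimally scaled geometric solution
  w <- geometric_weights(plan, src)
  scale_opt <- sum((A %*% w) * target) / sum((A %*% w)^2)
  expect_lte(sum((A %*% sol - target)^2),
             sum((A %*% (w * scale_opt) - target)^2) + 1e-9)
})

test_that("coverage normalization meets the 95/95 rule tightly", {
  grid <- voxel_grid(c(-40, -40, 0.5), c(2.5, 2.5, 2.5), c(33, 33, 24))
  src <- synthetic_ir192_source()
  plan <- small_test_plan(n_dwell_per = 9)
  co <- grid_coords(grid)
  ptv <- sqrt((co[, 1])^2 + co[, 2]^2 + (co[, 3] - 15)^2) <= 22
  norm <- normalize_to_coverage(plan, src, ptv, grid)
  k <- attr(norm, "scale_k")
  cov <- attr(norm, "coverage")
  expect_gte(cov, 0.95)
  # one-voxel quantum above the requirement at most (plus bisection slack)
  quantum <- 1 / sum(ptv)
  d <- dose_at_points(norm, src, co[ptv, , drop = FALSE])
  expect_lte(mean(d / 1.001 >= 0.95 * 340) - 0.95, quantum + 1e-9)
  # already compliant plan: k <= 1
  again <- normalize_to_coverage(norm, src, ptv, grid)
  expect_lte(attr(again, "scale_k"), 1 + 1e-3)
  # halving the input times doubles k
  halved <- norm; halved$times_s <- norm$times_s / 2
  renorm <- normalize_to_coverage(halved, src, ptv, grid)
  expect_equal(attr(renorm, "scale_k"), 2 * attr(again, "scale_k"),
               tolerance = 0.01)
})

test_that("optimized synthetic plans meet the clinical OAR constraints", {
  # end-to-end property of the study conditions: at least 90% of generated
  # patients satisfy every constraint after optimization
  coh <- generate_cohort(cohort_spec(n_patients = 17, seed = 1))
  pass <- vapply(coh$cases, function(cs) attr(cs$constraints, "overall_pass"),
                 logical(1))
  expect_gte(mean(pass), 0.9)
  # and every plan hits the coverage rule
  cov <- vapply(coh$cases, function(cs) attr(cs$plan, "coverage"), numeric(1))
  expect_true(all(cov >= 0.95))
})
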