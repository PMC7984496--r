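#' Dwell-time optimization configuration
#'
#' @param method `"geometric"` (inverse summed inter-dwell dose rate) or
#'   `"dose_point_lsq"` (nonnegative least squares on PTV-surface points).
#' @param coverage_fraction fraction of the target to cover (0.95).
#' @param coverage_dose_fraction fraction of the prescription defining
#'   coverage (0.95): the clinical rule is V_{0.95 PD}(PTV) >= 95%.
#' @param n_surface_points number of PTV boundary sampling points for the
#'   least-squares method.
#' @param max_iterations bisection iteration cap.
#' @param random_seed seed used for surface-point sampling (recorded).
#' @return An `optimization_config` object.
#' @export
optimization_config <- function(method = c("geometric", "dose_point_lsq"),
                                coverage_fraction = 0.95,
                                coverage_dose_fraction = 0.95,
                                n_surface_points = 200,
                                max_iterations = 60, random_seed = 1L) {
  method <- match.arg(method)
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1,
            coverage_dose_fraction > 0, coverage_dose_fraction <= 1)
  structure(list(method = method, coverage_fraction = coverage_fraction,
                 coverage_dose_fraction = coverage_dose_fraction,
                 n_surface_points = n_surface_points,
                 max_iterations = max_iterations,
                 random_seed = as.integer(random_seed)),
            class = "optimization_config")
}

#' Geometric dwell weights
#'
#' Classical geometric optimization: each dwell's relative time is inversely
#' proportional to the summed dose rate it receives from all other dwells
#' (unit times), so central dwells that "see" many neighbours are weighted
#' down.  Deterministic; a single dwell gets uniform weight.
#'
#' @param plan an [implant_plan()].
#' @param spec a [source_spec()].
#' @return Positive relative weights, mean 1.
#' @export
geometric_weights <- function(plan, spec) {
  pos <- plan$dwells$positions
  m <- nrow(pos)
  if (m == 1) return(1)
  base <- plan
  received <- numeric(m)
  for (k in seq_len(m)) {
    base$times_s <- replace(rep(0, m), k, 1)
    contrib <- as.numeric(dose_at_points(base, spec, pos))
    contrib[k] <- 0  # exclude the self term
    received <- received + contrib
  }
  w <- 1 / received
  if (any(!is.finite(w))) w <- rep(1, m)
  w / mean(w)
}

#' Fit dwell times to dose points (nonnegative least squares)
#'
#' Solves `min || A t - d ||` with `t >= 0`, where `A[p, k]` is the dose at
#' surface point p per second of dwell k, via `pracma::lsqnonneg`.
#'
#' @param plan an [implant_plan()].
#' @param spec a [source_spec()].
#' @param surface_points_mm n x 3 matrix of dose points.
#' @param target_cgy target dose per fraction at the points (recycled).
#' @return Nonnegative dwell times (seconds).
#' @export
fit_dose_points <- function(plan, spec, surface_points_mm, target_cgy) {
  surface_points_mm <- matrix(as.numeric(surface_points_mm), ncol = 3)
  np <- nrow(surface_points_mm)
  if (np < 1) stop("at least one surface point required")
  m <- nrow(plan$dwells$positions)
  A <- matrix(0, np, m)
  base <- plan
  for (k in seq_len(m)) {
    base$times_s <- replace(rep(0, m), k, 1)
    A[, k] <- dose_at_points(base, spec, surface_points_mm)
  }
  if (all(A == 0)) stop("infeasible: zero dose matrix")
  b <- rep_len(as.numeric(target_cgy), np)
  pracma::lsqnonneg(A, b)$x
}

#' Quasi-uniform sample of a mask boundary
#'
#' Boundary voxels (mask voxels with at least one 6-neighbour outside),
#' subsampled deterministically under the given seed.
#'
#' @param mask logical array.
#' @param grid a [voxel_grid()].
#' @param n number of points.
#' @param seed RNG seed (recorded in the optimizer config).
#' @return n x 3 matrix of voxel centers, mm.
#' @export
sample_mask_surface <- function(mask, grid, n = 200, seed = 1L) {
  m <- as_mask_array(mask, grid)
  sh <- grid$shape
  inner <- array(TRUE, sh)
  shift_and <- function(a, d, ax) {
    idx <- lapply(sh, seq_len)
    src <- idx; src[[ax]] <- pmin(pmax(idx[[ax]] + d, 1), sh[ax])
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  }
  for (ax in 1:3) for (d in c(-1, 1)) inner <- inner & shift_and(m, d, ax)
  boundary <- which(m & !inner)
  if (length(boundary) == 0) boundary <- which(m)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- sample(boundary, min(n, length(boundary)))
  grid_coords(grid)[pick, , drop = FALSE]
}

#' Scale a plan to the clinical coverage rule
#'
#' Finds (by bisection, to 0.1% relative tolerance) the smallest global
#' dwell-time scale k such that the fraction of the target mask receiving
#' `coverage_dose_fraction * PD` is at least `coverage_fraction`, and
#' returns the scaled plan.  Coverage is monotone nondecreasing in k, which
#' is asserted during the search.
#'
#' @param plan an [implant_plan()].
#' @param spec a [source_spec()].
#' @param ptv_mask logical array over `grid`.
#' @param grid a [voxel_grid()].
#' @param config an [optimization_config()].
#' @return The plan with `times_s` scaled; attributes `scale_k` and
#'   `coverage` record the result.
#' @export
normalize_to_coverage <- function(plan, spec, ptv_mask, grid,
                                  config = optimization_config()) {
  pts <- grid_coords(grid)[as.vector(as_mask_array(ptv_mask, grid)), , drop = FALSE]
  if (nrow(pts) == 0) stop("empty target mask")
  base <- dose_at_points(plan, spec, pts)  # linear in k
  thr <- config$coverage_dose_fraction * plan$prescription_cgy
  cov <- function(k) mean(k * base >= thr)
  # bracket, then bisect in log space
  lo <- 1e-6; hi <- 1
  while (cov(hi) < config$coverage_fraction && hi < 1e9) hi <- hi * 2
  it <- 0
  while ((hi - lo) / hi > 1e-3 && it < config$max_iterations) {
    mid <- sqrt(lo * hi)
    cm <- cov(mid)
    stopifnot(cov(hi) >= cm - 1e-12)  # coverage monotone nondecreasing in k
    if (cm >= config$coverage_fraction) hi <- mid else lo <- mid
    it <- it + 1
  }
  k <- hi
  plan$times_s <- plan$times_s * k
  attr(plan, "scale_k") <- k
  attr(plan, "coverage") <- cov(k)
  plan
}

#' Two-stage dwell-time optimization
#'
#' Geometric initialization, optional dose-point nonnegative least squares
#' against the prescription at PTV boundary points, then coverage
#' normalization — the package's auditable stand-in for a TPS inverse
#' optimizer.
#'
#' @param plan an [implant_plan()].
#' @param spec a [source_spec()].
#' @param ptv_mask logical array over `grid`.
#' @param grid a [voxel_grid()].
#' @param config an [optimization_config()].
#' @return Optimized, coverage-normalized [implant_plan()]; attributes
#'   `scale_k` and `coverage` as in [normalize_to_coverage()].
#' @export
optimize_plan <- function(plan, spec, ptv_mask, grid,
                          config = optimization_config()) {
  w <- geometric_weights(plan, spec)
  plan$times_s <- w
  if (config$method == "dose_point_lsq") {
    sp <- sample_mask_surface(ptv_mask, grid, n = config$n_surface_points,
                              seed = config$random_seed)
    t_lsq <- fit_dose_points(plan, spec, sp, plan$prescription_cgy)
    if (sum(t_lsq) > 0) plan$times_s <- t_lsq
  }
  normalize_to_coverage(plan, spec, ptv_mask, grid, config)
}
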