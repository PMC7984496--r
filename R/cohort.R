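#' Logistic backscatter-deficit model
#'
#' Fractional skin-dose deficit as a function of the depth of the
#' shallowest catheter under the measurement point:
#' `deficit(d) = A / (1 + exp(-(d - d0) / s))`.  The default parameters
#' (asymptote A = 0.33, midpoint d0 = 15 mm, slope s = 8 mm) place the
#' emulated film ratios in the measured 15-33% range over the generator's
#' depth range.
#'
#' @param asymptote A, maximal fractional deficit.
#' @param midpoint_mm d0, depth of half-maximal deficit, mm.
#' @param slope_mm s, transition width, mm.
#' @return A function of depth (mm) returning the fractional deficit, with
#'   the parameters attached as attribute `params`.
#' @export
logistic_deficit_model <- function(asymptote = 0.33, midpoint_mm = 15,
                                   slope_mm = 8) {
  f <- function(depth_mm) asymptote / (1 + exp(-(depth_mm - midpoint_mm) / slope_mm))
  attr(f, "params") <- c(asymptote = asymptote, midpoint_mm = midpoint_mm,
                         slope_mm = slope_mm)
  f
}

#' Deficit model interpolated from Monte Carlo results
#'
#' Turns a [surface_deficit()] table into a depth -> fractional-deficit
#' function (monotone linear interpolation, constant extrapolation).
#'
#' @param deficit_df data.frame with `depth_mm` and `deficit_pct`.
#' @return A function of depth (mm).
#' @export
deficit_from_mc <- function(deficit_df) {
  stats::approxfun(deficit_df$depth_mm, deficit_df$deficit_pct / 100, rule = 2)
}

#' Fit the logistic deficit model to (depth, ratio) pairs
#'
#' Recovers the asymptote of [logistic_deficit_model()] from per-case
#' overestimation ratios.  By default the midpoint and slope are held at
#' their known values and the asymptote is the exact least-squares
#' amplitude of the logistic shape: over the clinical range of
#' shallowest-catheter depths (roughly 18-26 mm) the logistic is sampled on
#' a narrow arc, so a joint (A, d0) fit at n = 17 is poorly conditioned.
#' Set `fit_midpoint = TRUE` for the joint nonlinear fit
#' (`minpack.lm::nlsLM`).
#'
#' @param depth_mm depths, mm.
#' @param ratio_pct overestimation ratios, percent.
#' @param slope_mm fixed slope, mm.
#' @param midpoint_mm fixed (or starting) midpoint, mm.
#' @param fit_midpoint also fit the midpoint.
#' @return Named vector `c(asymptote, midpoint_mm)`.
#' @export
fit_deficit_model <- function(depth_mm, ratio_pct, slope_mm = 8,
                              midpoint_mm = 15, fit_midpoint = FALSE) {
  df <- data.frame(d = depth_mm, y = ratio_pct / 100)
  if (fit_midpoint) {
    fit <- try(minpack.lm::nlsLM(
      y ~ A / (1 + exp(-(d - d0) / slope_mm)), data = df,
      start = list(A = 0.25, d0 = midpoint_mm),
      lower = c(A = 0.01, d0 = -20), upper = c(A = 1, d0 = 60),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- coef(fit)
      return(c(asymptote = unname(cf["A"]), midpoint_mm = unname(cf["d0"])))
    }
  }
  # amplitude-only fit: exact least squares against the known shape
  g <- 1 / (1 + exp(-(df$d - midpoint_mm) / slope_mm))
  c(asymptote = sum(df$y * g) / sum(g^2), midpoint_mm = midpoint_mm)
}

#' Synthetic cohort specification
#'
#' Distributions emulating the study population: 17 patients, two-plane
#' free-hand implants, per-fraction prescription 340 cGy x 10 fractions,
#' cavity sizes targeted so PTV volumes span roughly 32-125 cc, and a
#' film-measurement emulator whose deviation from the TG-43 dose follows a
#' depth-dependent backscatter deficit plus multiplicative lognormal noise.
#'
#' @param n_patients cohort size (default 17).
#' @param seed base RNG seed; every draw derives from it.
#' @param breast_height_meanlog,breast_height_sdlog lognormal parameters of
#'   the breast dome height (mm).
#' @param cavity_radius_meanlog,cavity_radius_sdlog lognormal parameters of
#'   the cavity radius (mm).
#' @param cavity_depth_frac_range cavity-center depth as a fraction of the
#'   feasible depth range (uniform draw).
#' @param skin_standoff_mm minimum depth of the shallow catheter plane
#'   below the skin (default 18; the hard floor remains the template's
#'   5 mm rule).
#' @param chest_standoff_mm minimum gap between the deep catheter plane and
#'   the chest wall (default 16; keeps rib doses clinically plausible).
#' @param spacing_range_cm catheter spacing draw, cm.
#' @param prescription_cgy,n_fractions fractionation (340 x 10).
#' @param film_noise_sdlog multiplicative lognormal noise of the film
#'   measurement (sigma = 0.03).
#' @param deficit_model depth -> fractional deficit function.
#' @param grid_spacing_mm voxel spacing of per-case grids.
#' @param S_K air-kerma strength, U.
#' @param source a [source_spec()] used for all plans.
#' @param opt_config an [optimization_config()]; the default uses the
#'   dose-point least-squares stage, emulating inverse optimization.
#' @param cavity_offset_frac_range lateral cavity-center offset as a
#'   fraction of the breast lateral semi-axis (uniform draw, random side).
#' @param max_ptv_cc eligibility cap on the (cropped) PTV volume, cc;
#'   geometry draws exceeding it are rejected, mirroring the size limits of
#'   partial-breast irradiation protocols.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 17, seed = 1L,
                        breast_height_meanlog = log(50),
                        breast_height_sdlog = 0.12,
                        cavity_radius_meanlog = log(6),
                        cavity_radius_sdlog = 0.22,
                        cavity_depth_frac_range = c(0.25, 0.75),
                        skin_standoff_mm = 18, chest_standoff_mm = 16,
                        spacing_range_cm = c(1.5, 2),
                        prescription_cgy = 340, n_fractions = 10,
                        film_noise_sdlog = 0.03,
                        deficit_model = logistic_deficit_model(),
                        grid_spacing_mm = c(2.5, 2.5, 2.5),
                        S_K = 40000,
                        source = synthetic_ir192_source(),
                        opt_config = optimization_config("dose_point_lsq"),
                        cavity_offset_frac_range = c(0.1, 0.3),
                        max_ptv_cc = 135) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  stopifnot(breast_height_sdlog > 0 || breast_height_sdlog == 0,
            film_noise_sdlog >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Emulate a radiochromic-film skin measurement
#'
#' `measured = D_TPS * (1 - deficit(depth)) * exp(sigma * Z)` with Z a
#' standard normal draw: the TPS full-scatter dose reduced by the
#' backscatter deficit at the shallowest-catheter depth under the
#' measurement point, with multiplicative lognormal film noise.
#'
#' @param tps_dose_cgy TPS-calculated skin dose, cGy/fr (> 0).
#' @param depth_mm shallowest catheter depth under the measurement point.
#' @param deficit_model depth -> fractional deficit function.
#' @param noise_sdlog lognormal sigma (0 disables noise).
#' @return Emulated measured dose, cGy/fr.
#' @export
emulate_film_measurement <- function(tps_dose_cgy, depth_mm,
                                     deficit_model = logistic_deficit_model(),
                                     noise_sdlog = 0.03) {
  if (any(tps_dose_cgy <= 0)) stop("TPS dose must be positive")
  noise <- if (noise_sdlog > 0) rlnorm(length(tps_dose_cgy), 0, noise_sdlog) else 1
  tps_dose_cgy * (1 - deficit_model(depth_mm)) * noise
}

draw_case_geometry <- function(spec) {
  # rejection-sample a feasible geometry; counts rejections
  rejections <- 0L
  repeat {
    H <- rlnorm(1, spec$breast_height_meanlog, spec$breast_height_sdlog)
    r_cav <- rlnorm(1, spec$cavity_radius_meanlog, spec$cavity_radius_sdlog)
    spacing <- runif(1, spec$spacing_range_cm[1], spec$spacing_range_cm[2])
    template <- freehand_template(n_planes = 2, spacing_cm = spacing)
    sep <- template$plane_separation_cm * 10
    # cavity center depth: shallow plane clears the skin standoff, deep
    # plane clears the chest standoff, cavity sits inside cropped tissue
    zmin <- max(spec$skin_standoff_mm + sep / 2, r_cav + 6)
    zmax <- min(H - spec$chest_standoff_mm - sep / 2, H - 4 - r_cav)
    if (zmax <= zmin) { rejections <- rejections + 1L; next }
    frac <- runif(1, spec$cavity_depth_frac_range[1],
                  spec$cavity_depth_frac_range[2])
    z_cav <- zmin + frac * (zmax - zmin)
    # eligibility: analytic slab-cropped PTV sphere volume (an upper bound
    # for the dome-cropped voxel mask) must stay under the protocol cap
    R <- r_cav + 25
    z1 <- max(10, z_cav - R); z2 <- min(H - 6, z_cav + R)
    v_est <- pi * (R^2 * (z2 - z1) -
                     ((z2 - z_cav)^3 - (z1 - z_cav)^3) / 3) / 1000
    if (v_est > spec$max_ptv_cc) { rejections <- rejections + 1L; next }
    off <- runif(1, spec$cavity_offset_frac_range[1],
                 spec$cavity_offset_frac_range[2]) *
      1.6 * H * sample(c(-1, 1), 1)
    return(list(H = H, r_cav = r_cav, z_cav = z_cav, x_off = off,
                template = template, rejections = rejections))
  }
}

#' Generate one synthetic case
#'
#' Draws the geometry, builds anatomy and implant, optimizes and normalizes
#' the plan, computes metrics and the constraint report (when
#' `compute_metrics`), and emulates the film measurement against the TPS
#' skin dose (D50% of the skin region).
#'
#' @param spec a [cohort_spec()].
#' @param case_id identifier stored in the case.
#' @param compute_metrics compute the full dose grid and plan metrics
#'   (slower); the skin point dose and film emulation are always computed.
#' @param normalize run the geometric optimization and coverage
#'   normalization (the film-ratio emulation is invariant to the global
#'   dwell-time scale, so parameter-recovery studies may skip it).
#' @return A `synthetic_case` list.
#' @export
generate_case <- function(spec, case_id = 1L, compute_metrics = TRUE,
                          normalize = TRUE) {
  geom <- draw_case_geometry(spec)
  H <- geom$H; r_cav <- geom$r_cav; z_cav <- geom$z_cav
  cc <- c(geom$x_off, 0, z_cav)
  caths <- generate_freehand_implant(cc, r_cav, geom$template)
  plan <- implant_plan(caths, S_K = spec$S_K,
                       prescription_cgy = spec$prescription_cgy,
                       n_fractions = spec$n_fractions)
  # grid: covers the breast dome and the OAR slab below the chest wall
  xy_half <- max(abs(geom$x_off) + r_cav + 25, 1.6 * H,
                 max(abs(plan$dwells$positions[, 1])),
                 max(abs(plan$dwells$positions[, 2]))) + 8
  sp <- spec$grid_spacing_mm
  shape <- c(ceiling(2 * xy_half / sp[1]), ceiling(2 * xy_half / sp[2]),
             ceiling((H + 73) / sp[3]))
  grid <- voxel_grid(c(-xy_half, -xy_half, 0.5), sp, shape)
  skin <- build_skin_region(caths, grid)
  if (compute_metrics || normalize) {
    anat <- synthetic_anatomy(grid, H, cc, r_cav)
    ss <- anat$structures
    ss$masks$skin_region <- skin
  } else {
    # film-emulation-only path: the full mask set is not needed
    anat <- list(cropped_fraction = NA_real_)
    ss <- NULL
  }
  if (normalize)
    plan <- optimize_plan(plan, spec$source, ss$masks$ptv, grid,
                          spec$opt_config)
  # scar on the skin above the cavity, along y
  scar <- rbind(c(geom$x_off, -20, 0), c(geom$x_off, 20, 0))
  mp <- skin_measurement_point(scar, 20)
  shallow_depth <- min(plan$dwells$positions[, 3])
  metrics <- NULL; constraints <- NULL; dose <- NULL
  if (compute_metrics) {
    eval_mask <- ss$masks$body | skin
    dose <- compute_dose_grid(plan, spec$source, grid, subset = eval_mask)
    metrics <- plan_metrics(dose, ss, spec$prescription_cgy)
    constraints <- check_constraints(metrics, spec$prescription_cgy)
    tps_skin <- metrics$skin_D50pct_cgy
  } else {
    # skin D50% from dose evaluated on the skin-region voxels only
    pts <- grid_coords(grid)[as.vector(skin), , drop = FALSE]
    d <- dose_at_points(plan, spec$source, pts)
    sd_dvh <- structure(list(sorted_doses = sort(d, decreasing = TRUE),
                             voxel_cc = voxel_volume_cc(grid),
                             structure_volume_cc = length(d) * voxel_volume_cc(grid)),
                        class = "dvh")
    tps_skin <- dose_at_volume_percent(sd_dvh, 50)
  }
  measured <- emulate_film_measurement(tps_skin, shallow_depth,
                                       spec$deficit_model,
                                       spec$film_noise_sdlog)
  structure(list(
    case_id = case_id, breast_height_mm = H, cavity_radius_mm = r_cav,
    v_ptv_cc = if (!is.null(ss)) mask_volume_cc(ss$masks$ptv, grid) else NA_real_,
    cavity_depth_mm = z_cav, template = geom$template, grid = grid,
    structures = ss, plan = plan, dose = dose,
    metrics = metrics, constraints = constraints,
    measurement_point_mm = mp, shallow_catheter_depth_mm = shallow_depth,
    tps_skin_dose_cgy = tps_skin, measured_skin_dose_cgy = measured,
    overestimation_pct = overestimation_ratio(tps_skin, measured),
    cropped_fraction = anat$cropped_fraction,
    rejections = geom$rejections),
    class = "synthetic_case")
}

#' Generate a synthetic patient cohort
#'
#' Deterministic given `spec$seed`; infeasible geometry draws are resampled
#' with the rejection count logged per case.
#'
#' @param spec a [cohort_spec()].
#' @param compute_metrics compute full dose grids and plan metrics per case.
#' @param normalize see [generate_case()].
#' @return A `synthetic_cohort`: list of cases plus the spec.
#' @export
generate_cohort <- function(spec = cohort_spec(), compute_metrics = TRUE,
                            normalize = TRUE) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  cases <- lapply(seq_len(spec$n_patients), function(i)
    generate_case(spec, case_id = i, compute_metrics = compute_metrics,
                  normalize = normalize))
  structure(list(cases = cases, spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", length(x$cases), "cases, seed", x$spec$seed, "\n")
  invisible(x)
}

#' Cohort summary table (study-shaped)
#'
#' Mean / median / max / min / SD of every per-case metric, one row per
#' metric, shaped like a clinical dosimetric characteristics table.
#'
#' @param cohort a [generate_cohort()] result with metrics computed.
#' @return data.frame with columns metric, mean, median, max, min, sd.
#' @export
cohort_report <- function(cohort) {
  cases <- Filter(function(cs) !is.null(cs$metrics), cohort$cases)
  if (length(cases) == 0) stop("cohort has no computed metrics")
  keys <- names(cases[[1]]$metrics)
  rows <- lapply(keys, function(k) {
    v <- vapply(cases, function(cs) {
      x <- cs$metrics[[k]]
      if (is.null(x) || length(x) != 1) NA_real_ else as.numeric(x)
    }, numeric(1))
    data.frame(metric = k, mean = mean(v, na.rm = TRUE),
               median = median(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               min = min(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  oe <- vapply(cohort$cases, `[[`, 1, "overestimation_pct")
  attr(out, "overestimation") <- data.frame(
    case_id = vapply(cohort$cases, `[[`, 1, "case_id"),
    depth_mm = vapply(cohort$cases, `[[`, 1, "shallow_catheter_depth_mm"),
    tps_cgy = vapply(cohort$cases, `[[`, 1, "tps_skin_dose_cgy"),
    measured_cgy = vapply(cohort$cases, `[[`, 1, "measured_skin_dose_cgy"),
    overestimation_pct = oe)
  out
}
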