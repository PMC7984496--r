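#' Monte Carlo configuration
#'
#' @param n_histories number of photon histories (>= 1).
#' @param seed RNG seed (recorded in results).
#' @param energy_mev source photon energy; default 0.38 MeV, the mean
#'   Ir-192 energy.
#' @param cutoff_mev photon cutoff energy (default 0.01 MeV).
#' @param geometry `"half_space"` (water at z > 0, vacuum beyond the skin
#'   plane z = 0) or `"full_water"`.
#' @param n_batches batches for standard-error estimation.
#' @param forced_absorption disable scattering (absorb at the first
#'   collision); the point tallies then equal the primary-beam closed form.
#' @param max_scatter safety cap on scatters per history.
#' @return An `mc_config` object.
#' @export
mc_config <- function(n_histories = 2e5, seed = 1L, energy_mev = 0.38,
                      cutoff_mev = 0.01,
                      geometry = c("half_space", "full_water"),
                      n_batches = 25, forced_absorption = FALSE,
                      max_scatter = 1000) {
  geometry <- match.arg(geometry)
  if (n_histories < 1) stop("n_histories must be >= 1")
  if (cutoff_mev <= 0) stop("cutoff energy must be positive")
  structure(list(n_histories = as.integer(n_histories), seed = as.integer(seed),
                 energy_mev = energy_mev, cutoff_mev = cutoff_mev,
                 geometry = geometry, n_batches = as.integer(n_batches),
                 forced_absorption = forced_absorption,
                 max_scatter = as.integer(max_scatter)),
            class = "mc_config")
}

#' Water attenuation tables
#'
#' Mass attenuation (mu/rho) and mass energy-absorption (muen/rho)
#' coefficients for liquid water versus photon energy (standard NIST
#' tabulation, 0.01-1.5 MeV), log-log interpolated by the transport kernel.
#'
#' @return data.frame with `energy_mev`, `mu_over_rho_cm2_g`,
#'   `muen_over_rho_cm2_g`.
#' @export
water_medium <- function() {
  utils::read.csv(system.file("extdata", "water_attenuation.csv",
                              package = "apbidose"))
}

#' Water linear attenuation coefficient
#' @param energy_mev photon energy, MeV.
#' @return mu in cm^-1 (unit-density water), log-log interpolated.
#' @export
water_mu_cm <- function(energy_mev) {
  tab <- water_medium()
  exp(approx(log(tab$energy_mev), log(tab$mu_over_rho_cm2_g),
             xout = log(energy_mev), rule = 2)$y)
}

#' Run the photon Monte Carlo over a set of tally points
#'
#' Emits `n_histories` monoenergetic photons isotropically from the plan's
#' dwell positions (dwell-time weighted) and scores collision kerma at the
#' tally points with a next-event (point-detector) estimator, in full water
#' and in the half-space (water z > 0, vacuum beyond) simultaneously from
#' the same histories.  With `geometry = "full_water"` both tallies include
#' every contribution and the deficit is identically zero.
#'
#' @param plan an [implant_plan()] (dwell positions/times used).
#' @param tally_mm n x 3 matrix of tally points (mm).
#' @param config an [mc_config()].
#' @return An `mc_result`: per-tally `dose_full`, `dose_half` (arbitrary,
#'   internally consistent units), standard errors, `deficit_pct` with
#'   `deficit_se_pct`, energy-accounting sums, and the configuration.
#' @export
mc_run <- function(plan, tally_mm, config = mc_config()) {
  tally_mm <- matrix(as.numeric(tally_mm), ncol = 3)
  tab <- water_medium()
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  res <- .cpp_mc_run(plan$dwells$positions, plan$times_s, tally_mm,
                     config$energy_mev, config$cutoff_mev,
                     config$n_histories, config$n_batches,
                     tab$energy_mev, tab$mu_over_rho_cm2_g,
                     tab$muen_over_rho_cm2_g,
                     config$forced_absorption,
                     config$geometry == "half_space",
                     config$max_scatter)
  nb <- nrow(res$full)
  per <- res$hist_per_batch
  mfull <- colMeans(res$full) / per
  mhalf <- colMeans(res$half) / per
  se <- function(m) apply(m / per, 2, stats::sd) / sqrt(nb)
  # batch-wise deficit for a correlated SE of the ratio
  dfb <- 100 * (1 - res$half / pmax(res$full, .Machine$double.xmin))
  deficit <- 100 * (1 - mhalf / mfull)
  structure(list(
    tally_mm = tally_mm, dose_full = mfull, dose_half = mhalf,
    se_full = se(res$full), se_half = se(res$half),
    deficit_pct = deficit,
    deficit_se_pct = apply(dfb, 2, stats::sd) / sqrt(nb),
    n_histories = res$n_histories, config = config,
    energy = list(deposited = sum(res$e_deposited),
                  escaped = sum(res$e_escaped),
                  below_cutoff = sum(res$e_below_cutoff),
                  emitted = res$n_histories * config$energy_mev,
                  max_per_history_error = res$max_energy_accounting_error)),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("mc_result:", x$n_histories, "histories,", length(x$dose_full),
      "tallies\n")
  for (i in seq_along(x$dose_full))
    cat(sprintf("  tally %d: deficit %.2f%% (SE %.2f)\n", i,
                x$deficit_pct[i], x$deficit_se_pct[i]))
  invisible(x)
}

#' Surface backscatter deficit versus catheter depth
#'
#' For each depth, builds the two-catheter phantom plan at that depth below
#' the surface and estimates the dose deficit at the surface point above
#' one catheter's center: `100 * (D_full - D_half) / D_full`, full-scatter
#' water versus the half-space with vacuum beyond the skin.  Both estimates
#' come from identical histories (correlated tally), so the deficit SE is
#' that of the ratio.
#'
#' @param depths_mm catheter depths, mm; default `c(5, 10, 15, 20)`.
#' @param config an [mc_config()].
#' @param setup base [phantom_setup()] (separation, active length).
#' @return data.frame: depth_mm, dose_full, dose_half, deficit_pct,
#'   deficit_se_pct; attribute `results` holds the per-depth `mc_result`s.
#' @export
surface_deficit <- function(depths_mm = c(5, 10, 15, 20),
                            config = mc_config(),
                            setup = phantom_setup()) {
  results <- lapply(depths_mm, function(d) {
    st <- setup; st$catheter_depth_mm <- d; st$variant <- "surface_points"
    plan <- build_phantom_plan(st)
    # tally on the surface directly above the center of catheter 1
    x0 <- -st$catheter_separation_cm * 10 / 2
    mc_run(plan, matrix(c(x0, 0, 0), 1, 3), config)
  })
  df <- data.frame(
    depth_mm = depths_mm,
    dose_full = vapply(results, function(r) r$dose_full[1], 1),
    dose_half = vapply(results, function(r) r$dose_half[1], 1),
    deficit_pct = vapply(results, function(r) r$deficit_pct[1], 1),
    deficit_se_pct = vapply(results, function(r) r$deficit_se_pct[1], 1))
  low_precision <- df$deficit_se_pct * 3 > pmax(abs(df$deficit_pct), 1)
  if (any(low_precision))
    warning("fewer histories than needed for 3-SE separation at depth(s) ",
            paste(df$depth_mm[low_precision], collapse = ", "), " mm; ",
            "achieved SE ",
            paste(signif(df$deficit_se_pct[low_precision], 2), collapse = ", "))
  attr(df, "results") <- results
  df
}

#' Deficit profile across the perpendicular-film plane
#'
#' The film stands perpendicular to the catheters with the catheters at
#' 2 cm depth; tallies run along the surface trace of the film plane,
#' symmetric about the midline between the two catheters.
#'
#' @param setup a [phantom_setup()] with `variant = "perpendicular_film"`.
#' @param config an [mc_config()].
#' @param x_range_mm lateral extent of the profile, mm.
#' @param n_points tallies across the profile (odd keeps a midline point).
#' @return An `mc_result` with `profile` (data.frame x_mm, deficit_pct,
#'   deficit_se_pct) and `summary_deficit_pct` (profile mean).
#' @export
perpendicular_film_profile <- function(setup = phantom_setup("perpendicular_film"),
                                       config = mc_config(),
                                       x_range_mm = 30, n_points = 7) {
  if (setup$variant != "perpendicular_film")
    stop("setup variant must be 'perpendicular_film'")
  plan <- build_phantom_plan(setup)
  xs <- seq(-x_range_mm, x_range_mm, length.out = n_points)
  tally <- cbind(xs, 0, 0)  # surface trace of the film plane (y = 0)
  res <- mc_run(plan, tally, config)
  res$profile <- data.frame(x_mm = xs, deficit_pct = res$deficit_pct,
                            deficit_se_pct = res$deficit_se_pct)
  res$summary_deficit_pct <- mean(res$deficit_pct)
  res
}

#' Export MC results as JSON
#' @param result an `mc_result` or the data.frame from [surface_deficit()].
#' @param path output JSON.
#' @export
write_mc_json <- function(result, path) {
  if (is.data.frame(result)) {
    jsonlite::write_json(result, path, dataframe = "rows", digits = NA)
  } else {
    jsonlite::write_json(list(
      tally_mm = result$tally_mm, dose_full = result$dose_full,
      dose_half = result$dose_half, se_full = result$se_full,
      se_half = result$se_half, deficit_pct = result$deficit_pct,
      deficit_se_pct = result$deficit_se_pct,
      n_histories = result$n_histories), path, digits = NA)
  }
  invisible(path)
}
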