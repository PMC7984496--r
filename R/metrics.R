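#' Cumulative dose-volume histogram
#'
#' Exact voxel counting: the curve value at a bin edge d is the absolute
#' volume (cc) of mask voxels with dose >= d.  No interpolation is involved
#' in building the curve, so values at shared edges are identical whatever
#' the bin width.
#'
#' @param dose a `dose_grid` from [compute_dose_grid()], or a numeric array
#'   over `grid`.
#' @param mask logical array (nonempty).
#' @param grid a [voxel_grid()]; taken from `dose` when it is a `dose_grid`.
#' @param bin_width_cgy histogram bin width, cGy (default 1).
#' @return A `dvh` object: `dose_cgy` (bin edges), `volume_cc` (cumulative,
#'   nonincreasing), `structure_volume_cc`, plus the sorted voxel doses used
#'   for exact Dx/Vx queries.
#' @export
cumulative_dvh <- function(dose, mask, grid = NULL, bin_width_cgy = 1) {
  if (inherits(dose, "dose_grid")) { grid <- dose$grid; dose <- dose$values }
  if (is.null(grid)) stop("grid required when dose is a bare array")
  mask <- as.logical(mask)
  if (!any(mask)) stop("cannot compute a DVH on an empty mask")
  d <- as.numeric(dose)[mask]
  vox <- voxel_volume_cc(grid)
  edges <- seq(0, max(d) + bin_width_cgy, by = bin_width_cgy)
  # exact counting: volume at edge e = #(d >= e) * voxel volume
  asc <- sort(d)
  vol <- (length(d) - findInterval(edges - 1e-12, asc)) * vox
  structure(list(dose_cgy = edges, volume_cc = vol,
                 structure_volume_cc = length(d) * vox,
                 sorted_doses = sort(d, decreasing = TRUE),
                 voxel_cc = vox),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat("dvh:", round(x$structure_volume_cc, 2), "cc,",
      length(x$dose_cgy), "bins up to", max(x$dose_cgy), "cGy\n")
  invisible(x)
}

#' Dose covering a given volume (D_x)
#'
#' Minimum dose received by the hottest `volume_cc` of the structure, by
#' exact counting over sorted voxel doses with linear interpolation inside
#' the boundary voxel.
#'
#' @param dvh a [cumulative_dvh()].
#' @param volume_cc volume, cc (0 < volume <= structure volume).
#' @return Dose in cGy.
#' @export
dose_at_volume <- function(dvh, volume_cc) {
  if (volume_cc > dvh$structure_volume_cc + 1e-9)
    stop("requested volume exceeds the structure volume")
  if (volume_cc <= 0) stop("volume must be positive")
  s <- dvh$sorted_doses
  k <- volume_cc / dvh$voxel_cc  # fractional voxel rank
  if (k <= 1) return(s[1])
  k <- min(k, length(s))
  i <- floor(k)
  if (i >= length(s)) return(s[length(s)])
  s[i] + (k - i) * (s[i + 1] - s[i])
}

#' Volume receiving at least a given dose (V_x)
#'
#' @param dvh a [cumulative_dvh()].
#' @param dose_cgy dose threshold, cGy.
#' @return Volume in cc (exact voxel counting).
#' @export
volume_at_dose <- function(dvh, dose_cgy) {
  sum(dvh$sorted_doses >= dose_cgy) * dvh$voxel_cc
}

#' Dose to the hottest x% of the structure (D_x%)
#' @param dvh a [cumulative_dvh()].
#' @param percent percentage of the structure volume (e.g. 50 for D50%).
#' @return Dose in cGy.
#' @export
dose_at_volume_percent <- function(dvh, percent) {
  dose_at_volume(dvh, percent / 100 * dvh$structure_volume_cc)
}

#' Coverage index CI
#'
#' Fraction of the PTV receiving the prescribed dose.
#'
#' @param ptv_dvh DVH of the PTV.
#' @param pd_cgy prescribed dose per fraction, cGy.
#' @return CI in \[0, 1\].
#' @export
coverage_index <- function(ptv_dvh, pd_cgy) {
  volume_at_dose(ptv_dvh, pd_cgy) / ptv_dvh$structure_volume_cc
}

#' Conformal index COIN
#'
#' `COIN = (PTV_PD / V_PTV) * (PTV_PD / V_PD)`: the product of target
#' coverage and the fraction of the prescription isodose inside the target.
#'
#' @param ptv_pd_cc PTV volume receiving the prescription, cc.
#' @param v_ptv_cc PTV volume, cc.
#' @param v_pd_cc whole-body volume receiving the prescription, cc.
#' @return COIN in \[0, 1\].
#' @export
conformal_index <- function(ptv_pd_cc, v_ptv_cc, v_pd_cc) {
  if (ptv_pd_cc > min(v_ptv_cc, v_pd_cc) + 1e-9)
    stop("PTV_PD cannot exceed min(V_PTV, V_PD)")
  (ptv_pd_cc / v_ptv_cc) * (ptv_pd_cc / v_pd_cc)
}

#' Homogeneity index DHI and non-uniformity ratio DNR
#'
#' `DHI = (V_PD - V_1.5xPD) / V_PD`, `DNR = V_1.5xPD / V_PD`; the two sum
#' to 1 exactly by construction.
#'
#' @param v_pd_cc volume receiving the prescription, cc (> 0).
#' @param v_1p5_cc volume receiving 1.5x the prescription, cc.
#' @return List with `DHI` and `DNR`.
#' @export
homogeneity_indices <- function(v_pd_cc, v_1p5_cc) {
  if (v_pd_cc <= 0) stop("V_PD must be positive")
  if (v_1p5_cc < 0 || v_1p5_cc > v_pd_cc + 1e-9)
    stop("V_1.5xPD must lie in [0, V_PD]")
  dnr <- v_1p5_cc / v_pd_cc
  list(DHI = 1 - dnr, DNR = dnr)
}

#' Overdose volume index OI
#'
#' `OI = V_200 / V_PTV` (PTV volume receiving twice the prescription over
#' total PTV volume).
#'
#' @param v200_cc PTV volume receiving 200% of the prescription, cc.
#' @param v_ptv_cc PTV volume, cc.
#' @return OI (dimensionless).
#' @export
overdose_index <- function(v200_cc, v_ptv_cc) v200_cc / v_ptv_cc

#' Skin-dose overestimation ratio
#'
#' `100 * (D_TPS - D_measured) / D_TPS` (percent by which the planning
#' system overestimates the measured dose).
#'
#' @param d_tps_cgy TPS-calculated dose, cGy (> 0).
#' @param d_meas_cgy measured dose, cGy.
#' @return Percent overestimation (vectorized).
#' @export
overestimation_ratio <- function(d_tps_cgy, d_meas_cgy) {
  if (any(d_tps_cgy <= 0)) stop("TPS dose must be positive")
  100 * (d_tps_cgy - d_meas_cgy) / d_tps_cgy
}

#' Total physical dose of the fractionation scheme
#' @param dose_per_fraction_cgy dose per fraction, cGy.
#' @param n_fractions number of fractions.
#' @return Total dose, cGy.
#' @export
total_dose <- function(dose_per_fraction_cgy, n_fractions) {
  dose_per_fraction_cgy * n_fractions
}

#' Plan-quality metrics for one case
#'
#' Computes every target index (Table-2 style) and the OAR quantities
#' (Table-3 style) from a dose grid and a structure set.  V_PD and
#' V_1.5xPD are whole-body volumes; V100/V150/V200 are within-PTV volumes.
#'
#' @param dose a `dose_grid`.
#' @param structures a [structure_set()] with at least `ptv` and `body`.
#' @param pd_cgy prescription per fraction, cGy.
#' @return A `plan_metrics` list.
#' @export
plan_metrics <- function(dose, structures, pd_cgy) {
  g <- dose$grid
  msk <- structures$masks
  dvh_body <- cumulative_dvh(dose, msk$body, g)
  dvh_ptv <- cumulative_dvh(dose, msk$ptv, g)
  v_pd <- volume_at_dose(dvh_body, pd_cgy)
  v_15 <- volume_at_dose(dvh_body, 1.5 * pd_cgy)
  v_ptv <- dvh_ptv$structure_volume_cc
  v100 <- volume_at_dose(dvh_ptv, pd_cgy)        # = PTV_PD
  v150 <- volume_at_dose(dvh_ptv, 1.5 * pd_cgy)
  v200 <- volume_at_dose(dvh_ptv, 2 * pd_cgy)
  hi <- homogeneity_indices(v_pd, v_15)
  out <- list(
    V_PD_cc = v_pd, V_1.5xPD_cc = v_15, V_PTV_cc = v_ptv,
    PTV_PD_cc = v100, V100_cc = v100, V150_cc = v150, V200_cc = v200,
    DNR = hi$DNR, DHI = hi$DHI,
    CI = coverage_index(dvh_ptv, pd_cgy),
    COIN = conformal_index(v100, v_ptv, v_pd),
    OI = overdose_index(v200, v_ptv),
    D95_pct = dose_at_volume(dvh_ptv, 0.95 * v_ptv) / pd_cgy * 100)
  oar <- function(name, dvh_fun) {
    if (is.null(msk[[name]]) || !any(msk[[name]])) return(NULL)
    cumulative_dvh(dose, msk[[name]], g)
  }
  dv <- as.numeric(dose$values)
  vox <- voxel_volume_cc(g)
  if (!is.null(msk$lung) && any(msk$lung)) {
    dl <- oar("lung")
    out$lung_mean_cgy <- mean(dv[as.vector(msk$lung)])
    out$lung_D0.1cc_cgy <- dose_at_volume(dl, 0.1)
  }
  if (!is.null(msk$heart) && any(msk$heart)) {
    dh <- oar("heart")
    out$heart_mean_cgy <- mean(dv[as.vector(msk$heart)])
    out$heart_D0.1cc_cgy <- dose_at_volume(dh, 0.1)
  }
  if (!is.null(msk$breast) && any(msk$breast)) {
    nt <- msk$breast & !msk$ptv  # nontarget breast
    if (any(nt)) {
      db <- cumulative_dvh(dose, nt, g)
      out$breast_V90_pct <- volume_at_dose(db, 0.9 * pd_cgy) /
        db$structure_volume_cc * 100
      out$breast_D90pct_cgy <- dose_at_volume_percent(db, 90)
    }
  }
  if (!is.null(msk$ribs) && any(msk$ribs)) {
    dr <- oar("ribs")
    out$rib_V80_cc <- volume_at_dose(dr, 0.8 * pd_cgy)
    out$rib_V90_cc <- volume_at_dose(dr, 0.9 * pd_cgy)
    out$rib_D1cc_cgy <- if (dr$structure_volume_cc >= 1) dose_at_volume(dr, 1) else NA_real_
    out$rib_D0.1cc_cgy <- dose_at_volume(dr, 0.1)
  }
  if (!is.null(msk$skin_region) && any(msk$skin_region)) {
    ds <- oar("skin_region")
    out$skin_V100_cc <- volume_at_dose(ds, pd_cgy)
    out$skin_V90_cc <- volume_at_dose(ds, 0.9 * pd_cgy)
    out$skin_D1cc_cgy <- if (ds$structure_volume_cc >= 1) dose_at_volume(ds, 1) else NA_real_
    out$skin_D0.2cc_cgy <- dose_at_volume(ds, 0.2)
    out$skin_D50pct_cgy <- dose_at_volume_percent(ds, 50)
  }
  structure(out, class = "plan_metrics")
}

#' Clinical constraint set
#'
#' The per-fraction limits, each expressed as a percentage of the
#' prescription: skin D0.2cc < 100% and D1cc < 90%; rib D0.1cc < 90% and
#' D1cc < 80%; nontarget breast D90% < 10%; heart mean < 8% and
#' D0.1cc < 50%; lung mean < 8% and D0.1cc < 60%.
#'
#' @return data.frame of limits (structure, metric key, percent of PD).
#' @export
clinical_constraints <- function() {
  data.frame(
    structure = c("skin", "skin", "rib", "rib", "breast",
                  "heart", "heart", "lung", "lung"),
    label = c("skin D0.2cc", "skin D1cc", "rib D0.1cc", "rib D1cc",
              "breast D90%", "heart mean", "heart D0.1cc",
              "lung mean", "lung D0.1cc"),
    metric = c("skin_D0.2cc_cgy", "skin_D1cc_cgy", "rib_D0.1cc_cgy",
               "rib_D1cc_cgy", "breast_D90pct_cgy", "heart_mean_cgy",
               "heart_D0.1cc_cgy", "lung_mean_cgy", "lung_D0.1cc_cgy"),
    percent_of_pd = c(100, 90, 90, 80, 10, 8, 50, 8, 60),
    stringsAsFactors = FALSE)
}

#' Check a plan against the clinical constraints
#'
#' Thresholds are computed as the stated percentage of the prescription per
#' fraction; a missing metric is an error naming it, except metrics that are
#' undefined for the case (structure smaller than the reference volume),
#' which pass as NA.
#'
#' @param metrics a [plan_metrics()] (or named list of the metric keys).
#' @param pd_cgy prescription per fraction, cGy.
#' @param constraints constraint table, default [clinical_constraints()].
#' @return A `constraint_report` data.frame: label, value (cGy/fr),
#'   threshold (cGy/fr), pass; attribute `overall_pass`.
#' @export
check_constraints <- function(metrics, pd_cgy,
                              constraints = clinical_constraints()) {
  rows <- lapply(seq_len(nrow(constraints)), function(i) {
    key <- constraints$metric[i]
    if (!key %in% names(metrics))
      stop("missing metric for constraint check: ", key)
    val <- metrics[[key]]
    thr <- constraints$percent_of_pd[i] / 100 * pd_cgy
    data.frame(label = constraints$label[i], value_cgy = val,
               threshold_cgy = thr,
               pass = if (is.na(val)) NA else val < thr)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "overall_pass") <- all(rep$pass, na.rm = TRUE)
  class(rep) <- c("constraint_report", "data.frame")
  rep
}

#' Export a DVH as CSV (`structure,dose_cgy,volume_cc`)
#' @param dvh a [cumulative_dvh()].
#' @param structure structure name for the first column.
#' @param path CSV file.
#' @export
write_dvh_csv <- function(dvh, structure, path) {
  utils::write.csv(data.frame(structure = structure, dose_cgy = dvh$dose_cgy,
                              volume_cc = dvh$volume_cc),
                   path, row.names = FALSE)
  invisible(path)
}
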