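#' TG-43 source characterization
#'
#' Bundle the TG-43 parameters of one HDR source: active length `L` (cm),
#' dose-rate constant `Lambda` (cGy h^-1 U^-1), radial dose function
#' `g_L(r)` as a table in r (cm), and 2-D anisotropy function `F(r, theta)`
#' on an (r, theta) grid with theta in degrees measured from the source long
#' axis (0 deg = tip).  TG-43 normalization is enforced: `g_L(1 cm) = 1` and
#' `F(r, 90 deg) = 1` for every tabulated r.
#'
#' @param L_cm active source length, cm (0 allowed in point mode).
#' @param lambda dose-rate constant, cGy/h per U.
#' @param radial_table data.frame with columns `r_cm`, `g` (must contain
#'   r = 1 with g = 1).
#' @param anisotropy_table data.frame with columns `r_cm`, `theta_deg`, `F`
#'   on a complete rectangular grid; `F(r, 90) = 1` required.
#' @param mode `"line"` or `"point"` geometry function.
#' @param mean_energy_mev mean photon energy (Ir-192: 0.38 MeV); carried as
#'   metadata for the interface Monte Carlo.
#' @return A `source_spec` object.
#' @examples
#' src <- unit_test_source()
#' dose_rate(src, dwell_source(c(0, 0, 0), c(0, 0, 1), S_K = 10),
#'           point_mm = c(10, 0, 0))  # = 10 * Lambda at the reference point
#' @export
source_spec <- function(L_cm, lambda, radial_table, anisotropy_table,
                        mode = c("line", "point"), mean_energy_mev = 0.38) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(radial_table), all(c("r_cm", "g") %in% names(radial_table)),
            is.data.frame(anisotropy_table),
            all(c("r_cm", "theta_deg", "F") %in% names(anisotropy_table)))
  if (L_cm < 0) stop("active length must be >= 0")
  if (lambda <= 0) stop("dose-rate constant must be positive")
  rt <- radial_table[order(radial_table$r_cm), , drop = FALSE]
  if (any(diff(rt$r_cm) <= 0)) stop("radial table r values must be strictly increasing")
  if (any(rt$g <= 0)) stop("radial dose function values must be positive")
  i1 <- which(abs(rt$r_cm - 1) < 1e-12)
  if (length(i1) != 1 || abs(rt$g[i1] - 1) > 1e-9)
    stop("radial table must contain r = 1 cm with g_L(1) = 1 (TG-43 normalization)")
  at <- anisotropy_table
  if (any(at$F <= 0)) stop("anisotropy values must be positive")
  if (any(at$theta_deg < 0 | at$theta_deg > 180))
    stop("theta must lie in [0, 180] degrees")
  rF <- sort(unique(at$r_cm)); thF <- sort(unique(at$theta_deg))
  if (nrow(at) != length(rF) * length(thF))
    stop("anisotropy table must be a complete rectangular (r, theta) grid")
  Fm <- matrix(NA_real_, length(rF), length(thF))
  Fm[cbind(match(at$r_cm, rF), match(at$theta_deg, thF))] <- at$F
  if (!any(abs(thF - 90) < 1e-9)) stop("anisotropy table must tabulate theta = 90")
  j90 <- which(abs(thF - 90) < 1e-9)
  if (any(abs(Fm[, j90] - 1) > 1e-9))
    stop("F(r, 90 deg) must equal 1 for all tabulated r (TG-43 normalization)")
  structure(list(L = L_cm, lambda = lambda, mode = mode,
                 mean_energy_mev = mean_energy_mev,
                 g_r = rt$r_cm, g = rt$g, g_log = log(rt$g),
                 F_r = rF, F_th = thF, F_val = Fm),
            class = "source_spec")
}

#' @export
print.source_spec <- function(x, ...) {
  cat("source_spec:", x$mode, "mode, L =", x$L, "cm, Lambda =", x$lambda,
      "cGy/h/U,", length(x$g_r), "radial nodes,",
      length(x$F_r), "x", length(x$F_th), "anisotropy grid\n")
  invisible(x)
}

#' Synthetic unit-test source
#'
#' A point-mode source with `g == 1` and `F == 1` everywhere, so that the
#' TG-43 dose rate reduces to `S_K * Lambda / r^2` exactly.  Used as a
#' self-contained fixture; real consensus datasets load with
#' [read_source_csv()].
#'
#' @param lambda dose-rate constant placeholder (default 1.109 cGy/h/U).
#' @param mode,L_cm geometry mode and active length for line-mode variants.
#' @return A [source_spec()].
#' @export
unit_test_source <- function(lambda = 1.109, mode = "point", L_cm = 0.36) {
  rg <- c(0.25, 0.5, 1, 2, 3, 5, 8, 10)
  th <- c(0, 30, 60, 90, 120, 150, 180)
  aniso <- expand.grid(r_cm = rg, theta_deg = th)
  aniso$F <- 1
  source_spec(
    L_cm = if (mode == "point") 0 else L_cm,
    lambda = lambda,
    radial_table = data.frame(r_cm = rg, g = rep(1, length(rg))),
    anisotropy_table = aniso,
    mode = mode
  )
}

#' Synthetic Ir-192-like source
#'
#' A line-mode source with smooth, synthetic g_L and F tables shaped like a
#' generic Ir-192 HDR source (slowly varying radial function, mild polar
#' anisotropy).  The tables are generated analytically and are NOT consensus
#' data for any commercial source; they exist so the cohort simulation has a
#' realistic line source without external files.
#'
#' @param lambda dose-rate constant, default 1.109 cGy/h/U.
#' @return A [source_spec()].
#' @export
synthetic_ir192_source <- function(lambda = 1.109) {
  r <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 5, 6, 8, 10)
  # smooth attenuation/buildup shape normalized at 1 cm
  shape <- function(r) (1 + 0.012 * r) * exp(-0.006 * r^2)
  g <- shape(r) / shape(1)
  th <- seq(0, 180, by = 10)
  aniso <- expand.grid(r_cm = r, theta_deg = th)
  # mild dip toward the source axis, symmetric, F(r,90)=1
  aniso$F <- 1 - 0.12 * (cos(aniso$theta_deg * pi / 180))^2 *
    (1 - exp(-aniso$r_cm))
  aniso$F[abs(aniso$theta_deg - 90) < 1e-9] <- 1
  source_spec(L_cm = 0.36, lambda = lambda,
              radial_table = data.frame(r_cm = r, g = g),
              anisotropy_table = aniso, mode = "line")
}

#' Load a source characterization from CSV tables
#'
#' Reads the dialect `radial.csv` (header `r_cm,g`), `anisotropy.csv`
#' (header `r_cm,theta_deg,F`) and a metadata JSON with fields `L_cm`,
#' `lambda_cgy_per_h_per_U` and `mode`.
#'
#' @param radial_csv,anisotropy_csv,meta_json file paths.
#' @return A [source_spec()].
#' @export
read_source_csv <- function(radial_csv, anisotropy_csv, meta_json) {
  meta <- jsonlite::read_json(meta_json, simplifyVector = TRUE)
  source_spec(L_cm = meta$L_cm, lambda = meta$lambda_cgy_per_h_per_U,
              radial_table = utils::read.csv(radial_csv),
              anisotropy_table = utils::read.csv(anisotropy_csv),
              mode = meta$mode)
}

#' Single dwell of an HDR stepping source
#'
#' @param position_mm 3-vector, mm.
#' @param axis_mm unit 3-vector, source long-axis direction.
#' @param S_K air-kerma strength in U (1 U = 1 uGy m^2 / h).
#' @return A `dwell_source` object.
#' @export
dwell_source <- function(position_mm, axis_mm, S_K) {
  position_mm <- as.numeric(position_mm); axis_mm <- as.numeric(axis_mm)
  stopifnot(length(position_mm) == 3, length(axis_mm) == 3)
  nrm <- sqrt(sum(axis_mm^2))
  if (abs(nrm - 1) > 1e-9) stop("axis direction must have unit norm")
  if (S_K <= 0) stop("air-kerma strength must be positive")
  structure(list(position = position_mm, axis = axis_mm, S_K = S_K),
            class = "dwell_source")
}

#' TG-43 geometry factor
#'
#' `G_P(r) = 1/r^2` for a point source; for a line source
#' `G_L(r, theta) = beta / (L r sin(theta))` with `beta` the angle subtended
#' by the active line at the field point, and the analytic on-axis limit
#' `1 / (r^2 - L^2/4)`.
#'
#' @param r distance from source center, cm (> 0); vectorized.
#' @param theta_deg polar angle from the source long axis, degrees.
#' @param L active length, cm.
#' @param mode `"line"` or `"point"`.
#' @return Geometry factor in cm^-2.
#' @examples
#' geometry_factor(2, 90, 0, "point")  # 0.25
#' @export
geometry_factor <- function(r, theta_deg = 90, L = 0, mode = c("line", "point")) {
  mode <- match.arg(mode)
  if (any(r <= 0)) stop("geometry factor is singular at r = 0; r must be > 0")
  if (L < 0) stop("active length must be >= 0")
  .cpp_geometry_factor(as.numeric(r), as.numeric(theta_deg), L,
                       mode == "line" && L > 0)
}

#' Radial dose function g_L(r)
#'
#' Log-linear interpolation in r of the tabulated radial dose function
#' (piecewise linear in log g); constant below the first node, last-segment
#' log-linear extrapolation above the last node.
#'
#' @param spec a [source_spec()].
#' @param r distance, cm (> 0); vectorized.
#' @return Dimensionless g_L(r).
#' @export
radial_dose <- function(spec, r) {
  if (any(r <= 0)) stop("r must be positive")
  n <- length(spec$g_r)
  vapply(as.numeric(r), function(ri) {
    if (ri <= spec$g_r[1]) return(spec$g[1])
    if (ri >= spec$g_r[n]) {
      slope <- (spec$g_log[n] - spec$g_log[n - 1]) /
        (spec$g_r[n] - spec$g_r[n - 1])
      return(exp(spec$g_log[n] + slope * (ri - spec$g_r[n])))
    }
    lo <- findInterval(ri, spec$g_r)
    w <- (ri - spec$g_r[lo]) / (spec$g_r[lo + 1] - spec$g_r[lo])
    exp(spec$g_log[lo] * (1 - w) + spec$g_log[lo + 1] * w)
  }, numeric(1))
}

#' 2-D anisotropy function F(r, theta)
#'
#' Bilinear interpolation on the tabulated (r, theta) grid; r is clamped to
#' the tabulated range (nearest-r policy), theta must lie in [0, 180].
#'
#' @param spec a [source_spec()].
#' @param r distance, cm; vectorized.
#' @param theta_deg polar angle, degrees in [0, 180].
#' @return Dimensionless F(r, theta).
#' @export
anisotropy <- function(spec, r, theta_deg) {
  if (any(theta_deg < 0 | theta_deg > 180)) stop("theta must lie in [0, 180] degrees")
  n <- max(length(r), length(theta_deg))
  r <- rep_len(as.numeric(r), n); theta_deg <- rep_len(as.numeric(theta_deg), n)
  rF <- spec$F_r; thF <- spec$F_th; Fm <- spec$F_val
  vapply(seq_len(n), function(k) {
    ri <- min(max(r[k], rF[1]), rF[length(rF)])
    ti <- min(max(theta_deg[k], thF[1]), thF[length(thF)])
    i <- min(max(findInterval(ri, rF), 1), length(rF) - 1)
    j <- min(max(findInterval(ti, thF), 1), length(thF) - 1)
    wr <- if (rF[i + 1] == rF[i]) 0 else (ri - rF[i]) / (rF[i + 1] - rF[i])
    wt <- if (thF[j + 1] == thF[j]) 0 else (ti - thF[j]) / (thF[j + 1] - thF[j])
    Fm[i, j] * (1 - wr) * (1 - wt) + Fm[i + 1, j] * wr * (1 - wt) +
      Fm[i, j + 1] * (1 - wr) * wt + Fm[i + 1, j + 1] * wr * wt
  }, numeric(1))
}

#' TG-43 dose rate from a single dwell
#'
#' `Ddot(r, theta) = S_K * Lambda * G(r, theta)/G(1 cm, 90 deg) * g_L(r)
#'  * F(r, theta)`, evaluated at a field point in patient coordinates (mm).
#'
#' @param spec a [source_spec()].
#' @param dwell a [dwell_source()].
#' @param point_mm field point, mm 3-vector (must differ from the dwell
#'   position).
#' @return Dose rate in cGy/h.
#' @export
dose_rate <- function(spec, dwell, point_mm) {
  d <- as.numeric(point_mm) - dwell$position
  dmm <- sqrt(sum(d^2))
  if (dmm == 0) stop("field point coincides with the dwell position (singular)")
  r <- dmm / 10
  ct <- sum(d * dwell$axis) / dmm
  ct <- min(1, max(-1, ct))
  theta <- acos(ct) * 180 / pi
  G <- geometry_factor(r, theta, spec$L, spec$mode)
  G0 <- geometry_factor(1, 90, spec$L, spec$mode)
  dwell$S_K * spec$lambda * (G / G0) * radial_dose(spec, r) *
    anisotropy(spec, r, theta)
}

#' Write source tables in the CSV dialect
#' @param spec a [source_spec()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_source_csv <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(r_cm = spec$g_r, g = spec$g),
                   file.path(dir, "radial.csv"), row.names = FALSE)
  at <- expand.grid(r_cm = spec$F_r, theta_deg = spec$F_th)
  at$F <- as.vector(spec$F_val)
  utils::write.csv(at, file.path(dir, "anisotropy.csv"), row.names = FALSE)
  jsonlite::write_json(list(L_cm = spec$L, lambda_cgy_per_h_per_U = spec$lambda,
                            mode = spec$mode),
                       file.path(dir, "source_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}
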