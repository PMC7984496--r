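#' Catheter model
#'
#' A catheter is a polyline in patient coordinates (mm) running from skin
#' entry to skin exit, secured with a button at each end.  Free-hand needles
#' are rigid, so catheters generated by [generate_freehand_implant()] are
#' straight; the polyline type allows curvature for completeness.
#'
#' @param id character identifier.
#' @param path_mm n x 3 matrix of polyline vertices, n >= 2, consecutive
#'   points distinct.
#' @param buttons_mm 2 x 3 matrix of button positions; must coincide with
#'   the first and last path points.
#' @return A `catheter` object.
#' @export
catheter <- function(id, path_mm, buttons_mm = path_mm[c(1, nrow(path_mm)), , drop = FALSE]) {
  path_mm <- as.matrix(path_mm)
  stopifnot(ncol(path_mm) == 3, nrow(path_mm) >= 2)
  seg <- diff(path_mm)
  if (any(sqrt(rowSums(seg^2)) == 0)) stop("consecutive path points must be distinct")
  buttons_mm <- as.matrix(buttons_mm)
  if (max(abs(buttons_mm[1, ] - path_mm[1, ])) > 1e-6 ||
      max(abs(buttons_mm[2, ] - path_mm[nrow(path_mm), ])) > 1e-6)
    stop("buttons must coincide with the first and last path points")
  structure(list(id = as.character(id), path = path_mm, buttons = buttons_mm),
            class = "catheter")
}

catheter_length <- function(cath) sum(sqrt(rowSums(diff(cath$path)^2)))

#' Free-hand implant template
#'
#' Parameters of the one- or two-plane free-hand arrangement: parallel
#' catheters at 1.5-2 cm triangular spacing, planes separated in depth, and
#' a minimum catheter depth below the skin of 5 mm.
#'
#' @param n_planes 1 or 2.
#' @param spacing_cm catheter spacing within a plane, cm, in [1.5, 2].
#' @param plane_separation_cm depth separation between planes, cm.
#' @param triangular_offset second-plane lateral offset as a fraction of the
#'   spacing (0.5 = centered triangular geometry).
#' @param min_skin_depth_mm minimum catheter depth below the skin, mm (>= 5).
#' @param allow_spacing_override allow spacing outside [1.5, 2] cm.
#' @return A `freehand_template` object.
#' @export
freehand_template <- function(n_planes = 2, spacing_cm = 2,
                              plane_separation_cm = 1.5,
                              triangular_offset = 0.5,
                              min_skin_depth_mm = 5,
                              allow_spacing_override = FALSE) {
  if (!n_planes %in% c(1, 2)) stop("n_planes must be 1 or 2")
  if (!allow_spacing_override && (spacing_cm < 1.5 || spacing_cm > 2))
    stop("catheter spacing must lie in [1.5, 2] cm (free-hand technique)")
  if (min_skin_depth_mm < 5)
    stop("catheters must not be placed within 5 mm of the skin surface")
  structure(list(n_planes = n_planes, spacing_cm = spacing_cm,
                 plane_separation_cm = plane_separation_cm,
                 triangular_offset = triangular_offset,
                 min_skin_depth_mm = min_skin_depth_mm),
            class = "freehand_template")
}

#' Generate a free-hand implant around a lumpectomy cavity
#'
#' Catheters are straight lines parallel to the y axis (the needle
#' direction), arranged in one or two planes parallel to the (planar) skin
#' surface at z = 0.  Within a plane, catheters tile the lateral footprint
#' of the cavity plus the 2 cm CTV margin at the template spacing; the
#' second (shallower) plane is offset laterally by
#' `triangular_offset * spacing`.  Active dwells later span the cavity plus
#' 2 cm along the catheter axis; the physical catheter extends one
#' retraction margin beyond that on each side.
#'
#' @param cavity_center_mm 3-vector, mm (z = depth below skin).
#' @param cavity_radius_mm cavity radius, mm.
#' @param template a [freehand_template()].
#' @param margin_mm target margin along and across the axis (CTV margin),
#'   default 20 mm.
#' @param tip_margin_mm extra catheter length beyond the active span per
#'   side, default 5 mm.
#' @return List of [catheter()] objects.
#' @export
generate_freehand_implant <- function(cavity_center_mm, cavity_radius_mm,
                                      template = freehand_template(),
                                      margin_mm = 20, tip_margin_mm = 5) {
  cc <- as.numeric(cavity_center_mm)
  r <- cavity_radius_mm
  pitch <- template$spacing_cm * 10
  sep <- template$plane_separation_cm * 10
  # plane depths bracket the cavity center (single plane: through the center)
  depths <- if (template$n_planes == 1) cc[3] else c(cc[3] + sep / 2, cc[3] - sep / 2)
  if (min(depths) < template$min_skin_depth_mm)
    stop(sprintf(paste0("infeasible implant: shallowest plane at %.1f mm is ",
                        "within the %.1f mm minimum skin depth"),
                 min(depths), template$min_skin_depth_mm))
  half_width <- r + margin_mm
  half_len <- r + margin_mm + tip_margin_mm
  n_per_plane <- floor(2 * half_width / pitch) + 1
  caths <- list()
  idx <- 0
  for (p in seq_along(depths)) {
    off <- if (p == 2) template$triangular_offset * pitch else 0
    xs <- cc[1] + (seq_len(n_per_plane) - (n_per_plane + 1) / 2) * pitch + off
    # keep the offset plane inside the same footprint
    xs <- xs[abs(xs - cc[1]) <= half_width + 1e-9]
    for (x in xs) {
      idx <- idx + 1
      path <- rbind(c(x, cc[2] - half_len, depths[p]),
                    c(x, cc[2] + half_len, depths[p]))
      caths[[idx]] <- catheter(sprintf("cath%02d", idx), path)
    }
  }
  caths
}

#' Dwell positions along a catheter
#'
#' Equally spaced (by arc length) source stops, retracted from both catheter
#' ends; the dwell axis is the local path tangent.
#'
#' @param cath a [catheter()].
#' @param step_mm dwell step, mm (> 0), default 5 (typical afterloader).
#' @param retraction_mm inactive length at each end, mm, default 5.
#' @return List with `positions` (n x 3 mm) and `axes` (n x 3 unit tangents);
#'   n = `floor((arclength - 2 * retraction) / step) + 1`.
#' @export
dwell_positions <- function(cath, step_mm = 5, retraction_mm = 5) {
  if (step_mm <= 0) stop("dwell step must be positive")
  len <- catheter_length(cath)
  if (len <= 2 * retraction_mm)
    stop("catheter arc length must exceed twice the retraction")
  n <- floor((len - 2 * retraction_mm) / step_mm) + 1
  s <- retraction_mm + (seq_len(n) - 1) * step_mm
  seg <- diff(cath$path)
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  pos <- matrix(NA_real_, n, 3)
  ax <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    j <- findInterval(s[i], cum, rightmost.closed = TRUE)
    j <- min(j, length(seglen))
    w <- (s[i] - cum[j]) / seglen[j]
    pos[i, ] <- cath$path[j, ] + w * seg[j, ]
    ax[i, ] <- seg[j, ] / seglen[j]
  }
  list(positions = pos, axes = ax)
}

#' HDR implant plan
#'
#' Catheters plus the afterloader's dwell sequence and the prescription.
#' Dwell positions/axes are derived from the catheters at construction.
#'
#' @param catheters list of [catheter()].
#' @param dwell_step_mm dwell step, mm.
#' @param retraction_mm tip retraction, mm.
#' @param dwell_times_s per-dwell times in seconds (recycled if length 1);
#'   default 1 s each (relative weights before optimization).
#' @param S_K air-kerma strength, U.
#' @param prescription_cgy prescribed dose per fraction, cGy (340 default).
#' @param n_fractions number of fractions (10 default).
#' @return An `implant_plan` object with `dwells` (positions, axes,
#'   catheter index) and `times_s`.
#' @export
implant_plan <- function(catheters, dwell_step_mm = 5, retraction_mm = 5,
                         dwell_times_s = 1, S_K = 40000,
                         prescription_cgy = 340, n_fractions = 10) {
  if (prescription_cgy <= 0) stop("prescription must be positive")
  if (dwell_step_mm <= 0) stop("dwell step must be positive")
  if (S_K <= 0) stop("air-kerma strength must be positive")
  dp <- lapply(catheters, dwell_positions, step_mm = dwell_step_mm,
               retraction_mm = retraction_mm)
  pos <- do.call(rbind, lapply(dp, `[[`, "positions"))
  ax <- do.call(rbind, lapply(dp, `[[`, "axes"))
  cidx <- rep(seq_along(catheters), vapply(dp, function(d) nrow(d$positions), 1L))
  times <- rep_len(as.numeric(dwell_times_s), nrow(pos))
  if (any(times < 0)) stop("dwell times must be >= 0")
  structure(list(catheters = catheters, dwell_step_mm = dwell_step_mm,
                 retraction_mm = retraction_mm,
                 dwells = list(positions = pos, axes = ax, catheter = cidx),
                 times_s = times, S_K = S_K,
                 prescription_cgy = prescription_cgy,
                 n_fractions = n_fractions),
            class = "implant_plan")
}

#' @export
print.implant_plan <- function(x, ...) {
  cat("implant_plan:", length(x$catheters), "catheters,",
      nrow(x$dwells$positions), "dwells, PD =", x$prescription_cgy,
      "cGy/fr x", x$n_fractions, "fractions, S_K =", x$S_K, "U\n")
  invisible(x)
}

#' Two-catheter phantom setup
#'
#' The control experiment: two parallel straight catheters 2 cm apart at a
#' fixed depth below a planar phantom surface (z = 0), with either surface
#' tally points or a film plane perpendicular to the catheters.
#'
#' @param variant `"surface_points"` or `"perpendicular_film"`.
#' @param catheter_depth_mm catheter depth below the surface, mm
#'   (5/10/15/20 in the experiments).
#' @param catheter_separation_cm separation, cm (2 in the experiment).
#' @param film_plane_depth_cm catheter depth used by the perpendicular-film
#'   variant, cm (2 in the experiment).
#' @param active_length_mm active dwell span per catheter, mm.
#' @return A `phantom_setup` object.
#' @export
phantom_setup <- function(variant = c("surface_points", "perpendicular_film"),
                          catheter_depth_mm = 10, catheter_separation_cm = 2,
                          film_plane_depth_cm = 2, active_length_mm = 100) {
  variant <- match.arg(variant)
  if (catheter_depth_mm <= 0) stop("catheter depth must be positive")
  if (catheter_separation_cm <= 0) stop("catheter separation must be positive")
  structure(list(variant = variant, catheter_depth_mm = catheter_depth_mm,
                 catheter_separation_cm = catheter_separation_cm,
                 film_plane_depth_cm = film_plane_depth_cm,
                 active_length_mm = active_length_mm),
            class = "phantom_setup")
}

#' Build the two-catheter phantom plan
#'
#' @param setup a [phantom_setup()].
#' @param dwell_step_mm dwell step, mm.
#' @param S_K air-kerma strength, U.
#' @param prescription_cgy prescription per fraction, cGy.
#' @return An [implant_plan()] with two parallel catheters at the setup
#'   depth, uniform dwell times.
#' @export
build_phantom_plan <- function(setup, dwell_step_mm = 5, S_K = 40000,
                               prescription_cgy = 340) {
  d <- if (setup$variant == "perpendicular_film")
    setup$film_plane_depth_cm * 10 else setup$catheter_depth_mm
  half_sep <- setup$catheter_separation_cm * 10 / 2
  half_len <- setup$active_length_mm / 2 + 5
  mk <- function(id, x) catheter(id, rbind(c(x, -half_len, d), c(x, half_len, d)))
  implant_plan(list(mk("phantom1", -half_sep), mk("phantom2", half_sep)),
               dwell_step_mm = dwell_step_mm, retraction_mm = 5,
               dwell_times_s = 1, S_K = S_K,
               prescription_cgy = prescription_cgy)
}

#' Export / import the dwell-table CSV dialect
#'
#' Columns: `catheter_id,dwell_index,x_mm,y_mm,z_mm,tx,ty,tz,time_s`.
#'
#' @param plan an [implant_plan()].
#' @param path CSV file.
#' @return `write_dwell_csv` returns `path` invisibly; `read_dwell_csv`
#'   returns the dwell table as a data.frame.
#' @export
write_dwell_csv <- function(plan, path) {
  dw <- plan$dwells
  ids <- vapply(plan$catheters, `[[`, "", "id")
  df <- data.frame(catheter_id = ids[dw$catheter],
                   dwell_index = stats::ave(seq_along(dw$catheter),
                                            dw$catheter, FUN = seq_along),
                   x_mm = dw$positions[, 1], y_mm = dw$positions[, 2],
                   z_mm = dw$positions[, 3],
                   tx = dw$axes[, 1], ty = dw$axes[, 2], tz = dw$axes[, 3],
                   time_s = plan$times_s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dwell_csv
#' @export
read_dwell_csv <- function(path) utils::read.csv(path)

#' Plan JSON round-trip
#'
#' Serializes prescription, source strength, dwell geometry and times.
#'
#' @param plan an [implant_plan()].
#' @param path JSON file.
#' @return `write_plan_json` returns `path` invisibly; `read_plan_json`
#'   rebuilds the [implant_plan()].
#' @export
write_plan_json <- function(plan, path) {
  obj <- list(
    prescription_cgy = plan$prescription_cgy, n_fractions = plan$n_fractions,
    S_K = plan$S_K, dwell_step_mm = plan$dwell_step_mm,
    retraction_mm = plan$retraction_mm,
    catheters = lapply(plan$catheters, function(ca)
      list(id = ca$id, path = apply(ca$path, 1, as.numeric, simplify = FALSE))),
    times_s = plan$times_s)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  caths <- lapply(obj$catheters, function(ca)
    catheter(ca$id, do.call(rbind, lapply(ca$path, unlist))))
  implant_plan(caths, dwell_step_mm = obj$dwell_step_mm,
               retraction_mm = obj$retraction_mm,
               dwell_times_s = unlist(obj$times_s), S_K = obj$S_K,
               prescription_cgy = obj$prescription_cgy,
               n_fractions = obj$n_fractions)
}
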