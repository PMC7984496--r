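#' Isotropic Euclidean margin expansion of a mask
#'
#' Expands a voxel mask by a Euclidean margin: the output contains every
#' voxel whose center lies within `margin_mm` of some voxel center of the
#' input set (exact squared distance transform, anisotropic spacing).
#'
#' @param mask logical vector/array over the grid (nonempty).
#' @param margin_mm margin, mm (>= 0); 0 returns the input.
#' @param grid a [voxel_grid()].
#' @return Logical array of dim `grid$shape`.
#' @export
expand_margin <- function(mask, margin_mm, grid) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("cannot expand an empty mask")
  if (margin_mm < 0) stop("margin must be >= 0")
  if (margin_mm == 0) return(as_mask_array(mask, grid))
  d2 <- .cpp_edt_sq(mask, grid$shape, grid$spacing)
  as_mask_array(d2 <= margin_mm^2 + 1e-9, grid)
}

#' Structure set for one case
#'
#' Boolean masks on a common grid with the nesting invariant
#' tumor_bed subset-of CTV subset-of PTV enforced, and the skin region
#' confined to 0 <= z <= 3 mm.
#'
#' @param grid a [voxel_grid()].
#' @param masks named list of logical arrays; recognised names:
#'   `tumor_bed`, `ctv`, `ptv`, `breast`, `skin_region`, `ribs`, `lung`,
#'   `heart`, `body`.
#' @return A `structure_set` object.
#' @export
structure_set <- function(grid, masks) {
  for (nm in names(masks)) {
    if (length(masks[[nm]]) != n_voxels(grid))
      stop("mask '", nm, "' does not match the grid")
    masks[[nm]] <- as_mask_array(as.logical(masks[[nm]]), grid)
  }
  nest <- function(a, b)
    if (!is.null(masks[[a]]) && !is.null(masks[[b]]) &&
        any(masks[[a]] & !masks[[b]]))
      stop("nesting violated: ", a, " must be contained in ", b)
  nest("tumor_bed", "ctv"); nest("ctv", "ptv")
  if (!is.null(masks$skin_region)) {
    z <- grid_coords(grid)[, 3]
    if (any(masks$skin_region & (z < -1e-9 | z > 3 + 1e-9)))
      stop("skin region must be confined to 0 <= z <= 3 mm")
  }
  structure(list(grid = grid, masks = masks), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, function(m) mask_volume_cc(m, x$grid), numeric(1))
  cat("structure_set on", paste(x$grid$shape, collapse = "x"), "grid:\n")
  for (nm in names(v)) cat(sprintf("  %-12s %8.2f cc\n", nm, v[nm]))
  invisible(x)
}

#' Skin-region specification
#'
#' The TPS skin-dose region: a quadrilateral footprint on the skin whose
#' long sides parallel the skin projections of the outermost catheters at
#' 1 cm lateral distance and whose short sides are the outermost button
#' edges, extruded from the skin surface to a 3 mm inner margin.
#'
#' @param lateral_margin_cm long-side distance from the outermost catheter
#'   projections, cm (default 1).
#' @param depth_mm inner margin from the skin surface, mm (default 3).
#' @return A `skin_region_spec` object.
#' @export
skin_region_spec <- function(lateral_margin_cm = 1, depth_mm = 3) {
  structure(list(lateral_margin_cm = lateral_margin_cm, depth_mm = depth_mm),
            class = "skin_region_spec")
}

#' Build the skin-region mask
#'
#' Catheters are projected onto the skin plane (z = 0).  The footprint spans
#' the extreme button positions along the mean catheter direction (short
#' sides) and the outermost catheter projections plus the lateral margin
#' across it (long sides); a single catheter degenerates to a strip of twice
#' the lateral margin.  The mask is the footprint extruded over
#' 0 <= z <= depth.
#'
#' @param catheters list of [catheter()] (assumed parallel to the y axis
#'   after projection; the general direction is taken from the first
#'   catheter).
#' @param grid a [voxel_grid()].
#' @param spec a [skin_region_spec()].
#' @return Logical array of dim `grid$shape`.
#' @export
build_skin_region <- function(catheters, grid, spec = skin_region_spec()) {
  if (length(catheters) < 1) stop("at least one catheter required")
  buttons <- do.call(rbind, lapply(catheters, `[[`, "buttons"))
  # skin projection: drop depth
  proj <- buttons[, 1:2, drop = FALSE]
  axis2d <- diff(catheters[[1]]$path[c(1, nrow(catheters[[1]]$path)), 1:2])
  nrm <- sqrt(sum(axis2d^2))
  if (nrm < 1e-9) stop("catheter has no skin projection (vertical path)")
  axis2d <- axis2d / nrm
  perp2d <- c(-axis2d[2], axis2d[1])
  along <- proj %*% as.numeric(axis2d)
  across <- proj %*% as.numeric(perp2d)
  lat <- spec$lateral_margin_cm * 10
  co <- grid_coords(grid)
  a <- co[, 1:2] %*% as.numeric(axis2d)
  b <- co[, 1:2] %*% as.numeric(perp2d)
  inside <- a >= min(along) - 1e-9 & a <= max(along) + 1e-9 &
    b >= min(across) - lat - 1e-9 & b <= max(across) + lat + 1e-9 &
    co[, 3] >= -1e-9 & co[, 3] <= spec$depth_mm + 1e-9
  as_mask_array(inside, grid)
}

#' Involved-ribs mask
#'
#' The rib volume just beneath the skin region: intersection of the rib
#' structure with the vertical prism under the skin-region footprint.
#'
#' @param skin_mask logical array from [build_skin_region()].
#' @param rib_mask logical array for the rib slab.
#' @param grid a [voxel_grid()].
#' @return Logical array (possibly empty).
#' @export
involved_ribs <- function(skin_mask, rib_mask, grid) {
  fp <- apply(as_mask_array(skin_mask, grid), c(1, 2), any)  # footprint in (x, y)
  prism <- array(rep(as.vector(fp), grid$shape[3]), dim = grid$shape)
  as_mask_array(prism & as_mask_array(rib_mask, grid), grid)
}

#' Film measurement point on the skin
#'
#' The marked skin point: on the skin surface (z = 0), at a perpendicular
#' distance from the midpoint (by arc length) of the surgical scar, on the
#' side selected by `side`.
#'
#' @param scar_mm n x 3 polyline on the skin (z = 0), positive length.
#' @param offset_mm perpendicular offset, mm (default 20; the clinical mark
#'   is 2 cm from the scar).
#' @param side +1 or -1, which side of the scar.
#' @return A 3-vector (mm) with z = 0.
#' @export
skin_measurement_point <- function(scar_mm, offset_mm = 20, side = 1) {
  scar_mm <- as.matrix(scar_mm)
  seg <- diff(scar_mm)
  seglen <- sqrt(rowSums(seg^2))
  len <- sum(seglen)
  if (len <= 0) stop("scar must have positive length")
  cum <- c(0, cumsum(seglen))
  smid <- len / 2
  j <- findInterval(smid, cum, rightmost.closed = TRUE)
  j <- min(j, length(seglen))
  w <- (smid - cum[j]) / seglen[j]
  mid <- scar_mm[j, ] + w * seg[j, ]
  tang <- seg[j, 1:2] / sqrt(sum(seg[j, 1:2]^2))
  n2 <- c(-tang[2], tang[1]) * sign(side)
  c(mid[1] + offset_mm * n2[1], mid[2] + offset_mm * n2[2], 0)
}

#' Synthetic breast/chest anatomy
#'
#' Builds the generator's minimal geometry on a voxel grid: the ipsilateral
#' breast modeled as an ellipsoidal dome (half-ellipsoid) whose base sits on
#' the chest wall at depth `z = breast_height_mm` and whose apex touches the
#' skin plane z = 0 above the implant (where the skin is locally planar);
#' a 20 mm chest-wall slab under the breast whose first 5 mm is the rib
#' layer; a 45 mm lung slab beyond the chest wall, with the medial part of
#' that slab (x < -30 mm) taken as heart.  The spherical tumor bed, CTV
#' (cavity + 2 cm) and PTV (CTV + 5 mm) are derived analytically and
#' cropped to breast tissue between the skin and pectoralis crops.
#'
#' @param grid a [voxel_grid()].
#' @param breast_height_mm dome height, mm.
#' @param cavity_center_mm cavity center (mm; z = depth).
#' @param cavity_radius_mm cavity radius, mm.
#' @param ctv_margin_mm CTV margin (default 20).
#' @param ptv_margin_mm PTV margin beyond CTV (default 5).
#' @param skin_crop_mm CTV/PTV crop below the skin surface (default 10).
#' @param chest_crop_mm CTV/PTV crop above the chest wall (default 6).
#' @param breast_lateral_factor dome lateral semi-axis as a multiple of its
#'   height (default 1.6).
#' @param oar_gap_mm chest-wall thickness separating breast base from the
#'   lung/heart slab, mm (default 25; the first 5 mm is the rib layer).
#' @param oar_slab_mm thickness of the lung/heart slab, mm (default 45).
#' @return List: a [structure_set()] plus `cropped_fraction` (fraction of
#'   the uncropped PTV sphere removed by the tissue crop).
#' @export
synthetic_anatomy <- function(grid, breast_height_mm, cavity_center_mm,
                              cavity_radius_mm, ctv_margin_mm = 20,
                              ptv_margin_mm = 5, skin_crop_mm = 10,
                              chest_crop_mm = 6, breast_lateral_factor = 1.6,
                              oar_gap_mm = 25, oar_slab_mm = 45) {
  H <- breast_height_mm
  a <- breast_lateral_factor * H
  co <- grid_coords(grid)
  z <- co[, 3]
  # half-ellipsoid dome, apex at the origin, base on the chest wall z = H
  edist <- sqrt((co[, 1] / a)^2 + (co[, 2] / a)^2 + ((z - H) / H)^2)
  breast <- edist <= 1 & z >= 0 & z <= H
  ribs <- z > H & z <= H + 5
  oar_z <- z > H + oar_gap_mm & z <= H + oar_gap_mm + oar_slab_mm
  heart <- oar_z & co[, 1] < -30
  lung <- oar_z & co[, 1] >= -30
  body <- breast | z > H  # dome plus everything below the chest wall
  dc <- sqrt((co[, 1] - cavity_center_mm[1])^2 +
             (co[, 2] - cavity_center_mm[2])^2 +
             (z - cavity_center_mm[3])^2)
  # CTV/PTV are cropped to breast tissue between the skin and chest crops
  tissue <- edist <= 1 & z >= skin_crop_mm & z <= H - chest_crop_mm
  tumor_bed <- dc <= cavity_radius_mm & tissue
  ctv <- dc <= cavity_radius_mm + ctv_margin_mm & tissue
  ptv <- dc <= cavity_radius_mm + ctv_margin_mm + ptv_margin_mm & tissue
  vox <- voxel_volume_cc(grid)
  uncropped <- sum(dc <= cavity_radius_mm + ctv_margin_mm + ptv_margin_mm) * vox
  cropped_fraction <- if (uncropped > 0) 1 - sum(ptv) * vox / uncropped else 0
  ss <- structure_set(grid, list(
    tumor_bed = tumor_bed, ctv = ctv, ptv = ptv, breast = breast,
    ribs = ribs, lung = lung, heart = heart, body = body))
  list(structures = ss, cropped_fraction = cropped_fraction)
}
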