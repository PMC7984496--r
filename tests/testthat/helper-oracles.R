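# Independent oracles used across the test files.  These deliberately
# re-derive the TG-43 factors from first principles (plain R arithmetic on
# the tables) rather than calling the package's evaluation path.

# line-source geometry factor via the subtended-angle definition
oracle_geom_line <- function(r_cm, theta_deg, L_cm) {
  th <- theta_deg * pi / 180
  x <- r_cm * sin(th); z <- r_cm * cos(th)
  if (abs(sin(th)) < 1e-7) return(1 / (r_cm^2 - L_cm^2 / 4))
  v1 <- c(-x, -L_cm / 2 - z); v2 <- c(-x, L_cm / 2 - z)
  beta <- abs(atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)))
  beta / (L_cm * r_cm * sin(th))
}

# quadrature reference: G_L = (1/L) * integral dl / |p - l|^2
oracle_geom_quadrature <- function(r_cm, theta_deg, L_cm) {
  th <- theta_deg * pi / 180
  x <- r_cm * sin(th); z <- r_cm * cos(th)
  f <- function(l) 1 / (x^2 + (z - l)^2)
  stats::integrate(f, -L_cm / 2, L_cm / 2, rel.tol = 1e-12)$value / L_cm
}

# log-linear radial dose interpolation, written independently
oracle_gL <- function(spec, r) {
  rt <- spec$g_r; lg <- log(spec$g)
  if (r <= rt[1]) return(spec$g[1])
  n <- length(rt)
  if (r >= rt[n]) {
    sl <- (lg[n] - lg[n - 1]) / (rt[n] - rt[n - 1])
    return(exp(lg[n] + sl * (r - rt[n])))
  }
  i <- max(which(rt <= r))
  w <- (r - rt[i]) / (rt[i + 1] - rt[i])
  exp((1 - w) * lg[i] + w * lg[i + 1])
}

# bilinear anisotropy interpolation, written independently
oracle_F <- function(spec, r, th) {
  rF <- spec$F_r; tF <- spec$F_th; Fm <- spec$F_val
  r <- min(max(r, rF[1]), rF[length(rF)])
  th <- min(max(th, tF[1]), tF[length(tF)])
  i <- min(max(max(which(rF <= r)), 1), length(rF) - 1)
  j <- min(max(max(which(tF <= th)), 1), length(tF) - 1)
  wr <- (r - rF[i]) / (rF[i + 1] - rF[i])
  wt <- (th - tF[j]) / (tF[j + 1] - tF[j])
  Fm[i, j] * (1 - wr) * (1 - wt) + Fm[i + 1, j] * wr * (1 - wt) +
    Fm[i, j + 1] * (1 - wr) * wt + Fm[i + 1, j + 1] * wr * wt
}

# single-dwell TG-43 dose rate composed term by term
oracle_dose_rate <- function(spec, pos_mm, axis, SK, point_mm) {
  d <- point_mm - pos_mm
  dmm <- sqrt(sum(d^2))
  r <- dmm / 10
  th <- acos(min(1, max(-1, sum(d * axis) / dmm))) * 180 / pi
  G <- if (spec$mode == "line" && spec$L > 0)
    oracle_geom_line(r, th, spec$L) else 1 / r^2
  G0 <- if (spec$mode == "line" && spec$L > 0)
    oracle_geom_line(1, 90, spec$L) else 1
  SK * spec$lambda * (G / G0) * oracle_gL(spec, r) * oracle_F(spec, r, th)
}

# naive per-voxel, per-dwell double loop over a grid (cGy per fraction)
oracle_dose_grid <- function(plan, spec, grid) {
  pts <- grid_coords(grid)
  out <- numeric(nrow(pts))
  pos <- plan$dwells$positions; ax <- plan$dwells$axes
  for (i in seq_len(nrow(pts))) {
    acc <- 0
    for (k in seq_len(nrow(pos))) {
      acc <- acc + oracle_dose_rate(spec, pos[k, ], ax[k, ], plan$S_K,
                                    pts[i, ]) * plan$times_s[k] / 3600
    }
    out[i] <- acc
  }
  array(out, dim = grid$shape)
}

# brute-force cumulative DVH count at given edges
oracle_dvh_counts <- function(dose_values, mask, edges) {
  d <- as.numeric(dose_values)[as.logical(mask)]
  vapply(edges, function(e) sum(d >= e), numeric(1))
}

# random rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# two-catheter test plan with a handful of dwells
small_test_plan <- function(n_dwell_per = 3, S_K = 40000) {
  len <- (n_dwell_per - 1) * 5 + 10
  c1 <- catheter("a", rbind(c(-10, -len / 2, 15), c(-10, len / 2, 15)))
  c2 <- catheter("b", rbind(c(10, -len / 2, 15), c(10, len / 2, 15)))
  implant_plan(list(c1, c2), dwell_times_s = 10, S_K = S_K)
}
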