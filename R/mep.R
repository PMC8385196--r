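#' Generate a 3D motor-endplate (MEP) distribution with ground truth
#'
#' Builds a muscle occupancy grid and an endplate density field on it, then
#' samples endplate points i.i.d. from that density. Two stylized lamellar
#' shapes are provided, matching the qualitative anatomy of the two muscles:
#'
#' * `m_sheet` (gastrocnemius): a curved lamellar band. Its depth below the
#'   local muscle surface and its proximo-distal position are both modulated
#'   by a two-humped ("M") profile across the medio-lateral axis, with
#'   Gaussian thickness and lateral width. The band of endplates visible on
#'   the muscle surface is the same curve shifted proximally by
#'   `surface_offset_um`: with obliquely staggered pennate fibers the
#'   superficial-fiber endplates that surface staining shows do not sit
#'   directly above the deep lamellar mass, which is precisely the
#'   information a surface-guided (2D) injection is missing.
#' * `triangular_pyramid` (tibialis anterior): density concentrated on three
#'   oblique planar faces that descend from three shallow base vertices to a
#'   single deep apex.
#'
#' `shape_params` (all micrometres unless noted), with defaults:
#' * m_sheet: `depth_offset_um = 1200` (sheet depth below the surface at the
#'   "M" valleys), `depth_amplitude_um = 300` (extra depth at the humps, so
#'   the sheet spans 1.2-1.5 mm below the surface), `half_thickness_um = 250`,
#'   `band_amplitude_um = 3000` (proximo-distal excursion of the "M" curve),
#'   `band_half_width_um = 2000` (lateral half-width of the band),
#'   `surface_offset_um = 1500` (stagger between the surface-visible band and
#'   the deep mass).
#' * triangular_pyramid: `apex_depth_um = 1400`, `base_depth_um = 700`,
#'   `base_radius_frac = 0.6` (base-vertex lateral offset as a fraction of
#'   the lateral semi-extents), `half_thickness_um = 200`.
#'
#' The `half_thickness_um` is the nominal half-width of the lamella: the
#' Gaussian depth profile uses `sigma = half_thickness_um / 2.5`, so about
#' 99% of sampled endplates lie within one half-thickness of the sheet/face
#' surface.
#'
#' @param muscle_kind `"gastrocnemius"` or `"tibialis_anterior"`.
#' @param shape_params named list overriding the defaults above.
#' @param n_points number of endplate points to sample (>= 1).
#' @param seed integer seed; identical calls are bit-identical.
#' @param voxel_size_um grid resolution passed to [muscle_geometry()].
#' @param geometry optional pre-built [muscle_geometry()] (must match
#'   `muscle_kind`).
#' @return an object of class `mep_scene`: list with `geometry`
#'   ([muscle_geometry()]) and `mep` (class `mep_map`: `density` 3D array
#'   integrating to 1 over the mask, `points` n x 3 matrix of (depth, row,
#'   col) micrometre coordinates, `shape_kind`, `params`).
#' @export
#' @examples
#' sc <- generate_mep_map("tibialis_anterior", n_points = 100, seed = 1,
#'                        voxel_size_um = 200)
#' nrow(sc$mep$points)
generate_mep_map <- function(muscle_kind = c("gastrocnemius", "tibialis_anterior"),
                             shape_params = list(),
                             n_points = 2000,
                             seed = 1,
                             voxel_size_um = 100,
                             geometry = NULL) {
  muscle_kind <- match.arg(muscle_kind)
  if (!is.numeric(n_points) || n_points < 1)
    stop_motomap("`n_points` must be >= 1")
  n_points <- as.integer(n_points)
  if (is.null(geometry)) {
    geometry <- muscle_geometry(muscle_kind, voxel_size_um = voxel_size_um)
  } else if (!identical(geometry$muscle_kind, muscle_kind)) {
    stop_motomap("`geometry` was built for a different muscle_kind")
  }
  shape_kind <- switch(muscle_kind,
    gastrocnemius     = "m_sheet",
    tibialis_anterior = "triangular_pyramid")
  params <- mep_shape_defaults(shape_kind)
  bad <- setdiff(names(shape_params), names(params))
  if (length(bad))
    stop_motomap("unknown shape_params: ", paste(bad, collapse = ", "))
  params[names(shape_params)] <- shape_params
  if (params$half_thickness_um <= 0)
    stop_motomap("half_thickness_um must be positive")

  dens <- switch(shape_kind,
    m_sheet            = density_m_sheet(geometry, params),
    triangular_pyramid = density_pyramid(geometry, params))
  dens$density[!geometry$mask] <- 0
  tot <- sum(dens$density)
  if (tot <= 0) stop_motomap("degenerate shape parameters: density vanished")
  vox_vol <- geometry$voxel_size_um^3
  density <- dens$density / (tot * vox_vol)   # integrates to 1 over the mask

  points <- with_seed(seed, {
    p <- as.vector(dens$density)
    vox <- sample.int(length(p), n_points, replace = TRUE, prob = p)
    ai <- arrayInd(vox, dim(geometry$mask))
    jit <- matrix(runif(3L * n_points), ncol = 3)
    (ai - 1L + jit) * geometry$voxel_size_um
  })
  colnames(points) <- c("depth_um", "row_um", "col_um")

  mep <- structure(
    list(density = density, points = points, shape_kind = shape_kind,
         params = params, surface_um = dens$surface_um,
         sheet_depth_um = dens$sheet_depth_um),
    class = "mep_map")
  structure(list(geometry = geometry, mep = mep), class = "mep_scene")
}

mep_shape_defaults <- function(shape_kind) {
  switch(shape_kind,
    m_sheet = list(depth_offset_um = 1200, depth_amplitude_um = 300,
                   half_thickness_um = 250, band_amplitude_um = 3000,
                   band_half_width_um = 2000, surface_offset_um = 1500),
    triangular_pyramid = list(apex_depth_um = 1400, base_depth_um = 700,
                              base_radius_frac = 0.6,
                              half_thickness_um = 200))
}

# Curved lamellar band. With u the normalized medio-lateral position across
# the muscle and M(u) = 0.5 - 0.5 cos(4 pi u) (two humps, the "M"):
#   * the band centre runs along row r_band(u) = r0 + band_amplitude*(M-1/2),
#     with Gaussian lateral half-width band_half_width_um;
#   * the sheet depth below the local surface is depth_offset + depth
#     amplitude * M(u) (a ridged mid-depth surface).
# The band of endplates visible on the muscle surface is the same curve
# shifted proximally by surface_offset_um: with obliquely staggered pennate
# fibers the superficial-fiber endplates (the only ones surface staining
# shows) do not sit directly above the deep lamellar mass. m_sheet_curves()
# exposes both curves.
density_m_sheet <- function(geometry, params) {
  vs <- geometry$voxel_size_um
  d  <- dim(geometry$mask)
  surf <- surface_depth_map(geometry)
  crv <- m_sheet_curves(geometry, params)
  u <- matrix(crv$u_of_col, d[2], d[3], byrow = TRUE)
  mshape <- 0.5 - 0.5 * cos(4 * pi * u)
  sheet <- surf + params$depth_offset_um + params$depth_amplitude_um * mshape
  r_band <- matrix(crv$band_row_of_col, d[2], d[3], byrow = TRUE)
  r_um <- matrix(index_to_center_um(seq_len(d[2]), vs), d[2], d[3])
  sig_b <- params$band_half_width_um / 2.5
  lateral <- exp(-((r_um - r_band)^2) / (2 * sig_b^2))
  sigma <- params$half_thickness_um / 2.5
  zc <- index_to_center_um(seq_len(d[1]), vs)
  sheet3 <- aperm(array(sheet, c(d[2], d[3], d[1])), c(3, 1, 2))
  lat3 <- aperm(array(lateral, c(d[2], d[3], d[1])), c(3, 1, 2))
  z3 <- array(zc, d)
  dens <- exp(-((z3 - sheet3)^2) / (2 * sigma^2)) * lat3
  dens[is.na(dens)] <- 0
  list(density = dens, surface_um = surf, sheet_depth_um = sheet)
}

# per-column band parameters of the m_sheet, in grid units
m_sheet_curves <- function(geometry, params) {
  d <- dim(geometry$mask)
  vs <- geometry$voxel_size_um
  occ_col <- which(apply(geometry$mask, 3, any))
  c_lo <- min(occ_col); c_hi <- max(occ_col)
  u <- clamp((seq_len(d[3]) - c_lo) / max(1L, c_hi - c_lo), 0, 1)
  mshape <- 0.5 - 0.5 * cos(4 * pi * u)
  r0 <- d[2] * vs / 2
  band_row <- r0 + params$band_amplitude_um * (mshape - 0.5)
  list(u_of_col = u, band_row_of_col = band_row,
       surface_row_of_col = band_row + params$surface_offset_um,
       col_um = index_to_center_um(seq_len(d[3]), vs),
       col_occupied = seq_len(d[3]) >= c_lo & seq_len(d[3]) <= c_hi)
}

# Three planar faces from shallow base vertices B1..B3 down to a deep apex A.
density_pyramid <- function(geometry, params) {
  vs <- geometry$voxel_size_um
  d  <- dim(geometry$mask)
  surf <- surface_depth_map(geometry)
  ctr_rc <- dim(geometry$mask)[2:3] * vs / 2
  semi <- geometry$extent_um[2:3] / 2 * 0.98
  at_surf <- function(r_um, c_um) {
    ri <- clamp(um_to_index(r_um, vs), 1L, d[2])
    ci <- clamp(um_to_index(c_um, vs), 1L, d[3])
    s <- surf[ri, ci]
    if (is.na(s)) s <- min(surf, na.rm = TRUE)
    s
  }
  apex <- c(at_surf(ctr_rc[1], ctr_rc[2]) + params$apex_depth_um,
            ctr_rc[1], ctr_rc[2])
  ang <- pi / 2 + c(0, 2, 4) * pi / 3
  base <- t(vapply(ang, function(a) {
    r_um <- ctr_rc[1] + params$base_radius_frac * semi[1] * cos(a)
    c_um <- ctr_rc[2] + params$base_radius_frac * semi[2] * sin(a)
    c(at_surf(r_um, c_um) + params$base_depth_um, r_um, c_um)
  }, numeric(3)))
  sigma <- params$half_thickness_um / 2.5

  zc <- index_to_center_um(seq_len(d[1]), vs)
  rc <- index_to_center_um(seq_len(d[2]), vs)
  cc <- index_to_center_um(seq_len(d[3]), vs)
  P <- cbind(rep(zc, times = d[2] * d[3]),
             rep(rep(rc, each = d[1]), times = d[3]),
             rep(cc, each = d[1] * d[2]))
  dens <- numeric(nrow(P))
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  for (pr in pairs) {
    A <- apex; B1 <- base[pr[1], ]; B2 <- base[pr[2], ]
    e1 <- B1 - A; e2 <- B2 - A
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n <- n / sqrt(sum(n^2))
    W <- sweep(P, 2, A)
    dist <- abs(W %*% n)
    # barycentric footprint via the Gram system
    g11 <- sum(e1 * e1); g12 <- sum(e1 * e2); g22 <- sum(e2 * e2)
    det <- g11 * g22 - g12^2
    w1 <- W %*% e1; w2 <- W %*% e2
    uu <- (g22 * w1 - g12 * w2) / det
    vv <- (g11 * w2 - g12 * w1) / det
    m <- 0.05
    inside <- uu >= -m & vv >= -m & (uu + vv) <= 1 + m
    dens <- dens + inside * exp(-(dist^2) / (2 * sigma^2))
  }
  list(density = array(dens, d), surface_um = surf,
       sheet_depth_um = NULL)
}

#' Distance from each MEP point to the nominal lamella surface
#'
#' For the `m_sheet` shape, the unsigned depth-axis distance from each sampled
#' point to the sheet surface at its (row, col) position. Used to check that
#' the sampler honours the stated half-thickness.
#'
#' @param scene a [generate_mep_map()] result with `shape_kind = "m_sheet"`.
#' @return numeric vector of distances in micrometres.
#' @export
mep_sheet_distance <- function(scene) {
  stopifnot(inherits(scene, "mep_scene"))
  mep <- scene$mep
  if (!identical(mep$shape_kind, "m_sheet"))
    stop_motomap("sheet distance is defined for the m_sheet shape only")
  vs <- scene$geometry$voxel_size_um
  d <- dim(scene$geometry$mask)
  ri <- clamp(um_to_index(mep$points[, 2], vs), 1L, d[2])
  ci <- clamp(um_to_index(mep$points[, 3], vs), 1L, d[3])
  abs(mep$points[, 1] - mep$sheet_depth_um[cbind(ri, ci)])
}

#' @export
print.mep_scene <- function(x, ...) {
  cat(sprintf("<mep_scene> %s (%s), %d endplate points\n",
              x$geometry$muscle_kind, x$mep$shape_kind, nrow(x$mep$points)))
  invisible(x)
}
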