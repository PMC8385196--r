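#' Published injection-strategy parameters
#'
#' Site counts, per-site volume and needle-depth ranges for the four
#' (strategy, muscle) combinations: the 3D strategy places sites according to
#' the volumetric MEP distribution, the 2D strategy according to the MEP band
#' visible on the muscle surface. The tibialis anterior 3D plan mixes depths:
#' three shallow sites (0.6-0.8 mm) and one deep site (1.3-1.5 mm).
#'
#' @return data.frame with one row per (strategy, muscle_kind): `n_sites`,
#'   `depth_lo_mm`, `depth_hi_mm` (per-site allowed needle depth; two rows for
#'   the mixed tibialis anterior 3D plan), `site_volume_nl`.
#' @export
injection_plan_table <- function() {
  data.frame(
    strategy      = c("3D", "3D", "3D", "2D", "2D"),
    muscle_kind   = c("gastrocnemius", "tibialis_anterior",
                      "tibialis_anterior", "gastrocnemius",
                      "tibialis_anterior"),
    n_sites       = c(7L, 3L, 1L, 7L, 4L),
    depth_lo_mm   = c(1.2, 0.6, 1.3, 1.2, 0.6),
    depth_hi_mm   = c(1.5, 0.8, 1.5, 1.5, 0.8),
    site_volume_nl = 500,
    stringsAsFactors = FALSE)
}

#' Plan intramuscular injection sites for a strategy
#'
#' Encodes the two injection strategies on a synthetic MEP scene. 3D sites
#' are placed greedily where the not-yet-covered 3D MEP density holds the
#' most mass within the diffusion reach of one deposit, each site inside its
#' published needle-depth stratum -- the strategy exploits the full
#' volumetric endplate distribution. 2D sites use only the surface
#' projection of that density (the MEP band visible on the muscle surface):
#' they are spaced evenly along the band at its centroid column, all at the
#' nominal mid-range needle depth. Per-site needle depths always lie inside
#' the published range for the combination (see [injection_plan_table()]).
#'
#' @param scene a [generate_mep_map()] result.
#' @param strategy `"3D"` or `"2D"`.
#' @param muscle_kind optional; must match `scene$geometry$muscle_kind`.
#' @param site_volume_nl volume per site, nanolitres (default 500).
#' @param target_radius_um lateral scale credited to one deposit when the 3D
#'   strategy allocates sites over the density (default 600, about 1.5x the
#'   default diffusion spread of a 500-nl deposit).
#' @return object of class `injection_plan`: `strategy`, `muscle_kind`,
#'   `sites` (data.frame: `depth_um` absolute position on the depth axis,
#'   `row_um`, `col_um`, `depth_mm` needle depth below the local surface,
#'   `volume_nl`), `total_volume_nl`.
#' @export
#' @examples
#' sc <- generate_mep_map("tibialis_anterior", n_points = 200, seed = 1,
#'                        voxel_size_um = 200)
#' p <- make_injection_plan(sc, "3D")
#' p$total_volume_nl
make_injection_plan <- function(scene, strategy = c("3D", "2D"),
                                muscle_kind = NULL,
                                site_volume_nl = 500,
                                target_radius_um = 600) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(scene, "mep_scene"))
  geometry <- scene$geometry
  if (!is.null(muscle_kind) && !identical(muscle_kind, geometry$muscle_kind))
    stop_motomap(sprintf("geometry is for %s, not %s",
                         geometry$muscle_kind, muscle_kind))
  muscle <- geometry$muscle_kind
  tab <- injection_plan_table()
  tab <- tab[tab$strategy == strategy & tab$muscle_kind == muscle, ,
             drop = FALSE]

  sites <- if (strategy == "3D") {
    strata <- data.frame(n = tab$n_sites,
                         lo_um = tab$depth_lo_mm * 1000,
                         hi_um = tab$depth_hi_mm * 1000)
    # deepest stratum first so the deep deposit claims the apex mass
    strata <- strata[order(-strata$lo_um), , drop = FALSE]
    place_sites_3d(scene, strata, target_radius_um)
  } else {
    place_sites_2d(scene, tab$n_sites,
                   mean(c(tab$depth_lo_mm, tab$depth_hi_mm)) * 1000)
  }
  sites$volume_nl <- site_volume_nl
  rownames(sites) <- NULL
  pts <- as.matrix(sites[, c("depth_um", "row_um", "col_um")])
  if (!all(point_in_mask(pts, geometry)))
    stop_motomap("planned injection site falls outside the muscle mask")
  structure(
    list(strategy = strategy, muscle_kind = muscle, sites = sites,
         total_volume_nl = site_volume_nl * nrow(sites)),
    class = "injection_plan")
}

# Greedy mass-coverage placement: each site goes to the admissible voxel
# (inside its below-surface depth stratum) whose surrounding Gaussian
# neighbourhood of scale `radius_um` holds the most not-yet-covered MEP
# density; the captured density is then discounted before the next site.
# Ties break to the smallest voxel index, so placement is deterministic.
place_sites_3d <- function(scene, strata, radius_um) {
  geometry <- scene$geometry
  vs <- geometry$voxel_size_um
  d <- dim(geometry$mask)
  surf <- surface_depth_map(geometry)
  zc <- index_to_center_um(seq_len(d[1]), vs)
  below <- array(zc, d) -
    aperm(array(surf, c(d[2], d[3], d[1])), c(3, 1, 2))
  below[is.na(below)] <- -Inf
  sig_vox <- rep(radius_um / vs, 3)
  remaining <- scene$mep$density
  rows <- list()
  for (st in seq_len(nrow(strata))) {
    admissible <- geometry$mask &
      below >= strata$lo_um[st] & below <= strata$hi_um[st]
    if (!any(admissible))
      stop_motomap("no admissible voxels in the depth stratum")
    for (i in seq_len(strata$n[st])) {
      score <- smooth_gaussian3(remaining, sig_vox)
      score[!admissible] <- -Inf
      best <- which.max(score)
      ai <- arrayInd(best, d)
      pos <- (ai - 0.5) * vs
      rows[[length(rows) + 1L]] <- data.frame(
        depth_um = pos[1], row_um = pos[2], col_um = pos[3],
        depth_mm = (pos[1] - surf[ai[2], ai[3]]) / 1000)
      # discount the density this deposit will reach
      r <- ceiling(3 * radius_um / vs)
      lo <- pmax(ai - r, 1L); hi <- pmin(ai + r, d)
      iz <- lo[1]:hi[1]; ir <- lo[2]:hi[2]; ic <- lo[3]:hi[3]
      kz <- exp(-((index_to_center_um(iz, vs) - pos[1])^2) / (2 * radius_um^2))
      kr <- exp(-((index_to_center_um(ir, vs) - pos[2])^2) / (2 * radius_um^2))
      kc <- exp(-((index_to_center_um(ic, vs) - pos[3])^2) / (2 * radius_um^2))
      remaining[iz, ir, ic] <- remaining[iz, ir, ic] *
        (1 - outer(outer(kz, kr), kc))
    }
  }
  do.call(rbind, rows)
}

# Sites along the surface-visible MEP band at a constant nominal depth.
# For the m_sheet the visible band is the staggered surface curve of the
# lamella (evenly spaced medio-laterally along it); otherwise the band is
# the depth-projection of the density (evenly spaced rows at the per-row
# centroid column). Either way the 2D strategy never sees depth structure.
place_sites_2d <- function(scene, n, nominal_depth_um) {
  geometry <- scene$geometry
  vs <- geometry$voxel_size_um
  surf <- surface_depth_map(geometry)
  thick <- column_thickness_map(geometry)
  admissible <- !is.na(surf) & thick >= nominal_depth_um + 2 * vs
  if (identical(scene$mep$shape_kind, "m_sheet"))
    return(place_sites_2d_band(scene, n, nominal_depth_um, admissible, surf))
  proj <- apply(scene$mep$density, c(2, 3), sum)
  wrow <- rowSums(proj)
  rows <- which(wrow >= 0.05 * max(wrow) & rowSums(admissible) > 0)
  ri <- unique(round(seq(min(rows), max(rows), length.out = n)))
  while (length(ri) < n) {     # degenerate tiny grids: duplicate nearest rows
    extra <- setdiff(rows, ri)
    if (!length(extra)) stop_motomap("projected band too small for n sites")
    ri <- sort(c(ri, extra[1]))
  }
  ci <- vapply(ri, function(r) {
    w <- proj[r, ]
    j <- sum(w * seq_along(w)) / sum(w)
    cols <- which(admissible[r, ])
    cols[which.min(abs(cols - j))]
  }, numeric(1))
  depth_abs <- surf[cbind(ri, ci)] + nominal_depth_um
  data.frame(depth_um = depth_abs,
             row_um = (ri - 0.5) * vs,
             col_um = (ci - 0.5) * vs,
             depth_mm = nominal_depth_um / 1000)
}

place_sites_2d_band <- function(scene, n, nominal_depth_um, admissible,
                                surf) {
  geometry <- scene$geometry
  vs <- geometry$voxel_size_um
  crv <- m_sheet_curves(geometry, scene$mep$params)
  cols <- which(crv$col_occupied & colSums(admissible) > 0)
  if (length(cols) < n) stop_motomap("surface band too small for n sites")
  span <- range(cols)
  ci <- unique(round(seq(span[1] + 0.06 * diff(span),
                         span[2] - 0.06 * diff(span), length.out = n)))
  ci <- vapply(ci, function(ch) cols[which.min(abs(cols - ch))], integer(1))
  ri <- vapply(ci, function(ch) {
    target <- um_to_index(crv$surface_row_of_col[ch], vs)
    ok <- which(admissible[, ch])
    ok[which.min(abs(ok - target))]
  }, integer(1))
  depth_abs <- surf[cbind(ri, ci)] + nominal_depth_um
  data.frame(depth_um = depth_abs,
             row_um = (ri - 0.5) * vs,
             col_um = (ci - 0.5) * vs,
             depth_mm = nominal_depth_um / 1000)
}

#' @export
print.injection_plan <- function(x, ...) {
  cat(sprintf("<injection_plan> %s %s: %d sites x %g nl = %g nl total\n",
              x$strategy, x$muscle_kind, nrow(x$sites),
              x$sites$volume_nl[1], x$total_volume_nl))
  print(x$sites, digits = 4)
  invisible(x)
}
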