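#' Build a muscle occupancy grid
#'
#' The muscle volume is modelled as an axis-aligned ellipsoid on a regular
#' voxel grid: the simplest smooth, connected solid consistent with the
#' silhouettes of a dissected gastrocnemius or tibialis anterior. Axis order
#' is fixed as (depth, row, col), depth being the direction of sectioning and
#' needle insertion.
#'
#' @param muscle_kind `"gastrocnemius"` or `"tibialis_anterior"`.
#' @param voxel_size_um edge length of the cubic voxels, micrometres.
#' @param extent_mm optional length-3 numeric (depth, row, col) overriding the
#'   default bounding extents in millimetres. Defaults: 6 x 14 x 9 mm for the
#'   gastrocnemius, 4 x 12 x 6 mm for the tibialis anterior, mouse-hindlimb
#'   scale.
#' @return an object of class `muscle_geometry` with elements `mask` (3D
#'   logical array), `voxel_size_um`, `muscle_kind`, `extent_um`.
#' @export
#' @examples
#' g <- muscle_geometry("tibialis_anterior", voxel_size_um = 200)
#' dim(g$mask)
muscle_geometry <- function(muscle_kind = c("gastrocnemius", "tibialis_anterior"),
                            voxel_size_um = 100,
                            extent_mm = NULL) {
  muscle_kind <- match.arg(muscle_kind)
  assert_scalar_pos(voxel_size_um, "voxel_size_um")
  if (is.null(extent_mm)) {
    extent_mm <- switch(muscle_kind,
      gastrocnemius     = c(6, 14, 9),
      tibialis_anterior = c(4, 12, 6))
  }
  if (length(extent_mm) != 3L || any(extent_mm <= 0))
    stop_motomap("`extent_mm` must be three positive extents (depth, row, col)")
  extent_um <- extent_mm * 1000
  dims <- pmax(3L, as.integer(ceiling(extent_um / voxel_size_um)))
  semi <- extent_um / 2 * 0.98          # keep the ellipsoid off the grid edge
  ctr  <- dims * voxel_size_um / 2
  zc <- index_to_center_um(seq_len(dims[1]), voxel_size_um)
  rc <- index_to_center_um(seq_len(dims[2]), voxel_size_um)
  cc <- index_to_center_um(seq_len(dims[3]), voxel_size_um)
  q1 <- ((zc - ctr[1]) / semi[1])^2
  q2 <- ((rc - ctr[2]) / semi[2])^2
  q3 <- ((cc - ctr[3]) / semi[3])^2
  mask <- outer(outer(q1, q2, `+`), q3, `+`) <= 1
  structure(
    list(mask = mask, voxel_size_um = voxel_size_um,
         muscle_kind = muscle_kind, extent_um = extent_um),
    class = "muscle_geometry")
}

#' Depth of the upper muscle surface under each (row, col) position
#'
#' @param geometry a [muscle_geometry()].
#' @return matrix (rows x cols) of surface depths in micrometres (top face of
#'   the first occupied voxel); `NA` where the column contains no muscle.
#' @export
surface_depth_map <- function(geometry) {
  stopifnot(inherits(geometry, "muscle_geometry"))
  m <- geometry$mask
  d <- dim(m)
  # first TRUE along the depth axis, vectorised over the (row, col) plane
  flat <- matrix(m, nrow = d[1])
  first <- rep(NA_integer_, ncol(flat))
  hit <- colSums(flat) > 0
  first[hit] <- max.col(t(flat[, hit, drop = FALSE]), ties.method = "first")
  matrix((first - 1L) * geometry$voxel_size_um, d[2], d[3])
}

# thickness of muscle below the surface per (row, col), in um
column_thickness_map <- function(geometry) {
  m <- geometry$mask
  d <- dim(m)
  matrix(colSums(matrix(m, nrow = d[1])) * geometry$voxel_size_um, d[2], d[3])
}

#' Test whether physical points lie inside the muscle mask
#'
#' @param points_um n x 3 matrix of (depth, row, col) positions in
#'   micrometres.
#' @param geometry a [muscle_geometry()].
#' @return logical vector of length n.
#' @export
point_in_mask <- function(points_um, geometry) {
  d <- dim(geometry$mask)
  idx <- cbind(um_to_index(points_um[, 1], geometry$voxel_size_um),
               um_to_index(points_um[, 2], geometry$voxel_size_um),
               um_to_index(points_um[, 3], geometry$voxel_size_um))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  inside <- rep(FALSE, nrow(points_um))
  inside[ok] <- geometry$mask[idx[ok, , drop = FALSE]]
  inside
}

#' @export
print.muscle_geometry <- function(x, ...) {
  cat(sprintf("<muscle_geometry> %s, grid %s @ %g um/voxel, %d muscle voxels\n",
              x$muscle_kind, paste(dim(x$mask), collapse = "x"),
              x$voxel_size_um, sum(x$mask)))
  invisible(x)
}
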