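#' Spot-detection parameters
#'
#' @param diameter_um expected soma diameter (default 20, the scale of an
#'   alpha-motoneuron soma).
#' @param threshold `"relative"` (background median + `k` x MAD-based SD of
#'   the smoothed volume) or `"absolute"` (fixed value on the smoothed
#'   volume).
#' @param k multiplier for the relative threshold (default 8).
#' @param value absolute threshold, required iff `threshold = "absolute"`.
#' @param min_separation_um minimum distance between accepted spots
#'   (default one diameter).
#' @return object of class `spot_params`.
#' @export
spot_params <- function(diameter_um = 20,
                        threshold = c("relative", "absolute"),
                        k = 8, value = NULL,
                        min_separation_um = diameter_um) {
  threshold <- match.arg(threshold)
  assert_scalar_pos(diameter_um, "diameter_um")
  assert_scalar_pos(min_separation_um, "min_separation_um")
  if (threshold == "absolute" && is.null(value))
    stop_motomap("absolute threshold requires `value`")
  structure(list(diameter_um = diameter_um, threshold = threshold, k = k,
                 value = value, min_separation_um = min_separation_um),
            class = "spot_params")
}

#' Detect bright somata in a 3D volume
#'
#' An open smoothed-local-maxima detector: the volume is Gaussian-smoothed
#' with `sigma = diameter / 4` per axis (anisotropic voxel sizes are handled
#' by converting to voxels per axis), voxels above the intensity threshold
#' that are `>=` all 26 neighbours are candidate spots, the minimum
#' separation is enforced greedily (brightest kept first; exact intensity
#' ties broken towards the lexicographically smaller voxel index, making the
#' result deterministic), and each surviving spot gets a sub-voxel centroid
#' as the intensity-weighted centroid of a diameter-sized window of the
#' background-subtracted smoothed volume.
#'
#' @param volume 3D non-negative array, axes (rc, ml, vd).
#' @param voxel_size_um length-3 voxel size per axis (a scalar is recycled).
#' @param params a [spot_params()]; the diameter must span at least 2 voxels
#'   on every axis.
#' @return a [spot_set()] with `source = "detected"`; `intensities` are the
#'   raw-volume values at the detected voxels.
#' @export
detect_spots <- function(volume, voxel_size_um, params = spot_params()) {
  if (length(dim(volume)) != 3L || !length(volume))
    stop_motomap("`volume` must be a non-empty 3D array")
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop_motomap("`voxel_size_um` must give a positive size for each axis")
  sig_vox <- (params$diameter_um / 4) / voxel_size_um
  if (any(params$diameter_um < 2 * voxel_size_um))
    stop_motomap("diameter must span at least 2 voxels on every axis")

  sm <- smooth_gaussian3(volume, sig_vox)
  bg <- median(sm)
  thr <- if (params$threshold == "relative")
    bg + params$k * mad(sm) else params$value
  d <- dim(volume)
  cand <- which(sm > thr)
  cand <- cand[is_local_max(sm, cand)]
  if (!length(cand))
    return(spot_set(matrix(numeric(0), 0, 3), numeric(0), "detected"))

  # greedy min-separation: brightest first, ties to the smaller voxel index
  ord <- cand[order(-sm[cand], cand)]
  ai <- arrayInd(ord, d)
  pos <- t(t(ai - 0.5) * voxel_size_um)
  kept <- integer(0)
  for (i in seq_len(nrow(ai))) {
    if (!length(kept) ||
        min(sqrt(colSums((t(pos[kept, , drop = FALSE]) - pos[i, ])^2))) >=
          params$min_separation_um)
      kept <- c(kept, i)
  }
  ai <- ai[kept, , drop = FALSE]

  w <- pmax(ceiling((params$diameter_um / 2) / voxel_size_um), 1L)
  cent <- t(vapply(seq_len(nrow(ai)), function(i) {
    lo <- pmax(ai[i, ] - w, 1L); hi <- pmin(ai[i, ] + w, d)
    sub <- pmax(sm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] - bg,
                0)
    sw <- sum(sub)
    vapply(1:3, function(a) {
      x <- index_to_center_um(lo[a]:hi[a], voxel_size_um[a])
      mg <- apply(sub, a, sum)
      if (sw > 0) sum(mg * x) / sw else index_to_center_um(ai[i, a],
                                                           voxel_size_um[a])
    }, numeric(1))
  }, numeric(3)))
  spot_set(cent, volume[ai], "detected")
}

# separable Gaussian smoothing with replicate padding, sigma in voxels/axis
smooth_gaussian3 <- function(volume, sigma_vox) {
  d <- dim(volume)
  out <- volume
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s < 0.2) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    out <- filter_axis1(aperm(out, c(a, setdiff(1:3, a))), k)
    out <- aperm(out, order(c(a, setdiff(1:3, a))))
  }
  out
}

filter_axis1 <- function(a, k) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(a, d[1], prod(d[-1]))
  m <- m[c(rep(1L, r), seq_len(d[1]), rep(d[1], r)), , drop = FALSE]
  f <- stats::filter(m, k, sides = 2)
  array(as.numeric(f[r + seq_len(d[1]), , drop = FALSE]), d)
}

# candidates (linear indices) that are >= all existing 26-neighbours
is_local_max <- function(vol, cand) {
  d <- dim(vol)
  ai <- arrayInd(cand, d)
  keep <- rep(TRUE, length(cand))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nz <- ai[, 1] + dz; ny <- ai[, 2] + dy; nx <- ai[, 3] + dx
    ok <- nz >= 1 & nz <= d[1] & ny >= 1 & ny <= d[2] & nx >= 1 & nx <= d[3]
    idx <- which(ok & keep)
    if (!length(idx)) next
    nb <- vol[cbind(nz[idx], ny[idx], nx[idx])]
    keep[idx] <- vol[cand[idx]] >= nb
  }
  keep
}

#' Count detected neurons
#'
#' @param spots a [spot_set()].
#' @return integer spot count.
#' @export
count_neurons <- function(spots) {
  stopifnot(inherits(spots, "spot_set"))
  nrow(spots$centroids)
}

#' Per-axis extent of a motor-neuron pool
#'
#' @param spots a [spot_set()] with at least one centroid.
#' @param mode `"minmax"` (range = max - min, default) or `"percentile"`
#'   (99th - 1st percentile, robust to stragglers).
#' @return object of class `pool_extent`: `range_rc_um`, `range_ml_um`,
#'   `range_vd_um`, `mode`.
#' @export
pool_extent <- function(spots, mode = c("minmax", "percentile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spots, "spot_set"))
  if (!nrow(spots$centroids)) stop_motomap("empty spot set has no extent")
  rng <- unname(apply(spots$centroids, 2, function(x) {
    if (mode == "minmax") diff(range(x))
    else diff(quantile(x, c(0.01, 0.99), names = FALSE, type = 7))
  }))
  structure(list(range_rc_um = rng[1], range_ml_um = rng[2],
                 range_vd_um = rng[3], mode = mode),
            class = "pool_extent")
}

#' @export
print.pool_extent <- function(x, ...) {
  cat(sprintf("<pool_extent> (%s) R-C %.1f, M-L %.1f, V-D %.1f um\n",
              x$mode, x$range_rc_um, x$range_ml_um, x$range_vd_um))
  invisible(x)
}

#' Maximum intensity projection
#'
#' @param volume 3D array.
#' @param axis axis to project along (1, 2 or 3).
#' @return 2D matrix of per-pixel maxima.
#' @export
max_intensity_projection <- function(volume, axis = 3) {
  if (length(dim(volume)) != 3L) stop_motomap("`volume` must be 3D")
  if (!axis %in% 1:3) stop_motomap("`axis` must be 1, 2 or 3")
  apply(volume, setdiff(1:3, axis), max)
}
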