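#' Motor-neuron pool parameters for the cord-scene generator
#'
#' Defaults emulate a hindlimb motoneuron pool: an elongated rostro-caudal
#' column (about 2.2 mm) with narrow medio-lateral and ventro-dorsal spreads,
#' alpha-motoneuron-sized somata, imaged at a 5-um axial step.
#'
#' @param spread_rc_um,spread_ml_um,spread_vd_um full per-axis extents of the
#'   box the somata are placed in (rostro-caudal, medio-lateral,
#'   ventro-dorsal), micrometres.
#' @param soma_diameter_um nominal soma diameter (default 20).
#' @param peak peak soma intensity above background (arbitrary units).
#' @param background constant background level.
#' @param background_sd standard deviation of the Gaussian background noise;
#'   the scene's nominal SNR is `peak / background_sd`.
#' @param min_separation_um minimum distance between soma centroids (default
#'   one soma diameter).
#' @param voxel_size_um length-3 voxel size (rc, ml, vd); default 5 um
#'   isotropic.
#' @return named list of class `pool_params`.
#' @export
pool_params <- function(spread_rc_um = 2200, spread_ml_um = 260,
                        spread_vd_um = 190, soma_diameter_um = 20,
                        peak = 10, background = 2, background_sd = 1,
                        min_separation_um = soma_diameter_um,
                        voxel_size_um = c(5, 5, 5)) {
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3)
  structure(list(spread_um = c(spread_rc_um, spread_ml_um, spread_vd_um),
                 soma_diameter_um = soma_diameter_um, peak = peak,
                 background = background, background_sd = background_sd,
                 min_separation_um = min_separation_um,
                 voxel_size_um = voxel_size_um),
            class = "pool_params")
}

#' Construct a set of soma centroids
#'
#' @param centroids n x 3 matrix of (rc, ml, vd) positions in micrometres.
#' @param intensities per-spot peak values.
#' @param source `"detected"` or `"ground_truth"`.
#' @return object of class `spot_set`.
#' @export
spot_set <- function(centroids, intensities = rep(NA_real_, nrow(centroids)),
                     source = c("detected", "ground_truth")) {
  source <- match.arg(source)
  centroids <- matrix(as.numeric(centroids), ncol = 3,
                      dimnames = list(NULL, c("rc_um", "ml_um", "vd_um")))
  structure(list(centroids = centroids, intensities = intensities,
                 source = source),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d %s spots\n", nrow(x$centroids), x$source))
  invisible(x)
}

#' Render a synthetic spinal-cord volume with labeled motoneurons
#'
#' Samples `n_neurons` soma centroids uniformly inside an axis-aligned pool
#' box (rejection sampling enforces the minimum centroid separation), renders
#' each soma as a 3D Gaussian blob whose brightest voxel equals `peak`, and
#' adds constant background plus Gaussian noise. A margin of twice the soma
#' diameter surrounds the pool so no blob is clipped by the volume edge.
#'
#' @param n_neurons number of somata (>= 0).
#' @param pool a [pool_params()].
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per soma before giving up.
#' @return object of class `cord_scene`: `volume` (3D array, axes rc/ml/vd),
#'   `voxel_size_um` (length 3), `truth_spots` ([spot_set()]), `pool`.
#' @export
render_cord_scene <- function(n_neurons = 200, pool = pool_params(),
                              seed = 1, max_tries = 10000) {
  stopifnot(inherits(pool, "pool_params"))
  if (n_neurons < 0) stop_motomap("`n_neurons` must be >= 0")
  vs <- pool$voxel_size_um
  if (any(pool$soma_diameter_um < 2 * vs))
    stop_motomap("soma diameter must span at least 2 voxels on every axis")
  margin <- 2 * pool$soma_diameter_um
  ext <- pool$spread_um + 2 * margin
  dims <- as.integer(ceiling(ext / vs))
  lo <- margin; hi <- margin + pool$spread_um

  res <- with_seed(seed, {
    cent <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(cent) < n_neurons) {
      cand <- lo + runif(3) * pool$spread_um
      ok <- !nrow(cent) ||
        min(sqrt(colSums((t(cent) - cand)^2))) >= pool$min_separation_um
      if (ok) cent <- rbind(cent, cand) else tries <- tries + 1L
      if (tries > max_tries)
        stop_motomap("pool too small to place all somata at the required ",
                     "separation")
    }
    vol <- array(rnorm(prod(dims), pool$background, pool$background_sd), dims)
    sigma <- pool$soma_diameter_um / 4
    for (i in seq_len(nrow(cent))) {
      b <- soma_blob(cent[i, ], sigma, vs, dims)
      vol[b$iz, b$ir, b$ic] <- vol[b$iz, b$ir, b$ic] + pool$peak * b$kern
    }
    list(vol = pmax(vol, 0), cent = cent)
  })
  truth <- spot_set(res$cent, rep(pool$peak, n_neurons), "ground_truth")
  structure(list(volume = res$vol, voxel_size_um = vs, truth_spots = truth,
                 pool = pool, pool_bounds = rbind(lo = lo, hi = hi)),
            class = "cord_scene")
}

# Gaussian blob on voxel centres, scaled so its brightest voxel is 1
soma_blob <- function(center_um, sigma_um, vs, dims) {
  r <- ceiling(2.5 * sigma_um / vs)
  ci <- um_to_index(center_um, vs)
  lo <- pmax(ci - r, 1L); hi <- pmin(ci + r, dims)
  ax <- lapply(1:3, function(a) {
    x <- index_to_center_um(lo[a]:hi[a], vs[a])
    exp(-((x - center_um[a])^2) / (2 * sigma_um^2))
  })
  kern <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
  list(iz = lo[1]:hi[1], ir = lo[2]:hi[2], ic = lo[3]:hi[3],
       kern = kern / max(kern))
}

#' @export
print.cord_scene <- function(x, ...) {
  cat(sprintf("<cord_scene> %s voxels, %d ground-truth somata, SNR %.1f\n",
              paste(dim(x$volume), collapse = "x"),
              nrow(x$truth_spots$centroids),
              x$pool$peak / x$pool$background_sd))
  invisible(x)
}
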