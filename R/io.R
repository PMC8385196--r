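#' Read a single-channel image stack from a multi-page TIFF
#'
#' Pages are stacked along axis 1, so a 10-page 64x64 file yields a
#' `(10, 64, 64)` array. If a JSON sidecar `<path>.json` exists (as written
#' by [write_stack()]), its `voxel_size_um` is attached; an explicit
#' `voxel_size_um` argument overrides it.
#'
#' @param path TIFF file path.
#' @param voxel_size_um optional length-3 voxel size, overriding the sidecar.
#' @return list: `volume` (3D array), `voxel_size_um` (length 3 or `NULL`),
#'   `sidecar` (parsed sidecar list or `NULL`).
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop_motomap("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_motomap("inconsistent page dimensions in ", path)
  vol <- aperm(array(unlist(pages), c(dims[1, 1], dims[2, 1], length(pages))),
               c(3, 1, 2))
  sidecar <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) sidecar <- jsonlite::read_json(sc_path,
                                                           simplifyVector = TRUE)
  if (is.null(voxel_size_um) && !is.null(sidecar$voxel_size_um))
    voxel_size_um <- as.numeric(sidecar$voxel_size_um)
  list(volume = vol, voxel_size_um = voxel_size_um, sidecar = sidecar)
}

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Integer-valued data within the chosen bit depth round-trip exactly through
#' [read_stack()]. Floating-point volumes must be scaled by the caller (the
#' scale used can be recorded in `metadata`).
#'
#' @param volume 3D array, axis 1 = pages; values must be integers in
#'   `[0, 2^bits - 1]`.
#' @param path output TIFF path.
#' @param bits bits per sample, 8 or 16.
#' @param voxel_size_um optional length-3 voxel size stored in the sidecar.
#' @param metadata optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, bits = 16L, voxel_size_um = NULL,
                        metadata = NULL) {
  if (length(dim(volume)) != 3L) stop_motomap("`volume` must be 3D")
  if (!bits %in% c(8L, 16L)) stop_motomap("`bits` must be 8 or 16")
  mx <- 2^bits - 1
  if (any(volume < 0) || any(volume > mx) ||
      any(abs(volume - round(volume)) > 1e-9))
    stop_motomap("values must be integers in [0, ", mx, "]; scale first")
  pages <- lapply(seq_len(dim(volume)[1]),
                  function(i) volume[i, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  sidecar <- c(list(pages = dim(volume)[1], rows = dim(volume)[2],
                    cols = dim(volume)[3], bits = bits,
                    axis_order = c("page/depth", "row", "col")),
               if (!is.null(voxel_size_um))
                 list(voxel_size_um = voxel_size_um),
               metadata)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# scale a non-negative float volume into 16-bit integers; returns list with
# the integer volume and the scale applied
quantize16 <- function(volume) {
  mx <- max(volume)
  scale <- if (mx > 0) 65535 / mx else 1
  list(volume = round(volume * scale), scale = scale)
}

#' Export rendered section images
#'
#' Writes one multi-page 16-bit TIFF per channel (`tracer.tif`, `mep.tif`,
#' pages ordered by depth) plus a JSON sidecar with depths, pixel size, slab
#' thickness, intensity scales and per-section ground truth counts.
#'
#' @param sections list of `section_image` objects from
#'   [render_section_images()].
#' @param dir output directory (created if needed).
#' @return the sidecar path, invisibly.
#' @export
write_section_images <- function(sections, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stack_of <- function(ch) {
    a <- array(0, c(length(sections), dim(sections[[1]][[ch]])))
    for (i in seq_along(sections)) a[i, , ] <- sections[[i]][[ch]]
    quantize16(a)
  }
  tr <- stack_of("tracer"); mp <- stack_of("mep")
  depths <- vapply(sections, `[[`, numeric(1), "depth_um")
  meta <- list(depths_um = depths,
               pixel_size_um = sections[[1]]$pixel_size_um,
               slab_um = sections[[1]]$slab_um,
               tracer_scale = tr$scale, mep_scale = mp$scale,
               n_puncta = vapply(sections, function(s) s$truth$n_puncta,
                                 numeric(1)))
  write_stack(tr$volume, file.path(dir, "tracer.tif"), metadata = meta)
  write_stack(mp$volume, file.path(dir, "mep.tif"), metadata = meta)
  invisible(file.path(dir, "tracer.tif.json"))
}

#' Export a cord scene
#'
#' Writes the volume as a 16-bit multi-page TIFF (pages along the
#' rostro-caudal axis) and a sidecar holding voxel sizes, the intensity
#' scale, the axis convention and the ground-truth centroids.
#'
#' @param scene a [render_cord_scene()] result.
#' @param dir output directory.
#' @return the TIFF path, invisibly.
#' @export
write_cord_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "cord_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- quantize16(scene$volume)
  path <- file.path(dir, "cord.tif")
  write_stack(q$volume, path, voxel_size_um = scene$voxel_size_um,
              metadata = list(
                intensity_scale = q$scale,
                axis_order = c("rc", "ml", "vd"),
                truth_centroids_um = scene$truth_spots$centroids))
  invisible(path)
}

#' Write / read an injection plan as YAML
#'
#' @param plan an [make_injection_plan()] result.
#' @param path YAML file path.
#' @return [write_plan_yaml()] returns `path` invisibly; [read_plan_yaml()]
#'   returns the `injection_plan`.
#' @export
write_plan_yaml <- function(plan, path) {
  stopifnot(inherits(plan, "injection_plan"))
  yaml::write_yaml(list(strategy = plan$strategy,
                        muscle_kind = plan$muscle_kind,
                        total_volume_nl = plan$total_volume_nl,
                        sites = lapply(seq_len(nrow(plan$sites)), function(i)
                          as.list(plan$sites[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_plan_yaml
#' @export
read_plan_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sites <- do.call(rbind, lapply(y$sites, as.data.frame))
  structure(list(strategy = y$strategy, muscle_kind = y$muscle_kind,
                 sites = sites, total_volume_nl = y$total_volume_nl),
            class = "injection_plan")
}

#' Write a coverage profile as CSV
#'
#' Columns `depth_um, mep_pixels, mep_pixels_in_ctb, coverage` with a footer
#' row (`depth_um = "mean"`) carrying the mean coverage.
#'
#' @param result a [coverage_profile()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(result, path) {
  stopifnot(inherits(result, "coverage_result"))
  df <- result$per_depth[, c("depth_um", "mep_pixels", "mep_pixels_in_ctb",
                             "coverage")]
  df$depth_um <- as.character(df$depth_um)
  df <- rbind(df, data.frame(depth_um = "mean", mep_pixels = NA,
                             mep_pixels_in_ctb = NA,
                             coverage = result$mean_coverage))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write detected spots as CSV
#'
#' Columns `id, rc_um, ml_um, vd_um, peak`.
#'
#' @param spots a [spot_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spots_csv <- function(spots, path) {
  stopifnot(inherits(spots, "spot_set"))
  df <- data.frame(id = seq_len(nrow(spots$centroids)),
                   rc_um = spots$centroids[, 1],
                   ml_um = spots$centroids[, 2],
                   vd_um = spots$centroids[, 3],
                   peak = spots$intensities)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
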