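#' Threshold specification for channel binarization
#'
#' The published workflow adjusts the binarization threshold manually per
#' image; for reproducible batch runs an automatic mode (Otsu's criterion)
#' is the default, with manual override.
#'
#' @param mode `"auto"` (Otsu) or `"manual"`.
#' @param value intensity threshold, required iff `mode = "manual"`.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("auto", "manual"), value = NULL) {
  mode <- match.arg(mode)
  if (mode == "manual" && (is.null(value) || !is.finite(value)))
    stop_motomap("manual mode requires a finite `value`")
  if (mode == "auto" && !is.null(value))
    stop_motomap("`value` must be absent in auto mode")
  structure(list(mode = mode, value = value), class = "threshold_spec")
}

# resolve a threshold_spec against an image; NA signals a degenerate image
resolve_threshold <- function(image, spec) {
  if (spec$mode == "manual") return(spec$value)
  mx <- max(image)
  if (mx <= min(image)) {
    warning("constant image: no threshold separable, returning empty mask",
            call. = FALSE)
    return(NA_real_)
  }
  EBImage::otsu(image / mx, range = c(0, 1)) * mx
}

new_binary_mask <- function(pixels, pixel_size_um = NA_real_,
                            threshold = NA_real_) {
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 threshold = threshold),
            class = "binary_mask")
}

as_mask_matrix <- function(m, name = "mask") {
  if (inherits(m, "binary_mask")) m <- m$pixels
  if (!is.matrix(m)) stop_motomap(sprintf("`%s` must be a 2D mask", name))
  if (!is.logical(m)) {
    storage.mode(m) <- "logical"
  }
  m
}

#' Fill enclosed background holes in a binary mask
#'
#' Every background region not connected to the image border becomes
#' foreground. Background connectivity is 4-connected (foreground is
#' therefore 8-connected), the standard dual pairing; this is fixed so the
#' operation is bit-exactly reproducible.
#'
#' @param mask logical matrix (or `binary_mask`).
#' @return logical matrix of the same shape.
#' @export
fill_holes <- function(mask) {
  m <- as_mask_matrix(mask)
  filled <- EBImage::fillHull(m * 1L)
  matrix(as.vector(filled) > 0, nrow(m), ncol(m))
}

#' Segment the tracer (CTB) diffusion region
#'
#' Binarizes the tracer channel (auto Otsu or manual threshold: pixels
#' strictly above the threshold are foreground) and then fills enclosed
#' holes, which arise from the heterogeneity of the fluorescence signal
#' inside the diffusion region.
#'
#' @param image 2D non-negative image (matrix) or a `section_image` (its
#'   tracer channel is used).
#' @param threshold a [threshold_spec()].
#' @param pixel_size_um recorded in the returned mask for bookkeeping.
#' @return a `binary_mask` (fields `pixels`, `pixel_size_um`, `threshold` —
#'   the threshold actually applied, for audit).
#' @export
segment_tracer_region <- function(image, threshold = threshold_spec("auto"),
                                  pixel_size_um = NA_real_) {
  if (inherits(image, "section_image")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$tracer
  }
  check_image(image)
  th <- resolve_threshold(image, threshold)
  if (is.na(th))
    return(new_binary_mask(matrix(FALSE, nrow(image), ncol(image)),
                           pixel_size_um, NA_real_))
  new_binary_mask(fill_holes(image > th), pixel_size_um, th)
}

#' Segment the motor-endplate signal
#'
#' Filters the MEP channel to suppress impulse-like muscle autofluorescence
#' (default: 3x3 median), then binarizes. No hole filling is applied: the
#' endplate signal is punctate, not a solid region.
#'
#' @param image 2D non-negative image or a `section_image` (MEP channel).
#' @param filter `"median3"` (3x3 median, default) or `"none"`.
#' @param threshold a [threshold_spec()].
#' @param pixel_size_um recorded in the returned mask.
#' @return a `binary_mask`.
#' @export
segment_mep_signal <- function(image, filter = c("median3", "none"),
                               threshold = threshold_spec("auto"),
                               pixel_size_um = NA_real_) {
  filter <- match.arg(filter)
  if (inherits(image, "section_image")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$mep
  }
  check_image(image)
  if (filter == "median3") image <- median_filter3(image)
  th <- resolve_threshold(image, threshold)
  if (is.na(th))
    return(new_binary_mask(matrix(FALSE, nrow(image), ncol(image)),
                           pixel_size_um, NA_real_))
  new_binary_mask(image > th, pixel_size_um, th)
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_motomap("image must be a numeric matrix")
  if (any(image < 0)) stop_motomap("image must be non-negative")
  invisible(image)
}

#' 3x3 median filter
#'
#' Exact 3x3 median with replicate padding at the borders, computed with a
#' vectorised 19-comparison sorting network so the result is bit-exact and
#' independent of any intensity binning.
#'
#' @param image numeric matrix.
#' @return filtered matrix, same shape.
#' @export
median_filter3 <- function(image) {
  check_image(image)
  nr <- nrow(image); nc <- ncol(image)
  pad <- image[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  v <- vector("list", 9)
  k <- 1L
  for (dc in 0:2) for (dr in 0:2) {
    v[[k]] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
    k <- k + 1L
  }
  swap <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  # Paeth's median-of-9 network (indices shifted to 1-based)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 2); swap(4, 5); swap(7, 8)
  swap(2, 3); swap(5, 6); swap(8, 9)
  swap(1, 4); swap(6, 9); swap(5, 8)
  swap(4, 7); swap(2, 5); swap(3, 6)
  swap(5, 8); swap(5, 3); swap(7, 5)
  swap(5, 3)
  v[[5]]
}

#' Coverage ratio of the MEP signal by the tracer region
#'
#' The fraction of MEP-signal pixels that lie inside the tracer (CTB)
#' diffusion region: the two binary masks are multiplied elementwise and the
#' surviving MEP pixels counted, i.e. `|mep & ctb| / |mep|`.
#'
#' @param mep_mask,ctb_mask logical matrices or `binary_mask` objects of the
#'   same shape.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' mep <- matrix(FALSE, 4, 4); mep[1, 1:3] <- TRUE
#' ctb <- matrix(FALSE, 4, 4); ctb[1, 1:2] <- TRUE
#' coverage_ratio(mep, ctb)  # 2/3
coverage_ratio <- function(mep_mask, ctb_mask) {
  mep <- as_mask_matrix(mep_mask, "mep_mask")
  ctb <- as_mask_matrix(ctb_mask, "ctb_mask")
  if (!identical(dim(mep), dim(ctb)))
    stop_motomap("mask shapes differ")
  n_mep <- sum(mep)
  if (n_mep == 0)
    stop_motomap("coverage is undefined for an empty MEP mask")
  sum(mep & ctb) / n_mep
}

#' Per-depth coverage profile and mean coverage
#'
#' Runs both segmentations on every section, computes the per-depth coverage
#' ratio, and aggregates the unweighted mean across depths. Sections whose
#' MEP mask is empty have undefined coverage: they are reported as `NA`,
#' excluded from the mean, and flagged with a warning.
#'
#' @param sections list of `section_image` objects, or list of
#'   `list(depth_um =, tracer =, mep =)` channel pairs.
#' @param filter MEP-channel filter, see [segment_mep_signal()].
#' @param threshold a [threshold_spec()] applied to both channels.
#' @return object of class `coverage_result`: `per_depth` (data.frame:
#'   `depth_um`, `mep_pixels`, `mep_pixels_in_ctb`, `coverage`,
#'   `tracer_threshold`, `mep_threshold`) and `mean_coverage`.
#' @export
coverage_profile <- function(sections, filter = "median3",
                             threshold = threshold_spec("auto")) {
  if (!length(sections)) stop_motomap("need at least one section")
  rows <- lapply(sections, function(s) {
    ctb <- segment_tracer_region(s$tracer, threshold)
    mep <- segment_mep_signal(s$mep, filter, threshold)
    n_mep <- sum(mep$pixels)
    n_in  <- sum(mep$pixels & ctb$pixels)
    data.frame(depth_um = s$depth_um,
               mep_pixels = n_mep, mep_pixels_in_ctb = n_in,
               coverage = if (n_mep > 0) n_in / n_mep else NA_real_,
               tracer_threshold = ctb$threshold,
               mep_threshold = mep$threshold)
  })
  per_depth <- do.call(rbind, rows)
  if (anyDuplicated(per_depth$depth_um))
    stop_motomap("section depths must be distinct")
  if (anyNA(per_depth$coverage))
    warning(sprintf(
      "%d section(s) had an empty MEP mask; excluded from the mean",
      sum(is.na(per_depth$coverage))), call. = FALSE)
  structure(list(per_depth = per_depth,
                 mean_coverage = mean(per_depth$coverage, na.rm = TRUE)),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat("<coverage_result>\n")
  print(x$per_depth, digits = 4, row.names = FALSE)
  cat(sprintf("mean coverage: %.4f\n", x$mean_coverage))
  invisible(x)
}

#' Render a mask for display
#'
#' Converts a binary mask to an 8-bit image (0/255), optionally inverted so
#' foreground prints dark on white, as binarized figures are conventionally
#' shown. Purely cosmetic: inversion changes no pixel count or coverage
#' value.
#'
#' @param mask logical matrix or `binary_mask`.
#' @param invert flip foreground/background grey levels.
#' @return integer matrix with values 0 and 255.
#' @export
as_display <- function(mask, invert = TRUE) {
  m <- as_mask_matrix(mask)
  if (invert) (1L - (m * 1L)) * 255L else (m * 1L) * 255L
}
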