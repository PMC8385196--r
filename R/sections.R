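#' Noise parameters for rendered section images
#'
#' All amplitudes are fractions of the noise-free channel maximum, so the
#' same settings give a comparable signal-to-background on both channels.
#'
#' @param offset_frac constant autofluorescence background level.
#' @param sd_frac standard deviation of additive Gaussian noise.
#' @param impulse_frac fraction of pixels hit by impulse ("salt") noise.
#' @param impulse_amp_frac amplitude of the impulse noise.
#' @return named list of class `section_noise`.
#' @export
section_noise <- function(offset_frac = 0.08, sd_frac = 0.04,
                          impulse_frac = 0.001, impulse_amp_frac = 0.6) {
  structure(list(offset_frac = offset_frac, sd_frac = sd_frac,
                 impulse_frac = impulse_frac,
                 impulse_amp_frac = impulse_amp_frac),
            class = "section_noise")
}

#' Render two-channel muscle section images
#'
#' Emulates sectioning the injected muscle horizontally and imaging each
#' section as a maximum intensity projection (MIP) over a slab of the stated
#' thickness (default 60 um): the tracer channel is the slab MIP of the
#' diffusion field (bilinearly upsampled from the simulation grid to the
#' requested pixel size), and the MEP channel renders every endplate point
#' whose depth falls inside the slab as a small Gaussian punctum truncated at
#' its half-maximum radius. Muscle autofluorescence is added as a constant
#' offset plus Gaussian noise and optional impulse noise.
#'
#' Ground truth accompanies each section: `truth$tracer_mask` is the
#' noise-free tracer channel thresholded at half its per-section maximum,
#' `truth$mep_mask` the noise-free MEP channel thresholded at half a single
#' punctum's peak (because puncta are truncated at half-maximum this equals
#' their rendered support), and `truth$n_puncta` the number of endplate
#' points inside the slab.
#'
#' @param field a [simulate_tracer_diffusion()] result.
#' @param scene the [generate_mep_map()] scene the field lives in.
#' @param depths_um numeric vector of section-centre depths, micrometres.
#' @param noise a [section_noise()]; use zeros for noise-free renders.
#' @param pixel_size_um pixel size of the rendered images; must divide the
#'   simulation voxel size (default `voxel_size_um / 5`).
#' @param slab_um slab thickness for the MIP (default 60).
#' @param punctum_sigma_um Gaussian sigma of one rendered endplate punctum
#'   (default 30).
#' @param seed integer seed for the noise.
#' @return list of `section_image` objects: `depth_um`, `tracer`, `mep`
#'   (matrices, rows x cols), `pixel_size_um`, `slab_um`, `truth`.
#' @export
render_section_images <- function(field, scene, depths_um,
                                  noise = section_noise(),
                                  pixel_size_um = NULL,
                                  slab_um = 60,
                                  punctum_sigma_um = 30,
                                  seed = 1) {
  stopifnot(inherits(field, "tracer_field"), inherits(scene, "mep_scene"))
  if (!length(depths_um)) stop_motomap("`depths_um` must be non-empty")
  assert_scalar_pos(slab_um, "slab_um")
  geometry <- scene$geometry
  vs <- geometry$voxel_size_um
  d  <- dim(geometry$mask)
  if (any(depths_um < 0 | depths_um > d[1] * vs))
    stop_motomap("section depth outside the muscle volume")
  if (is.null(pixel_size_um)) pixel_size_um <- vs / 5
  f <- vs / pixel_size_um
  if (abs(f - round(f)) > 1e-8 || f < 1)
    stop_motomap("`pixel_size_um` must divide the simulation voxel size")
  f <- as.integer(round(f))
  out_dim <- c(d[2], d[3]) * f

  kern <- punctum_kernel(punctum_sigma_um, pixel_size_um)
  sections <- vector("list", length(depths_um))
  for (si in seq_along(depths_um)) {
    dep <- depths_um[si]
    win <- c(dep - slab_um / 2, dep + slab_um / 2)
    iz <- max(1L, um_to_index(win[1], vs)):min(d[1], um_to_index(win[2] - 1e-9, vs))
    slab <- field$concentration[iz, , , drop = FALSE]
    tracer0 <- apply(slab, c(2, 3), max)
    if (f > 1L)
      tracer0 <- as.matrix(EBImage::resize(tracer0, w = out_dim[1],
                                           h = out_dim[2]))
    pts <- scene$mep$points
    in_slab <- pts[, 1] >= win[1] & pts[, 1] < win[2]
    mep0 <- splat_puncta(pts[in_slab, 2:3, drop = FALSE], out_dim,
                         pixel_size_um, kern)
    tr_truth <- tracer0 >= 0.5 * max(tracer0)
    mep_truth <- mep0 >= 0.5      # puncta peak 1, truncated at half-maximum
    ch <- with_seed(derive_seed(seed, si), {
      list(tracer = add_section_noise(tracer0, noise),
           mep    = add_section_noise(mep0, noise))
    })
    sections[[si]] <- structure(
      list(depth_um = dep, tracer = ch$tracer, mep = ch$mep,
           pixel_size_um = pixel_size_um, slab_um = slab_um,
           truth = list(tracer_mask = tr_truth, mep_mask = mep_truth,
                        n_puncta = sum(in_slab))),
      class = "section_image")
  }
  sections
}

# Gaussian punctum kernel truncated at its half-maximum contour (peak 1)
punctum_kernel <- function(sigma_um, pixel_size_um) {
  s <- sigma_um / pixel_size_um
  r <- max(1L, as.integer(ceiling(1.1774 * s)))   # sqrt(2 log 2) sigma
  off <- -r:r
  k <- exp(-outer(off^2, off^2, `+`) / (2 * s^2))
  k[k < 0.5] <- 0
  k
}

splat_puncta <- function(rc_um, out_dim, pixel_size_um, kern) {
  img <- matrix(0, out_dim[1], out_dim[2])
  if (!nrow(rc_um)) return(img)
  r <- (dim(kern)[1] - 1L) %/% 2L
  for (i in seq_len(nrow(rc_um))) {
    ci <- um_to_index(rc_um[i, ], pixel_size_um)
    rr <- (ci[1] - r):(ci[1] + r); cc <- (ci[2] - r):(ci[2] + r)
    okr <- rr >= 1 & rr <= out_dim[1]; okc <- cc >= 1 & cc <= out_dim[2]
    img[rr[okr], cc[okc]] <- pmax(img[rr[okr], cc[okc]],
                                  kern[okr, okc, drop = FALSE])
  }
  img
}

add_section_noise <- function(img, noise) {
  mx <- max(img)
  if (mx <= 0) mx <- 1
  out <- img + noise$offset_frac * mx
  if (noise$sd_frac > 0)
    out <- out + rnorm(length(img), 0, noise$sd_frac * mx)
  if (noise$impulse_frac > 0) {
    hit <- runif(length(img)) < noise$impulse_frac
    out[hit] <- out[hit] + noise$impulse_amp_frac * mx
  }
  pmax(out, 0)
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "<section_image> depth %g um, %dx%d px @ %g um, %d puncta in slab\n",
    x$depth_um, nrow(x$tracer), ncol(x$tracer), x$pixel_size_um,
    x$truth$n_puncta))
  invisible(x)
}

#' Pick section depths spanning the MEP-bearing part of the muscle
#'
#' Returns depths at evenly spaced quantiles of the MEP density mass along
#' the depth axis (between the 5th and 95th percentile), i.e. where sections
#' would actually be cut to see endplates.
#'
#' @param scene a [generate_mep_map()] scene.
#' @param n number of sections.
#' @return numeric vector of depths, micrometres.
#' @export
mep_section_depths <- function(scene, n = 5) {
  stopifnot(inherits(scene, "mep_scene"), n >= 1)
  vs <- scene$geometry$voxel_size_um
  mass <- apply(scene$mep$density, 1, sum)
  cum <- cumsum(mass) / sum(mass)
  z <- index_to_center_um(seq_along(mass), vs)
  probs <- seq(0.05, 0.95, length.out = n)
  vapply(probs, function(p) z[which.min(abs(cum - p))], numeric(1))
}
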