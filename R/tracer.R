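#' Simulate intramuscular tracer diffusion
#'
#' Deposits each injection as an isotropic Gaussian concentration kernel
#' centred at the site, with standard deviation scaling with the cube root of
#' the injected volume:
#' `sigma = spread_um_per_500nl * (volume_nl / 500)^(1/3)`.
#' The fascia is modelled as a reflecting envelope: concentration outside the
#' muscle mask is clipped and each site's clipped mass is renormalized into
#' the mask, so every site contributes total mass equal to its injected
#' volume (mass is therefore proportional to total injected volume).
#'
#' @param plan an [make_injection_plan()] result.
#' @param geometry the [muscle_geometry()] the plan was made on.
#' @param spread_um_per_500nl diffusion scale of a single 500-nl deposit,
#'   micrometres (default 400).
#' @param seed kept for interface uniformity; the operation is deterministic.
#' @return object of class `tracer_field`: `concentration` (3D array, same
#'   grid as `geometry$mask`, in nanolitre-mass units), `plan`,
#'   `voxel_size_um`.
#' @export
simulate_tracer_diffusion <- function(plan, geometry,
                                      spread_um_per_500nl = 400,
                                      seed = NULL) {
  stopifnot(inherits(plan, "injection_plan"),
            inherits(geometry, "muscle_geometry"))
  assert_scalar_pos(spread_um_per_500nl, "spread_um_per_500nl")
  vs <- geometry$voxel_size_um
  d  <- dim(geometry$mask)
  pts <- as.matrix(plan$sites[, c("depth_um", "row_um", "col_um")])
  if (!all(point_in_mask(pts, geometry)))
    stop_motomap("injection site outside the muscle mask")

  conc <- array(0, d)
  for (i in seq_len(nrow(plan$sites))) {
    s <- plan$sites[i, ]
    sigma <- spread_um_per_500nl * (s$volume_nl / 500)^(1 / 3)
    r <- ceiling(4 * sigma / vs)
    ctr <- c(s$depth_um, s$row_um, s$col_um)
    ci <- um_to_index(ctr, vs)
    lo <- pmax(ci - r, 1L); hi <- pmin(ci + r, d)
    iz <- lo[1]:hi[1]; ir <- lo[2]:hi[2]; ic <- lo[3]:hi[3]
    kz <- exp(-((index_to_center_um(iz, vs) - ctr[1])^2) / (2 * sigma^2))
    kr <- exp(-((index_to_center_um(ir, vs) - ctr[2])^2) / (2 * sigma^2))
    kc <- exp(-((index_to_center_um(ic, vs) - ctr[3])^2) / (2 * sigma^2))
    k <- outer(outer(kz, kr), kc) * geometry$mask[iz, ir, ic]
    tot <- sum(k)
    if (tot <= 0) stop_motomap("injection kernel has no mass inside the mask")
    conc[iz, ir, ic] <- conc[iz, ir, ic] + k * (s$volume_nl / tot)
  }
  structure(list(concentration = conc, plan = plan, voxel_size_um = vs),
            class = "tracer_field")
}

#' Empirical spatial standard deviation of a tracer field
#'
#' Mass-weighted standard deviation of voxel-centre positions, averaged over
#' the three axes; a scale measure used to verify the volume-to-spread
#' scaling law.
#'
#' @param field a [simulate_tracer_diffusion()] result.
#' @return scalar, micrometres.
#' @export
tracer_spatial_sd <- function(field) {
  stopifnot(inherits(field, "tracer_field"))
  w <- as.vector(field$concentration)
  d <- dim(field$concentration)
  vs <- field$voxel_size_um
  ai <- arrayInd(seq_along(w), d)
  sw <- sum(w)
  v <- vapply(1:3, function(a) {
    x <- (ai[, a] - 0.5) * vs
    mu <- sum(w * x) / sw
    sum(w * (x - mu)^2) / sw
  }, numeric(1))
  mean(sqrt(v))
}
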