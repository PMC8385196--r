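#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils head read.csv write.csv str packageVersion
NULL

# Axis convention used throughout: arrays are indexed [depth, row, col] for
# muscle volumes (depth = sectioning/injection axis) and [rc, ml, vd] for
# spinal-cord volumes (axis 1 = rostro-caudal, 2 = medio-lateral,
# 3 = ventro-dorsal). Physical coordinates are in micrometres; the voxel with
# index i spans [(i-1)*vs, i*vs) so um -> index is floor(um/vs) + 1.

um_to_index <- function(um, voxel_size_um) {
  as.integer(floor(um / voxel_size_um)) + 1L
}

index_to_center_um <- function(i, voxel_size_um) {
  (i - 0.5) * voxel_size_um
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a child RNG seed
#'
#' All stochastic operations take a single integer seed; nested stages derive
#' their own seeds deterministically so a pipeline rerun with the same master
#' seed is bit-identical.
#'
#' @param seed integer master seed.
#' @param offset non-negative integer identifying the consumer.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + as.double(offset) * 12289L) %%
               2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_motomap <- function(...) stop(..., call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_motomap(sprintf("`%s` must be a positive finite scalar", name))
  invisible(x)
}
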