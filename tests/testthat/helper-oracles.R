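# Independent reference implementations used as oracles. These deliberately
# use naive per-pixel algorithms, not the package's code paths.

# Border flood fill: every background pixel 4-connected to the border stays
# background, every other background pixel is a hole and becomes foreground.
brute_force_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if ((r == 1 || r == nr || c == 1 || c == nc) && !mask[r, c]) {
      reach[r, c] <- TRUE
      queue[[length(queue) + 1L]] <- c(r, c)
    }
  }
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          !mask[q[1], q[2]] && !reach[q[1], q[2]]) {
        reach[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1L]] <- q
      }
    }
  }
  mask | !reach
}

# 3x3 median by explicit sort, replicate-padded borders
median3_oracle <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc))
    out[r, c] <- sort(as.vector(pad[r:(r + 2), c:(c + 2)]))[5]
  out
}

# coverage by an explicit double loop
coverage_loop_oracle <- function(mep, ctb) {
  n_mep <- 0L; n_in <- 0L
  for (r in seq_len(nrow(mep))) for (c in seq_len(ncol(mep))) {
    if (mep[r, c]) {
      n_mep <- n_mep + 1L
      if (ctb[r, c]) n_in <- n_in + 1L
    }
  }
  n_in / n_mep
}

rand_mask <- function(nr, nc, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# hand-built injection plan (bypasses the placement logic) for tracer tests
manual_plan <- function(sites_df, muscle_kind = "gastrocnemius",
                        strategy = "3D") {
  structure(list(strategy = strategy, muscle_kind = muscle_kind,
                 sites = sites_df,
                 total_volume_nl = sum(sites_df$volume_nl)),
            class = "injection_plan")
}

# small, fast scene for tests that only need plumbing, not realism
tiny_ta_scene <- function(seed = 1, n_points = 300) {
  generate_mep_map("tibialis_anterior", n_points = n_points, seed = seed,
                   voxel_size_um = 200)
}
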