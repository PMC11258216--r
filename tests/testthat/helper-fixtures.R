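# Shared fixtures, built in code at test time.

# tiny deterministic 4-D volume with distinct values per voxel and bin
tiny_volume <- function(nx = 4, ny = 5, nz = 3, binning = default_binning()) {
  nb <- n_bins(binning)
  data <- array(seq_len(nx * ny * nz * nb) / 10, dim = c(nx, ny, nz, nb))
  spectral_volume(data, binning, voxel_size_um = 90)
}

# small phantom configuration used across modules (fast to build)
small_phantom_config <- function(seed = 11, ...) {
  phantom_config(grid = c(24, 24, 16), seed = seed, ...)
}

# cohort at the generator's default conditions (grid, noise, geometry)
small_cohort_spec <- function(seed, model_a = NULL, model_b = NULL,
                              n_mice = 6L) {
  args <- list(n_mice = n_mice, seed = seed)
  if (!is.null(model_a)) args$model_a <- model_a
  if (!is.null(model_b)) args$model_b <- model_b
  do.call(cohort_spec, args)
}

# slicewise-jittered disc stack: smooth in the annotation (axial) view,
# zigzag across slices
jittered_ellipse_mask <- function(grid = c(30, 30, 20), seed = 5) {
  mask <- array(FALSE, dim = grid)
  set.seed(seed)
  for (k in 5:16) {
    cx <- grid[1] / 2 + sample(-2:2, 1)
    cy <- grid[2] / 2 + sample(-2:2, 1)
    r <- 7 + sample(-1:1, 1)
    xs <- matrix(seq_len(grid[1]), grid[1], grid[2])
    ys <- matrix(seq_len(grid[2]), grid[1], grid[2], byrow = TRUE)
    mask[, , k] <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  }
  mask
}

punctate_model <- function(vessel_density) {
  list(regime = "punctate_np", agent = "barium_np", agent_fraction = 0.08,
       vessel_density = vessel_density, vessel_radius = 1.5)
}

# usable-channel material signatures of the default phantom materials
default_signatures <- function() {
  bn <- default_binning()
  lapply(default_materials(), function(m) bin_attenuation(m, bn)[bn$usable])
}

# volume whose usable-channel voxels take prescribed values inside masks:
# base value everywhere, per-mask overrides (same value in all channels
# unless a length-3 vector is given)
mask_volume <- function(grid, assignments, base = 0) {
  nb <- 5L
  data <- array(base, dim = c(grid, nb))
  for (a in assignments) {
    vals <- if (length(a$value) == 1L) rep(a$value, nb) else
      c(a$value[1], a$value, a$value[3])  # pad unusable bins
    for (b in seq_len(nb)) {
      sl <- data[, , , b]
      sl[a$mask] <- vals[b]
      data[, , , b] <- sl
    }
  }
  spectral_volume(data, default_binning())
}

# right-tailed rank-sum p by full enumeration over index subsets
enumerate_ranksum_p <- function(x, y) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  subsets <- utils::combn(N, n)
  sums <- apply(subsets, 2, function(idx) sum(r[idx]))
  mean(sums >= W)
}
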