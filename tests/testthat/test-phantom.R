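# fine-grid numerical oracle for the bin-averaged attenuation
numeric_bin_attenuation <- function(m, binning, cap_keV = 80) {
  vapply(seq_len(n_bins(binning)), function(b) {
    iv <- bin_interval(binning, b, cap_keV)
    E <- seq(iv[1], iv[2], length.out = 20001)
    jump <- if (is.null(m$kedge_keV)) rep(1, length(E)) else
      ifelse(E >= m$kedge_keV, m$kedge_jump, 1)
    mu <- m$pe_coeff * E^-3 * jump + m$compton_coeff
    mean((mu[-1] + mu[-length(mu)]) / 2)  # trapezoid / uniform grid
  }, numeric(1))
}

test_that("material spec validates coefficients and K-edge jump", {
  expect_error(material_spec("x", -1, 0.2), "pe_coeff")
  expect_error(material_spec("x", 1, 0.2, kedge_keV = 33), "kedge_jump")
  expect_error(material_spec("x", 1, 0.2, kedge_keV = 33, kedge_jump = 1),
               "kedge_jump")
})

test_that("energy-flat material has the Compton value in every bin", {
  m <- material_spec("flat", pe_coeff = 0, compton_coeff = 0.2)
  expect_equal(bin_attenuation(m, default_binning()), rep(0.2, 5))
})

test_that("closed-form bin attenuation matches the fine-grid oracle", {
  bn <- default_binning()
  for (m in default_materials()) {
    expect_equal(bin_attenuation(m, bn), numeric_bin_attenuation(m, bn),
                 tolerance = 1e-6)
  }
})

test_that("a 33 keV K-edge raises the (30,47) bin and leaves lower bins", {
  bn <- default_binning()
  with_edge <- material_spec("i", 30000, 0.2, kedge_keV = 33,
                             kedge_jump = 5)
  without <- material_spec("i0", 30000, 0.2)
  a <- bin_attenuation(with_edge, bn)
  b <- bin_attenuation(without, bn)
  expect_gt(a[3], b[3])
  expect_equal(a[1:2], b[1:2])  # bins entirely below 30 keV unchanged
})

test_that("soft-tissue bins decrease monotonically with energy", {
  mu <- bin_attenuation(default_materials()$soft_tissue, default_binning())
  expect_true(all(diff(mu) < 0))
})

test_that("noiseless phantom voxels equal the material mixtures exactly", {
  cfg <- small_phantom_config(noise_snr = Inf)
  ph <- build_phantom(cfg)
  bn <- cfg$binning
  mu <- lapply(cfg$materials, bin_attenuation, binning = bn)
  gt <- ph$ground_truth
  expect_true(all(gt$agent_fraction >= 0 & gt$agent_fraction <= 1))

  # pure-muscle voxels (no agent) carry the muscle bin vector exactly
  muscle_vox <- which(gt$labels == match("muscle", gt$material_names) &
                        gt$agent_fraction == 0)[1]
  idx <- arrayInd(muscle_vox, dim(gt$labels))
  expect_equal(as.numeric(ph$volume$data[idx[1], idx[2], idx[3], ]),
               mu$muscle)

  # diffuse tumor voxels are the exact (1-f) muscle + f agent mixture
  f <- cfg$tumors[[1]]$agent_fraction
  tmask <- ph$rois$masks$tumor_left
  tidx <- which(tmask, arr.ind = TRUE)[1, , drop = FALSE]
  expect_equal(as.numeric(ph$volume$data[tidx[1], tidx[2], tidx[3], ]),
               (1 - f) * mu$muscle + f * mu$iodine_agent)
})

test_that("doubling the agent fraction doubles its noiseless contribution", {
  base_mu <- NULL
  vals <- lapply(c(0.02, 0.04), function(f) {
    tumors <- list(list(name = "tumor_left",
                        center = c(0.28, 0.64, 0.50) * c(24, 24, 16),
                        radii = c(0.14, 0.14, 0.16) * c(24, 24, 16),
                        regime = "diffuse_iodine", agent = "iodine_agent",
                        agent_fraction = f))
    ph <- build_phantom(small_phantom_config(noise_snr = Inf,
                                             tumors = tumors))
    list(tumor = roi_values(ph$volume, ph$rois$masks$tumor_left)[1, ],
         muscle = roi_values(ph$volume, ph$rois$masks$muscle)[1, ])
  })
  d1 <- vals[[1]]$tumor - vals[[1]]$muscle
  d2 <- vals[[2]]$tumor - vals[[2]]$muscle
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("background SNR calibration hits the target within 10%", {
  ph <- build_phantom(small_phantom_config(seed = 21, noise_snr = 20))
  measured <- snr(ph$volume, ph$rois$masks$muscle)
  expect_true(all(abs(measured - 20) / 20 < 0.10))
})

test_that("the seed fixes all randomness; different seeds differ", {
  a <- build_phantom(small_phantom_config(seed = 5))
  b <- build_phantom(small_phantom_config(seed = 5))
  c <- build_phantom(small_phantom_config(seed = 6))
  expect_identical(a$volume$data, b$volume$data)
  expect_false(identical(a$volume$data, c$volume$data))
  # noiseless structure is seed-independent
  expect_identical(a$ground_truth$labels, c$ground_truth$labels)
})

test_that("build_phantom leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(build_phantom(small_phantom_config(seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("geometry outside the grid is a configuration error", {
  expect_error(
    phantom_config(grid = c(24, 24, 16),
                   body = list(center = c(12, 12, 8), radii = c(30, 5, 5))),
    "outside the grid")
})

test_that("a cohort yields n volumes with paired tumor masks", {
  co <- build_cohort(small_cohort_spec(seed = 31))
  expect_length(co, 6L)
  tumor_masks <- unlist(lapply(co, function(ph)
    names(roi_masks(ph$rois, "tumor"))))
  expect_length(tumor_masks, 12L)
  expect_setequal(unique(tumor_masks), c("tumor_left", "tumor_right"))
  expect_error(cohort_spec(n_mice = 1), ">= 2")
  # independent noise between mice
  expect_false(identical(co[[1]]$volume$data, co[[2]]$volume$data))
})

test_that("identical tumor models give paired differences centered on 0", {
  m <- punctate_model(8)
  dbar <- vapply(7000 + 97 * (1:25), function(s) {
    co <- build_cohort(small_cohort_spec(seed = s, model_a = m,
                                         model_b = m))
    f <- cohort_features(co)
    fa <- f[f$model == "A" & f$channel == 2, "mean"]
    fb <- f[f$model == "B" & f$channel == 2, "mean"]
    mean(fa - fb)
  }, numeric(1))
  expect_lt(abs(mean(dbar)), 3 * stats::sd(dbar) / sqrt(length(dbar)))
})

test_that("higher vessel density raises tumor std in expectation", {
  co <- build_cohort(small_cohort_spec(seed = 41,
                                       model_a = punctate_model(20),
                                       model_b = punctate_model(2.5)))
  f <- cohort_features(co)
  for (ch in 1:3) {
    sa <- f[f$model == "A" & f$channel == ch, "std"]
    sb <- f[f$model == "B" & f$channel == ch, "std"]
    expect_gt(mean(sa), mean(sb))
  }
})
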