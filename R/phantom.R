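# Synthetic spectral phantom generator.
#
# Emulates contrast-enhanced mouse scans so the whole pipeline can be
# exercised without scan data: a soft-tissue body, a muscle background
# region, a bone rod, and paired tumors enhanced either diffusely (small-
# molecule iodine-like agent) or as punctate vessel dots (barium
# nanoparticle-like agent). Attenuation follows a parametric
# photoelectric + Compton model with a multiplicative K-edge jump;
# reconstruction noise is additive Gaussian, calibrated to a target
# background SNR.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Parametric spectral attenuation model of one material
#'
#' Linear attenuation is modeled as
#' `mu(E) = pe_coeff * E^-3 * jump(E) + compton_coeff`, with
#' `jump(E) = kedge_jump` at and above the K-edge energy and 1 below it.
#' The `E^-3` term captures photoelectric absorption, the flat term
#' Compton scattering; the multiplicative jump reproduces the abrupt
#' attenuation increase at the K-shell binding energy that high-Z contrast
#' agents (iodine ~33 keV, barium ~37 keV) exhibit.
#'
#' @param name Material identifier.
#' @param pe_coeff Photoelectric amplitude (cm^-1 keV^3), >= 0.
#' @param compton_coeff Energy-flat amplitude (cm^-1), >= 0.
#' @param kedge_keV Optional K-edge energy (keV).
#' @param kedge_jump Multiplicative jump factor (> 1) applied to the
#'   photoelectric term at and above `kedge_keV`.
#' @return An object of class `material_spec`.
#' @export
material_spec <- function(name, pe_coeff, compton_coeff,
                          kedge_keV = NULL, kedge_jump = NULL) {
  stopifnot(pe_coeff >= 0, compton_coeff >= 0)
  if (!is.null(kedge_keV)) {
    if (is.null(kedge_jump) || !isTRUE(kedge_jump > 1))
      stop("kedge_jump must be > 1 when kedge_keV is set", call. = FALSE)
    stopifnot(kedge_keV > 0)
  }
  structure(list(name = name, pe_coeff = pe_coeff,
                 compton_coeff = compton_coeff,
                 kedge_keV = kedge_keV, kedge_jump = kedge_jump),
            class = "material_spec")
}

#' Default phantom materials
#'
#' Coefficients are chosen to give realistic soft-tissue/bone attenuation
#' at diagnostic energies (water-like tissue ~0.5 cm^-1 in the 20-30 keV
#' bin, cortical-bone-like ~2 cm^-1 at 30 keV) and agent signatures whose
#' K-edges fall inside the (30,47) keV bin. Tumor parenchyma is matched to
#' muscle so that tumor contrast in the phantom comes from the agent alone.
#'
#' @return Named list of `material_spec` objects: `soft_tissue`, `muscle`,
#'   `bone`, `iodine_agent` (K-edge 33 keV), `barium_np` (K-edge 37 keV).
#' @export
default_materials <- function() {
  list(
    soft_tissue  = material_spec("soft_tissue", pe_coeff = 5300,
                                 compton_coeff = 0.18),
    muscle       = material_spec("muscle", pe_coeff = 5800,
                                 compton_coeff = 0.19),
    bone         = material_spec("bone", pe_coeff = 50000,
                                 compton_coeff = 0.28),
    iodine_agent = material_spec("iodine_agent", pe_coeff = 30000,
                                 compton_coeff = 0.20,
                                 kedge_keV = 33, kedge_jump = 5),
    barium_np    = material_spec("barium_np", pe_coeff = 30000,
                                 compton_coeff = 0.20,
                                 kedge_keV = 37, kedge_jump = 5)
  )
}

# exact integral of E^-3 * jump(E) over [lo, hi]
pe_integral <- function(lo, hi, kedge, jump) {
  intE3 <- function(a, b) (a^-2 - b^-2) / 2
  if (is.null(kedge) || kedge <= lo) {
    j <- if (is.null(kedge)) 1 else jump
    return(j * intE3(lo, hi))
  }
  if (kedge >= hi) return(intE3(lo, hi))
  intE3(lo, kedge) + jump * intE3(kedge, hi)
}

#' Bin-averaged attenuation of a material
#'
#' Mean of `mu(E)` over each energy bin, computed in closed form (the
#' photoelectric integral has the antiderivative `-E^-2/2`, split at the
#' K-edge when it falls inside a bin). The open top bin is integrated up to
#' `cap_keV`, the tube potential.
#'
#' @param m A `material_spec`.
#' @param binning An `energy_binning`.
#' @param cap_keV Finite cap for the open top bin (keV), default 80.
#' @return Numeric vector, one mean attenuation (cm^-1) per bin.
#' @export
bin_attenuation <- function(m, binning, cap_keV = 80) {
  stopifnot(inherits(m, "material_spec"), inherits(binning, "energy_binning"))
  vapply(seq_len(n_bins(binning)), function(b) {
    iv <- bin_interval(binning, b, cap_keV)
    m$pe_coeff * pe_integral(iv[1], iv[2], m$kedge_keV, m$kedge_jump) /
      (iv[2] - iv[1]) + m$compton_coeff
  }, numeric(1))
}

# ---- geometry primitives -------------------------------------------------

ellipsoid_mask <- function(grid, center, radii) {
  dx2 <- ((seq_len(grid[1]) - center[1]) / radii[1])^2
  dy2 <- ((seq_len(grid[2]) - center[2]) / radii[2])^2
  dz2 <- ((seq_len(grid[3]) - center[3]) / radii[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  array(m, dim = grid)
}

cylinder_mask_z <- function(grid, center_xy, radius, z_range) {
  dx2 <- (seq_len(grid[1]) - center_xy[1])^2
  dy2 <- (seq_len(grid[2]) - center_xy[2])^2
  inplane <- outer(dx2, dy2, "+") <= radius^2
  zin <- seq_len(grid[3]) >= z_range[1] & seq_len(grid[3]) <= z_range[2]
  array(outer(inplane, zin, "&"), dim = grid)
}

check_inside_grid <- function(center, radii, grid, what) {
  if (any(center - radii < 0.5) || any(center + radii > grid + 0.5))
    stop(what, " geometry extends outside the grid", call. = FALSE)
}

ellipsoid_spec <- function(center, radii) list(center = center, radii = radii)

#' Phantom configuration
#'
#' Describes one synthetic scan: grid, binning, geometry and enhancement
#' regimes. Geometry defaults scale with the grid: an elliptical body, a
#' muscle region (the CNR/SNR background), a bone rod, and two lateral
#' tumors. Per-tumor regimes:
#' \describe{
#'   \item{`diffuse_iodine`}{the agent is mixed uniformly through the whole
#'     tumor at volume fraction `agent_fraction` (whole-volume enhancement
#'     of a freely diffusing small-molecule agent).}
#'   \item{`punctate_np`}{Poisson-count spherical vessel dots of the agent
#'     are placed uniformly inside the tumor (vessel-confined nanoparticle
#'     enhancement: bright spots, unenhanced parenchyma between them).}
#' }
#'
#' @param grid Integer spatial dimensions `c(nx, ny, nz)`.
#' @param voxel_size_um Isotropic voxel pitch (um), default 90.
#' @param binning Energy binning; default [default_binning()].
#' @param cap_keV Finite cap for the open top bin (keV).
#' @param materials Named list of `material_spec`s.
#' @param tumors List of tumor specs; each a list with `name`, `center`,
#'   `radii`, `regime` (`"diffuse_iodine"` or `"punctate_np"`), `agent`
#'   (material name), `agent_fraction`, and for the punctate regime
#'   `vessel_density` (expected dots per 1000 tumor voxels) and
#'   `vessel_radius` (voxels). `NULL` gives one diffuse and one punctate
#'   tumor at the default lateral positions.
#' @param body,muscle,bone Geometry overrides (`ellipsoid_spec(center,
#'   radii)`; for bone a list with `center_xy`, `radius`, `z_range`).
#' @param noise_snr Target background-muscle SNR (mean/std over the muscle
#'   region); noise sigma per bin is calibrated to reach it. `Inf` disables
#'   noise. Default 20, the midpoint of image quality typical of in vivo
#'   photon-counting micro-CT.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid = c(40, 40, 24), voxel_size_um = 90,
                           binning = default_binning(), cap_keV = 80,
                           materials = default_materials(),
                           tumors = NULL, body = NULL, muscle = NULL,
                           bone = NULL, noise_snr = 20, seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, all(grid >= 4L), noise_snr > 0)
  if (is.null(body))
    body <- ellipsoid_spec(grid / 2 + 0.5, 0.46 * grid)
  if (is.null(muscle))
    muscle <- ellipsoid_spec(c(0.50, 0.28, 0.50) * grid,
                             c(0.12, 0.10, 0.30) * grid)
  if (is.null(bone))
    bone <- list(center_xy = c(0.5, 0.45) * grid[1:2],
                 radius = 0.05 * grid[1],
                 z_range = c(1L, grid[3]))
  if (is.null(tumors)) {
    radii <- c(0.14, 0.14, 0.16) * grid
    tumors <- list(
      list(name = "tumor_left", center = c(0.28, 0.64, 0.50) * grid,
           radii = radii, regime = "diffuse_iodine", agent = "iodine_agent",
           agent_fraction = 0.03),
      list(name = "tumor_right", center = c(0.72, 0.64, 0.50) * grid,
           radii = radii, regime = "punctate_np", agent = "barium_np",
           agent_fraction = 0.08, vessel_density = 20, vessel_radius = 1.5)
    )
  }
  check_inside_grid(body$center, body$radii, grid, "body")
  check_inside_grid(muscle$center, muscle$radii, grid, "muscle")
  for (tm in tumors) {
    check_inside_grid(tm$center, tm$radii, grid, tm$name)
    tm$regime <- match.arg(tm$regime, c("diffuse_iodine", "punctate_np"))
    if (!tm$agent %in% names(materials))
      stop("unknown agent material: ", tm$agent, call. = FALSE)
  }
  structure(list(grid = grid, voxel_size_um = voxel_size_um,
                 binning = binning, cap_keV = cap_keV,
                 materials = materials, tumors = tumors, body = body,
                 muscle = muscle, bone = bone, noise_snr = noise_snr,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# place Poisson-count spherical dots uniformly inside a tumor mask;
# returns the logical dot mask (clipped to the tumor)
place_vessel_dots <- function(grid, tumor_mask, density_per_1000, radius) {
  idx <- which(tumor_mask, arr.ind = TRUE)
  n_vox <- nrow(idx)
  n_dots <- stats::rpois(1, density_per_1000 * n_vox / 1000)
  dots <- array(FALSE, dim = grid)
  if (n_dots == 0L) return(dots)
  centers <- idx[sample.int(n_vox, n_dots, replace = TRUE), , drop = FALSE]
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2, , drop = FALSE]
  for (k in seq_len(n_dots)) {
    pts <- cbind(centers[k, 1] + off$dx, centers[k, 2] + off$dy,
                 centers[k, 3] + off$dz)
    keep <- pts[, 1] >= 1 & pts[, 1] <= grid[1] &
            pts[, 2] >= 1 & pts[, 2] <= grid[2] &
            pts[, 3] >= 1 & pts[, 3] <= grid[3]
    dots[pts[keep, , drop = FALSE]] <- TRUE
  }
  dots & tumor_mask
}

#' Build one synthetic spectral phantom
#'
#' Composes the configured geometry into a noiseless multi-bin volume
#' (voxel value in bin b = sum over materials of fraction x bin-averaged
#' attenuation), adds the enhancement regime of each tumor, then additive
#' zero-mean Gaussian noise whose per-bin sigma is the noiseless muscle
#' mean divided by the target SNR (so the measured background SNR matches
#' the target in expectation). All randomness is fixed by `cfg$seed`.
#'
#' @param cfg A `phantom_config`.
#' @return List with elements `volume` (a `spectral_volume`), `rois` (an
#'   `roi_set` with the tumor masks and the muscle background mask), and
#'   `ground_truth` (list: `labels` integer material map, `material_names`,
#'   `agent_fraction` per-voxel agent volume fraction, `noise_sigma`
#'   per-bin sigma used).
#' @export
build_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  grid <- cfg$grid
  nb <- n_bins(cfg$binning)
  mu <- lapply(cfg$materials, bin_attenuation, binning = cfg$binning,
               cap_keV = cfg$cap_keV)
  mat_names <- names(cfg$materials)

  labels <- array(0L, dim = grid)  # 0 = air
  code <- function(nm) match(nm, mat_names)
  labels[ellipsoid_mask(grid, cfg$body$center, cfg$body$radii)] <-
    code("soft_tissue")
  labels[cylinder_mask_z(grid, cfg$bone$center_xy, cfg$bone$radius,
                         cfg$bone$z_range)] <- code("bone")
  muscle_mask <- ellipsoid_mask(grid, cfg$muscle$center, cfg$muscle$radii)
  labels[muscle_mask] <- code("muscle")

  agent_frac <- array(0, dim = grid)
  agent_code <- array(0L, dim = grid)
  masks <- list(muscle = muscle_mask)
  roles <- c(muscle = "background_muscle")

  with_seed(cfg$seed, {
    for (tm in cfg$tumors) {
      tmask <- ellipsoid_mask(grid, tm$center, tm$radii)
      labels[tmask] <- code("muscle")  # parenchyma matched to muscle
      if (tm$regime == "diffuse_iodine") {
        enhanced <- tmask
      } else {
        enhanced <- place_vessel_dots(grid, tmask, tm$vessel_density,
                                      tm$vessel_radius)
      }
      agent_frac[enhanced] <- tm$agent_fraction
      agent_code[enhanced] <- code(tm$agent)
      masks[[tm$name]] <- tmask
      roles[[tm$name]] <- "tumor"
    }

    data <- array(0, dim = c(grid, nb))
    for (b in seq_len(nb)) {
      mu_b <- c(0, vapply(mu, `[`, numeric(1), b))  # 0 for air
      base <- array(mu_b[labels + 1L], dim = grid)
      agent_b <- array(mu_b[agent_code + 1L], dim = grid)
      data[, , , b] <- (1 - agent_frac) * base + agent_frac * agent_b
    }

    sigma <- rep(0, nb)
    if (is.finite(cfg$noise_snr)) {
      for (b in seq_len(nb)) {
        sl <- data[, , , b]
        sigma[b] <- mean(sl[muscle_mask]) / cfg$noise_snr
      }
      noise <- array(stats::rnorm(prod(grid) * nb), dim = c(grid, nb))
      data <- data + sweep(noise, 4, sigma, "*")
    }

    list(
      volume = spectral_volume(data, cfg$binning,
                               voxel_size_um = cfg$voxel_size_um),
      rois = roi_set(masks, roles, geometry = grid),
      ground_truth = list(labels = labels, material_names = mat_names,
                          agent_fraction = agent_frac, noise_sigma = sigma)
    )
  })
}

#' Cohort specification for paired two-tumor experiments
#'
#' Each simulated mouse bears one tumor of model A (left) and one of model
#' B (right), scanned simultaneously — the paired design that lets the
#' discrimination stage cancel per-animal differences. Models are lists of
#' tumor parameters (`regime`, `agent`, `agent_fraction`, `vessel_density`,
#' `vessel_radius`) applied to the default lateral tumor geometry.
#'
#' Defaults emulate a high-vascularity vs low-vascularity contrast under
#' nanoparticle enhancement: both tumors punctate, model A with 8x the
#' vessel-dot density of model B.
#'
#' @param n_mice Number of mice (>= 2; 6 in a typical imaging session).
#' @param model_a,model_b Tumor model parameter lists (see above).
#' @param base Shared `phantom_config` template (grid, noise, materials).
#' @param seed Cohort seed; mouse i uses `seed + i`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mice = 6L,
                        model_a = list(regime = "punctate_np",
                                       agent = "barium_np",
                                       agent_fraction = 0.08,
                                       vessel_density = 20,
                                       vessel_radius = 1.5),
                        model_b = list(regime = "punctate_np",
                                       agent = "barium_np",
                                       agent_fraction = 0.08,
                                       vessel_density = 2.5,
                                       vessel_radius = 1.5),
                        base = phantom_config(),
                        seed = 1L) {
  n_mice <- as.integer(n_mice)
  if (n_mice < 2L)
    stop("n_mice must be >= 2 for paired testing", call. = FALSE)
  structure(list(n_mice = n_mice, model_a = model_a, model_b = model_b,
                 base = base, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a paired cohort of two-tumor phantoms
#'
#' @param spec A `cohort_spec`.
#' @return List of length `n_mice`; each element is the [build_phantom()]
#'   result plus `mouse` (index) and tumor masks named `tumor_left`
#'   (model A) and `tumor_right` (model B).
#' @export
build_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- spec$base
  tumor_geom <- lapply(base$tumors, function(tm) tm[c("name", "center", "radii")])
  stopifnot(length(tumor_geom) == 2L)
  lapply(seq_len(spec$n_mice), function(i) {
    tumors <- list(
      utils::modifyList(tumor_geom[[1]], spec$model_a),
      utils::modifyList(tumor_geom[[2]], spec$model_b)
    )
    cfg <- phantom_config(grid = base$grid,
                          voxel_size_um = base$voxel_size_um,
                          binning = base$binning, cap_keV = base$cap_keV,
                          materials = base$materials, tumors = tumors,
                          body = base$body, muscle = base$muscle,
                          bone = base$bone, noise_snr = base$noise_snr,
                          seed = spec$seed + i)
    ph <- build_phantom(cfg)
    ph$mouse <- i
    ph
  })
}
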