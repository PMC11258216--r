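# K-edge-aware RGB colorization of spectral volumes.
#
# A pixel's three usable-channel values form a vector y in RGB space: its
# direction (color tone) is a material signature invariant to concentration,
# its length is intensity. The basic view assigns channels directly to
# R,G,B; the improved view first applies an invertible 3x3 matrix C that
# magnifies inter-material tone differences (weighted inter-channel
# subtractions) without breaking tone uniqueness, since C is invertible.

#' Invertible channel transform for RGB colorization
#'
#' @param C Invertible 3x3 weight matrix applied per pixel to the usable
#'   channel vector (I1, I2, I3). The identity reproduces the basic direct
#'   channel assignment exactly.
#' @param brightness_mode `"percentile_auto"` (scale so the given
#'   percentile of positive pre-render values maps to 1) or
#'   `"fixed_scalar"` (multiply by a fixed constant).
#' @param brightness_value Percentile (default 99) or the fixed scalar.
#' @param det_tol Singularity tolerance on `|det C|`.
#' @return An object of class `channel_transform`.
#' @export
channel_transform <- function(C = diag(3),
                              brightness_mode = c("percentile_auto",
                                                  "fixed_scalar"),
                              brightness_value = 99, det_tol = 1e-8) {
  C <- as.matrix(C)
  if (!identical(dim(C), c(3L, 3L)))
    stop("C must be a 3x3 matrix", call. = FALSE)
  if (abs(det(C)) <= det_tol)
    stop("C is singular (|det| <= ", det_tol, "): the transform must be ",
         "invertible to preserve tone uniqueness", call. = FALSE)
  brightness_mode <- match.arg(brightness_mode)
  structure(list(C = C, brightness_mode = brightness_mode,
                 brightness_value = brightness_value),
            class = "channel_transform")
}

#' Published channel-weight presets
#'
#' `"session23"` is the preset tuned for the filtered higher-dose protocol:
#' R = 1.5 (I1 - I2), G = 2.5 (I2 - I3), B = 0.34 I3. `"session1"` uses
#' coefficients 1, 2, 0.3 for the unfiltered protocol so both render with
#' similar tones. `"identity"` reproduces the basic direct assignment.
#' Weights are data, not constants: other scanning protocols or agents
#' need their own tuning.
#'
#' @param name Preset name.
#' @param ... Passed to [channel_transform()] (brightness settings).
#' @return A `channel_transform`.
#' @export
transform_preset <- function(name = c("session23", "session1", "identity"),
                             ...) {
  name <- match.arg(name)
  C <- switch(name,
    session23 = rbind(c(1.5, -1.5, 0), c(0, 2.5, -2.5), c(0, 0, 0.34)),
    session1  = rbind(c(1, -1, 0), c(0, 2, -2), c(0, 0, 0.3)),
    identity  = diag(3))
  channel_transform(C, ...)
}

# accept [n, 3] matrix, [u, v, 3] slice or [x, y, z, 3] sub-volume;
# returns list(mat = n x 3, redim = original dim or NULL)
as_channel_matrix <- function(channels) {
  d <- dim(channels)
  if (is.null(d) && length(channels) == 3L) {
    return(list(mat = matrix(channels, 1L, 3L), redim = NULL, vec = TRUE))
  }
  if (d[length(d)] != 3L)
    stop("last dimension must hold the 3 channels", call. = FALSE)
  list(mat = matrix(channels, ncol = 3L), redim = d, vec = FALSE)
}

reshape_back <- function(mat, info) {
  if (isTRUE(info$vec)) return(drop(mat))
  if (is.null(info$redim)) return(mat)
  array(mat, dim = info$redim)
}

#' Basic RGB assignment: channels mapped directly to R, G, B
#'
#' Pure relabeling (I_R = I1, I_G = I2, I_B = I3): output equals input.
#' Kept as an explicit stage so provenance records which view was rendered.
#'
#' @param channels 3-channel array (last dimension = channel) or length-3
#'   vector.
#' @return The same values, unchanged.
#' @export
rgb_basic <- function(channels) {
  info <- as_channel_matrix(channels)
  reshape_back(info$mat, info)
}

#' Apply a channel transform: per pixel, C %*% y
#'
#' Linear in y, so tone (direction) is invariant to concentration scaling.
#' Negative components may arise from the subtractions and are preserved
#' here; clamping is a rendering concern.
#'
#' @param channels 3-channel array or length-3 vector.
#' @param t A `channel_transform`.
#' @return Transformed values, same shape as input.
#' @export
rgb_transform <- function(channels, t) {
  stopifnot(inherits(t, "channel_transform"))
  info <- as_channel_matrix(channels)
  reshape_back(info$mat %*% t(t$C), info)
}

#' Render a pre-render array to a displayable RGB image
#'
#' Negative values are clamped to 0 (they have no display meaning in a
#' true-color [0,1] window), then a multiplicative brightness constant is
#' applied — fixed, or chosen so the configured percentile of the positive
#' values maps to 1 — and the result is clipped to [0,1]. The constant
#' used is recorded in the result's provenance.
#'
#' @param pre 3-channel pre-render array (e.g. from [rgb_transform()]).
#' @param t The `channel_transform` whose brightness settings to use.
#' @return An `rgb_image`: list with `data` in [0,1], `provenance`
#'   (transform matrix, brightness mode and constant applied).
#' @export
render_rgb <- function(pre, t) {
  stopifnot(inherits(t, "channel_transform"), all(is.finite(pre)))
  info <- as_channel_matrix(pre)
  m <- pmax(info$mat, 0)
  if (t$brightness_mode == "fixed_scalar") {
    const <- t$brightness_value
  } else {
    pos <- m[m > 0]
    if (!length(pos))
      stop("all-zero image: percentile brightness is degenerate",
           call. = FALSE)
    q <- stats::quantile(pos, t$brightness_value / 100, names = FALSE)
    const <- 1 / q
  }
  out <- pmin(m * const, 1)
  structure(list(data = reshape_back(out, info),
                 provenance = list(C = t$C,
                                   brightness_mode = t$brightness_mode,
                                   brightness_value = t$brightness_value,
                                   brightness_constant = const)),
            class = "rgb_image")
}

#' Color tone of a pixel vector or set of vectors
#'
#' The tone is the direction `y / ||y||` of the 3-channel vector; it
#' identifies the material independently of concentration. Two tones are
#' reported: the unit vector of the raw (pre-clamp) vector, which carries
#' the mathematical uniqueness property, and the HSV hue angle of the
#' clamped vector, which is the displayed hue.
#'
#' @param y Length-3 vector or `n x 3` matrix.
#' @return For a vector: list with `unit` (length-3), `hue_deg` (degrees,
#'   `NA` for achromatic), `norm`. For a matrix: list of per-row results.
#'   A zero vector yields `unit = c(NA, NA, NA)` (undefined tone).
#' @export
tone <- function(y) {
  if (is.matrix(y)) return(apply(y, 1L, tone, simplify = FALSE))
  stopifnot(length(y) == 3L)
  nrm <- sqrt(sum(y^2))
  if (nrm == 0)
    return(list(unit = c(NA_real_, NA_real_, NA_real_), hue_deg = NA_real_,
                norm = 0))
  cl <- pmax(y, 0)
  hue <- if (all(cl == cl[1])) NA_real_ else {
    grDevices::rgb2hsv(cl[1], cl[2], cl[3], maxColorValue = max(cl))[1] * 360
  }
  list(unit = y / nrm, hue_deg = unname(hue), norm = nrm)
}

#' Angle between two tones, in degrees
#' @param a,b Length-3 vectors (need not be normalized).
#' @return Angle in degrees; `NA` if either vector is zero.
#' @export
tone_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  cosang <- sum(a * b) / (na * nb)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Check that material signatures keep distinct tones under a transform
#'
#' Pushes each material's usable-channel signature through the transform,
#' clamps negatives (display space) and measures all pairwise tone angles.
#' Any pair closer than the threshold is flagged as a collision — the
#' diagnostic used when tuning transform weights for a new protocol or
#' agent set.
#'
#' @param signatures Named list (or `n x 3` matrix with rownames) of
#'   usable-channel attenuation signatures.
#' @param t A `channel_transform`.
#' @param threshold_deg Minimum acceptable pairwise tone angle (degrees).
#' @return List with `pairs` (data.frame: material_a, material_b,
#'   angle_deg, collision), `ok` (no collisions), `threshold_deg`.
#' @export
tone_uniqueness_check <- function(signatures, t, threshold_deg = 5) {
  if (is.matrix(signatures))
    signatures <- stats::setNames(
      lapply(seq_len(nrow(signatures)), function(i) signatures[i, ]),
      rownames(signatures))
  if (length(signatures) < 2L)
    stop("need at least two signatures", call. = FALSE)
  nm <- names(signatures)
  if (is.null(nm)) nm <- paste0("material", seq_along(signatures))
  transformed <- lapply(signatures, function(s)
    pmax(drop(rgb_transform(as.numeric(s), t)), 0))
  combos <- utils::combn(seq_along(transformed), 2L)
  pairs <- data.frame(
    material_a = nm[combos[1, ]],
    material_b = nm[combos[2, ]],
    angle_deg = apply(combos, 2L, function(ij)
      tone_angle(transformed[[ij[1]]], transformed[[ij[2]]]))
  )
  pairs$collision <- is.na(pairs$angle_deg) | pairs$angle_deg < threshold_deg
  list(pairs = pairs, ok = !any(pairs$collision),
       threshold_deg = threshold_deg)
}

#' Write a rendered RGB image to PNG
#'
#' The slice array is `[u, v, channel]` with u the horizontal display
#' axis; PNG rows run top to bottom, so the array is transposed (and the
#' vertical axis reversed) for display.
#'
#' @param img An `rgb_image` with 2-D spatial data.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_rgb_png <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- img$data
  if (length(dim(a)) != 3L)
    stop("only 2-D slices can be written to PNG", call. = FALSE)
  png::writePNG(aperm(a, c(2L, 1L, 3L))[rev(seq_len(dim(a)[2])), , ,
                                        drop = FALSE], path)
  invisible(path)
}
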