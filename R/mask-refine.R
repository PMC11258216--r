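# Refinement of slicewise manual tumor annotations.
#
# Manual outlines drawn slice by slice are smooth in the annotation view
# but zigzag in the orthogonal views. The raw binary mask is treated as a
# real-valued indicator field and convolved with an anisotropic Gaussian
# whose through-plane sigma exceeds the in-plane sigma, so adjacent slices
# vote on each voxel; thresholding the vote (0.5 = majority) yields the
# refined mask. No morphological operators are involved.

#' Parameters for annotation-mask refinement
#'
#' @param sigma_inplane Gaussian sigma (voxels) in the two annotation-plane
#'   directions. `0` disables smoothing along those axes.
#' @param sigma_through Sigma (voxels) across slices, the direction in
#'   which adjacent-slice voting acts; normally >= `sigma_inplane`.
#' @param threshold Vote threshold in (0, 1); 0.5 implements majority
#'   voting.
#' @param annotation_plane Plane in which the outlines were drawn:
#'   `"axial"` (through axis z) or `"coronal"` (through axis y).
#' @return An object of class `mask_refine_params`.
#' @export
mask_refine_params <- function(sigma_inplane = 0.7, sigma_through = 2,
                               threshold = 0.5,
                               annotation_plane = c("axial", "coronal")) {
  stopifnot(sigma_inplane >= 0, sigma_through >= 0,
            threshold > 0, threshold < 1)
  structure(list(sigma_inplane = sigma_inplane,
                 sigma_through = sigma_through, threshold = threshold,
                 annotation_plane = match.arg(annotation_plane)),
            class = "mask_refine_params")
}

# unit-sum 1-D Gaussian kernel truncated at 3 sigma; sigma = 0 -> identity
gauss_kernel <- function(sigma) {
  if (sigma == 0) return(1)
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w / sum(w)
}

# 1-D convolution of a 3-D array along one axis, zero padding at the ends
convolve_axis <- function(a, w, axis) {
  if (length(w) == 1L) return(a * w)
  d <- dim(a)
  n <- d[axis]
  r <- (length(w) - 1L) / 2L
  out <- array(0, dim = d)
  full <- lapply(d, seq_len)
  for (j in seq_along(w)) {
    off <- j - r - 1L
    dest <- max(1L, 1L - off):min(n, n - off)
    if (!length(dest) || dest[1] > dest[length(dest)]) next
    src <- dest + off
    di <- full; di[[axis]] <- dest
    si <- full; si[[axis]] <- src
    out <- do.call(`[<-`, c(list(out), di, list(
      do.call(`[`, c(list(out), di, list(drop = FALSE))) +
        w[j] * do.call(`[`, c(list(a), si, list(drop = FALSE))))))
  }
  out
}

# separable anisotropic Gaussian smoothing of a 3-D field
smooth_anisotropic <- function(field, sigmas) {
  for (axis in 1:3)
    field <- convolve_axis(field, gauss_kernel(sigmas[axis]), axis)
  field
}

#' Refine a slicewise-annotated binary mask
#'
#' Convolves the mask's indicator field with the anisotropic Gaussian of
#' `p` and keeps voxels whose smoothed vote reaches `p$threshold`. With
#' all sigmas 0 the mask is returned unchanged.
#'
#' @param raw Non-empty 3-D binary mask.
#' @param p A `mask_refine_params`.
#' @return 3-D logical mask on the same grid.
#' @export
refine_mask <- function(raw, p = mask_refine_params()) {
  stopifnot(inherits(p, "mask_refine_params"), length(dim(raw)) == 3L)
  if (!any(raw != 0)) stop("raw mask is empty", call. = FALSE)
  sigmas <- switch(p$annotation_plane,
    axial   = c(p$sigma_inplane, p$sigma_inplane, p$sigma_through),
    coronal = c(p$sigma_inplane, p$sigma_through, p$sigma_inplane))
  field <- smooth_anisotropic(array(as.numeric(raw != 0), dim = dim(raw)),
                              sigmas)
  array(field >= p$threshold, dim = dim(raw))
}

#' Mean per-slice perimeter-to-area ratio of a mask in a view
#'
#' Quantifies boundary roughness: within each non-empty slice of the given
#' plane, the perimeter is the count of exposed 4-neighbor voxel faces and
#' the area the voxel count; the mean ratio over slices is returned.
#' Zigzag annotation artifacts raise the ratio in views orthogonal to the
#' annotation plane, and refinement should lower it there.
#'
#' @param mask Non-empty 3-D binary mask.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return Mean perimeter/area over non-empty slices.
#' @export
boundary_roughness <- function(mask,
                               plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  stopifnot(length(dim(mask)) == 3L)
  if (!any(mask != 0)) stop("mask is empty", call. = FALSE)
  mask <- array(mask != 0, dim = dim(mask))
  axis <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
  ratios <- vapply(seq_len(dim(mask)[axis]), function(i) {
    sl <- switch(plane,
      axial = mask[, , i], coronal = mask[, i, ], sagittal = mask[i, , ])
    area <- sum(sl)
    if (area == 0) return(NA_real_)
    perimeter_2d(sl) / area
  }, numeric(1))
  mean(ratios, na.rm = TRUE)
}

# exposed 4-neighbor edges of a binary 2-D slice (image border counts)
perimeter_2d <- function(sl) {
  nr <- nrow(sl); nc <- ncol(sl)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sl
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) +
    sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) +
    sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

#' Rasterize per-slice polygon annotations to a 3-D mask
#'
#' Input dialect for polygon outlines (e.g. exported from LabelMe-style
#' annotation tools): each element gives a slice index and an `n x 2`
#' matrix of polygon vertices in 1-based in-plane pixel coordinates of the
#' stored array (no display flip). Voxel centers inside the polygon
#' (even-odd rule) are set.
#'
#' @param annotations List of `list(slice =, points =)` elements.
#' @param grid Integer spatial dimensions of the target mask.
#' @param plane Annotation plane: `"axial"` (points are (x, y)) or
#'   `"coronal"` (points are (x, z)).
#' @return 3-D logical mask.
#' @export
rasterize_annotations <- function(annotations, grid,
                                  plane = c("axial", "coronal")) {
  plane <- match.arg(plane)
  grid <- as.integer(grid)
  mask <- array(FALSE, dim = grid)
  dims <- if (plane == "axial") grid[1:2] else grid[c(1, 3)]
  for (ann in annotations) {
    i <- ann$slice
    pts <- as.matrix(ann$points)
    pg <- expand.grid(u = seq_len(dims[1]), v = seq_len(dims[2]))
    inside <- point_in_polygon(pg$u, pg$v, pts[, 1], pts[, 2])
    sl <- matrix(inside, dims[1], dims[2])
    if (plane == "axial") mask[, , i] <- mask[, , i] | sl
    else mask[, i, ] <- mask[, i, ] | sl
  }
  mask
}

# even-odd ray-crossing test, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read polygon annotations from a LabelMe-style JSON file
#'
#' Expects the common layout `{"shapes": [{"label": ..., "points":
#' [[u, v], ...]}, ...]}` plus a `"slice"` field per shape (or a single
#' top-level `"slice"`).
#'
#' @param path JSON file path.
#' @return List of `list(label =, slice =, points =)` suitable for
#'   [rasterize_annotations()].
#' @export
read_labelme_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$shapes)) stop("no 'shapes' key in ", path, call. = FALSE)
  shapes <- js$shapes
  default_slice <- js$slice
  if (is.data.frame(shapes)) {
    shapes <- lapply(seq_len(nrow(shapes)), function(i)
      list(label = shapes$label[i],
           slice = if (!is.null(shapes$slice)) shapes$slice[i],
           points = shapes$points[[i]]))
  }
  lapply(shapes, function(s) {
    slice <- if (!is.null(s$slice)) s$slice else default_slice
    if (is.null(slice))
      stop("annotation shape lacks a slice index", call. = FALSE)
    list(label = s$label, slice = as.integer(slice),
         points = matrix(as.numeric(unlist(s$points)), ncol = 2L,
                         byrow = !is.matrix(s$points)))
  })
}
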