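# Core domain types and I/O for multi-energy-bin (spectral) micro-CT volumes.
#
# A SpectralVolume is a 4-D array [x, y, z, bin] of linear attenuation
# coefficients (cm^-1) plus an energy binning and physical metadata. All
# downstream stages (colorization, ROI metrics, discrimination) consume it.

#' Energy binning of a photon-counting acquisition
#'
#' Describes the contiguous energy bins of a photon-counting detector. With
#' `open_top = TRUE` the last edge opens an unbounded top bin, so `n` edges
#' define `n` bins; otherwise `n` edges define `n - 1` bins.
#'
#' @param edges_keV Strictly increasing positive bin boundaries in keV.
#' @param open_top Logical; is the last bin unbounded above?
#' @param usable Logical vector, one per bin, flagging the bins used as
#'   analysis channels. The default five-bin protocol
#'   (7,20), (20,30), (30,47), (47,73), >73 keV marks bins 2-4 usable:
#'   the lowest bin is degraded by fluorescence escape and the open top bin
#'   by quantum noise.
#' @return An object of class `energy_binning`.
#' @export
energy_binning <- function(edges_keV, open_top = TRUE, usable = NULL) {
  edges_keV <- as.numeric(edges_keV)
  if (length(edges_keV) < 2L)
    stop("at least two bin edges are required", call. = FALSE)
  if (any(edges_keV <= 0) || any(diff(edges_keV) <= 0))
    stop("bin edges must be positive and strictly increasing", call. = FALSE)
  n_bins <- if (open_top) length(edges_keV) else length(edges_keV) - 1L
  if (is.null(usable)) usable <- rep(TRUE, n_bins)
  usable <- as.logical(usable)
  if (length(usable) != n_bins)
    stop("`usable` must have one flag per bin (", n_bins, ")", call. = FALSE)
  structure(
    list(edges_keV = edges_keV, open_top = isTRUE(open_top), usable = usable),
    class = "energy_binning"
  )
}

#' @export
print.energy_binning <- function(x, ...) {
  lo <- x$edges_keV[seq_len(n_bins(x))]
  hi <- c(x$edges_keV[-1], if (x$open_top) Inf)
  cat("<energy_binning> ", n_bins(x), " bins (keV):\n", sep = "")
  for (i in seq_along(lo))
    cat(sprintf("  bin %d: (%g, %s)%s\n", i, lo[i],
                if (is.finite(hi[i])) format(hi[i]) else "Inf",
                if (x$usable[i]) "  [usable]" else ""))
  invisible(x)
}

#' Number of bins of an energy binning
#' @param binning An `energy_binning`.
#' @return Integer bin count.
#' @export
n_bins <- function(binning) {
  stopifnot(inherits(binning, "energy_binning"))
  length(binning$edges_keV) - if (binning$open_top) 0L else 1L
}

#' Lower/upper interval of one energy bin
#'
#' The open top bin is capped at `cap_keV` (the tube potential by default)
#' for any numerical work that needs a finite interval.
#'
#' @param binning An `energy_binning`.
#' @param bin Bin index.
#' @param cap_keV Finite substitute for the open upper edge, in keV.
#' @return Numeric `c(lo, hi)` in keV.
#' @export
bin_interval <- function(binning, bin, cap_keV = 80) {
  nb <- n_bins(binning)
  if (bin < 1L || bin > nb) stop("bin index out of range", call. = FALSE)
  lo <- binning$edges_keV[bin]
  hi <- if (bin < length(binning$edges_keV)) binning$edges_keV[bin + 1L] else cap_keV
  if (hi <= lo) stop("cap_keV must exceed the last finite edge", call. = FALSE)
  c(lo, hi)
}

#' Default five-bin acquisition protocol
#'
#' Energy bins (7,20), (20,30), (30,47), (47,73) and >73 keV, with bins 2-4
#' flagged usable. Both contrast-agent K-edges (iodine ~33 keV, barium
#' ~37 keV) fall inside the third bin, which is what makes the usable
#' triplet spectrally informative.
#'
#' @return An `energy_binning` with 5 bins, bins 2-4 usable.
#' @export
default_binning <- function() {
  energy_binning(c(7, 20, 30, 47, 73), open_top = TRUE,
                 usable = c(FALSE, TRUE, TRUE, TRUE, FALSE))
}

#' Spectral micro-CT volume
#'
#' @param data 4-D numeric array `[x, y, z, bin]` of linear attenuation
#'   coefficients in cm^-1. Negative values are preserved: reconstruction
#'   noise legitimately undershoots zero and statistics must see it.
#' @param binning An `energy_binning` whose bin count matches `dim(data)[4]`.
#' @param voxel_size_um Isotropic voxel pitch in micrometres.
#' @param orientation Display convention; `"mouse_prone_display"` means the
#'   animal lies prone and its left side is displayed on the right of the
#'   image (the flip is applied at slice extraction, never to stored data).
#' @return An object of class `spectral_volume`.
#' @export
spectral_volume <- function(data, binning, voxel_size_um = 90,
                            orientation = "mouse_prone_display") {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-D array [x, y, z, bin]", call. = FALSE)
  if (!inherits(binning, "energy_binning"))
    stop("`binning` must be an energy_binning", call. = FALSE)
  if (dim(data)[4] != n_bins(binning))
    stop("bin count mismatch: data has ", dim(data)[4], " bins, binning has ",
         n_bins(binning), call. = FALSE)
  if (!all(is.finite(data)))
    stop("attenuation values must be finite", call. = FALSE)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (!isTRUE(voxel_size_um > 0))
    stop("voxel_size_um must be positive", call. = FALSE)
  orientation <- match.arg(orientation, "mouse_prone_display")
  structure(
    list(data = data, binning = binning, voxel_size_um = voxel_size_um,
         orientation = orientation),
    class = "spectral_volume"
  )
}

#' @export
print.spectral_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_volume> %d x %d x %d voxels, %d bins, %g um voxels\n",
              d[1], d[2], d[3], d[4], x$voxel_size_um))
  cat(sprintf("  LAC range: [%.4g, %.4g] cm^-1; usable bins: %s\n",
              min(x$data), max(x$data),
              paste(which(x$binning$usable), collapse = ",")))
  invisible(x)
}

#' @export
dim.spectral_volume <- function(x) dim(x$data)

spatial_dim <- function(v) dim(v$data)[1:3]

# ---- sidecar + NIfTI I/O -------------------------------------------------

sidecar_from_volume <- function(v) {
  list(edges_keV = v$binning$edges_keV,
       open_top = v$binning$open_top,
       usable = v$binning$usable,
       voxel_size_um = v$voxel_size_um,
       orientation = v$orientation)
}

binning_from_sidecar <- function(sc, sidecar_path) {
  required <- c("edges_keV", "open_top", "usable", "voxel_size_um", "orientation")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop("sidecar ", sidecar_path, " is missing keys: ",
         paste(missing, collapse = ", "), call. = FALSE)
  energy_binning(unlist(sc$edges_keV), isTRUE(sc$open_top), unlist(sc$usable))
}

#' Write a spectral volume as NIfTI plus a JSON sidecar
#'
#' The canonical layout is a single 4-D NIfTI with bin as the 4th dimension;
#' the sidecar carries the bin edges, usable flags, voxel size and display
#' orientation that NIfTI-1 cannot.
#'
#' @param v A `spectral_volume`.
#' @param path Output NIfTI path (`.nii`).
#' @param sidecar Output JSON path; defaults to `path` with `.json` extension.
#' @return Invisibly, `path`.
#' @export
write_spectral_volume <- function(v, path, sidecar = NULL) {
  stopifnot(inherits(v, "spectral_volume"))
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  vs_mm <- v$voxel_size_um / 1000
  img <- RNifti::asNifti(v$data, pixdim = c(vs_mm, vs_mm, vs_mm, 1),
                         datatype = "double")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(sidecar_from_volume(v), sidecar,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral volume from NIfTI plus a JSON sidecar
#'
#' Accepts either a single 4-D NIfTI file or a directory of per-bin 3-D
#' NIfTI files (sorted by file name, one file per bin in ascending energy
#' order). The bin count is cross-checked against the sidecar.
#'
#' @param path A 4-D NIfTI file, or a directory of per-bin 3-D NIfTI files.
#' @param sidecar JSON sidecar path; defaults to `path` with `.json`
#'   extension (required when `path` is a directory).
#' @return A validated `spectral_volume`.
#' @export
read_spectral_volume <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (dir.exists(path) || identical(sidecar, path))
      stop("`sidecar` must be given explicitly for directory input",
           call. = FALSE)
  }
  if (!file.exists(sidecar))
    stop("sidecar not found: ", sidecar, call. = FALSE)
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  binning <- binning_from_sidecar(sc, sidecar)

  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) != n_bins(binning))
      stop("found ", length(files), " per-bin files but sidecar declares ",
           n_bins(binning), " bins", call. = FALSE)
    bins <- lapply(files, function(f) {
      a <- as.array(RNifti::readNifti(f))
      if (length(dim(a)) != 3L)
        stop("per-bin file is not 3-D: ", f, call. = FALSE)
      a
    })
    data <- array(unlist(bins, use.names = FALSE),
                  dim = c(dim(bins[[1]]), length(bins)))
  } else {
    data <- as.array(RNifti::readNifti(path))
    if (length(dim(data)) != 4L)
      stop("expected a 4-D NIfTI volume: ", path, call. = FALSE)
    if (dim(data)[4] != n_bins(binning))
      stop("bin count mismatch: volume has ", dim(data)[4],
           " bins, sidecar declares ", n_bins(binning), call. = FALSE)
  }
  spectral_volume(data, binning, voxel_size_um = sc$voxel_size_um,
                  orientation = sc$orientation)
}

#' Write / read a 3-D binary mask as NIfTI
#' @param mask 3-D logical (or 0/1) array.
#' @param path NIfTI path.
#' @return `write_mask` invisibly returns `path`; `read_mask` returns a 3-D
#'   logical array.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = dim(mask)),
                                     datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3L) stop("mask is not 3-D: ", path, call. = FALSE)
  array(a != 0, dim = dim(a))
}

# ---- ROI sets ------------------------------------------------------------

#' Named set of 3-D binary ROI masks on a volume's grid
#'
#' @param masks Named list of 3-D logical arrays, all on the same grid.
#' @param labels Named character vector mapping mask names to roles,
#'   `"tumor"` or `"background_muscle"`. At least one background-muscle
#'   mask is required for CNR computation downstream.
#' @param geometry Integer spatial dimensions the masks must match; taken
#'   from the first mask when `NULL`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, labels, geometry = NULL) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("masks must be a named list", call. = FALSE)
  if (is.null(geometry)) geometry <- dim(masks[[1]])
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), as.integer(geometry)) &&
        !identical(as.integer(dim(masks[[nm]])), as.integer(geometry)))
      stop("mask '", nm, "' does not match the volume grid", call. = FALSE)
    masks[[nm]] <- array(masks[[nm]] != 0, dim = dim(masks[[nm]]))
  }
  labels <- vapply(labels, match.arg,
                   character(1), c("tumor", "background_muscle"))
  if (!setequal(names(labels), names(masks)))
    stop("labels must name exactly the masks", call. = FALSE)
  structure(list(masks = masks, labels = labels,
                 geometry = as.integer(geometry)),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> on grid", paste(x$geometry, collapse = " x "), "\n")
  for (nm in names(x$masks))
    cat(sprintf("  %s [%s]: %d voxels\n", nm, x$labels[[nm]],
                sum(x$masks[[nm]])))
  invisible(x)
}

#' Masks of a given role from an ROI set
#' @param rois An `roi_set`.
#' @param role `"tumor"` or `"background_muscle"`.
#' @return Named list of masks.
#' @export
roi_masks <- function(rois, role = c("tumor", "background_muscle")) {
  role <- match.arg(role)
  rois$masks[names(rois$labels)[rois$labels == role]]
}

# ---- slice extraction ----------------------------------------------------

#' Extract a display-oriented 2-D slice across all bins
#'
#' Returns the multi-channel slice at `index` in the requested plane with
#' the prone-mouse display convention applied: the animal's left appears on
#' the right of the image, realized as a flip of the first in-plane axis for
#' axial and coronal views. Stored data are never flipped; the convention
#' lives only here.
#'
#' @param v A `spectral_volume`.
#' @param plane `"axial"` (fixed z), `"coronal"` (fixed y) or `"sagittal"`
#'   (fixed x).
#' @param index 1-based slice index within the plane's extent.
#' @param flip Apply the left-right display flip (default `TRUE`).
#' @return 3-D array `[u, v, bin]`.
#' @export
extract_slice <- function(v, plane = c("axial", "coronal", "sagittal"),
                          index, flip = TRUE) {
  stopifnot(inherits(v, "spectral_volume"))
  plane <- match.arg(plane)
  d <- dim(v$data)
  extent <- switch(plane, axial = d[3], coronal = d[2], sagittal = d[1])
  if (index < 1L || index > extent)
    stop("slice index ", index, " out of range 1..", extent, call. = FALSE)
  sl <- switch(plane,
    axial    = v$data[, , index, , drop = FALSE],
    coronal  = v$data[, index, , , drop = FALSE],
    sagittal = v$data[index, , , , drop = FALSE])
  # drop the fixed spatial axis, keep [u, v, bin]
  dim(sl) <- switch(plane,
    axial    = c(d[1], d[2], d[4]),
    coronal  = c(d[1], d[3], d[4]),
    sagittal = c(d[2], d[3], d[4]))
  if (flip && plane %in% c("axial", "coronal"))
    sl <- sl[rev(seq_len(dim(sl)[1])), , , drop = FALSE]
  sl
}

#' Project a volume onto its usable analysis channels
#'
#' Pure selection of the usable bins (no values altered), in ascending
#' energy order; under the default protocol these are bins 2-4, the
#' channels (I1, I2, I3) every analysis stage works with.
#'
#' @param v A `spectral_volume`.
#' @return 4-D array `[x, y, z, 3]`.
#' @export
usable_channels <- function(v) {
  stopifnot(inherits(v, "spectral_volume"))
  idx <- which(v$binning$usable)
  if (length(idx) != 3L)
    stop("exactly 3 usable bins are required, found ", length(idx),
         call. = FALSE)
  v$data[, , , idx, drop = FALSE]
}
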