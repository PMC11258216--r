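# ROI-based image-quality and enhancement metrics.
#
# CNR = (mean_signal - mean_background) / sd_background and
# SNR = mean_background / sd_background, computed per usable channel over
# named ROI masks, plus a right-tailed Wilcoxon rank-sum test of the
# tumor-vs-muscle median difference. Sample (n-1) standard deviations are
# used throughout and recorded in the output.

# usable-channel values inside a mask, as an n_voxel x 3 matrix
roi_values <- function(v, mask) {
  stopifnot(inherits(v, "spectral_volume"))
  if (!identical(as.integer(dim(mask)), as.integer(spatial_dim(v))))
    stop("mask does not match the volume grid", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  ch <- usable_channels(v)
  vapply(seq_len(3L), function(c) ch[, , , c][mask],
         numeric(sum(mask != 0)))
}

#' Per-channel first-order statistics of an ROI
#'
#' @param v A `spectral_volume`.
#' @param mask Non-empty 3-D mask on the volume's grid.
#' @param name ROI name recorded in the result.
#' @return An `roi_stats` data.frame: one row per usable channel with
#'   `mean`, `sd` (sample), `median`, `q1`, `q3`, `n_voxels` in cm^-1.
#' @export
roi_stats <- function(v, mask, name = "roi") {
  vals <- roi_values(v, mask)
  out <- data.frame(
    roi = name,
    channel = seq_len(3L),
    mean = colMeans(vals),
    sd = apply(vals, 2L, stats::sd),
    median = apply(vals, 2L, stats::median),
    q1 = apply(vals, 2L, stats::quantile, 0.25, names = FALSE),
    q3 = apply(vals, 2L, stats::quantile, 0.75, names = FALSE),
    n_voxels = nrow(vals)
  )
  class(out) <- c("roi_stats", "data.frame")
  out
}

#' Contrast-to-noise ratio per usable channel
#'
#' The difference in mean attenuation between the signal (tumor) ROI and
#' the background (muscle) ROI, normalized by the background standard
#' deviation. The sign is preserved: a tumor darker than background gives
#' a negative CNR.
#'
#' @param v A `spectral_volume`.
#' @param signal,background Non-empty 3-D masks on the volume's grid.
#' @return Numeric length-3 vector of per-channel CNR.
#' @export
cnr <- function(v, signal, background) {
  sv <- roi_values(v, signal)
  bv <- roi_values(v, background)
  sd_b <- apply(bv, 2L, stats::sd)
  if (any(sd_b == 0))
    stop("background ROI has zero standard deviation", call. = FALSE)
  (colMeans(sv) - colMeans(bv)) / sd_b
}

#' Signal-to-noise ratio of a background ROI per usable channel
#'
#' Mean over standard deviation of the background (muscle) ROI — the
#' image-quality figure of merit of the scan.
#'
#' @param v A `spectral_volume`.
#' @param background Non-empty 3-D mask.
#' @return Numeric length-3 vector of per-channel SNR.
#' @export
snr <- function(v, background) {
  bv <- roi_values(v, background)
  sd_b <- apply(bv, 2L, stats::sd)
  if (any(sd_b == 0))
    stop("background ROI has zero standard deviation", call. = FALSE)
  colMeans(bv) / sd_b
}

#' Right-tailed Wilcoxon rank-sum test
#'
#' Tests whether the first sample (tumor ROI values) is stochastically
#' greater than the second (muscle), i.e. a right-tailed test on the
#' median difference. Ties receive midranks. When the smaller sample has
#' at most `exact_cutoff` observations (and the enumeration is tractable)
#' the permutation distribution of the rank sum is enumerated exactly;
#' otherwise the normal approximation with tie and continuity corrections
#' is used.
#'
#' @param tumor_values,muscle_values Non-empty numeric samples.
#' @param exact_cutoff Exact enumeration when `min(n, m)` is at most this.
#' @param max_enum Cap on `choose(n + m, min(n, m))` for enumeration.
#' @return A `ranksum_test` list: `statistic` (rank sum of the first
#'   sample), `p_value` (right tail), `method` (`"exact"` or
#'   `"normal_approx"`), `n`, `m`.
#' @export
ranksum_right <- function(tumor_values, muscle_values, exact_cutoff = 10,
                          max_enum = 2e5) {
  x <- as.numeric(tumor_values); y <- as.numeric(muscle_values)
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("samples must be non-empty", call. = FALSE)
  N <- n + m
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(n)])

  k <- min(n, m)
  if (k <= exact_cutoff && choose(N, k) <= max_enum) {
    # enumerate rank assignments of the smaller sample
    if (n <= m) {
      sums <- utils::combn(r, n, sum)
      p <- mean(sums >= W)
    } else {
      total <- sum(r)
      sums <- utils::combn(r, m, sum)  # candidate muscle rank sums
      p <- mean(total - sums >= W)
    }
    method <- "exact"
  } else {
    ties <- table(r)
    mu_W <- n * (N + 1) / 2
    var_W <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu_W - 0.5) / sqrt(var_W)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_approx"
  }
  structure(list(statistic = W, p_value = p, method = method, n = n, m = m),
            class = "ranksum_test")
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat(sprintf(
    "Right-tailed Wilcoxon rank-sum test (%s)\n  W = %g, n = %d, m = %d, p = %.4g\n",
    x$method, x$statistic, x$n, x$m, x$p_value))
  invisible(x)
}

#' Full ROI metric report for a volume and its ROI set
#'
#' Convenience wrapper computing per-ROI statistics, CNR of every tumor
#' ROI against the (first) muscle background, SNR of the background, and
#' the right-tailed rank-sum test per tumor and channel.
#'
#' @param v A `spectral_volume`.
#' @param rois An `roi_set` with at least one `background_muscle` mask.
#' @param alpha Significance threshold recorded with the rank-sum results
#'   (default 0.01).
#' @return List with `stats` (stacked `roi_stats`), `snr`, `cnr` (matrix
#'   tumor x channel), `ranksum` (data.frame tumor, channel, W, p_value,
#'   significant), `sd_type = "sample"`.
#' @export
roi_metrics <- function(v, rois, alpha = 0.01) {
  stopifnot(inherits(rois, "roi_set"))
  bg <- roi_masks(rois, "background_muscle")
  if (!length(bg))
    stop("a background_muscle ROI is required", call. = FALSE)
  tumors <- roi_masks(rois, "tumor")
  stats_all <- do.call(rbind, lapply(names(rois$masks), function(nm)
    roi_stats(v, rois$masks[[nm]], nm)))
  cnr_mat <- NULL
  rs <- NULL
  if (length(tumors)) {
    cnr_mat <- t(vapply(tumors, function(mk) cnr(v, mk, bg[[1]]),
                        numeric(3)))
    colnames(cnr_mat) <- paste0("channel", 1:3)
    bvals <- roi_values(v, bg[[1]])
    rs <- do.call(rbind, lapply(names(tumors), function(nm) {
      tvals <- roi_values(v, tumors[[nm]])
      do.call(rbind, lapply(1:3, function(c) {
        res <- ranksum_right(tvals[, c], bvals[, c])
        data.frame(tumor = nm, channel = c, W = res$statistic,
                   p_value = res$p_value,
                   significant = res$p_value < alpha)
      }))
    }))
  }
  list(stats = stats_all, snr = snr(v, bg[[1]]), cnr = cnr_mat,
       ranksum = rs, alpha = alpha, sd_type = "sample")
}
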