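# Tumor discrimination from first-order attenuation statistics.
#
# Per tumor and channel, the mean attenuation reflects the average amount
# of contrast medium (perfusion) and the standard deviation its spatial
# heterogeneity (for a vessel-confined agent, richer vasculature means a
# larger std). With both tumor models implanted in each animal, paired
# differences cancel per-animal effects; normality of the differences is
# screened with a one-sample Kolmogorov-Smirnov test and the paired
# t-test decides significance.

#' First-order features of one tumor
#'
#' @param v A `spectral_volume`.
#' @param tumor_mask Non-empty 3-D mask.
#' @param tumor Tumor identifier.
#' @param mouse Mouse identifier.
#' @param model Tumor model label.
#' @return A `tumor_features` data.frame: one row per usable channel with
#'   `mean` and sample `std` (cm^-1) over the full tumor mask.
#' @export
tumor_features <- function(v, tumor_mask, tumor = "tumor", mouse = NA,
                           model = NA_character_) {
  vals <- roi_values(v, tumor_mask)
  out <- data.frame(tumor = tumor, mouse = mouse, model = model,
                    channel = seq_len(3L), mean = colMeans(vals),
                    std = apply(vals, 2L, stats::sd))
  class(out) <- c("tumor_features", "data.frame")
  out
}

#' Features of every tumor in a simulated cohort
#'
#' @param cohort Result of [build_cohort()].
#' @param models Named character vector mapping tumor mask names to model
#'   labels; defaults to `tumor_left` = "A", `tumor_right` = "B" (the
#'   [build_cohort()] convention).
#' @return Stacked `tumor_features` for all mice and tumors.
#' @export
cohort_features <- function(cohort,
                            models = c(tumor_left = "A", tumor_right = "B")) {
  out <- do.call(rbind, lapply(cohort, function(ph) {
    do.call(rbind, lapply(names(models), function(nm)
      tumor_features(ph$volume, ph$rois$masks[[nm]], tumor = nm,
                     mouse = ph$mouse, model = models[[nm]])))
  }))
  class(out) <- c("tumor_features", "data.frame")
  out
}

# survival function of the Kolmogorov distribution, both series branches
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  if (lambda < 1) {
    # theta-function form, fast for small lambda
    k <- 1:20
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
    return(min(max(1 - sqrt(2 * pi) / lambda * s, 0), 1))
  }
  k <- 1:100
  min(max(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2)), 0), 1)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Standardizes the data (subtract the sample mean, divide by the sample
#' standard deviation) and computes the sup distance between the empirical
#' CDF and the standard normal CDF over the order statistics,
#' `max_i max(i/n - Phi(z_(i)), Phi(z_(i)) - (i-1)/n)`, with the p-value
#' from the asymptotic Kolmogorov distribution. Because the location and
#' scale are estimated from the same data this p-value is conservative;
#' `lilliefors = TRUE` applies the Lilliefors correction instead.
#'
#' @param d Numeric vector, `n >= 3`, nonzero variance.
#' @param standardize Standardize before testing (default `TRUE`; with
#'   `FALSE` the raw values are compared to N(0,1)).
#' @param lilliefors Use the Lilliefors-corrected p-value (via the
#'   `nortest` package) instead of the asymptotic one.
#' @return A `ks_test` list: `statistic`, `p_value`, `n`, `standardized`,
#'   `lilliefors`.
#' @export
ks_normality <- function(d, standardize = TRUE, lilliefors = FALSE) {
  d <- as.numeric(d)
  n <- length(d)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("zero variance: normality is degenerate", call. = FALSE)
  z <- if (standardize) (d - mean(d)) / s else d
  z <- sort(z)
  cdf <- stats::pnorm(z)
  i <- seq_len(n)
  statistic <- max(pmax(i / n - cdf, cdf - (i - 1) / n))
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("the nortest package is required for lilliefors = TRUE",
           call. = FALSE)
    p <- nortest::lillie.test(d)$p.value
  } else {
    p <- kolmogorov_sf(sqrt(n) * statistic)
  }
  structure(list(statistic = statistic, p_value = p, n = n,
                 standardized = standardize, lilliefors = lilliefors),
            class = "ks_test")
}

#' @export
print.ks_test <- function(x, ...) {
  cat(sprintf("One-sample KS normality check: D = %.4f, n = %d, p = %.4g%s\n",
              x$statistic, x$n, x$p_value,
              if (x$lilliefors) " (Lilliefors)" else ""))
  invisible(x)
}

# two-sided Student-t tail probability via the regularized incomplete beta
t_two_sided_p <- function(t, df) {
  if (t == 0) return(1)
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

#' Paired t-test on matched observations
#'
#' For paired observations `(x1_i, x2_i)` the differences
#' `D_i = x1_i - x2_i` are tested against `H0: mu_D = 0` with the
#' statistic `t = (Dbar - mu_D) / (S_D / sqrt(n)) ~ t_{n-1}`, where
#' `S_D = sqrt(sum((D_i - Dbar)^2) / (n - 1))`, and the two-sided p-value
#' `P(|t_{n-1}| > |t|)` evaluated through the regularized incomplete beta
#' function.
#'
#' @param x1,x2 Equal-length numeric vectors, `n >= 2`.
#' @param alpha Significance level (default 0.05).
#' @param mu_d Hypothesized mean difference under H0 (default 0).
#' @return A `paired_test` list: `n`, `differences`, `mean_diff`,
#'   `sd_diff`, `statistic`, `df`, `p_value`, `alpha`, `reject`.
#' @export
paired_t_test <- function(x1, x2, alpha = 0.05, mu_d = 0) {
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  if (length(x1) != length(x2))
    stop("x1 and x2 must have equal length", call. = FALSE)
  n <- length(x1)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  D <- x1 - x2
  Dbar <- mean(D)
  S_D <- sqrt(sum((D - Dbar)^2) / (n - 1))
  if (S_D == 0)
    stop("paired differences have zero variance", call. = FALSE)
  t_stat <- (Dbar - mu_d) / (S_D / sqrt(n))
  p <- t_two_sided_p(t_stat, n - 1)
  structure(list(n = n, differences = D, mean_diff = Dbar, sd_diff = S_D,
                 statistic = t_stat, df = n - 1, p_value = p,
                 alpha = alpha, reject = p < alpha),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test: t = %.4f, df = %d, p = %.4g (%s H0 at alpha = %g)\n",
    x$statistic, x$df, x$p_value,
    if (x$reject) "reject" else "cannot reject", x$alpha))
  invisible(x)
}

# ---- exact 2-D linear separability --------------------------------------

# strict linear separability of two small 2-D point sets via the
# separating axis theorem: project on all convex-hull edge normals and all
# cross-pair directions (which covers degenerate hulls)
linearly_separable_2d <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  axes <- list()
  edge_normals <- function(p) {
    if (nrow(p) < 2L) return(list())
    h <- p[grDevices::chull(p), , drop = FALSE]
    n <- nrow(h)
    lapply(seq_len(n), function(i) {
      e <- h[i %% n + 1L, ] - h[i, ]
      c(-e[2], e[1])
    })
  }
  axes <- c(edge_normals(a), edge_normals(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      axes <- c(axes, list(a[i, ] - b[j, ]))
  for (ax in axes) {
    if (all(ax == 0)) next
    pa <- a %*% ax; pb <- b %*% ax
    if (max(pa) < min(pb) || max(pb) < min(pa)) return(TRUE)
  }
  FALSE
}

#' Paired discrimination report for two tumor models
#'
#' For each usable channel, forms the per-mouse paired differences of the
#' mean and of the std features between the two models, screens them with
#' [ks_normality()], and applies [paired_t_test()]. Also decides, per
#' channel, whether the two models' `(mean, std)` scatter points are
#' strictly linearly separable (exact convex-hull separating-axis check,
#' intended for small cohorts).
#'
#' @param features Stacked `tumor_features` (e.g. [cohort_features()]);
#'   every mouse must contribute exactly one tumor of each model.
#' @param model_a,model_b Model labels; differences are model A minus
#'   model B.
#' @param alpha Significance level (default 0.05).
#' @param lilliefors Passed to [ks_normality()].
#' @return A `discrimination_report` list: `tests` (data.frame channel x
#'   feature with ks_p, t, df, p_value, reject), `separable` (per-channel
#'   logical), `features`, `n`, `alpha`, `model_a`, `model_b`.
#' @export
discrimination_report <- function(features, model_a = "A", model_b = "B",
                                  alpha = 0.05, lilliefors = FALSE) {
  f <- as.data.frame(features)
  f <- f[f$model %in% c(model_a, model_b), ]
  mice <- sort(unique(f$mouse))
  for (mo in mice) {
    sub <- f[f$mouse == mo & f$channel == 1L, ]
    if (!identical(sort(as.character(sub$model)),
                   sort(c(model_a, model_b))))
      stop("mouse ", mo, " does not contribute exactly one tumor of each ",
           "model: the design must be paired", call. = FALSE)
  }
  n <- length(mice)

  tests <- do.call(rbind, lapply(1:3, function(ch) {
    fa <- f[f$model == model_a & f$channel == ch, ]
    fb <- f[f$model == model_b & f$channel == ch, ]
    fa <- fa[match(mice, fa$mouse), ]
    fb <- fb[match(mice, fb$mouse), ]
    do.call(rbind, lapply(c("mean", "std"), function(feat) {
      ks <- ks_normality(fa[[feat]] - fb[[feat]], lilliefors = lilliefors)
      tt <- paired_t_test(fa[[feat]], fb[[feat]], alpha = alpha)
      data.frame(channel = ch, feature = feat, ks_D = ks$statistic,
                 ks_p = ks$p_value, mean_diff = tt$mean_diff,
                 sd_diff = tt$sd_diff, t = tt$statistic, df = tt$df,
                 p_value = tt$p_value, reject = tt$reject)
    }))
  }))

  separable <- vapply(1:3, function(ch) {
    fa <- f[f$model == model_a & f$channel == ch, c("mean", "std")]
    fb <- f[f$model == model_b & f$channel == ch, c("mean", "std")]
    linearly_separable_2d(fa, fb)
  }, logical(1))
  names(separable) <- paste0("channel", 1:3)

  structure(list(tests = tests, separable = separable, features = f,
                 n = n, alpha = alpha, model_a = model_a,
                 model_b = model_b),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("Paired discrimination of %s vs %s (n = %d mice)\n",
              x$model_a, x$model_b, x$n))
  print(x$tests, row.names = FALSE)
  cat("Strict (mean, std) linear separability per channel:",
      paste(ifelse(x$separable, "yes", "no"), collapse = ", "), "\n")
  invisible(x)
}
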