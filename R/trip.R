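#' Align gene profiles to their predicted replication time
#'
#' Builds Transcription-Replication Interaction Profiles: each gene's
#' 100-bin cell-angle profile is rotated so bin zero sits at the gene's
#' predicted expression minimum (`theta_c_min`, the replication-predicted
#' timing of the gene), giving the replication-relative angle
#' `theta_c_rep = (theta_c - theta_c_min) mod 360`. Profiles are divided
#' by their mean to center them but not otherwise scaled, preserving
#' amplitude differences. All-zero (non-positive mean) profiles are
#' excluded.
#'
#' @param binned_profiles Bins x genes matrix of expression profiles
#'   (typically normalized expression averaged in 100 `theta_c` bins).
#' @param predicted_profiles Bins x genes matrix of replication-only
#'   predictions on the same bin grid ([predict_replication_expression()]).
#' @param theta_grid Bin angles, degrees; defaults to bin centers.
#' @return List: `profiles` (bins x genes, aligned and mean-normalized),
#'   `theta_c_min` (degrees per gene), `excluded` (gene names).
#' @export
align_to_replication <- function(binned_profiles, predicted_profiles,
                                 theta_grid = NULL) {
  stopifnot(all(dim(binned_profiles) == dim(predicted_profiles)))
  n_bins <- nrow(binned_profiles)
  if (is.null(theta_grid)) theta_grid <- (seq_len(n_bins) - 0.5) * 360 / n_bins
  means <- colMeans(binned_profiles)
  keep <- which(means > 0)
  excluded <- colnames(binned_profiles)[setdiff(seq_along(means), keep)]
  min_bin <- apply(predicted_profiles[, keep, drop = FALSE], 2, which.min)
  aligned <- vapply(seq_along(keep), function(j) {
    prof <- binned_profiles[, keep[j]]
    shift <- min_bin[j] - 1L
    prof[((seq_len(n_bins) - 1L + shift) %% n_bins) + 1L] / means[keep[j]]
  }, numeric(n_bins))
  colnames(aligned) <- colnames(binned_profiles)[keep]
  list(profiles = aligned, theta_c_min = theta_grid[min_bin],
       excluded = excluded)
}

#' Amplitude of an aligned cell-cycle profile
#'
#' Robust peak/trough ratio (fourth-highest over fourth-lowest bin, so a
#' single outlier bin cannot dominate) and the standard deviation of the
#' mean-normalized profile.
#'
#' @param profile Numeric profile vector, or a bins x genes matrix.
#' @return Tibble with `peak_trough` (NA with a flag when the trough is
#'   non-positive) and `sd_normalized`, one row per profile.
#' @export
profile_amplitude <- function(profile) {
  m <- if (is.matrix(profile)) profile else matrix(profile, ncol = 1)
  ratio <- apply(m, 2, peak_trough_ratio)
  norm_sd <- apply(m, 2, function(p) stats::sd(p / mean(p)))
  tibble::tibble(
    gene_id = colnames(m) %||% as.character(seq_len(ncol(m))),
    peak_trough = ratio,
    sd_normalized = norm_sd,
    trough_nonpositive = is.na(ratio)
  )
}

#' Cluster aligned TRIP profiles by k-means
#'
#' Partitions genes into `k` clusters of shared replication-relative
#' dynamics using k-means (squared Euclidean distance on the
#' mean-normalized 100-bin profiles, 10 restarts, seeded).
#'
#' @param profiles Bins x genes matrix of aligned profiles
#'   ([align_to_replication()]).
#' @param k Number of clusters (default 20).
#' @param seed Integer seed.
#' @param nstart k-means restarts (default 10).
#' @return List: `labels` (named integer per gene), `centroids`
#'   (bins x k), `inertia` (total within-cluster sum of squares).
#' @export
cluster_profiles <- function(profiles, k = 20, seed = 1, nstart = 10) {
  if (k > ncol(profiles)) stop("k exceeds the number of profiles",
                               call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(t(profiles), centers = k, nstart = nstart,
                      iter.max = 100)
  list(labels = stats::setNames(km$cluster, colnames(profiles)),
       centroids = t(km$centers), inertia = km$tot.withinss)
}

#' Signed circular difference between observed and predicted gene angles
#'
#' `atan2(sin(a - b), cos(a - b))` in degrees, wrapped to `(-180, 180]`.
#' Positive values mean the observed angle is clockwise of the prediction,
#' i.e. the gene's expression wave is delayed relative to its replication
#' timing.
#'
#' @param theta_g Observed gene angles, degrees.
#' @param theta_g_pred Predicted gene angles, degrees.
#' @return Signed differences in degrees.
#' @export
angle_difference <- function(theta_g, theta_g_pred) {
  wrap_signed_deg(theta_g - theta_g_pred)
}

#' RNA polymerase speed from operon-position expression delays
#'
#' Within polycistronic transcription units, genes further from the start
#' site show later replication-relative expression. Converting each gene's
#' angle difference into time (angle / 360 x doubling time in seconds) and
#' regressing delay time on TSS distance gives a slope in s/bp whose
#' inverse estimates the average RNA polymerase speed in nt/s. A bootstrap
#' (resampling genes) provides the confidence interval.
#'
#' @param angle_diff Signed angle differences, degrees
#'   ([angle_difference()]); polycistronic genes only.
#' @param tss_dist TSS distances, bp ([tss_distance()]).
#' @param t_d Doubling time, minutes.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row tibble: `slope_s_per_bp`, `intercept_s`, `speed_nt_s`
#'   (NA with a warning when the slope is non-positive), bootstrap
#'   `ci_lo` / `ci_hi`, `n_genes`, `p_value` of the slope.
#' @export
rnap_speed_from_delays <- function(angle_diff, tss_dist, t_d,
                                   n_boot = 1000, seed = 1) {
  ok <- is.finite(angle_diff) & is.finite(tss_dist)
  angle_diff <- angle_diff[ok]; tss_dist <- tss_dist[ok]
  if (length(angle_diff) < 20) {
    stop("need at least 20 polycistronic genes", call. = FALSE)
  }
  delay_s <- angle_diff / 360 * t_d * 60
  fit <- stats::lm(delay_s ~ tss_dist)
  slope <- unname(stats::coef(fit)[2])
  p_val <- summary(fit)$coefficients[2, 4]
  speed <- if (slope > 0) 1 / slope else NA_real_
  if (is.na(speed)) warning("non-positive delay slope: speed undefined")
  set.seed(seed)
  n <- length(delay_s)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    s <- unname(stats::coef(stats::lm(delay_s[i] ~ tss_dist[i]))[2])
    if (is.finite(s) && s > 0) 1 / s else NA_real_
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE)
  tibble::tibble(slope_s_per_bp = slope,
                 intercept_s = unname(stats::coef(fit)[1]),
                 speed_nt_s = speed, ci_lo = ci[1], ci_hi = ci[2],
                 n_genes = n, p_value = p_val)
}
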