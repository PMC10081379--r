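#' Plot a gene-gene or bin-bin correlation map
#'
#' Heatmap of the chromosome-position correlation fingerprint; the
#' arm-symmetric "X" and its nested "multi-X" variant under overlapping
#' replication are visible as off-diagonal bands.
#'
#' @param corr Symmetric correlation matrix ([gene_correlation_map()] or
#'   [simulated_correlation_matrix()]).
#' @return A ggplot object.
#' @export
plot_correlation_map <- function(corr) {
  df <- tidyr::expand_grid(i = seq_len(nrow(corr)), j = seq_len(ncol(corr)))
  df$value <- corr[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "chromosome bin", y = "chromosome bin") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_tripcycle heatmap of binned expression over the
#'   cell angle, genes ordered by column.
#' @export
autoplot.binned_expression <- function(object, ...) {
  m <- object$values
  df <- tidyr::expand_grid(bin = seq_len(nrow(m)), gene = seq_len(ncol(m)))
  df$value <- m[cbind(df$bin, df$gene)]
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "z") +
    ggplot2::labs(x = "cell angle bin", y = "gene") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for tripcycle result objects
#'
#' @param object A fitted tripcycle object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_tripcycle
NULL

#' @describeIn autoplot_tripcycle gene angle against origin distance with
#'   the posterior-mean wrapped-linear prediction overlaid.
#' @export
autoplot.replication_fit <- function(object, ...) {
  df <- tibble::tibble(D = object$D / 1e6,
                       theta_g_pred = object$theta_g_pred)
  grid <- tibble::tibble(D = seq(0, object$D_max, length.out = 400))
  grid$theta <- predict_gene_angle(object, grid$D)
  grid$D <- grid$D / 1e6
  ggplot2::ggplot(df, ggplot2::aes(.data$D, .data$theta_g_pred)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = grid, ggplot2::aes(.data$D, .data$theta),
                        colour = "firebrick", size = 0.3) +
    ggplot2::labs(x = "origin distance (Mb)",
                  y = expression(theta[g] ~ "(predicted, deg)")) +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot_tripcycle measured length histogram with the
#'   fitted smoothed length law.
#' @export
autoplot.length_fit <- function(object, ...) {
  grid <- tibble::tibble(
    L = seq(0.5 * object$L0, 3 * object$L0, length.out = 300))
  grid$density <- length_pdf(grid$L, object$L0, object$sigma)
  ggplot2::ggplot(grid, ggplot2::aes(.data$L, .data$density)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "cell length (um)", y = "density",
                  title = sprintf("L0 = %.2f um, sigma = %.2f um",
                                  object$L0, object$sigma)) +
    ggplot2::theme_minimal()
}

#' Plot aligned TRIP cluster centroids
#'
#' @param clusters Output of [cluster_profiles()].
#' @return A ggplot object; one line per cluster centroid over the
#'   replication-relative angle.
#' @export
plot_trip_clusters <- function(clusters) {
  m <- clusters$centroids
  df <- tidyr::expand_grid(bin = seq_len(nrow(m)),
                           cluster = seq_len(ncol(m)))
  df$value <- m[cbind(df$bin, df$cluster)]
  df$theta <- (df$bin - 0.5) * 360 / nrow(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$value,
                                   group = .data$cluster)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = expression(theta["c-rep"] ~ "(deg)"),
                  y = "mean-normalized expression") +
    ggplot2::theme_minimal()
}
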