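#' Default pipeline configuration
#'
#' All thresholds default to the values used throughout the package:
#' UMI filters 15 (per cell) / 50 (per gene), HVG ratio 1.3 at log2 mean
#' > -10, `sigma_corrected` threshold 0.6, 100 angle bins, ridge alpha 10,
#' 20 k-means clusters.
#'
#' @param ... Named overrides of any default.
#' @param file Optional path to a YAML file whose keys override the
#'   defaults (explicit `...` arguments win over the file).
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    min_umi_per_cell = 15, min_gene_total = 50,
    denoise_method = "passthrough-normalize", knn_k = 10,
    smooth_window = 9,
    bin_size_bp = 50000, embed_bin_size_bp = 200000, n_theta_bins = 100,
    hvg_ratio = 1.3, hvg_min_log2_mean = -10,
    sigma_threshold = 0.6, k_clusters = 20,
    t_d = 26, seed = 0, run_divergence = TRUE, run_trip = TRUE,
    out_dir = NULL
  )
  if (!is.null(file)) cfg <- utils::modifyList(cfg, yaml::read_yaml(file))
  utils::modifyList(cfg, list(...))
}

#' Run the full cell-cycle analysis pipeline
#'
#' Orchestrates the stages end to end on a count matrix and genome model:
#' filter, library-normalize, denoise, z-score, position-bin, embed, cell
#' angle, angle-bin, gene angle, circular replication regression, ridge
#' expression model, zero-rotation, replication-only prediction,
#' divergence scoring, TRIP alignment, clustering, and (when an operon
#' table is given) the TSS-delay regression. Every stochastic stage is
#' seeded from `config$seed`; rerunning with the same inputs and seed
#' reproduces the outputs exactly.
#'
#' @param counts Sparse genes x cells UMI count matrix.
#' @param gm A `genome_model`.
#' @param config A [pipeline_config()] list.
#' @param operon_table Optional operon membership table for the delay
#'   regression ([tss_distance()]).
#' @return List of stage artifacts (`theta_c`, `theta_g`, `replication_fit`,
#'   `stats`, `expression_model`, `predicted`, `divergence`, `aligned`,
#'   `clusters`, `delay`) plus a `manifest` tibble recording each stage,
#'   its outputs and parameters. When `config$out_dir` is set, CSV
#'   artifacts and the manifest are written there.
#' @export
run_pipeline <- function(counts, gm, config = pipeline_config(),
                         operon_table = NULL) {
  manifest <- list()
  note <- function(stage, what) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, artifact = what, timestamp = format(Sys.time()))
  }
  res <- list(config = config)

  filtered <- filter_matrix(counts, config$min_umi_per_cell,
                            config$min_gene_total)
  note("filter", sprintf("%d genes x %d cells", nrow(filtered),
                         ncol(filtered)))
  gm_used <- gm[gm$gene_id %in% rownames(filtered), ]
  attributes(gm_used)[c("genome_length", "ori_position", "ter_position")] <-
    attributes(gm)[c("genome_length", "ori_position", "ter_position")]

  den <- denoise(filtered, method = config$denoise_method, k = config$knn_k)
  note("denoise", config$denoise_method)
  # embedding input: counts pooled per position bin, then normalized,
  # log-transformed and z-scored -- the low-sparsity route to the wheel
  pos_binned <- zscore_log(normalize_library(
    bin_counts_by_position(filtered, gm_used, config$embed_bin_size_bp)))
  note("position_bin", sprintf("%d bins", nrow(pos_binned)))

  emb <- embed_cells(pos_binned, seed = config$seed)
  theta_c <- cell_angle(emb)
  note("cell_angle", "theta_c per cell")

  D_all <- stats::setNames(gm_used$origin_distance, gm_used$gene_id)

  # one full model pass in a given theta_c gauge: gene angles, circular
  # replication regression, cycle-smoothed z-scores, and the ridge model
  model_pass <- function(theta_c, pass_seed) {
    binned <- bin_profiles(den, theta_c, config$n_theta_bins)
    ga <- gene_angle(binned, gm_used)
    D <- D_all[ga$gene_id]
    rf <- fit_gene_angle_regression(ga$theta_g, D, seed = pass_seed)
    # divergence scoring happens on the per-cell z scale (z-scores across
    # cells of cycle-smoothed expression, then averaged within theta_c
    # bins): residuals measure shape mismatch relative to each gene's own
    # cycle variation
    z_cells <- zscore_log(smooth_by_angle(den, theta_c, config$n_theta_bins,
                                          config$smooth_window))
    binned_z <- bin_by_cell_angle(z_cells, theta_c, config$n_theta_bins)
    grid2 <- bin_by_gene_angle(binned_z, ga$theta_g, config$n_theta_bins)
    em <- fit_cell_gene_model(grid2$values, binned_z$theta, grid2$theta_g)
    list(binned = binned, ga = ga, D = D, rf = rf, binned_z = binned_z,
         em = em)
  }

  pass1 <- model_pass(theta_c, config$seed + 1)
  note("gene_angle", sprintf("theta_g per gene (reversed = %s)",
                             attr(pass1$ga, "reversed")))
  note("replication_fit", sprintf("gamma = %.2f", pass1$rf$gamma_mean))
  note("ridge_fit", sprintf("r^2 = %.2f", pass1$em$r_squared))

  # fix the gauge so theta_c = 0 is replication initiation, then refit the
  # angle-dependent models in the rotated gauge
  rz <- rotate_zero(theta_c, pass1$em, pass1$rf,
                    theta_grid = pass1$binned_z$theta)
  theta_c <- rz$theta_c
  note("rotate_zero", sprintf("theta_0 = %.1f deg", rz$theta_0))
  pass2 <- model_pass(theta_c, config$seed + 1)
  binned <- pass2$binned
  binned_z <- pass2$binned_z
  ga <- pass2$ga
  rf <- pass2$rf
  em <- pass2$em
  D <- pass2$D
  stats_tbl <- replication_stats(rf, config$t_d)

  predicted <- predict_replication_expression(em, rf, binned_z$theta, D)
  note("predict", "replication-only 100 x genes matrix")

  res <- c(res, list(theta_c = theta_c, theta_g = ga,
                     replication_fit = rf, stats = stats_tbl,
                     expression_model = em, binned = binned,
                     binned_z = binned_z,
                     predicted = predicted, theta_0 = rz$theta_0))

  if (config$run_divergence) {
    hvg <- highly_variable_genes(filtered, theta_c,
                                 ratio_threshold = config$hvg_ratio,
                                 min_log2_mean = config$hvg_min_log2_mean)
    flags <- hvg$highly_variable[match(colnames(predicted), hvg$gene_id)]
    obs <- binned_z$values[, colnames(predicted), drop = FALSE]
    div <- divergence_score(obs, predicted, flags,
                            threshold = config$sigma_threshold)
    res$hvg <- hvg
    res$divergence <- div
    note("divergence", sprintf("%d divergent genes", sum(div$divergent)))
  } else {
    warning("divergence stage disabled: TRIP stages skipped")
    config$run_trip <- FALSE
  }

  if (config$run_trip) {
    norm_binned <- bin_by_cell_angle(
      normalize_library(filtered)[colnames(predicted), , drop = FALSE],
      theta_c, config$n_theta_bins)
    aligned <- align_to_replication(norm_binned$values, predicted,
                                    theta_grid = binned$theta)
    k <- min(config$k_clusters, ncol(aligned$profiles))
    clusters <- cluster_profiles(aligned$profiles, k = k,
                                 seed = config$seed + 2)
    res$aligned <- aligned
    res$clusters <- clusters
    note("trip", sprintf("%d aligned profiles in %d clusters",
                         ncol(aligned$profiles), k))
    if (!is.null(operon_table)) {
      td <- tss_distance(operon_table, gm_used)
      poly <- td$polycistronic & !td$flagged &
        td$gene_id %in% colnames(predicted)
      i <- match(td$gene_id[poly], ga$gene_id)
      ad <- angle_difference(
        ga$theta_g[i],
        attr(predicted, "theta_g_pred")[match(td$gene_id[poly],
                                              colnames(predicted))])
      res$delay <- rnap_speed_from_delays(ad, td$tss_distance[poly],
                                          config$t_d,
                                          seed = config$seed + 3)
      note("delay_regression",
           sprintf("speed = %.1f nt/s", res$delay$speed_nt_s))
    }
  }

  res$manifest <- dplyr::bind_rows(manifest)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(res, config$out_dir)
  }
  res
}

write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(tibble::tibble(barcode = names(res$theta_c),
                                  theta_c = res$theta_c),
                   file.path(dir, "theta_c.csv"), row.names = FALSE)
  utils::write.csv(res$theta_g, file.path(dir, "theta_g.csv"),
                   row.names = FALSE)
  utils::write.csv(res$stats, file.path(dir, "replication_stats.csv"),
                   row.names = FALSE)
  if (!is.null(res$divergence)) {
    utils::write.csv(res$divergence, file.path(dir, "divergence.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
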