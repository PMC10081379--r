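test_that("cell angle follows the clockwise-from-+y convention", {
  emb <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0), c(0, 0))
  th <- cell_angle(emb)
  expect_equal(unname(th), c(0, 90, 180, 270, 0), ignore_attr = TRUE)
  expect_equal(attr(th, "origin_cells"), 5L)
})

test_that("PCA embedding maps noiseless harmonics onto an exact circle", {
  phase <- seq(0, 2 * pi, length.out = 41)[-41]
  z <- rbind(cos(phase), sin(phase))   # two orthogonal harmonics
  colnames(z) <- paste0("c", seq_along(phase))
  emb <- embed_cells(z)
  r <- sqrt(rowSums(emb^2))
  expect_lt(diff(range(r)) / mean(r), 1e-8)
  # angles reproduce the phase ordering exactly up to rotation/reflection
  expect_equal(abs(circular_cor(cell_angle(emb), phase * 180 / pi)), 1,
               tolerance = 1e-8)
  # duplicated cell lands on identical coordinates
  z2 <- cbind(z, dup = z[, 3])
  emb2 <- embed_cells(z2)
  expect_equal(unname(emb2[ncol(z2), ]), unname(emb2[3, ]))
  expect_error(embed_cells(z[, 1:5]), "10 cells")
})

test_that("cell angles recover the true cycle ordering on synthetic counts", {
  gm <- make_test_genome(n = 300)
  # high depth: phase noise is small and ordering is nearly exact
  syn <- generate_sc_counts(gm, n_cells = 1200, depth_mean = 3000,
                            seed = 31)
  pb <- zscore_log(normalize_library(
    bin_counts_by_position(syn$counts, gm, 2e5)))
  th <- cell_angle(embed_cells(pb))
  truth <- syn$truth$cells$phase * 360
  expect_gt(abs(circular_cor(th, truth)), 0.9)
  # at the sparse depth of real data (~135 UMI/cell) the ordering is still
  # recovered far above chance, but per-cell sampling noise bounds it
  syn2 <- generate_sc_counts(gm, n_cells = 1200, depth_mean = 135,
                             seed = 32)
  pb2 <- zscore_log(normalize_library(
    bin_counts_by_position(syn2$counts, gm, 2e5)))
  th2 <- cell_angle(embed_cells(pb2))
  expect_gt(abs(circular_cor(th2, syn2$truth$cells$phase * 360)), 0.4)
})

test_that("angle binning averages cells and interpolates empty bins", {
  z <- matrix(rnorm(3 * 50), 3, 50, dimnames = list(c("a", "b", "c"), NULL))
  # all cells at one angle: a single occupied bin
  b1 <- bin_by_cell_angle(z, rep(10, 50), n_bins = 20)
  expect_equal(sum(!b1$interpolated), 1L)
  expect_equal(sum(b1$occupancy), 50)
  # uniform angles: occupancy is about n/bins everywhere
  set.seed(33)
  th <- runif(5000, 0, 360)
  b2 <- bin_by_cell_angle(matrix(rnorm(5000), 1), th, n_bins = 100)
  expect_true(all(b2$occupancy > 20 & b2$occupancy < 90))
  # bin centers are stable under re-binning of the bin means
  expect_equal(b2$theta[!b2$interpolated],
               (which(!b2$interpolated) - 0.5) * 3.6, tolerance = 0.6)
})

test_that("gene angles separate harmonic profiles by their phase", {
  th_bins <- (0:99 + 0.5) * 3.6
  rad <- th_bins * pi / 180
  # twelve genes with harmonic profiles at evenly spread phases, so the
  # per-bin centering over genes cancels
  shifts <- (0:11) * 30 * pi / 180
  vals <- sapply(shifts, function(s) cos(rad + s))
  colnames(vals) <- sprintf("p%02d", 0:11)
  binned <- structure(list(values = vals, theta = th_bins,
                           occupancy = rep(1, 100),
                           interpolated = rep(FALSE, 100), n_bins = 100L),
                      class = "binned_expression")
  ga <- gene_angle(binned)
  # cos(x) and cos(x + 90 deg) = -sin profiles sit a quarter turn apart
  d <- abs(angle_difference(ga$theta_g[ga$gene_id == "p00"],
                            ga$theta_g[ga$gene_id == "p03"]))
  expect_equal(unname(d), 90, tolerance = 1e-6)
  # all adjacent phase steps are 30 degrees
  steps <- abs(angle_difference(ga$theta_g[-1], ga$theta_g[-12]))
  expect_equal(unname(steps), rep(30, 11), tolerance = 1e-6)
  # duplicated profile gets an identical angle
  binned$values <- cbind(vals, dup = vals[, "p00"])
  ga2 <- gene_angle(binned)
  expect_equal(unname(ga2$theta_g[ga2$gene_id == "dup"]),
               unname(ga2$theta_g[ga2$gene_id == "p00"]))
  # rank-1 response: degenerate
  binned$values <- cbind(a = cos(rad), b = 2 * cos(rad))
  expect_error(gene_angle(binned), "rank")
})

test_that("gene angles track the true replication timing", {
  gm <- make_test_genome(n = 300)
  syn <- generate_sc_counts(gm, n_cells = 3000, depth_mean = 1000,
                            seed = 34)
  truth_deg <- syn$truth$cells$phase * 360
  binned <- bin_profiles(normalize_library(syn$counts), truth_deg)
  ga <- gene_angle(binned, gm)
  rp <- syn$truth$genes$rep_phase[match(ga$gene_id,
                                        syn$truth$genes$gene_id)] * 360
  expect_gt(abs(circular_cor(ga$theta_g, rp)), 0.9)
})

test_that("zero rotation lands near initiation and is self-consistent", {
  gm <- make_test_genome(n = 300)
  syn <- generate_sc_counts(gm, n_cells = 3000, depth_mean = 3000,
                            seed = 35)
  truth_deg <- syn$truth$cells$phase * 360
  binned <- bin_profiles(normalize_library(syn$counts), truth_deg)
  ga <- gene_angle(binned, gm)
  D <- stats::setNames(gm$origin_distance, gm$gene_id)[ga$gene_id]
  rf <- fit_gene_angle_regression(ga$theta_g, D, seed = 1)
  g2 <- bin_by_gene_angle(binned, ga$theta_g)
  em <- fit_cell_gene_model(g2$values, binned$theta, g2$theta_g)
  rz <- rotate_zero(truth_deg, em, rf, theta_grid = binned$theta)
  # the predicted-minimum gauge sits within a quarter turn of the true
  # initiation phase (the harmonic ridge smooths the sharp dosage step,
  # biasing the argmin; see the methods vignette)
  rel_truth <- (truth_deg - syn$truth$init_phase * 360) %% 360
  offset <- mean_circular_offset(rz$theta_c, rel_truth)
  expect_lt(abs(offset), 90)
  # rotating by theta_0 and back is the identity
  back <- (rz$theta_c + rz$theta_0) %% 360
  expect_equal(back, truth_deg %% 360, tolerance = 1e-9)
  # theta_0 does not depend on gene labeling
  perm <- sample(length(ga$theta_g))
  rf_p <- fit_gene_angle_regression(ga$theta_g[perm], D[perm], seed = 1)
  rz_p <- rotate_zero(truth_deg, em, rf_p, theta_grid = binned$theta)
  expect_equal(rz_p$theta_0, rz$theta_0, tolerance = 15)
})
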